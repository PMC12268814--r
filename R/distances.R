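#' Enumerate all candidate primer mixes
#'
#' A candidate primer mix assigns exactly one primer set to each target of
#' the panel; the candidates are the full Cartesian product of the
#' per-target options, in deterministic order with mix ids `PM1, PM2, ...`
#' (the first target's primer set varies fastest).
#'
#' @param primer_sets named list: one element per target, each a character
#'   vector of candidate primer-set ids (non-empty).
#' @return Data frame with column `mix_id` plus one column per target
#'   holding the assigned primer-set id.
#' @examples
#' enumerate_candidates(list(A = c("a1", "a2"), B = c("b1", "b2")))
#' @export
enumerate_candidates <- function(primer_sets) {
  if (!length(primer_sets) || is.null(names(primer_sets)))
    stop("primer_sets must be a named list (targets)")
  n <- vapply(primer_sets, length, integer(1))
  if (any(n == 0))
    stop("no candidate primer set for target(s): ",
         paste(names(primer_sets)[n == 0], collapse = ", "))
  grid <- expand.grid(primer_sets, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  cbind(data.frame(mix_id = sprintf("PM%d", seq_len(nrow(grid))),
                   stringsAsFactors = FALSE),
        grid)
}

#' Assemble a candidate's simulated multiplex feature dataset
#'
#' Smart in-silico multiplexing rests on the assumption that the kinetic
#' information of a primer set's singleplex curves is maintained in the
#' multiplex reaction: a candidate's simulated dataset is simply the union
#' of the singleplex feature vectors of its assigned primer sets, labelled
#' by target. No resampling or trace mixing takes place, so the result is
#' deterministic.
#'
#' @param candidate named character vector (or one-row data frame slice)
#'   mapping target to assigned primer-set id.
#' @param features data frame of singleplex features with metadata columns
#'   `target` and `primer_set` plus feature columns.
#' @return Data frame of the selected rows (all columns preserved).
#' @export
simulate_multiplex <- function(candidate, features) {
  candidate <- unlist(candidate)
  candidate <- candidate[setdiff(names(candidate), "mix_id")]
  missing <- character(0)
  rows <- lapply(names(candidate), function(tg) {
    sel <- features$target == tg & features$primer_set == candidate[[tg]]
    if (!any(sel))
      missing <<- c(missing, sprintf("%s/%s", tg, candidate[[tg]]))
    features[sel, , drop = FALSE]
  })
  if (length(missing))
    stop("no singleplex curves for target/primer set: ",
         paste(missing, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median-based distance between two target clusters
#'
#' Euclidean distance between the per-feature medians of the two clusters.
#' Fast but blind to within-cluster spread: two widely overlapping clusters
#' with distant medians still score high.
#'
#' @param a,b numeric matrices (rows are points) or vectors with matching
#'   feature dimension; features should be standardized first.
#' @return Single non-negative number.
#' @export
median_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("feature dimension mismatch")
  ma <- apply(a, 2, stats::median)
  mb <- apply(b, 2, stats::median)
  sqrt(sum((ma - mb)^2))
}

#' Clustering-based distance between two target clusters
#'
#' The mean silhouette score of the two clusters taken alone (see
#' [mean_silhouette()]): it accounts for both the inter-cluster separation
#' and the within-cluster spread, so overlapping clusters score near 0
#' regardless of how far apart their medians are. Range \[-1, 1\].
#'
#' @inheritParams median_distance
#' @return Single number in \[-1, 1\].
#' @export
clustering_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("feature dimension mismatch")
  mean_silhouette(rbind(a, b),
                  c(rep("A", nrow(a)), rep("B", nrow(b))))
}

#' Score one candidate primer mix by ADS and MDS
#'
#' Standardizes the candidate's pooled feature dataset (each candidate
#' independently), computes the chosen inter-target distance for every pair
#' of targets, and returns the Average Distance Score (mean over pairs) and
#' Minimum Distance Score (minimum over pairs). Both should be large for an
#' assay whose targets are easy to tell apart from a single channel.
#'
#' @param dataset data frame with a `target` column and the feature
#'   columns, e.g. from [simulate_multiplex()].
#' @param feature_set character vector of feature columns to use.
#' @param distance `"median"` or `"clustering"`.
#' @return A list with `ads`, `mds`, and `pairs` (data frame of per-pair
#'   distances).
#' @export
score_candidate <- function(dataset, feature_set = feature_names_selected(),
                            distance = c("median", "clustering")) {
  distance <- match.arg(distance)
  targets <- sort(unique(as.character(dataset$target)))
  if (length(targets) < 2) stop("need >= 2 targets to score a candidate")
  miss <- setdiff(feature_set, colnames(dataset))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  x <- standardize_features(dataset[, feature_set, drop = FALSE])$x
  dfun <- if (distance == "median") median_distance else clustering_distance
  prs <- utils::combn(targets, 2)
  d <- apply(prs, 2, function(pr) {
    dfun(x[dataset$target == pr[1], , drop = FALSE],
         x[dataset$target == pr[2], , drop = FALSE])
  })
  list(ads = mean(d), mds = min(d),
       pairs = data.frame(target_a = prs[1, ], target_b = prs[2, ],
                          distance = d, stringsAsFactors = FALSE))
}

#' Strategy configuration for assay scoring
#'
#' Three scoring strategies:
#' * **S1** — the single slope-coefficient feature `Sc` with median-based
#'   distances (the original single-feature approach);
#' * **S2** — the selected multi-feature vector with median-based
#'   distances;
#' * **S3** — the selected multi-feature vector with clustering-based
#'   (silhouette) distances.
#'
#' @param strategy `"S1"`, `"S2"` or `"S3"`.
#' @param feature_set features for S2/S3; S1 always uses `c("Sc")`.
#' @return A list with `strategy`, `feature_set`, `distance`.
#' @export
strategy_config <- function(strategy = c("S3", "S1", "S2"),
                            feature_set = feature_names_selected()) {
  strategy <- match.arg(strategy)
  switch(strategy,
         S1 = list(strategy = "S1", feature_set = "Sc",
                   distance = "median"),
         S2 = list(strategy = "S2", feature_set = feature_set,
                   distance = "median"),
         S3 = list(strategy = "S3", feature_set = feature_set,
                   distance = "clustering"))
}

#' Score and rank every candidate primer mix under one strategy
#'
#' Runs [simulate_multiplex()] and [score_candidate()] for each candidate,
#' then ranks with [rank_candidates()].
#'
#' @param features singleplex feature data frame (metadata columns
#'   `target`, `primer_set` plus feature columns).
#' @param candidates data frame from [enumerate_candidates()].
#' @param config list from [strategy_config()].
#' @return Data frame with `mix_id`, `strategy`, `ads`, `mds`, `rank`,
#'   ordered by rank then `mix_id`.
#' @export
score_assays <- function(features, candidates,
                         config = strategy_config("S3")) {
  targets <- setdiff(colnames(candidates), "mix_id")
  scores <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- unlist(candidates[i, targets, drop = FALSE])
    ds <- simulate_multiplex(cand, features)
    sc <- score_candidate(ds, config$feature_set, config$distance)
    data.frame(mix_id = candidates$mix_id[i], strategy = config$strategy,
               ads = sc$ads, mds = sc$mds, stringsAsFactors = FALSE)
  })
  rank_candidates(do.call(rbind, scores))
}

#' Rank scored candidates by combined ADS and MDS
#'
#' Candidates are ranked by the ascending sum of their rank by descending
#' ADS and their rank by descending MDS (average ranks on ties within each
#' column). Candidates with equal rank sums share a rank — so two mixes can
#' legitimately occupy the same place — and rows are ordered by rank and
#' then `mix_id` for a deterministic listing.
#'
#' @param scores data frame with columns `mix_id`, `ads`, `mds` and a
#'   single common `strategy`.
#' @return `scores` with a `rank` column, reordered.
#' @export
rank_candidates <- function(scores) {
  if ("strategy" %in% names(scores) &&
      length(unique(scores$strategy)) > 1)
    stop("all scores must come from one strategy")
  rs <- rank(-scores$ads, ties.method = "average") +
        rank(-scores$mds, ties.method = "average")
  scores$rank <- as.integer(rank(rs, ties.method = "min"))
  scores[order(scores$rank, scores$mix_id), , drop = FALSE]
}

#' Distance-map table for plotting
#'
#' One row per candidate with its ADS, MDS and rank, optionally joined with
#' empirically measured classification accuracies by `mix_id` — the tidy
#' form behind an ADS-vs-MDS scatter map shaded by accuracy.
#'
#' @param scores ranked scores from [rank_candidates()] / [score_assays()].
#' @param accuracy optional data frame with columns `mix_id`, `accuracy`.
#' @return Data frame `mix_id`, `strategy`, `ads`, `mds`, `rank`,
#'   `accuracy` (`NA` where unknown).
#' @export
distance_map <- function(scores, accuracy = NULL) {
  out <- scores[, c("mix_id", "strategy", "ads", "mds", "rank")]
  if (is.null(accuracy)) {
    out$accuracy <- NA_real_
  } else {
    out$accuracy <- accuracy$accuracy[match(out$mix_id, accuracy$mix_id)]
  }
  rownames(out) <- NULL
  out
}
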