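#' Concentration robustness by the Kruskal-Wallis test
#'
#' Tests whether a feature's distribution differs across template
#' concentration groups. A feature is flagged concentration-robust when the
#' Kruskal-Wallis test *fails* to reject at `alpha` (default 0.01), i.e. no
#' significant distribution shift across concentrations is detected. This
#' mirrors the screening use of the test; note the usual caveat that
#' non-significance is not equivalence.
#'
#' @param values numeric feature values.
#' @param groups concentration labels, one per value; at least two groups
#'   with at least two observations each.
#' @param alpha significance threshold; default 0.01.
#' @return A list with `statistic` (tie-corrected H), `p_value`, `df`, and
#'   `robust` (`p_value > alpha`).
#' @export
kruskal_wallis_robustness <- function(values, groups, alpha = 0.01) {
  groups <- as.factor(as.character(groups))
  if (length(values) != length(groups)) stop("length mismatch")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 concentration groups with >= 2 observations each")
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), robust = kt$p.value > alpha)
}

#' Dunn's post-hoc test for pairwise concentration differences
#'
#' Pairwise z-tests on rank means following a Kruskal-Wallis test, with tie
#' correction and a multiple-comparison adjustment (Holm step-down by
#' default). Used to localise which concentration pairs drive a
#' Kruskal-Wallis rejection.
#'
#' @inheritParams kruskal_wallis_robustness
#' @param method adjustment method passed to [stats::p.adjust()];
#'   default `"holm"`.
#' @return Symmetric matrix of adjusted p-values with unit diagonal,
#'   rows/columns named by group.
#' @export
dunn_posthoc <- function(values, groups, method = "holm") {
  groups <- as.factor(as.character(groups))
  if (length(values) != length(groups)) stop("length mismatch")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 observations each")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties)
  v0 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  g <- names(tab)
  k <- length(g)
  p <- matrix(1, k, k, dimnames = list(g, g))
  zp <- c()
  idx <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(v0 * (1 / tab[[g[i]]] + 1 / tab[[g[j]]]))
    z <- (rbar[[g[i]]] - rbar[[g[j]]]) / se
    zp <- c(zp, 2 * stats::pnorm(-abs(z)))
    idx[[length(idx) + 1]] <- c(i, j)
  }
  zp <- stats::p.adjust(zp, method = method)
  for (m in seq_along(idx)) {
    i <- idx[[m]][1]; j <- idx[[m]][2]
    p[i, j] <- p[j, i] <- zp[m]
  }
  p
}

#' Singleplex-to-multiplex consistency of a feature
#'
#' For each primer set present in both reaction conditions, builds the
#' median curve (per-cycle median fluorescence over that set's curves),
#' fits the five-parameter sigmoid, extracts the named feature, and returns
#' the Pearson correlation of the paired singleplex/multiplex values. A
#' strong linear correlation (default criterion `r >= 0.85`) means the
#' feature's inter-target distance structure survives the efficiency drop
#' of multiplexing, so distances simulated from singleplex data remain
#' predictive of the empirical multiplex.
#'
#' @param singleplex,multiplex named lists, one element per primer set,
#'   each a list of curves (`list(cycles, fluorescence)`) sharing a cycle
#'   grid within the set.
#' @param feature feature name (see [feature_names()]).
#' @param th_fraction relative first-derivative threshold for feature
#'   extraction.
#' @param r_min pass threshold on the correlation; default 0.85.
#' @return A list with `r`, `passed` (`r >= r_min`), and `pairs`, a data
#'   frame of per-primer-set paired feature values.
#' @export
singleplex_multiplex_correlation <- function(singleplex, multiplex, feature,
                                             th_fraction = 0.05,
                                             r_min = 0.85) {
  common <- intersect(names(singleplex), names(multiplex))
  dropped <- setdiff(union(names(singleplex), names(multiplex)), common)
  if (length(dropped))
    warning("primer set(s) missing in one condition, excluded: ",
            paste(dropped, collapse = ", "))
  if (length(common) < 3)
    stop("need >= 3 primer sets present in both conditions")
  fval <- function(curves) {
    med <- median_curve(curves)
    fit <- fit_sigmoid(med$cycles, med$fluorescence)
    extract_features(fit$params, th_fraction)[[feature]]
  }
  sp <- vapply(singleplex[common], fval, numeric(1))
  mp <- vapply(multiplex[common], fval, numeric(1))
  r <- stats::cor(sp, mp)
  list(r = r, passed = r >= r_min,
       pairs = data.frame(primer_set = common, singleplex = sp,
                          multiplex = mp, row.names = NULL))
}

#' Per-cycle median curve of a set of amplification curves
#'
#' @param curves list of curves sharing one cycle grid.
#' @return A list with `cycles` and `fluorescence` (per-cycle medians).
#' @export
median_curve <- function(curves) {
  if (!length(curves)) stop("empty curve set")
  grid <- curves[[1]]$cycles
  for (cv in curves)
    if (length(cv$cycles) != length(grid) || any(cv$cycles != grid))
      stop("median_curve requires a common cycle grid")
  fmat <- vapply(curves, function(cv) cv$fluorescence, numeric(length(grid)))
  list(cycles = grid,
       fluorescence = apply(as.matrix(fmat), 1, stats::median))
}

#' Per-target mean silhouette of a single feature
#'
#' Splits the per-point silhouettes of [mean_silhouette()] by true target
#' and averages within each target: a feature that separates most targets
#' well but collapses for one will show a low minimum here.
#'
#' @inheritParams feature_mss
#' @return Named numeric vector, one mean silhouette per target.
#' @export
per_target_silhouette <- function(features, labels, feature) {
  features <- as.data.frame(features)
  v <- features[[feature]]
  labels <- as.character(labels)
  ulab <- sort(unique(labels))
  x <- matrix(v, ncol = 1)
  d <- as.matrix(stats::dist(x))
  tab <- table(labels)
  md <- vapply(ulab, function(l) rowMeans(d[, labels == l, drop = FALSE]),
               numeric(length(v)))
  s <- numeric(length(v))
  for (i in seq_along(v)) {
    li <- labels[i]; ni <- tab[[li]]
    a_i <- md[i, li] * ni / (ni - 1)
    b_i <- min(md[i, setdiff(ulab, li)])
    m <- max(a_i, b_i)
    s[i] <- if (m > 0) (b_i - a_i) / m else 0
  }
  vapply(split(s, labels), mean, numeric(1))[ulab]
}

#' Screen candidate features against the three selection criteria
#'
#' Computes, for each candidate feature: its mean silhouette score across
#' targets (criterion 1, separability), Kruskal-Wallis p-values across
#' concentrations within each efficiency group (criterion 2, robustness),
#' and optionally its per-target minimum mean silhouette (consistency).
#' Singleplex-multiplex correlations (criterion 3) are computed separately
#' with [singleplex_multiplex_correlation()] since they need raw curves.
#'
#' @param features feature matrix or data frame (one row per curve).
#' @param targets target labels per row.
#' @param concentrations concentration labels per row.
#' @param efficiency optional efficiency-group labels per row (defaults to
#'   one group).
#' @param candidates feature names to screen; default all columns.
#' @return A data frame with one row per feature: `feature`, `mss`,
#'   `kw_p_min` (minimum Kruskal-Wallis p over efficiency groups),
#'   `min_target_sil`.
#' @export
screen_features <- function(features, targets, concentrations,
                            efficiency = NULL,
                            candidates = colnames(as.data.frame(features))) {
  features <- as.data.frame(features)
  if (is.null(efficiency)) efficiency <- rep("all", nrow(features))
  out <- lapply(candidates, function(f) {
    kw <- vapply(split(seq_len(nrow(features)), efficiency), function(i) {
      kruskal_wallis_robustness(features[[f]][i],
                                concentrations[i])$p_value
    }, numeric(1))
    data.frame(feature = f,
               mss = feature_mss(features, targets, f),
               kw_p_min = min(kw),
               min_target_sil = min(per_target_silhouette(features,
                                                          targets, f)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select features satisfying all three criteria
#'
#' A feature is selected iff (a) its mean silhouette score is positive and
#' at least `mss_ratio` times the median MSS of all candidates
#' (separability gate),
#' (b) its minimum Kruskal-Wallis p-value over efficiency groups exceeds
#' `alpha` (concentration-robust in every efficiency regime), (c) its
#' singleplex-multiplex Pearson correlation is at least `r_min`, and (d)
#' its per-target minimum mean silhouette is at least `min_target_sil`
#' (excludes features that fail badly for one particular target even if
#' good on average). The result is ordered by decreasing MSS.
#'
#' @param screen data frame from [screen_features()] (columns `feature`,
#'   `mss`, `kw_p_min`, and optionally `min_target_sil`).
#' @param sp_mp_r named numeric vector of singleplex-multiplex Pearson
#'   correlations per feature; features without an entry fail criterion 3
#'   unless `sp_mp_r` is `NULL` (criterion skipped, e.g. when no multiplex
#'   data exist).
#' @param mss_ratio MSS-to-median ratio gate; default 2.
#' @param alpha Kruskal-Wallis robustness threshold; default 0.01.
#' @param r_min correlation gate; default 0.85.
#' @param min_target_sil per-target consistency floor; default -0.05.
#' @return A list with `selected` (feature names by decreasing MSS) and
#'   `report` (per-feature gate flags and `passed`).
#' @export
select_features <- function(screen, sp_mp_r = NULL, mss_ratio = 2,
                            alpha = 0.01, r_min = 0.85,
                            min_target_sil = -0.05) {
  rep <- screen
  med <- stats::median(rep$mss)
  rep$mss_ok <- rep$mss > 0 & rep$mss >= mss_ratio * med
  rep$kw_ok <- rep$kw_p_min > alpha
  if (is.null(sp_mp_r)) {
    rep$r <- NA_real_
    rep$r_ok <- TRUE
  } else {
    rep$r <- unname(sp_mp_r[rep$feature])
    rep$r_ok <- !is.na(rep$r) & rep$r >= r_min
  }
  rep$consistency_ok <- if ("min_target_sil" %in% names(rep))
    rep$min_target_sil >= min_target_sil else TRUE
  rep$passed <- rep$mss_ok & rep$kw_ok & rep$r_ok & rep$consistency_ok
  sel <- rep$feature[rep$passed]
  sel <- sel[order(-rep$mss[rep$passed])]
  if (!length(sel))
    stop("no feature passed all selection gates; ",
         "consider relaxing mss_ratio, alpha, or r_min")
  list(selected = sel, report = rep)
}
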