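#' Read amplification curves from long-format CSV
#'
#' The curve file must have columns `curve_id`, `cycle`, `fluorescence`
#' (UTF-8, header row, comma-separated). The optional metadata file is
#' keyed by `curve_id` with columns `target`, `primer_set`,
#' `concentration`, `panel_id`, `reaction_type`; curves without a metadata
#' row are kept with `NA` metadata and a warning.
#'
#' @param curves_path path to the curves CSV.
#' @param metadata_path optional path to the metadata CSV.
#' @return A list with `curves` (named list of `list(cycles,
#'   fluorescence)`, ordered by cycle) and `metadata` (data frame, one row
#'   per curve).
#' @export
read_curves <- function(curves_path, metadata_path = NULL) {
  df <- utils::read.csv(curves_path, stringsAsFactors = FALSE)
  need <- c("curve_id", "cycle", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("curves file missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[, c("curve_id", "cycle")]))
    stop("duplicate (curve_id, cycle) rows in ", curves_path)
  curves <- lapply(split(df, df$curve_id), function(d) {
    d <- d[order(d$cycle), ]
    list(cycles = d$cycle, fluorescence = d$fluorescence)
  })
  ids <- names(curves)
  meta <- data.frame(curve_id = ids, target = NA_character_,
                     primer_set = NA_character_, concentration = NA_real_,
                     panel_id = NA_character_,
                     reaction_type = NA_character_,
                     stringsAsFactors = FALSE)
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    if (!"curve_id" %in% names(md))
      stop("metadata file missing column: curve_id")
    unmatched <- setdiff(ids, md$curve_id)
    if (length(unmatched))
      warning("curve(s) without metadata: ",
              paste(utils::head(unmatched, 5), collapse = ", "),
              if (length(unmatched) > 5) ", ...")
    for (col in intersect(c("target", "primer_set", "concentration",
                            "panel_id", "reaction_type", "contaminant"),
                          names(md)))
      meta[[col]] <- md[[col]][match(ids, md$curve_id)]
  }
  list(curves = curves, metadata = meta)
}

#' Write amplification curves and metadata to CSV
#'
#' Inverse of [read_curves()]: `write_curves()` writes the long-format
#' curve table, `write_metadata()` the per-curve metadata table.
#'
#' @param curves named list of curves.
#' @param path output CSV path.
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(names(curves), function(id) {
    data.frame(curve_id = id, cycle = curves[[id]]$cycles,
               fluorescence = curves[[id]]$fluorescence,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @param metadata data frame keyed by `curve_id`.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' Fit every curve of a set
#'
#' @param curves named list of curves.
#' @param ... passed to [fit_sigmoid()].
#' @return Named list of `sigmoid_fit` objects.
#' @export
fit_curve_set <- function(curves, ...) {
  lapply(curves, function(cv) fit_sigmoid(cv$cycles, cv$fluorescence, ...))
}

#' Tabulate fitted parameters
#'
#' @param fits named list of `sigmoid_fit` objects.
#' @return Data frame: `curve_id`, the five parameters, `rss`,
#'   `r_squared`, `converged`, `n_iter`.
#' @export
fits_table <- function(fits) {
  rows <- lapply(names(fits), function(id) {
    ft <- fits[[id]]
    cbind(data.frame(curve_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(ft$params))),
          data.frame(rss = ft$rss, r_squared = ft$r_squared,
                     converged = ft$converged, n_iter = ft$n_iter))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the per-curve kinetic feature table
#'
#' Extracts the full feature vector from every fit and joins the metadata
#' columns by `curve_id`.
#'
#' @param fits named list of `sigmoid_fit` objects (typically the filtered
#'   set).
#' @param metadata optional metadata data frame keyed by `curve_id`.
#' @param th_fraction relative first-derivative threshold for
#'   [extract_features()].
#' @return Data frame: `curve_id`, metadata columns, feature columns.
#' @export
feature_table <- function(fits, metadata = NULL, th_fraction = 0.05) {
  feats <- t(vapply(fits, function(ft)
    extract_features(ft$params, th_fraction),
    numeric(length(feature_names()))))
  out <- cbind(data.frame(curve_id = names(fits),
                          stringsAsFactors = FALSE),
               as.data.frame(feats))
  if (!is.null(metadata)) {
    i <- match(out$curve_id, metadata$curve_id)
    for (col in setdiff(names(metadata), "curve_id"))
      out[[col]] <- metadata[[col]][i]
  }
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] in one validated list;
#' serializable to/from YAML (unknown keys are rejected).
#'
#' @param output_dir directory for stage outputs (created if needed).
#' @param curves_path,metadata_path input CSVs; ignored when `scenario`
#'   is given.
#' @param scenario optional [plex_scenario()]; when present the synthetic
#'   generator provides the input curves.
#' @param strategy scoring strategy, `"S1"`, `"S2"` or `"S3"`.
#' @param feature_set features for S2/S3.
#' @param th_fraction first-derivative threshold fraction.
#' @param gain_min,r2_min,sc_min filter gates (see [filter_curves()]).
#' @param k_folds cross-validation folds for the classification stage.
#' @param knn_k k-NN neighbours.
#' @param seed integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, curves_path = NULL,
                            metadata_path = NULL, scenario = NULL,
                            strategy = "S3",
                            feature_set = feature_names_selected(),
                            th_fraction = 0.05, gain_min = 0.10,
                            r2_min = 0.99, sc_min = 0.1, k_folds = 10,
                            knn_k = 5, seed = 1) {
  structure(list(output_dir = output_dir, curves_path = curves_path,
                 metadata_path = metadata_path, scenario = scenario,
                 strategy = strategy, feature_set = feature_set,
                 th_fraction = th_fraction, gain_min = gain_min,
                 r2_min = r2_min, sc_min = sc_min, k_folds = k_folds,
                 knn_k = knn_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching the arguments of
#'   [pipeline_config()] (unknown keys raise an error).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "scenario")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the full assay-selection pipeline
#'
#' Executes fit, filter, feature extraction, candidate scoring/ranking and
#' classification of the top-ranked candidate, writing every stage's output
#' to `output_dir`:
#' `curves.csv`/`metadata.csv` (when generated), `fits.csv`,
#' `filter_report.csv`, `features.csv`, `scores.csv` (ranked candidates),
#' `distance_map.csv`, `confusion.csv` and `classification.csv`.
#' With a fixed seed the run is fully deterministic, so repeated runs
#' produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the ranked `scores`, the top candidate's
#'   `report` (an `aca_report`), the `features` table and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out, f)

  if (!is.null(config$scenario)) {
    sp <- generate_singleplex(config$scenario)
    ct <- generate_contaminants(config$scenario)
    curves <- c(sp$curves, ct$curves)
    metadata <- if (length(ct$curves))
      rbind(sp$metadata, ct$metadata) else sp$metadata
    write_curves(curves, pth("curves.csv"))
    write_metadata(metadata, pth("metadata.csv"))
  } else {
    if (is.null(config$curves_path))
      stop("stage input: either a scenario or curves_path is required")
    rd <- read_curves(config$curves_path, config$metadata_path)
    curves <- rd$curves
    metadata <- rd$metadata
  }

  fits <- fit_curve_set(curves)
  utils::write.csv(fits_table(fits), pth("fits.csv"), row.names = FALSE)

  fl <- filter_curves(curves, fits, gain_min = config$gain_min,
                      r2_min = config$r2_min, sc_min = config$sc_min)
  utils::write.csv(fl$report, pth("filter_report.csv"), row.names = FALSE)
  if (!length(fl$kept)) stop("stage filter: no curve passed the gates")
  fits <- fits[fl$kept]

  feats <- feature_table(fits, metadata, config$th_fraction)
  utils::write.csv(feats, pth("features.csv"), row.names = FALSE)

  sp_feats <- feats[!is.na(feats$target) &
                    feats$reaction_type == "singleplex", ]
  if (!nrow(sp_feats))
    stop("stage score: no singleplex curves with target metadata")
  sets <- lapply(split(sp_feats$primer_set, sp_feats$target), unique)
  candidates <- enumerate_candidates(sets[sort(names(sets))])
  cfg <- strategy_config(config$strategy, config$feature_set)
  scores <- score_assays(sp_feats, candidates, cfg)
  utils::write.csv(scores, pth("scores.csv"), row.names = FALSE)
  utils::write.csv(distance_map(scores), pth("distance_map.csv"),
                   row.names = FALSE)

  top <- candidates[match(scores$mix_id[1], candidates$mix_id), ]
  ds <- simulate_multiplex(top, sp_feats)
  kf <- min(config$k_folds, min(table(ds$target)))
  report <- cross_validate(ds[, config$feature_set, drop = FALSE],
                           ds$target, k_folds = kf, seed = config$seed,
                           knn_k = config$knn_k)
  utils::write.csv(as.data.frame(report$confusion), pth("confusion.csv"))
  utils::write.csv(data.frame(scheme = report$scheme,
                              accuracy = report$accuracy,
                              folds = kf, mix_id = scores$mix_id[1],
                              strategy = cfg$strategy,
                              embedding_mss = report$embedding_mss,
                              seed = config$seed),
                   pth("classification.csv"), row.names = FALSE)

  invisible(list(scores = scores, report = report, features = feats,
                 paths = list.files(out, full.names = TRUE)))
}
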