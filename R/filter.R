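#' Filter out NTC, flat, nonspecific and low-efficiency curves
#'
#' A three-gate quality filter applied after fitting and before feature
#' extraction. A curve is kept iff it passes all of:
#' * relative gain `(max - min) / min >= gain_min` (rejects flat and
#'   no-template-control traces; reason `"flat"`, or `"low_gain"` when the
#'   gain is positive but below threshold);
#' * fit converged with `r_squared >= r2_min` (rejects nonspecific,
#'   notched or otherwise non-sigmoidal traces; reason `"poor_fit"`);
#' * effective slope coefficient `>= sc_min` (rejects low-efficiency
#'   reactions; reason `"low_efficiency"`). The effective slope
#'   coefficient is `4 F'(x_ms) / Fm`, the `Sc` of the symmetric sigmoid
#'   with the same relative maximum slope; it equals the fitted `Sc` when
#'   `As = 1` but, unlike raw `Sc`, is robust to the `Sc`/`As` trade-off
#'   the five-parameter model admits on slow ramps.
#'
#' Gates are checked in that order and the first failure is reported.
#' Filtering is deterministic and idempotent for fixed thresholds.
#'
#' @param curves named list of curves, each a list with numeric `cycles` and
#'   `fluorescence` (as produced by [read_curves()] or the synthetic
#'   generators).
#' @param fits named list of [fit_sigmoid()] results, one per curve, with
#'   matching names.
#' @param gain_min minimum relative gain; default 0.10.
#' @param r2_min minimum coefficient of determination; default 0.99.
#' @param sc_min minimum slope coefficient per cycle; default 0.1.
#' @return A list with `kept` (names of retained curves) and `report`, a
#'   data frame with one row per input curve: `curve_id`, `kept`, `reason`
#'   (`NA` when kept).
#' @export
filter_curves <- function(curves, fits, gain_min = 0.10, r2_min = 0.99,
                          sc_min = 0.1) {
  ids <- names(curves)
  if (is.null(ids) || any(ids == ""))
    stop("curves must be a named list (curve ids)")
  if (!all(ids %in% names(fits)))
    stop("every curve needs a fit attempt; missing: ",
         paste(setdiff(ids, names(fits)), collapse = ", "))
  reason <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    cv <- curves[[ids[i]]]
    ft <- fits[[ids[i]]]
    f <- cv$fluorescence
    gain <- (max(f) - min(f)) / max(min(f), .Machine$double.eps)
    if (max(f) - min(f) <= 1e-12 * max(abs(f), 1)) {
      reason[i] <- "flat"
    } else if (gain < gain_min) {
      reason[i] <- "low_gain"
    } else if (!isTRUE(ft$converged) || !is.finite(ft$r_squared) ||
               ft$r_squared < r2_min) {
      reason[i] <- "poor_fit"
    } else {
      p <- ft$params
      x_ms <- p[["Cs"]] + log(p[["As"]]) / p[["Sc"]]
      sc_eff <- 4 * eval_sigmoid_deriv1(p, x_ms) / p[["Fm"]]
      if (sc_eff < sc_min) reason[i] <- "low_efficiency"
    }
  }
  report <- data.frame(curve_id = ids, kept = is.na(reason),
                       reason = reason, stringsAsFactors = FALSE)
  list(kept = ids[is.na(reason)], report = report)
}
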