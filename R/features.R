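#' Locate fiducial points on a fitted amplification curve
#'
#' Five fiducial points summarise the kinetic phases of the fitted curve:
#' `x_ms`, the maximum-slope location, has the closed form
#' \eqn{C_s + \ln(A_s)/S_c}; `x_s` and `x_e` are the two crossings of the
#' first derivative with the threshold `TH = th_fraction * F'(x_ms)`,
#' marking the start of the exponential phase and the start of the plateau;
#' `x_p1` and `x_p2` are the positive and negative peaks of the second
#' derivative, marking the accelerating and decelerating periods. The
#' second-derivative extrema are exact: with \eqn{u = e^{-S_c(t - C_s)}}
#' they are the roots of \eqn{A_s^2 u^2 - (3 A_s + 1) u + 1 = 0}.
#'
#' @param params a [sigmoid_params] vector.
#' @param th_fraction relative first-derivative threshold in (0, 1);
#'   default 0.05 (5 percent of the maximum slope).
#' @return A list of class `fiducial_points` with `x_s`, `x_p1`, `x_ms`,
#'   `x_p2`, `x_e`, `slope_ms = F'(x_ms)`, `curv_p1 = F''(x_p1)`,
#'   `curv_p2 = F''(x_p2)`.
#' @examples
#' locate_fiducials(sigmoid_params(Fm = 1, Sc = 1, Cs = 20, As = 2))$x_ms
#' # 20 + log(2)
#' @export
locate_fiducials <- function(params, th_fraction = 0.05) {
  p <- validate_sigmoid_params(params)
  if (!(th_fraction > 0 && th_fraction < 1))
    stop("th_fraction must be in (0, 1)")
  Sc <- p[["Sc"]]; Cs <- p[["Cs"]]; As <- p[["As"]]

  x_ms <- Cs + log(As) / Sc
  slope_ms <- eval_sigmoid_deriv1(p, x_ms)

  # second-derivative extrema: roots in u = exp(-Sc (t - Cs))
  disc <- (3 * As + 1)^2 - 4 * As^2
  u_hi <- ((3 * As + 1) + sqrt(disc)) / (2 * As^2)  # u > 1/As -> t < x_ms
  u_lo <- ((3 * As + 1) - sqrt(disc)) / (2 * As^2)
  x_p1 <- Cs - log(u_hi) / Sc
  x_p2 <- Cs - log(u_lo) / Sc

  th <- th_fraction * slope_ms
  x_s <- .th_crossing(p, th, x_ms, side = -1L)
  x_e <- .th_crossing(p, th, x_ms, side = +1L)

  out <- list(x_s = x_s, x_p1 = x_p1, x_ms = x_ms, x_p2 = x_p2, x_e = x_e,
              slope_ms = slope_ms,
              curv_p1 = eval_sigmoid_deriv2(p, x_p1),
              curv_p2 = eval_sigmoid_deriv2(p, x_p2),
              th = th, th_fraction = th_fraction)
  class(out) <- "fiducial_points"
  out
}

# F' is unimodal about x_ms; step outwards until below th, then uniroot
.th_crossing <- function(p, th, x_ms, side) {
  Sc <- p[["Sc"]]
  step <- 1 / Sc
  x <- x_ms + side * step
  for (i in 1:200) {
    if (eval_sigmoid_deriv1(p, x) < th) break
    x <- x + side * step
  }
  if (eval_sigmoid_deriv1(p, x) >= th)
    stop("failed to bracket the TH crossing x_",
         if (side < 0) "s" else "e", call. = FALSE)
  interval <- sort(c(x_ms, x))
  stats::uniroot(function(t) eval_sigmoid_deriv1(p, t) - th,
                 interval = interval, tol = 1e-12)$root
}

#' @export
print.fiducial_points <- function(x, ...) {
  cat("Fiducial points (TH =", format(x$th_fraction), "* max slope):\n")
  v <- unlist(x[c("x_s", "x_p1", "x_ms", "x_p2", "x_e",
                  "slope_ms", "curv_p1", "curv_p2")])
  print(round(v, 4))
  invisible(x)
}

#' Names of the kinetic features
#'
#' The five sigmoid parameters plus the derived kinetic features computed by
#' [extract_features()]. `feature_names_selected()` returns the default
#' feature vector used for multi-feature assay scoring: the maximum slope,
#' the two second-derivative peak heights and the slope coefficient `Sc` —
#' the combination that is both strongly target-separating and
#' concentration-robust.
#'
#' @return Character vector of feature names.
#' @export
feature_names <- function() {
  c("Fm", "Fb", "Sc", "Cs", "As",
    "span_exp", "span_p", "slope_ms", "curv_p1", "neg_curv_p2",
    "asym_span", "asym_area", "asym_curv", "A1", "A2")
}

#' @rdname feature_names
#' @export
feature_names_selected <- function() c("slope_ms", "curv_p1", "neg_curv_p2", "Sc")

#' Extract the kinetic feature vector from fitted sigmoid parameters
#'
#' Returns the five parameters and the derived kinetic features:
#' * `span_exp = x_e - x_s`, the exponential-to-plateau span;
#' * `span_p = x_p2 - x_p1`, the span between second-derivative peaks;
#' * `slope_ms = F'(x_ms)`, the maximum slope;
#' * `curv_p1 = F''(x_p1)` and `neg_curv_p2 = -F''(x_p2)`, the heights of
#'   the accelerating and decelerating curvature peaks (both positive);
#' * `asym_span = (x_e - x_ms) / (x_ms - x_s)`;
#' * `A1 = F(x_ms) - F(x_s)` and `A2 = F(x_e) - F(x_ms)`, the fluorescence
#'   rises of the exponential and plateau-approach phases (equal to the
#'   integrals of `F'` over those intervals);
#' * `asym_area = A2 / A1` and `asym_curv = -F''(x_p1) / F''(x_p2)`.
#'
#' The ratio features (`asym_*`) are invariant to fluorescence rescaling and
#' to shifts of `Cs`, which is what makes them robust to template
#' concentration.
#'
#' @inheritParams locate_fiducials
#' @return Named numeric vector (see [feature_names()]).
#' @export
extract_features <- function(params, th_fraction = 0.05) {
  p <- validate_sigmoid_params(params)
  fp <- locate_fiducials(p, th_fraction)
  A1 <- eval_sigmoid(p, fp$x_ms) - eval_sigmoid(p, fp$x_s)
  A2 <- eval_sigmoid(p, fp$x_e) - eval_sigmoid(p, fp$x_ms)
  c(p[c("Fm", "Fb", "Sc", "Cs", "As")],
    span_exp = fp$x_e - fp$x_s,
    span_p = fp$x_p2 - fp$x_p1,
    slope_ms = fp$slope_ms,
    curv_p1 = fp$curv_p1,
    neg_curv_p2 = -fp$curv_p2,
    asym_span = (fp$x_e - fp$x_ms) / (fp$x_ms - fp$x_s),
    asym_area = A2 / A1,
    asym_curv = -fp$curv_p1 / fp$curv_p2,
    A1 = A1, A2 = A2)
}

#' Standardize a feature matrix to zero mean and unit standard deviation
#'
#' Each feature (column) is centred on its mean and divided by its
#' population standard deviation (denominator `n`). Standardization is
#' applied before any distance calculation so that features of different
#' units contribute comparably.
#'
#' @param x numeric matrix or data frame of features, one row per curve.
#' @return A list with `x` (standardized matrix), `center` and `scale`
#'   (named per-feature vectors).
#' @seealso [unstandardize_features()] for the inverse transform.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 curves to standardize")
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero))
    stop("zero-variance feature(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' @rdname standardize_features
#' @param std a list as returned by `standardize_features()`.
#' @export
unstandardize_features <- function(std) {
  sweep(sweep(std$x, 2, std$scale, "*"), 2, std$center, "+")
}
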