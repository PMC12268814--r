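#' Asymmetric five-parameter sigmoid model of an amplification curve
#'
#' The fluorescence of a real-time PCR (or digital PCR partition)
#' amplification curve is modelled as
#' \deqn{F(t) = \frac{F_m}{\left(1 + e^{-S_c (t - C_s)}\right)^{A_s}} + F_b}
#' where `Fm` is the maximum fluorescence above baseline, `Fb` the baseline
#' fluorescence, `Sc` a slope coefficient (per cycle), `Cs` the curve centre
#' linked to the cycle threshold (Ct), and `As` a dimensionless asymmetry
#' index (`As = 1` gives the symmetric logistic).
#'
#' @param Fm maximum fluorescence above baseline; must be `> 0`.
#' @param Fb baseline fluorescence.
#' @param Sc slope coefficient per cycle; must be `> 0`.
#' @param Cs curve centre in cycles.
#' @param As asymmetry index; must be `> 0`.
#' @return A named numeric vector of class `sigmoid_params`.
#' @examples
#' p <- sigmoid_params(Fm = 1000, Fb = 50, Sc = 0.8, Cs = 25, As = 2)
#' eval_sigmoid(p, 25)  # = Fm/2^As + Fb = 300
#' @export
sigmoid_params <- function(Fm, Fb = 0, Sc = 1, Cs = 0, As = 1) {
  p <- c(Fm = Fm, Fb = Fb, Sc = Sc, Cs = Cs, As = As)
  validate_sigmoid_params(p)
  class(p) <- "sigmoid_params"
  p
}

validate_sigmoid_params <- function(p) {
  nm <- c("Fm", "Fb", "Sc", "Cs", "As")
  if (!all(nm %in% names(p)))
    stop("sigmoid parameters must be named ", paste(nm, collapse = ", "))
  p <- p[nm]
  if (any(!is.finite(p))) stop("sigmoid parameters must be finite")
  if (p[["Fm"]] <= 0) stop("Fm must be positive")
  if (p[["Sc"]] <= 0) stop("Sc must be positive")
  if (p[["As"]] <= 0) stop("As must be positive")
  invisible(p)
}

# softplus log(1 + e^z), stable in both tails
.log1pexp <- function(z) {
  out <- numeric(length(z))
  lo <- z <= 18
  out[lo] <- log1p(exp(z[lo]))
  out[!lo] <- z[!lo] + log1p(exp(-z[!lo]))
  out
}

#' Evaluate the five-parameter sigmoid and its analytic derivatives
#'
#' `eval_sigmoid()` evaluates the model curve \eqn{F(t)};
#' `eval_sigmoid_deriv1()` its first derivative
#' \deqn{F'(t) = \frac{F_m S_c A_s e^{-S_c(t-C_s)}}{(1+e^{-S_c(t-C_s)})^{A_s+1}}}
#' and `eval_sigmoid_deriv2()` its second derivative
#' \deqn{F''(t) = \frac{F_m S_c^2 A_s e^{-S_c(t-C_s)}\,(A_s e^{-S_c(t-C_s)} - 1)}
#'   {(1+e^{-S_c(t-C_s)})^{A_s+2}}.}
#' All three are evaluated through log-space (softplus) forms so that far
#' tails return the correct asymptote (`Fb`, `Fm + Fb`, or 0) rather than
#' overflowing.
#'
#' @param params a [sigmoid_params] vector (any named numeric with the five
#'   components is accepted).
#' @param t cycle value or vector (need not be integer or unit-spaced).
#' @return Numeric vector of the same length as `t`.
#' @export
eval_sigmoid <- function(params, t) {
  p <- validate_sigmoid_params(params)
  z <- -p[["Sc"]] * (t - p[["Cs"]])
  p[["Fm"]] * exp(-p[["As"]] * .log1pexp(z)) + p[["Fb"]]
}

#' @rdname eval_sigmoid
#' @export
eval_sigmoid_deriv1 <- function(params, t) {
  p <- validate_sigmoid_params(params)
  z <- -p[["Sc"]] * (t - p[["Cs"]])
  p[["Fm"]] * p[["Sc"]] * p[["As"]] * exp(z - (p[["As"]] + 1) * .log1pexp(z))
}

#' @rdname eval_sigmoid
#' @export
eval_sigmoid_deriv2 <- function(params, t) {
  p <- validate_sigmoid_params(params)
  As <- p[["As"]]
  z <- -p[["Sc"]] * (t - p[["Cs"]])
  L <- .log1pexp(z)
  # e^z (As e^z - 1) / (1+e^z)^(As+2), split to avoid overflow of As*e^z
  p[["Fm"]] * p[["Sc"]]^2 * As *
    (As * exp(2 * z - (As + 2) * L) - exp(z - (As + 2) * L))
}

#' Fit the five-parameter sigmoid to one amplification curve
#'
#' Nonlinear least squares by bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm]), minimising \eqn{\sum_i (F_i - F(t_i))^2} with no
#' weighting. Starting values are data driven: `Fb` from the minimum
#' fluorescence, `Fm` from the range, `Cs` from the half-range crossing, `Sc`
#' from the maximum finite-difference slope scaled by `4/Fm` (the symmetric
#' maximum-slope identity), `As = 1`. Bounds keep the optimiser out of
#' degenerate regimes while admitting strong asymmetry; see the package
#' vignette. Optimiser failure is reported through `converged = FALSE`, never
#' as an error.
#'
#' @param cycles strictly increasing numeric vector of cycle indices (or
#'   time stamps), length at least 20.
#' @param fluorescence numeric vector of fluorescence readings, same length.
#' @param start optional named numeric vector overriding any of the
#'   data-driven starting values.
#' @param lower,upper optional named vectors overriding default bounds.
#' @param maxiter maximum number of optimiser iterations.
#' @param ftol cost tolerance passed to the optimiser.
#' @return An object of class `sigmoid_fit`: a list with elements `params`
#'   (a [sigmoid_params] vector), `rss`, `r_squared`, `converged`, `n_iter`,
#'   `cycles`, `fluorescence`.
#' @examples
#' p <- sigmoid_params(Fm = 1000, Fb = 50, Sc = 0.8, Cs = 25, As = 1)
#' f <- eval_sigmoid(p, 1:45)
#' fit <- fit_sigmoid(1:45, f)
#' coef(fit)
#' @export
fit_sigmoid <- function(cycles, fluorescence, start = NULL,
                        lower = NULL, upper = NULL,
                        maxiter = 200, ftol = 1e-10) {
  if (length(cycles) != length(fluorescence))
    stop("cycles and fluorescence must have equal length")
  if (length(cycles) < 20)
    stop("need at least 20 cycles to fit a sigmoid")
  if (any(diff(cycles) <= 0))
    stop("cycles must be strictly increasing")
  if (any(!is.finite(fluorescence)))
    stop("fluorescence must be finite")

  Fobs <- fluorescence
  rng <- max(Fobs) - min(Fobs)
  flat <- rng <= 0 || rng < 1e-12 * max(abs(Fobs), 1)

  s0 <- .sigmoid_start(cycles, Fobs)
  if (!is.null(start)) s0[names(start)] <- start
  lo <- c(Fm = 1e-8, Fb = min(Fobs) - max(rng, 1e-8),
          Sc = 1e-6, Cs = cycles[1] - 10, As = 0.01)
  hi <- c(Fm = 10 * max(rng, 1e-8), Fb = max(Fobs),
          Sc = 10, Cs = cycles[length(cycles)] + 10, As = 20)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  s0 <- pmin(pmax(s0, lo), hi)

  out <- list(params = NULL, rss = NA_real_, r_squared = NA_real_,
              converged = FALSE, n_iter = 0L,
              cycles = cycles, fluorescence = Fobs)
  class(out) <- "sigmoid_fit"

  if (flat) {
    out$params <- structure(s0, class = "sigmoid_params")
    out$rss <- sum((Fobs - mean(Fobs))^2)
    out$r_squared <- 0
    return(out)
  }

  resid_fn <- function(par) {
    z <- -par[["Sc"]] * (cycles - par[["Cs"]])
    Fobs - (par[["Fm"]] * exp(-par[["As"]] * .log1pexp(z)) + par[["Fb"]])
  }
  # non-convergence is reported via the info code, not as a condition
  ans <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = s0, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = ftol, ptol = 1e-12,
                           maxfev = 5000))),
    error = function(e) NULL)

  if (is.null(ans)) {
    out$params <- structure(s0, class = "sigmoid_params")
    return(out)
  }
  par <- ans$par
  rss <- sum(resid_fn(par)^2)
  tss <- sum((Fobs - mean(Fobs))^2)
  out$params <- structure(unlist(par)[c("Fm", "Fb", "Sc", "Cs", "As")],
                          class = "sigmoid_params")
  out$rss <- rss
  out$r_squared <- 1 - rss / tss
  out$n_iter <- ans$niter
  # info codes 1:4 indicate successful termination for nls.lm
  out$converged <- ans$info %in% 1:4 && is.finite(out$r_squared)
  out
}

.sigmoid_start <- function(cycles, Fobs) {
  fmin <- min(Fobs); fmax <- max(Fobs); rng <- max(fmax - fmin, 1e-8)
  half <- fmin + rng / 2
  i <- which(Fobs >= half)[1]
  Cs0 <- if (is.na(i)) stats::median(cycles) else cycles[i]
  slopes <- diff(Fobs) / diff(cycles)
  Sc0 <- 4 * max(slopes, 1e-6) / rng
  c(Fm = rng, Fb = fmin, Sc = Sc0, Cs = Cs0, As = 1)
}

#' @export
print.sigmoid_fit <- function(x, digits = 4, ...) {
  cat("Five-parameter sigmoid fit\n")
  cat(sprintf("  n = %d cycles [%g, %g]\n", length(x$cycles),
              min(x$cycles), max(x$cycles)))
  print(round(unclass(x$params), digits))
  cat(sprintf("  RSS = %.4g, R^2 = %.6f, converged = %s (%d iter)\n",
              x$rss, x$r_squared, x$converged, x$n_iter))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) unclass(object$params)

#' @export
fitted.sigmoid_fit <- function(object, ...)
  eval_sigmoid(object$params, object$cycles)

#' @export
residuals.sigmoid_fit <- function(object, ...)
  object$fluorescence - fitted(object)

#' Predict fluorescence (or its derivatives) from a fitted sigmoid
#'
#' @param object a `sigmoid_fit`.
#' @param newdata optional numeric vector of cycle values; defaults to the
#'   fitted cycles.
#' @param deriv 0 for the curve, 1 or 2 for the analytic derivatives.
#' @param ... unused.
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, deriv = 0, ...) {
  t <- if (is.null(newdata)) object$cycles else newdata
  switch(as.character(deriv),
         "0" = eval_sigmoid(object$params, t),
         "1" = eval_sigmoid_deriv1(object$params, t),
         "2" = eval_sigmoid_deriv2(object$params, t),
         stop("deriv must be 0, 1 or 2"))
}

#' @export
summary.sigmoid_fit <- function(object, ...) {
  fp <- tryCatch(locate_fiducials(object$params), error = function(e) NULL)
  structure(list(fit = object, fiducials = fp), class = "summary.sigmoid_fit")
}

#' @export
print.summary.sigmoid_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fiducials)) {
    f <- x$fiducials
    cat(sprintf("  fiducials: x_s = %.3f, x_p1 = %.3f, x_ms = %.3f, x_p2 = %.3f, x_e = %.3f\n",
                f$x_s, f$x_p1, f$x_ms, f$x_p2, f$x_e))
    cat(sprintf("  max slope = %.4g at x_ms\n", f$slope_ms))
  }
  invisible(x)
}

#' @export
plot.sigmoid_fit <- function(x, ...) {
  graphics::plot(x$cycles, x$fluorescence, pch = 16, cex = 0.6,
                 xlab = "cycle", ylab = "fluorescence (a.u.)", ...)
  tt <- seq(min(x$cycles), max(x$cycles), length.out = 200)
  graphics::lines(tt, eval_sigmoid(x$params, tt), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate noisy amplification curves from a fitted sigmoid
#'
#' Draws `nsim` replicate curves on the fitted cycle grid with i.i.d.
#' Gaussian noise whose standard deviation is the residual standard error of
#' the fit.
#'
#' @param object a `sigmoid_fit`.
#' @param nsim number of replicate curves.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @param ... unused.
#' @return A matrix with one column per replicate.
#' @export
simulate.sigmoid_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  mu <- fitted(object)
  sigma <- sqrt(object$rss / max(length(mu) - 5, 1))
  matrix(stats::rnorm(length(mu) * nsim, rep(mu, nsim), sigma),
         ncol = nsim)
}
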