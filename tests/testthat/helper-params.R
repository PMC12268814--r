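# Random valid sigmoid parameter draws for property-style tests.
# Ranges reflect plausible qPCR curves: strong asymmetry admitted, slopes
# spanning slow to steep reactions.
rand_params <- function(n) {
  lapply(seq_len(n), function(i) {
    sigmoid_params(Fm = runif(1, 100, 5000),
                   Fb = runif(1, 0, 200),
                   Sc = runif(1, 0.2, 2),
                   Cs = runif(1, 10, 35),
                   As = exp(runif(1, log(0.2), log(5))))
  })
}

# Central finite difference of a scalar function
fdiff <- function(f, t, h = 1e-5) (f(t + h) - f(t - h)) / (2 * h)

# Independent brute-force silhouette: literal per-point loops, no shared
# code with mean_silhouette()
brute_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums(sweep(x, 2, x[i, ])^2))
    own <- which(labels == labels[i] & seq_len(n) != i)
    a <- mean(di[own])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(di[labels == l]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Noiseless synthetic curve from known parameters
make_curve <- function(p, cycles = 1:45, noise_sd = 0) {
  f <- eval_sigmoid(p, cycles)
  if (noise_sd > 0) f <- f + rnorm(length(cycles), 0, noise_sd)
  list(cycles = cycles, fluorescence = f)
}
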