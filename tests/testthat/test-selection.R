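test_that("Kruskal-Wallis robustness: identical groups give H = 0, p = 1", {
  res <- kruskal_wallis_robustness(c(1, 2, 3, 1, 2, 3),
                                   rep(c("g1", "g2"), each = 3))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_true(res$robust)
})

test_that("strongly shifted groups are detected as non-robust", {
  res <- kruskal_wallis_robustness(c(1, 2, 3, 101, 102, 103),
                                   rep(c("g1", "g2"), each = 3))
  expect_lt(res$p_value, 0.05)
  res2 <- kruskal_wallis_robustness(c(1, 2, 3, 101, 102, 103),
                                    rep(c("g1", "g2"), each = 3),
                                    alpha = 0.05)
  expect_false(res2$robust)
  expect_error(kruskal_wallis_robustness(1:3, c("a", "a", "b")),
               ">= 2")
})

test_that("Kruskal-Wallis p is invariant under strictly monotone transforms", {
  set.seed(31)
  v <- rnorm(60)
  g <- rep(c("a", "b", "c"), each = 20)
  p0 <- kruskal_wallis_robustness(v, g)$p_value
  expect_equal(kruskal_wallis_robustness(exp(v), g)$p_value, p0)
  expect_equal(kruskal_wallis_robustness(v^3 + 5 * v, g)$p_value, p0)
})

test_that("Dunn post-hoc: identical groups give all off-diagonal p = 1", {
  p <- dunn_posthoc(rep(c(1, 2, 3), 4), rep(c("a", "b", "c", "d"), each = 3))
  expect_true(all(p == 1))
  expect_equal(p, t(p))
})

test_that("Dunn post-hoc localises a single shifted group", {
  set.seed(47)
  v <- c(rnorm(10 * 6), rnorm(10, 8))
  g <- rep(sprintf("c%d", 1:7), each = 10)
  p <- dunn_posthoc(v, g)
  expect_equal(p, t(p))
  expect_true(all(diag(p) == 1))
  off <- p[upper.tri(p)]
  pairs <- which(upper.tri(p), arr.ind = TRUE)
  involves7 <- pairs[, 1] == 7 | pairs[, 2] == 7
  expect_lt(max(p[cbind(1:6, 7)]), min(off[!involves7]))
})

test_that("singleplex-multiplex correlation is 1 under exact attenuation", {
  cycles <- seq(0.5, 45, by = 0.5)
  sc <- seq(0.4, 1.2, length.out = 5)
  sp <- mp <- list()
  for (i in seq_along(sc)) {
    p <- sigmoid_params(Fm = 1000, Fb = 50, Sc = sc[i], Cs = 25, As = 1.5)
    pm <- p; pm[["Fm"]] <- 0.8 * p[["Fm"]]; pm[["Sc"]] <- 0.8 * p[["Sc"]]
    id <- sprintf("ps%d", i)
    sp[[id]] <- list(make_curve(p, cycles), make_curve(p, cycles))
    mp[[id]] <- list(make_curve(pm, cycles), make_curve(pm, cycles))
  }
  for (f in c("Sc", "slope_ms", "curv_p1", "neg_curv_p2")) {
    res <- singleplex_multiplex_correlation(sp, mp, f)
    expect_equal(res$r, 1, tolerance = 1e-6)
    expect_true(res$passed)
    expect_equal(nrow(res$pairs), 5)
  }
})

test_that("primer sets missing in one condition are excluded with a warning", {
  cycles <- 1:45
  mk <- function(sc) list(make_curve(
    sigmoid_params(Fm = 1000, Fb = 50, Sc = sc, Cs = 25, As = 1.5),
    cycles), make_curve(
    sigmoid_params(Fm = 1000, Fb = 50, Sc = sc, Cs = 25, As = 1.5),
    cycles))
  sp <- list(a = mk(0.5), b = mk(0.7), c = mk(0.9), d = mk(1.1))
  mp <- sp[c("a", "b", "c")]
  expect_warning(res <- singleplex_multiplex_correlation(sp, mp, "Sc"),
                 "excluded: d")
  expect_equal(sort(res$pairs$primer_set), c("a", "b", "c"))
  expect_error(
    suppressWarnings(singleplex_multiplex_correlation(sp[1:2], mp[1:2],
                                                      "Sc")),
    ">= 3 primer sets")
})

test_that("median_curve takes per-cycle medians and checks the grid", {
  cs <- list(list(cycles = 1:20, fluorescence = rep(1, 20)),
             list(cycles = 1:20, fluorescence = rep(2, 20)),
             list(cycles = 1:20, fluorescence = rep(9, 20)))
  expect_equal(median_curve(cs)$fluorescence, rep(2, 20))
  cs[[2]]$cycles <- 2:21
  expect_error(median_curve(cs), "common cycle grid")
})

test_that("select_features applies all gates and orders by MSS", {
  screen <- data.frame(
    feature = c("slope_ms", "curv_p1", "neg_curv_p2", "Sc",
                "span_p", "asym_area", "Fb", "Cs"),
    mss = c(0.80, 0.75, 0.72, 0.70, 0.70, 0.10, 0.05, 0.60),
    kw_p_min = c(0.5, 0.4, 0.6, 0.3, 0.5, 0.5, 0.5, 0.001),
    min_target_sil = c(0.3, 0.3, 0.3, 0.2, -0.4, 0.1, 0.0, 0.2))
  r <- c(slope_ms = 0.95, curv_p1 = 0.92, neg_curv_p2 = 0.9, Sc = 0.97,
         span_p = 0.9, asym_area = 0.9, Fb = 0.2, Cs = 0.9)
  sel <- select_features(screen, r, mss_ratio = 1.0)
  # span_p fails the per-target floor, Cs fails Kruskal-Wallis, Fb fails
  # both MSS and correlation, asym_area fails the MSS gate
  expect_identical(sel$selected,
                   c("slope_ms", "curv_p1", "neg_curv_p2", "Sc"))
  expect_true(all(sel$report$passed ==
                  (sel$report$feature %in% sel$selected)))
})

test_that("featureless inputs give the empty-selection error, gates are monotone", {
  screen0 <- data.frame(feature = c("a", "b"), mss = c(0, 0),
                        kw_p_min = c(0.5, 0.5),
                        min_target_sil = c(0, 0))
  expect_error(select_features(screen0), "no feature passed")
  screen <- data.frame(feature = letters[1:5],
                       mss = c(0.9, 0.6, 0.4, 0.2, 0.1),
                       kw_p_min = rep(0.5, 5),
                       min_target_sil = rep(0.2, 5))
  n_sel <- vapply(c(2.2, 2, 1, 0.1), function(r)
    length(select_features(screen, mss_ratio = r)$selected), numeric(1))
  expect_true(all(diff(n_sel) >= 0))
})

test_that("screen_features combines MSS, robustness and consistency", {
  set.seed(17)
  n <- 20
  feats <- data.frame(
    sep = rep(c(0, 5, 10), each = n) + rnorm(3 * n, 0, 0.05),
    conc_dep = rep(seq_len(4), times = 15) * 2 + rnorm(3 * n, 0, 0.05))
  targets <- rep(c("a", "b", "c"), each = n)
  conc <- rep(rep(c("c1", "c2", "c3", "c4"), length.out = n), 3)
  sc <- screen_features(feats, targets, conc)
  expect_equal(sc$feature, c("sep", "conc_dep"))
  expect_gt(sc$mss[1], 0.9)
  expect_gt(sc$kw_p_min[1], 0.01)   # separable feature is conc-robust
  expect_lt(sc$kw_p_min[2], 0.01)   # concentration-leaking feature is not
})
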