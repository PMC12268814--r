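# Well-separated 1-D clusters for quick classifier checks
sep_fixture <- function(n_per = 20, k = 3, gap = 10, sd = 0.2, seed = 1) {
  set.seed(seed)
  data.frame(f = rnorm(n_per * k, rep(seq_len(k) * gap, each = n_per), sd),
             lab = rep(letters[seq_len(k)], each = n_per))
}

test_that("training on separated clusters gives perfect training accuracy", {
  fx <- sep_fixture()
  m <- aca_train(matrix(fx$f, ncol = 1), fx$lab)
  expect_equal(predict(m, matrix(fx$f, ncol = 1)), fx$lab)
  expect_output(print(m), "k-NN")
})

test_that("training rejects degenerate class structure", {
  expect_error(aca_train(matrix(1:5, ncol = 1), rep("a", 5)), "2 classes")
  expect_error(aca_train(matrix(1:5, ncol = 1), c("a", "a", "a", "a", "b")),
               "< 2 samples")
})

test_that("predictions are deterministic and ties break to the lowest label", {
  fx <- sep_fixture(seed = 4)
  x <- matrix(fx$f, ncol = 1)
  m1 <- aca_train(x, fx$lab)
  m2 <- aca_train(x, fx$lab)
  q <- matrix(rnorm(50, 20, 8), ncol = 1)
  expect_identical(predict(m1, q), predict(m2, q))
  # symmetric 2-NN vote tie: one neighbour per class, equidistant
  mt <- aca_train(matrix(c(0, 0.1, 2, 1.9), ncol = 1),
                  c("b", "b", "a", "a"), k = 2, standardize = FALSE)
  expect_equal(predict(mt, matrix(1, ncol = 1)), "a")
})

test_that("k-NN agrees with class::knn on tie-free data", {
  skip_if_not_installed("class")
  fx <- sep_fixture(n_per = 15, k = 3, gap = 3, sd = 1, seed = 8)
  x <- matrix(fx$f, ncol = 1)
  set.seed(9)
  q <- matrix(runif(30, 0, 12), ncol = 1)
  m <- aca_train(x, fx$lab, k = 5, standardize = FALSE)
  ref <- as.character(class::knn(x, q, fx$lab, k = 5))
  expect_identical(predict(m, q), ref)
})

test_that("stratified k-fold CV aggregates a consistent confusion matrix", {
  fx <- sep_fixture(n_per = 30, seed = 2)
  rep <- cross_validate(matrix(fx$f, ncol = 1), fx$lab, k_folds = 10,
                        seed = 1)
  expect_equal(sum(rep$confusion), 90)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_equal(rep$accuracy, 1)
  expect_equal(rowSums(rep$confusion), table(fx$lab)[c("a", "b", "c")],
               ignore_attr = TRUE)
  # leave-one-out on well-separated targets is perfect
  rep_loo <- cross_validate(matrix(fx$f, ncol = 1), fx$lab, k_folds = 30,
                            seed = 1)
  expect_equal(rep_loo$accuracy, 1)
  expect_output(print(rep), "kfold")
})

test_that("CV is reproducible under a fixed seed and validates k", {
  fx <- sep_fixture(n_per = 12, gap = 2, sd = 1, seed = 3)
  r1 <- cross_validate(matrix(fx$f, ncol = 1), fx$lab, k_folds = 6,
                       seed = 42)
  r2 <- cross_validate(matrix(fx$f, ncol = 1), fx$lab, k_folds = 6,
                       seed = 42)
  expect_identical(r1$confusion, r2$confusion)
  expect_error(cross_validate(matrix(fx$f, ncol = 1), fx$lab,
                              k_folds = 13), "smaller k")
  expect_error(cross_validate(matrix(1:5, ncol = 1), rep("a", 5),
                              k_folds = 2), "2 classes")
})

test_that("embedding MSS equals mean_silhouette on the same standardized features", {
  fx <- sep_fixture(n_per = 10, seed = 6)
  x <- matrix(fx$f, ncol = 1)
  rep <- cross_validate(x, fx$lab, k_folds = 5, seed = 1)
  expect_equal(rep$embedding_mss,
               mean_silhouette(standardize_features(x)$x, fx$lab),
               tolerance = 1e-12)
})

test_that("LOCO matches k-fold for concentration-invariant features", {
  set.seed(13)
  n_per <- 12; conc <- rep(c("c1", "c2", "c3", "c4"), length.out = n_per)
  fx <- data.frame(
    f = rnorm(n_per * 3, rep(c(0, 10, 20), each = n_per), 0.3),
    lab = rep(c("a", "b", "c"), each = n_per),
    conc = rep(conc, 3))
  kf <- cross_validate(matrix(fx$f, ncol = 1), fx$lab, k_folds = 6,
                       seed = 1)
  lc <- loco_evaluate(matrix(fx$f, ncol = 1), fx$lab, fx$conc)
  expect_lte(abs(kf$accuracy - lc$accuracy), 0.02)
  expect_equal(sum(lc$confusion), nrow(fx))
  expect_equal(lc$scheme, "loco")
  expect_error(loco_evaluate(matrix(fx$f, ncol = 1), fx$lab,
                             rep("c1", nrow(fx))), ">= 2 concentration")
})

test_that("concentration-leaking features degrade LOCO relative to k-fold", {
  set.seed(19)
  # Cs-style feature coupled to concentration: classes separated within a
  # concentration but shifted across concentrations by more than the
  # class gap, so held-out concentrations land between training classes
  n_per <- 20
  conc_shift <- c(c1 = 0, c2 = 6, c3 = 12, c4 = 18)
  conc <- rep(names(conc_shift), length.out = n_per)
  fx <- data.frame(
    f = rnorm(n_per * 3, rep(c(0, 2, 4), each = n_per), 0.2) +
      rep(conc_shift[conc], 3),
    lab = rep(c("a", "b", "c"), each = n_per),
    conc = rep(conc, 3))
  kf <- cross_validate(matrix(fx$f, ncol = 1), fx$lab, k_folds = 5,
                       seed = 1)
  lc <- loco_evaluate(matrix(fx$f, ncol = 1), fx$lab, fx$conc)
  expect_lt(lc$accuracy, kf$accuracy)
})

test_that("LOCO flags classes absent from training", {
  set.seed(23)
  # each class confined to one concentration: every fold tests a class its
  # training set never saw
  fx2 <- data.frame(f = rnorm(24, rep(c(0, 10), each = 12), 0.3),
                    lab = rep(c("a", "b"), each = 12),
                    conc = c(rep("c1", 12), rep("c2", 12)))
  lc2 <- loco_evaluate(matrix(fx2$f, ncol = 1), fx2$lab, fx2$conc)
  expect_equal(length(lc2$flagged), 2)
  expect_match(lc2$flagged[1], "absent from training")
})

test_that("shuffled labels drive CV accuracy to chance", {
  set.seed(29)
  fx <- sep_fixture(n_per = 40, k = 4, seed = 31)
  shuffled <- sample(fx$lab)
  rep <- cross_validate(matrix(fx$f, ncol = 1), shuffled, k_folds = 8,
                        seed = 1)
  p0 <- 1 / 4
  ci <- 3 * sqrt(p0 * (1 - p0) / length(shuffled))
  expect_lt(abs(rep$accuracy - p0), ci + 0.05)
})

test_that("panel ensemble majority vote with deterministic ties", {
  pred <- c(rep("A", 6), rep("B", 3))
  res <- panel_ensemble(pred, rep("p1", 9))
  expect_equal(unname(res$calls), "A")
  # 2-vs-2 tie goes to the lowest label
  res2 <- panel_ensemble(c("B", "B", "A", "A"), rep("p1", 4))
  expect_equal(unname(res2$calls), "A")
  expect_error(panel_ensemble(character(0), character(0)), "empty")
  expect_error(panel_ensemble(c("A", "B"), "p1"), "one panel id")
})

test_that("panel voting amplifies per-curve accuracy", {
  set.seed(37)
  n_panels <- 60; per_panel <- 25; p_correct <- 0.8
  truth <- rep(rep(c("A", "B"), length.out = n_panels), each = per_panel)
  panel <- rep(sprintf("p%02d", seq_len(n_panels)), each = per_panel)
  correct <- runif(length(truth)) < p_correct
  pred <- ifelse(correct, truth, ifelse(truth == "A", "B", "A"))
  res <- panel_ensemble(pred, panel, truth)
  expect_gt(res$accuracy, mean(correct))
  truth_bad <- truth
  truth_bad[1] <- setdiff(c("A", "B"), truth[1])
  expect_error(panel_ensemble(pred, panel, truth_bad),
               "constant within a panel")
})
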