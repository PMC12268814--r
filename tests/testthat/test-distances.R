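test_that("candidate enumeration is the full Cartesian product", {
  c3 <- enumerate_candidates(list(A = c("a1", "a2"), B = c("b1", "b2"),
                                  C = c("c1", "c2")))
  expect_equal(nrow(c3), 8)
  expect_equal(c3$mix_id, sprintf("PM%d", 1:8))
  c7 <- enumerate_candidates(setNames(
    lapply(1:7, function(i) paste0("s", i, c("x", "y"))),
    paste0("T", 1:7)))
  expect_equal(nrow(c7), 128)
  expect_equal(nrow(enumerate_candidates(list(A = "a1"))), 1)
  expect_error(enumerate_candidates(list(A = character(0), B = "b")),
               "target")
})

test_that("simulate_multiplex pools singleplex features deterministically", {
  feats <- data.frame(target = rep(c("A", "B", "C"), each = 4),
                      primer_set = rep(c("a1", "a2", "b1", "b2",
                                         "c1", "c2"), each = 2),
                      Sc = 1:12)
  cand <- c(A = "a1", B = "b1", C = "c2")
  ds <- simulate_multiplex(cand, feats)
  expect_equal(nrow(ds), 6)
  expect_setequal(unique(ds$target), c("A", "B", "C"))
  expect_identical(ds, simulate_multiplex(cand, feats))
  expect_error(simulate_multiplex(c(A = "zz", B = "b1", C = "c1"), feats),
               "A/zz")
})

test_that("median distance: hand geometry", {
  expect_equal(median_distance(c(0, 0, 0), c(2, 2, 2)), 2)
  expect_equal(median_distance(c(-1, 0, 1), c(1, 2, 3)), 2)
  a <- matrix(c(0, 0, 0, 0, 0, 0), ncol = 2)
  b <- matrix(c(3, 3, 3, 4, 4, 4), ncol = 2)
  expect_equal(median_distance(a, b), 5)
  x <- matrix(rnorm(20), ncol = 2)
  expect_equal(median_distance(x, x), 0)
  expect_error(median_distance(matrix(1:4, ncol = 2),
                               matrix(1:3, ncol = 1)), "dimension")
})

test_that("clustering distance equals the two-cluster silhouette", {
  expect_equal(clustering_distance(c(0, 1), c(2, 3)), 7 / 15,
               tolerance = 1e-12)
  u <- seq(0, 1, length.out = 20)
  expect_lt(abs(clustering_distance(u, u)), 0.06)
  expect_gt(clustering_distance(c(0, 0.01), c(100, 100.01)), 0.999)
  expect_error(clustering_distance(c(0, 1), 5), "singleton")
})

test_that("median distance ignores variance inflation; clustering distance does not", {
  set.seed(61)
  base_a <- rnorm(31, 0, 0.5)
  base_b <- rnorm(31, 4, 0.5)
  # inflate spread about the median, medians fixed
  inflate <- function(x, k) median(x) + k * (x - median(x))
  m0 <- median_distance(base_a, base_b)
  c0 <- clustering_distance(base_a, base_b)
  prev <- c0
  for (k in c(2, 5, 10)) {
    a <- inflate(base_a, k)
    expect_equal(median_distance(a, base_b), m0, tolerance = 1e-12)
    ck <- clustering_distance(a, base_b)
    expect_lt(ck, prev)
    prev <- ck
  }
})

test_that("score_candidate aggregates pairwise distances into ADS/MDS", {
  set.seed(71)
  ds <- data.frame(target = rep(c("A", "B", "C"), each = 10),
                   f1 = c(rnorm(10, 0), rnorm(10, 3), rnorm(10, 9)),
                   f2 = c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 2)))
  sc <- score_candidate(ds, feature_set = c("f1", "f2"),
                        distance = "median")
  expect_equal(sc$ads, mean(sc$pairs$distance))
  expect_equal(sc$mds, min(sc$pairs$distance))
  expect_lte(sc$mds, sc$ads)
  expect_equal(nrow(sc$pairs), 3)
  # two targets: ads == mds
  sc2 <- score_candidate(ds[ds$target != "C", ],
                         feature_set = c("f1", "f2"))
  expect_equal(sc2$ads, sc2$mds)
  expect_error(score_candidate(ds[ds$target == "A", ],
                               feature_set = c("f1", "f2")), ">= 2 targets")
  expect_error(score_candidate(ds, feature_set = c("f1", "nope")),
               "missing feature")
})

test_that("MDS <= ADS for random candidates under both distance kinds", {
  set.seed(81)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    ds <- data.frame(target = rep(letters[1:k], each = 8),
                     f1 = rnorm(8 * k, rep(runif(k, 0, 6), each = 8)),
                     f2 = rnorm(8 * k, rep(runif(k, 0, 6), each = 8)))
    for (dk in c("median", "clustering")) {
      sc <- score_candidate(ds, c("f1", "f2"), dk)
      expect_lte(sc$mds, sc$ads)
      if (dk == "clustering")
        expect_true(sc$mds >= -1 && sc$ads <= 1)
    }
  }
})

test_that("ranking: dominance, shared ranks on ties, hand-checked rank sums", {
  s <- data.frame(mix_id = c("PM1", "PM2"), strategy = "S3",
                  ads = c(2, 1), mds = c(1, 0.5))
  r <- rank_candidates(s)
  expect_equal(r$rank[r$mix_id == "PM1"], 1L)
  expect_equal(r$rank[r$mix_id == "PM2"], 2L)
  s2 <- data.frame(mix_id = c("PM1", "PM2"), strategy = "S3",
                   ads = c(2, 2), mds = c(1, 1))
  expect_equal(rank_candidates(s2)$rank, c(1L, 1L))
  # anti-correlated ADS/MDS: hand-computed rank sums
  s3 <- data.frame(mix_id = sprintf("PM%d", 1:4), strategy = "S1",
                   ads = c(4, 3, 2, 1), mds = c(3, 4, 1, 2))
  r3 <- rank_candidates(s3)
  expect_equal(r3$rank[match(sprintf("PM%d", 1:4), r3$mix_id)],
               c(1L, 1L, 3L, 3L))
  expect_error(rank_candidates(data.frame(mix_id = c("a", "b"),
                                          strategy = c("S1", "S3"),
                                          ads = 1:2, mds = 1:2)),
               "one strategy")
})

test_that("S1 and S2 coincide when the feature set is exactly Sc", {
  ov <- simulate_overlap_panel(seed = 3)
  s1 <- score_assays(ov$features, ov$candidates, strategy_config("S1"))
  s2 <- score_assays(ov$features, ov$candidates,
                     strategy_config("S2", feature_set = "Sc"))
  expect_equal(s1$ads, s2$ads, tolerance = 1e-12)
  expect_equal(s1$mds, s2$mds, tolerance = 1e-12)
  expect_equal(s1$rank, s2$rank)
})

test_that("median strategy promotes the overlapping candidate, clustering demotes it", {
  ov <- simulate_overlap_panel(seed = 1)
  bad <- ov$candidates$mix_id[ov$candidates$A == "a2"]
  n <- nrow(ov$candidates)
  s1 <- score_assays(ov$features, ov$candidates, strategy_config("S1"))
  s3 <- score_assays(ov$features, ov$candidates, strategy_config("S3"))
  expect_lte(s1$rank[s1$mix_id == bad], n / 2)
  expect_gt(s3$rank[s3$mix_id == bad], n / 2)
})

test_that("distance_map joins optional accuracies by mix id", {
  ov <- simulate_overlap_panel(seed = 2)
  s3 <- score_assays(ov$features, ov$candidates, strategy_config("S3"))
  dm <- distance_map(s3)
  expect_equal(nrow(dm), nrow(ov$candidates))
  expect_true(all(is.na(dm$accuracy)))
  acc <- data.frame(mix_id = s3$mix_id[1:2], accuracy = c(0.97, 0.91))
  dm2 <- distance_map(s3, acc)
  expect_equal(dm2$accuracy[match(s3$mix_id[1:2], dm2$mix_id)],
               c(0.97, 0.91))
  expect_true(is.na(dm2$accuracy[match(s3$mix_id[3], dm2$mix_id)]))
})
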