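# small helper: cohort with one perfectly separating feature plus noise
separable_study <- function(seed, n_per_class = 10, n_noise = 4) {
  set.seed(seed)
  n <- n_per_class
  tum <- rbind(
    stats::rnorm(n, 4, 0.2),
    matrix(stats::rnorm(n_noise * n), n_noise, n)
  )
  nor <- rbind(
    stats::rnorm(n, 0, 0.2),
    matrix(stats::rnorm(n_noise * n), n_noise, n)
  )
  make_study(tum, nor)
}

test_that("a perfectly separating feature gives near-zero OOB error", {
  errs <- vapply(1:20, function(seed) {
    fm <- fit_forest(
      separable_study(seed),
      forest_config(n_trees = 200, seed = seed)
    )
    fm$oob_error
  }, numeric(1))
  expect_true(all(errs <= 0.05))
})

test_that("signal-free data gives chance-level OOB error", {
  errs <- vapply(1:20, function(seed) {
    set.seed(seed)
    tum <- matrix(stats::rnorm(200), 10, 20)
    nor <- matrix(stats::rnorm(200), 10, 20)
    fm <- fit_forest(make_study(tum, nor), forest_config(n_trees = 500, seed = seed))
    fm$oob_error
  }, numeric(1))
  # per-seed estimates fluctuate binomially around 0.5 (40 voted samples)
  expect_true(all(errs > 0.25 & errs < 0.75))
  expect_gt(mean(errs), 0.35)
  expect_lt(mean(errs), 0.65)
})

test_that("a single tree's OOB set is exactly the held-out subsample", {
  st <- separable_study(1, n_per_class = 8)
  fm <- fit_forest(st, forest_config(n_trees = 1, subsample_fraction = 0.632, seed = 2))
  n <- nrow(fm$X)
  k <- round(0.632 * n)
  oob <- fm$oob[[1]]
  expect_equal(length(oob), n - k)
  expect_true(all(oob >= 1 & oob <= n))
  expect_equal(length(unique(oob)), length(oob))
})

test_that("fits and importances are bit-reproducible for a fixed seed", {
  st <- separable_study(3)
  cfg <- forest_config(n_trees = 50, seed = 9)
  a <- fit_forest(st, cfg)
  b <- fit_forest(st, cfg)
  expect_identical(a$trees, b$trees)
  expect_identical(a$oob, b$oob)
  expect_identical(conditional_mda(a), conditional_mda(b))
})

test_that("OOB error stabilises as the forest grows", {
  st <- separable_study(5, n_per_class = 10, n_noise = 14)
  err_at <- function(n_trees) {
    vapply(1:10, function(seed) {
      fit_forest(st, forest_config(n_trees = n_trees, seed = seed))$oob_error
    }, numeric(1))
  }
  expect_lt(stats::sd(err_at(2000)), stats::sd(err_at(100)))
})

test_that("informative features earn the top MDA rank", {
  top <- vapply(1:20, function(seed) {
    cfg <- generator_config(20, 51,
      noise_sd = 0.25,
      de_plan = data.frame(feature = 1, fold_change = 4), seed = seed
    )
    st <- generate_paired_cohort(cfg)
    fm <- fit_forest(st, forest_config(n_trees = 500, seed = seed))
    imp <- conditional_mda(fm)
    imp$rank[imp$feature_id == "miR-001"]
  }, numeric(1))
  expect_gte(mean(top == 1), 0.95)
})

test_that("pure-noise feature MDA is negligible against the signal's", {
  # raw (unscaled) MDA of a noise feature carries a tiny offset from
  # overfit noise splits — the reference implementation shows the same —
  # so centring is asserted at the scale of the importances
  ratio <- vapply(1:20, function(seed) {
    set.seed(seed + 100)
    tum <- rbind(stats::rnorm(10, 3, 0.3), matrix(stats::rnorm(100), 10, 10))
    nor <- rbind(stats::rnorm(10, 0, 0.3), matrix(stats::rnorm(100), 10, 10))
    st <- make_study(tum, nor)
    fm <- fit_forest(st, forest_config(n_trees = 300, seed = seed))
    imp <- conditional_mda(fm)
    null_mean <- mean(imp$mda[imp$feature_id != "f01"])
    abs(null_mean) / imp$mda[imp$feature_id == "f01"]
  }, numeric(1))
  expect_lt(mean(ratio), 0.1)
})

test_that("null-feature MDA matches the reference implementation's offset", {
  mine <- numeric(10)
  ref <- numeric(10)
  for (seed in 1:10) {
    cfg <- generator_config(20, 31,
      noise_sd = 0.25,
      de_plan = data.frame(feature = 1, fold_change = 4), seed = seed
    )
    st <- generate_paired_cohort(cfg)
    fm <- fit_forest(st, forest_config(n_trees = 500, seed = seed))
    imp <- conditional_mda(fm, conditional_corr_threshold = 1)
    mine[seed] <- mean(imp$mda[imp$feature_id != "miR-001"])
    set.seed(seed)
    rf <- randomForest::randomForest(
      x = fm$X, y = factor(fm$y), ntree = 500, importance = TRUE
    )
    rimp <- randomForest::importance(rf, type = 1, scale = FALSE)
    ref[seed] <- mean(rimp[rownames(rimp) != "miR-001", 1])
  }
  expect_lt(abs(mean(mine) - mean(ref)), 0.005)
})

test_that("conditioning shrinks the importance of a cloned informative feature", {
  diffs <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 15
    sig_t <- stats::rnorm(n, 2, 0.5)
    sig_n <- stats::rnorm(n, 0, 0.5)
    tum <- rbind(sig_t, sig_t + stats::rnorm(n, 0, 0.05), matrix(stats::rnorm(8 * n), 8, n))
    nor <- rbind(sig_n, sig_n + stats::rnorm(n, 0, 0.05), matrix(stats::rnorm(8 * n), 8, n))
    st <- make_study(tum, nor)
    fm <- fit_forest(st, forest_config(n_trees = 300, seed = seed))
    cond <- conditional_mda(fm, conditional_corr_threshold = 0.2)
    uncond <- conditional_mda(fm, conditional_corr_threshold = 1)
    uncond$mda[uncond$feature_id == "f02"] - cond$mda[cond$feature_id == "f02"]
  }, numeric(1))
  expect_gt(mean(diffs), 0) # Strobl correction: conditional < unconditional
  expect_gt(mean(diffs > 0), 0.7)
})

test_that("threshold one means no conditioning variables at all", {
  st <- separable_study(7)
  fm <- fit_forest(st, forest_config(n_trees = 100, seed = 4))
  a <- conditional_mda(fm, conditional_corr_threshold = 1)
  b <- conditional_mda(fm, conditional_corr_threshold = 1.5)
  expect_identical(a, b)
  expect_true(all(is.finite(a$mda)))
  expect_setequal(a$rank, seq_len(ncol(fm$X)))
})

test_that("OOB error agrees with an established forest implementation", {
  st <- separable_study(11, n_per_class = 12, n_noise = 9)
  fm <- fit_forest(st, forest_config(n_trees = 500, seed = 1))
  rf <- randomForest::randomForest(
    x = fm$X, y = factor(fm$y), ntree = 500
  )
  ref_err <- rf$err.rate[500, "OOB"]
  expect_lt(abs(fm$oob_error - ref_err), 0.1)
})

test_that("proximity matrices are symmetric, unit-diagonal and class-aware", {
  st <- separable_study(13)
  fm <- fit_forest(st, forest_config(n_trees = 400, seed = 3))
  for (all_trees in c(FALSE, TRUE)) {
    prox <- proximity_matrix(fm, all_trees = all_trees)
    expect_true(isSymmetric(unname(unclass(prox))))
    expect_equal(unname(diag(prox)), rep(1, nrow(prox)))
    ok <- !is.na(prox)
    expect_true(all(prox[ok] >= 0 & prox[ok] <= 1))
  }
  prox <- proximity_matrix(fm, all_trees = TRUE)
  cls <- fm$y
  within <- mean(prox[cls == 1, cls == 1][upper.tri(diag(sum(cls == 1)))])
  between <- mean(prox[cls == 1, cls == 0])
  expect_gt(within, between)
})

test_that("identical observations share every leaf", {
  tum <- matrix(rep(c(5, 5, 1, 2, 3), 2), 5, 2) # two identical tumour samples
  nor <- matrix(c(0, 0, 1, 2, 3, 0.1, 0.1, 1, 2, 3), 5, 2)
  st <- make_study(tum, nor)
  fm <- fit_forest(st, forest_config(n_trees = 200, subsample_fraction = 0.5, seed = 5))
  prox <- proximity_matrix(fm, all_trees = TRUE)
  expect_equal(unname(prox["P01_T", "P02_T"]), 1)
})

test_that("classical MDS reproduces simple configurations", {
  # all-ones proximity: every point at the origin
  p1 <- matrix(1, 4, 4)
  xy <- mds_embedding(p1, dims = 2)
  expect_equal(unname(xy), matrix(0, 4, 2))
  # two samples, proximity 0: points at distance 1
  p2 <- diag(2) * 1
  p2[1, 2] <- p2[2, 1] <- 0
  diag(p2) <- 1
  xy2 <- mds_embedding(p2, dims = 1)
  expect_equal(unname(abs(xy2[1, 1] - xy2[2, 1])), 1, tolerance = 1e-9)
  # Euclidean-realizable input: embedding distances match within 10%
  set.seed(2)
  pts <- matrix(stats::runif(10 * 2), 10, 2)
  d <- as.matrix(stats::dist(pts))
  d <- d / max(d) # keep dissimilarities in [0, 1]
  prox <- 1 - d
  emb <- mds_embedding(prox, dims = 2)
  d2 <- as.matrix(stats::dist(emb))
  off <- upper.tri(d)
  expect_lt(max(abs(d2[off] - d[off]) / d[off]), 0.1)
  expect_error(mds_embedding(p1, dims = 4), "dims")
})
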