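# Two-stage outlier screening: PCA contracts, Mahalanobis-distance
# properties, the robust MD gate with a hand-computed oracle, the strict
# 0.4% residual gate, and stage assignment on data with known outliers.

test_that("PCA scores are centered with valid variance ratios", {
  set.seed(1)
  X <- matrix(rnorm(200), 20, 10)
  pc <- pca_scores(X, k = 3)
  expect_lt(max(abs(colMeans(pc$scores))), 1e-10)
  evr <- pc$explained_variance_ratio
  expect_true(all(evr >= 0 & evr <= 1))
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-12)

  # exactly collinear data: one component explains everything
  t1 <- rnorm(15)
  X1 <- outer(t1, c(1, 2, 3))
  expect_equal(pca_scores(X1, k = 1)$explained_variance_ratio, 1)

  expect_error(pca_scores(X, k = 10), "k must satisfy")
})

test_that("four components dominate the variance of screened synthetic spectra", {
  ds <- simulate_nir_dataset(synthetic_config(seed = 2))
  pc <- pca_scores(apply_chain("SNV", ds$spectra), k = 4)
  expect_gt(sum(pc$explained_variance_ratio), 0.9)
})

test_that("Mahalanobis distance matches Euclidean under identity covariance
           and is invariant to invertible linear maps", {
  set.seed(3)
  Z <- matrix(rnorm(400), 100, 4)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  # whiten so the sample covariance is exactly the identity
  Zw <- Z %*% t(chol(solve(cov(Z))))
  md <- mahalanobis_distances(Zw)
  eu <- sqrt(rowSums(sweep(Zw, 2, colMeans(Zw))^2))
  expect_equal(as.vector(md), unname(eu), tolerance = 1e-8)

  for (rep in 1:5) {
    A <- matrix(rnorm(16), 4, 4) + diag(4)
    expect_equal(unname(mahalanobis_distances(Zw %*% A)), unname(md),
                 tolerance = 1e-6)
  }

  # duplicated rows get identical distances
  md2 <- mahalanobis_distances(rbind(Zw, Zw))
  expect_equal(unname(md2[1:100]), unname(md2[101:200]), tolerance = 1e-10)
})

test_that("MD gate applies the median + 3*MAD rule", {
  md <- c(1, 1.1, 0.9, 1.2, 0.8, 6.0)
  g <- md_gate(md)
  expect_equal(g$threshold, 1.05 + 3 * 0.15)
  expect_equal(g$flagged, 6L)

  # shifting all distances shifts the threshold, not the flags
  g2 <- md_gate(md + 10)
  expect_equal(g2$threshold, g$threshold + 10)
  expect_equal(g2$flagged, g$flagged)

  expect_warning(g0 <- md_gate(c(1, 1, 1, 1, 10)), "MAD")
  expect_length(g0$flagged, 0)
})

test_that("residual gate uses a strict 0.4% inequality", {
  expect_length(residual_gate(c(9, 10, 11), c(9, 10, 11)), 0)
  flags <- residual_gate(c(0, 0, 0), c(0.39, 0.40, 0.41))
  expect_equal(flags, 3L)
})

test_that("screen assigns injected outliers to their stages", {
  hitS <- hitC <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    ds <- simulate_nir_dataset(synthetic_config(seed = 200 + r))
    set.seed(r)
    idx <- sample(124, 5)
    ds2 <- inject_outliers(ds, spectral_idx = idx[1:2], chemical_idx = idx[3:5])
    scr <- suppressWarnings(screen_outliers(ds2, seed = r))
    hitS <- hitS + mean(idx[1:2] %in% scr$md_flagged)
    hitC <- hitC + mean(idx[3:5] %in% scr$residual_flagged)
    # report invariants
    expect_identical(scr$removed,
                     sort(union(scr$md_flagged, scr$residual_flagged)))
    expect_identical(scr$retained, setdiff(1:124, scr$removed))
    surv <- setdiff(1:124, scr$md_flagged)
    expect_setequal(scr$residual_flagged,
                    surv[abs(scr$residuals[surv]) > 0.4])
  }
  expect_gte(hitS / reps, 0.9)
  expect_gte(hitC / reps, 0.9)
})

test_that("clean synthetic data keeps the expected flag rate low", {
  rates <- vapply(1:12, function(s) {
    ds <- simulate_nir_dataset(synthetic_config(seed = s))
    scr <- suppressWarnings(screen_outliers(ds, seed = s))
    length(scr$removed) / 124
  }, 0)
  expect_lte(mean(rates), 0.10)
})

test_that("gross additive offsets are caught when screening raw spectra", {
  hits <- vapply(1:20, function(r) {
    ds <- simulate_nir_dataset(synthetic_config(seed = 300 + r))
    set.seed(r)
    i <- sample(124, 1)
    ds2 <- inject_outliers(ds, spectral_idx = i, artifact = "offset",
                           spectral_magnitude = 1.0)
    pre <- apply_chain("Original", ds2$spectra)
    md <- mahalanobis_distances(pca_scores(pre, k = 4))
    i %in% md_gate(md)$flagged
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("screening is deterministic and serializable", {
  ds <- simulate_nir_dataset(quick_cfg(seed = 8))
  s1 <- suppressWarnings(screen_outliers(ds, seed = 8, folds = 5))
  s2 <- suppressWarnings(screen_outliers(ds, seed = 8, folds = 5))
  expect_identical(s1$removed, s2$removed)
  expect_identical(s1$md_values, s2$md_values)

  df <- as.data.frame(s1)
  expect_named(df, c("stage", "sample_id"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_outlier_report(s1, path)
  expect_true(file.exists(path))
})
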