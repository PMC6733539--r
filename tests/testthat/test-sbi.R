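test_that("group mask uses the strict group-mean rule", {
  expect_true(all(build_group_mask(matrix(0.31, 4, 10))))
  expect_error(build_group_mask(matrix(0.30, 4, 10)), "empty")
  m <- build_group_mask(rbind(c(0.2, 0.1), c(0.5, 0.2)))  # means 0.35, 0.15
  expect_equal(m, c(TRUE, FALSE))
  expect_error(build_group_mask(matrix(1.2, 2, 2)), "0, 1")
})

test_that("MDL order selection finds planted dimensionality", {
  # rank-1 noiseless stack
  set.seed(1)
  X1 <- outer(rnorm(10), rnorm(500))
  expect_equal(as.integer(estimate_n_components(X1)), 1L)

  # 5 strong planted sources at default conditions
  co <- default_cohort()
  expect_equal(as.integer(estimate_n_components(co$stack)), 5L)

  # pure white noise collapses to low order
  ks <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    as.integer(estimate_n_components(matrix(rnorm(42 * 2000), 42)))
  }, integer(1))
  expect_gte(mean(ks <= 2), 0.9)

  expect_error(estimate_n_components(matrix(1, 2, 5)), "3 subjects")
})

test_that("spatial ICA recovers planted sources and loadings", {
  co <- default_cohort()
  d <- sbi_decompose(co$stack, n_components = 5L, seed = 13L)
  mm <- matched_source_correlations(d, co$truth$true_sources)
  expect_true(all(mm$r > 0.9))
  # loadings of the matched target component track the planted loadings
  tgt_est <- which(mm$assignment == co$truth$target_component)
  expect_gt(abs(cor(d$loadings[, tgt_est],
                    co$truth$true_loadings[, co$truth$target_component])),
            0.95)
  # sources unit variance (population convention), positive skewness
  vv <- rowMeans(d$sources^2) - rowMeans(d$sources)^2
  expect_equal(vv, rep(1, 5), tolerance = 1e-6, ignore_attr = TRUE)
  sk <- apply(d$sources, 1, function(s) mean((s - mean(s))^3))
  expect_true(all(sk > 0))
})

test_that("rank-1 data yields the single planted source up to sign/scale", {
  set.seed(5)
  src <- abs(rnorm(400))^2  # skewed spatial profile
  X <- outer(rnorm(12, 2), src)
  d <- sbi_decompose(X, n_components = 1L, seed = 3L)
  expect_gt(abs(cor(d$sources[1, ], src)), 0.999)
})

test_that("decomposition is deterministic given the seed", {
  co <- default_cohort()
  d1 <- sbi_decompose(co$stack, n_components = 5L, seed = 42L)
  d2 <- sbi_decompose(co$stack, n_components = 5L, seed = 42L)
  expect_identical(d1$sources, d2$sources)
  expect_identical(d1$loadings, d2$loadings)
})

test_that("reconstruction matches the rank-k PCA truncation", {
  co <- default_cohort()
  d <- sbi_decompose(co$stack, n_components = 5L, seed = 13L)
  Xc <- co$stack$maps - rowMeans(co$stack$maps)
  ss_res <- sum((Xc - d$loadings %*% d$sources)^2)
  sv <- svd(Xc, nu = 0, nv = 0)
  pca_res <- sum(sv$d[-(1:5)]^2)
  expect_lte(ss_res, pca_res + 1e-6 * sum(Xc^2))
})

test_that("loading group test gives null results on exchangeable groups", {
  vals <- rep(c(-1, 0, 1, 2), 6)
  d <- fake_decomp(cbind(vals))
  g <- rep(c("AD_MCI", "HC"), each = 12)
  res <- test_loading_group_difference(d, g, n_perm = 199L, seed = 1L)
  expect_lt(abs(res$group_t), 0.8)
  expect_gt(res$group_p_perm, 0.2)

  expect_message(
    res0 <- test_loading_group_difference(fake_decomp(cbind(rep(1, 24))), g,
                                          n_perm = 99L),
    "constant")
  expect_equal(res0$group_t, 0)
  expect_equal(res0$group_p_perm, 1)
})

test_that("permutation p matches the analytic t reference for Gaussian data", {
  set.seed(8)
  y <- rnorm(42)
  y[1:28] <- y[1:28] + 0.6
  d <- fake_decomp(cbind(y))
  g <- rep(c("AD_MCI", "HC"), c(28, 14))
  res <- test_loading_group_difference(d, g, n_perm = 4999L, seed = 2L)
  p_analytic <- 2 * pt(-abs(res$group_t), df = 40)
  expect_lt(abs(res$group_p_perm - p_analytic), 0.02)
})

test_that("gray-matter association recovers exact and null relations", {
  set.seed(6)
  gm <- rnorm(42, 600, 30)
  g <- rep(c("AD_MCI", "HC"), c(28, 14))
  d <- fake_decomp(cbind(-gm))
  res <- test_loading_gm_association(d, gm, g)
  expect_equal(res$gm_r_all, -1, tolerance = 1e-6)
  expect_equal(res$gm_r_patients, -1, tolerance = 1e-6)
  expect_equal(res$gm_r_controls, -1, tolerance = 1e-6)

  # independent loadings: weak association in the patient stratum
  weak <- vapply(1:50, function(s) {
    set.seed(s)
    dd <- fake_decomp(cbind(rnorm(42)))
    rr <- test_loading_gm_association(dd, gm, g)
    abs(rr$gm_r_patients) < 0.4
  }, logical(1))
  expect_gte(mean(weak), 0.9)

  expect_message(
    res2 <- test_loading_gm_association(d, rep(500, 42), g),
    "constant gray matter")
  expect_true(all(is.na(res2$gm_r_all)))
})

test_that("component selection enforces the two-criterion rule", {
  tests <- data.frame(component = 1:5,
                      group_p_perm = c(0.5, 0.3, 0.01, 0.8, 0.2),
                      gm_p_patients = c(0.9, 0.02, 0.003, 0.5, 0.6),
                      gm_r_patients = c(0.1, -0.5, -0.6, 0.2, 0.3))
  expect_equal(select_component(tests), 3L)

  null_tests <- tests
  null_tests$group_p_perm <- rep(0.4, 5)
  expect_error(select_component(null_tests), class = "no_selection_error")

  dual <- tests
  dual$group_p_perm[2] <- 0.02
  expect_error(select_component(dual), class = "ambiguous_selection_error")

  # a qualifying component with positive GM sign must not be selected
  pos <- tests
  pos$gm_r_patients[3] <- 0.6
  expect_error(select_component(pos), class = "no_selection_error")
})

test_that("a dual-effect cohort triggers the ambiguity error end-to-end", {
  co <- default_cohort()
  tr <- co$truth
  # plant a second group-differentiating, atrophy-associated component
  A <- tr$true_loadings
  patient <- as.numeric(co$stack$group == "AD_MCI")
  k2 <- if (tr$target_component == 1L) 2L else 1L
  A[, k2] <- A[, k2] + 1.2 * patient
  maps <- A %*% tr$true_sources
  stack2 <- co$stack
  stack2$maps <- maps
  d <- sbi_decompose(stack2, n_components = 5L, seed = 7L)
  mm <- matched_source_correlations(d, tr$true_sources)
  lt <- A[, tr$target_component] - mean(A[, tr$target_component])
  l2 <- A[, k2] - mean(A[, k2])
  set.seed(30)
  gm <- 620 - 15 * lt * patient - 15 * l2 * patient + rnorm(42, 0, 15)
  gt <- test_loading_group_difference(d, co$stack$group, n_perm = 499L,
                                      seed = 3L)
  gma <- test_loading_gm_association(d, gm, co$stack$group)
  tests <- merge(gt, gma, by = "component")
  expect_error(select_component(tests), class = "ambiguous_selection_error")
})

test_that("Grubbs test matches closed-form and brute-force oracles", {
  expect_equal(grubbs_test(c(1, 2, 3, 4, 50)), 5L)
  expect_length(grubbs_test(c(-2, -1, 0, 1, 2)), 0L)
  expect_message(out <- grubbs_test(c(5, 5, 5, 5)), "zero variance")
  expect_length(out, 0L)

  # brute-force oracle with simulated critical values, n <= 8
  set.seed(99)
  instances <- list(c(1, 2, 3, 4, 50), c(-2, -1, 0, 1, 2),
                    c(0.1, 0.2, 0.15, 9), c(1, 1.1, 0.9, 1.05, 0.95, 30),
                    c(5, 6, 7, 8, 9, 10, 11, 60), rnorm(8),
                    c(-40, 1, 2, 3, 2.5, 1.5, 45))
  for (x in instances)
    expect_equal(grubbs_test(x), grubbs_oracle(x), info = paste(x, collapse = ","))
})
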