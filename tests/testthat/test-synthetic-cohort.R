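test_that("configuration validates counts and encodes the study conditions", {
  cfg <- sim_config()
  expect_equal(cfg$n_patients + cfg$n_controls, 42L)
  expect_equal(cfg$n_timepoints, 263L)  # 269 acquired minus 6 discarded
  expect_equal(cfg$n_nodes, 13L)
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(n_sources = 50), "n_sources")
  expect_error(sim_config(tr_seconds = 0), "tr_seconds")
})

test_that("sources are smooth, compact, near-independent blobs", {
  s1 <- generate_sources(sim_config(n_sources = 1L, n_patients = 4L,
                                    n_controls = 3L,
                                    grid_dims = c(10L, 10L, 10L)))
  expect_equal(nrow(s1), 1L)
  expect_equal(max(s1), 1)          # unit maximum at the center voxel
  expect_true(all(s1 >= 0))

  s5 <- generate_sources(sim_config(seed = 5L))
  expect_equal(dim(s5), c(5L, 8000L))
  C <- cor(t(s5))
  expect_true(all(abs(C[upper.tri(C)]) < 0.2))

  expect_error(generate_sources(sim_config(n_sources = 40L,
                                           n_patients = 30L,
                                           n_controls = 30L,
                                           grid_dims = c(5L, 5L, 5L))),
               "grid too small")
})

test_that("pk maps follow the generative model with the planted group shift", {
  cfg0 <- small_sim_config(map_noise_sd = 0)
  src <- generate_sources(cfg0)
  pk <- generate_pk_maps(src, cfg0)
  recon <- pk$truth$true_loadings %*% src
  expect_equal(pk$stack$maps, recon, tolerance = 1e-12)

  # same seed with and without the group effect: patients shifted by
  # exactly group_effect on the target component, controls untouched
  cfg_a <- small_sim_config(group_effect = 0)
  cfg_b <- small_sim_config(group_effect = 1.0)
  la <- generate_pk_maps(generate_sources(cfg_a), cfg_a)$truth
  lb <- generate_pk_maps(generate_sources(cfg_b), cfg_b)$truth
  k <- la$target_component
  patient <- lb$true_loadings[, k] - la$true_loadings[, k]
  expect_equal(unname(patient[1:8]), rep(1.0, 8))
  expect_equal(unname(patient[9:14]), rep(0, 6))
})

test_that("null group effect produces non-significant loading differences", {
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, group_effect = 0,
                      grid_dims = c(8L, 8L, 8L), n_sources = 2L)
    tr <- generate_pk_maps(generate_sources(cfg), cfg)$truth
    y <- tr$true_loadings[, tr$target_component]
    g <- rep(c(0, 1), c(28, 14))
    t.test(y[g == 0], y[g == 1], var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("connectivity coupling is planted with the designed sign structure", {
  co <- default_cohort()
  w <- co$truth$true_connection_weights
  atlas <- inflammetry:::node_atlas(13L)
  pairs <- inflammetry:::pair_index(13L, atlas$name)
  dmn <- which(atlas$network == "DMN")
  within_dmn <- pairs$i %in% dmn & pairs$j %in% dmn
  expect_true(all(w[within_dmn] < 0))
  hip <- grep("Hipp", atlas$name)
  dmn_hip <- (pairs$i %in% dmn & pairs$j %in% hip)
  expect_true(all(w[dmn_hip] > 0))
  expect_equal(length(w), 78L)
})

test_that("zero coupling leaves connectivity unrelated to loadings", {
  # With n = 42 subjects the null sampling SD of a correlation is ~0.16,
  # so single connections can stray past 0.3; the calibrated property is
  # that the exceedance fraction and mean |r| match the null expectation.
  exceed <- mean_abs <- numeric(3)
  for (i in 1:3) {
    cfg <- sim_config(seed = 300 + i, coupling = 0)
    co <- suppressMessages(simulate_cohort(cfg))
    fc <- t(vapply(co$series, function(ts) connectivity_vector(ts)$r,
                   numeric(78)))
    y <- co$truth$true_loadings[, co$truth$target_component]
    r <- cor(fc, y)
    exceed[i] <- mean(abs(r) >= 0.3)
    mean_abs[i] <- mean(abs(r))
  }
  expect_lt(mean(exceed), 0.15)
  expect_lt(mean(mean_abs), 0.18)
})

test_that("positive planted weight yields positive loading-connectivity association", {
  atlas <- inflammetry:::node_atlas(13L)
  pairs <- inflammetry:::pair_index(13L, atlas$name)
  j <- which(pairs$label == "vACC—lHipp")
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = 600 + s, n_timepoints = 120L,
                      grid_dims = c(8L, 8L, 8L), n_sources = 2L)
    tr <- generate_pk_maps(generate_sources(cfg), cfg)$truth
    series <- suppressMessages(generate_timeseries(tr, cfg))
    fc_j <- vapply(series, function(ts) connectivity_vector(ts)$r[j],
                   numeric(1))
    cor(fc_j, tr$true_loadings[, tr$target_component]) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cognition calibration hits the designed shared-variance fraction", {
  # rank-1 limit: no noise anywhere
  cfg0 <- sim_config(cognition_noise_sd = 0, test_noise_sd = 0)
  g <- factor(rep(c("AD_MCI", "HC"), c(28, 14)), levels = c("AD_MCI", "HC"))
  set.seed(1)
  cg <- generate_cognition(rnorm(42), g, cfg0)
  expect_equal(cognitive_pca(cg)$variance_explained, 1.0, tolerance = 1e-9)

  # default calibration across seeds
  ve <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s)
    set.seed(s)
    cg <- generate_cognition(rnorm(42) + as.numeric(g == "AD_MCI"), g, cfg)
    cognitive_pca(cg)$variance_explained
  }, numeric(1))
  expect_true(all(ve >= 0.75 & ve <= 0.85))
})

test_that("null interaction slope is rejected at the nominal rate only", {
  g <- factor(rep(c("AD_MCI", "HC"), c(28, 14)), levels = c("AD_MCI", "HC"))
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = 700 + s, interaction_slope = 0)
    set.seed(700 + s)
    bs <- rnorm(42) + as.numeric(g == "AD_MCI")
    cg <- generate_cognition(bs, g, cfg)
    comp <- cognitive_pca(cg)
    m <- fit_interaction_model(comp$pc1_scores, bs, g)
    m$terms$p[m$terms$term == "brain_score:group"] < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("written cohorts round-trip through disk", {
  co <- suppressMessages(simulate_cohort(small_sim_config()))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$cohort), 14L)
  expect_equal(dim(back$stack$maps), dim(co$stack$maps))
  expect_equal(back$stack$maps, co$stack$maps, tolerance = 1e-6)  # float32
  expect_equal(back$truth$true_loadings, co$truth$true_loadings,
               ignore_attr = TRUE)
  expect_equal(back$truth$target_component, co$truth$target_component)
  expect_equal(back$series[[3]]$values, co$series[[3]]$values,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_no_error(write_cohort(co, file.path(tempfile(), "a", "b")))
})
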