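grid3 <- function(n = 6L, vs = 2) list(dims = rep(n, 3L),
                                       voxel_size = rep(vs, 3L))

test_that("node extraction returns the sphere's first principal component", {
  gm <- grid3(6L)
  nv <- prod(gm$dims)
  tt <- 40L
  s <- sin(seq_len(tt) / 3)
  # single-voxel sphere: output is that voxel's series, standardized
  vox <- matrix(rnorm(nv * tt), nv, tt)
  center_mm <- (c(3, 3, 3) - 0.5) * 2
  idx <- 3L + 2L * 6L + 2L * 36L  # linear index of voxel (3,3,3)
  one <- extract_node_series(vox, center_mm, radius_mm = 1.0, gm)
  expect_equal(one, as.numeric(scale(vox[idx, ])), tolerance = 1e-8)

  # identical voxels: standardized common series, positively oriented
  out <- extract_node_series(matrix(rep(s, nv), nv, tt, byrow = TRUE),
                             center_mm, radius_mm = 5, gm)
  expect_equal(out, as.numeric(scale(s)), tolerance = 1e-8)
  expect_gt(cor(out, s), 0.999)

  # 60/40 anti-phase mix: sign follows the majority population
  vox3 <- matrix(rep(s, nv), nv, tt, byrow = TRUE)
  nneg <- round(0.4 * nv)
  vox3[seq_len(nneg), ] <- -vox3[seq_len(nneg), ] * 0.9
  out3 <- extract_node_series(vox3, center_mm, radius_mm = 50, gm)
  expect_gt(cor(out3, s), 0)

  expect_error(extract_node_series(vox, c(1e3, 1e3, 1e3), 8, gm,
                                   node_name = "hip"), "hip")
})

test_that("nuisance design holds the documented column set", {
  tt <- 263L
  tr <- 2.43
  # independent enumeration of stop-band DCT frequencies
  k <- 1:(tt - 1)
  f <- k / (2 * tt * tr)
  n_dct <- sum(f < 0.0078 | f > 0.1)
  mp <- matrix(rnorm(tt * 6, sd = 0.1), tt, 6)
  wm <- rnorm(tt)
  csf <- rnorm(tt)
  d <- build_nuisance_design(tt, tr, mp, wm, csf)
  expect_equal(sum(d$labels == "dct"), n_dct)
  expect_equal(sum(d$labels == "intercept"), 1L)
  expect_equal(sum(d$labels == "motion"), 6L)
  expect_equal(sum(d$labels == "motion_derivative"), 6L)
  expect_equal(sum(d$labels == "motion_quadratic"), 12L)
  expect_equal(sum(d$labels %in% c("tissue", "tissue_derivative",
                                   "tissue_quadratic")), 8L)

  # all-zero motion dropped with a message
  expect_message(d0 <- build_nuisance_design(tt, tr, matrix(0, tt, 6)),
                 "all-zero")
  expect_false(any(grepl("motion", d0$labels)))

  expect_error(build_nuisance_design(tt, tr, passband = c(0.05, 0.3)),
               "Nyquist")
})

test_that("cleaning removes stop-band and preserves pass-band signal", {
  tt <- 263L
  tr <- 2.43
  t_sec <- (seq_len(tt) - 1) * tr
  d <- build_nuisance_design(tt, tr)
  mk <- function(x) node_timeseries(rbind(x, rnorm(tt)), tr = tr)

  # a design column regresses to numerical zero
  ts0 <- mk(d$regressors[, 5])
  cl0 <- clean_timeseries(ts0, d)
  expect_lt(max(abs(cl0$values[1, ])), 1e-8)

  # 0.2 Hz (stop band) almost fully removed
  hi <- sin(2 * pi * 0.2 * t_sec)
  cl_hi <- clean_timeseries(mk(hi), d)
  expect_lt(var(cl_hi$values[1, ]) / var(hi), 0.01)

  # 0.05 Hz (pass band) almost fully retained
  lo <- sin(2 * pi * 0.05 * t_sec)
  cl_lo <- clean_timeseries(mk(lo), d)
  expect_gt(var(cl_lo$values[1, ]) / var(lo), 0.95)

  # residuals orthogonal to every design column
  set.seed(4)
  ts <- node_timeseries(matrix(rnorm(3 * tt), 3, tt), tr = tr)
  cl <- clean_timeseries(ts, d)
  cc <- cor(t(cl$values), d$regressors[, d$labels != "intercept"])
  expect_lt(max(abs(cc)), 1e-8)
})

test_that("white noise keeps under 5% relative power outside the passband", {
  tt <- 263L
  tr <- 2.43
  d <- build_nuisance_design(tt, tr)
  set.seed(9)
  cl <- clean_timeseries(node_timeseries(matrix(rnorm(2 * tt), 2, tt),
                                         tr = tr), d)
  pg <- stats::spec.pgram(ts(cl$values[1, ], deltat = tr), taper = 0,
                          plot = FALSE, detrend = FALSE)
  out_band <- pg$freq < 0.0078 | pg$freq > 0.1
  expect_lt(sum(pg$spec[out_band]) / sum(pg$spec), 0.05)
})

test_that("motion summary is the RMS of volume-to-volume displacement", {
  expect_equal(compute_fd_rms(matrix(0, 10, 6)), 0)
  expect_equal(compute_fd_rms(matrix(1.3, 10, 6)), 0)  # constant offset
  m <- matrix(0, 2, 6)
  m[2, 1] <- 1
  expect_equal(compute_fd_rms(m), 1)
  # rotations scale onto the 50 mm sphere
  m2 <- matrix(0, 2, 6)
  m2[2, 4] <- 0.01
  expect_equal(compute_fd_rms(m2), 0.5)
  expect_error(compute_fd_rms(matrix(0, 5, 5)), "6 columns")
})

test_that("connectivity vectors follow the fixed pair order and bounds", {
  set.seed(3)
  tt <- 50L
  v <- matrix(rnorm(13 * tt), 13, tt)
  ts <- node_timeseries(v, tr = 2)
  cv <- connectivity_vector(ts)
  expect_length(cv$r, 78L)
  expect_equal(cv$pair_index$label[1], "node01—node02")
  expect_equal(cv$pair_index$label[78], "node12—node13")
  expect_true(all(abs(cv$r) <= 1))

  v2 <- v
  v2[2, ] <- v2[1, ]
  expect_equal(connectivity_vector(node_timeseries(v2, 2))$r[1], 1)
  s <- sin(seq_len(tt))
  v3 <- rbind(s, -s, rnorm(tt))
  expect_equal(connectivity_vector(node_timeseries(v3, 2))$r[1], -1)
  v4 <- v
  v4[5, ] <- 7
  expect_error(connectivity_vector(node_timeseries(v4, 2)), "node05")
})

test_that("group connectivity statistics detect planted differences", {
  # identical connectivity in both groups
  r_same <- matrix(seq(0.1, 0.5, length.out = 10), 6, 10, byrow = TRUE)
  vecs <- lapply(1:6, function(i)
    structure(list(r = r_same[i, ],
                   pair_index = inflammetry:::pair_index(5),
                   node_names = paste0("n", 1:5)),
              class = "connectivity_vector"))
  gs <- group_connectivity_stats(vecs, rep(c("a", "b"), each = 3))
  expect_true(all(gs$t == 0))
  expect_equal(nrow(gs), 10L)

  # planted z-difference of 1.0 on connection 7 is the top |t| nearly always
  pairs13 <- inflammetry:::pair_index(13)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    z <- matrix(rnorm(42 * 78, sd = 0.3), 42, 78)
    z[1:28, 7] <- z[1:28, 7] + 1.0
    vl <- lapply(1:42, function(i)
      structure(list(r = tanh(z[i, ]), pair_index = pairs13,
                     node_names = paste0("n", 1:13)),
                class = "connectivity_vector"))
    gs <- group_connectivity_stats(vl, rep(c("p", "c"), c(28, 14)))
    which.max(abs(gs$t)) == 7
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(group_connectivity_stats(vecs, rep(c("a", "b"), c(5, 1))),
               "at least 2")
})

test_that("tissue signals average supra-threshold voxels only", {
  v <- rbind(rep(1, 5), rep(3, 5), rep(10, 5))
  expect_equal(tissue_mean_signal(v, c(0.9, 0.8, 0.1)), rep(2, 5))
  expect_error(tissue_mean_signal(v, c(0.1, 0.2, 0.3)), "no voxels")
})
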