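#' Simulation configuration for a synthetic multimodal cohort
#'
#' Encodes the study conditions the analysis assumes: a 28-patient /
#' 14-control cohort, five spatial inflammation sources of which exactly one
#' differentiates the groups, 13 network nodes (5 default-mode, 4
#' frontoparietal, 4 subcortical) observed over 263 usable volumes at a
#' repetition time of 2.43 s, and three cognitive tests whose first
#' principal component carries about 80% of the shared variance.
#'
#' @param n_patients,n_controls group sizes.
#' @param grid_dims integer 3-vector of voxel counts per axis.
#' @param n_sources number of planted spatial sources.
#' @param group_effect shift (in loading SD units) added to the patients'
#'   mean loading on the target component.
#' @param map_noise_sd SD of i.i.d. Gaussian voxel noise added to the
#'   reconstructed binding maps (binding units; sources have unit maximum).
#' @param n_nodes number of network nodes.
#' @param n_timepoints usable fMRI volumes per subject.
#' @param tr_seconds repetition time in seconds.
#' @param coupling slope tying a connection's latent correlation to the
#'   subject's centered target loading (via the planted connection weights).
#' @param interaction_slope cognition units of latent decline per unit of
#'   brain score, applied in patients only (negative: more inflammation-
#'   coupled connectivity, worse cognition).
#' @param cognition_noise_sd SD of subject-level noise on the latent
#'   cognition factor.
#' @param test_noise_sd SD of test-specific noise added to each of the three
#'   standardized cognitive tests. The default sqrt(3/7) makes the pairwise
#'   inter-test correlation 0.7, so the first principal component carries
#'   (1 + 2*0.7)/3 = 80% of the variance in expectation.
#' @param seed master seed; every sub-stream is derived from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 28L, n_controls = 14L,
                       grid_dims = c(20L, 20L, 20L), n_sources = 5L,
                       group_effect = 1.0, map_noise_sd = 0.1,
                       n_nodes = 13L, n_timepoints = 263L,
                       tr_seconds = 2.43, coupling = 0.5,
                       interaction_slope = -0.5, cognition_noise_sd = 0.10,
                       test_noise_sd = sqrt(3 / 7), seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              grid_dims = as.integer(grid_dims),
              n_sources = as.integer(n_sources),
              group_effect = group_effect, map_noise_sd = map_noise_sd,
              n_nodes = as.integer(n_nodes),
              n_timepoints = as.integer(n_timepoints),
              tr_seconds = tr_seconds, coupling = coupling,
              interaction_slope = interaction_slope,
              cognition_noise_sd = cognition_noise_sd,
              test_noise_sd = test_noise_sd, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_patients >= 1L, n_controls >= 1L, n_sources >= 1L,
              n_nodes >= 1L, n_timepoints >= 1L,
              length(grid_dims) == 3L, all(grid_dims >= 1L),
              n_sources <= n_patients + n_controls,
              tr_seconds > 0, map_noise_sd >= 0, cognition_noise_sd >= 0,
              test_noise_sd >= 0)
  })
  structure(cfg, class = "sim_config")
}

# Node names and network assignment. At the canonical 13 nodes: 5 DMN, 4
# FPN, 4 subcortical (bilateral putamen + hippocampus); otherwise networks
# are assigned by thirds with generic names.
node_atlas <- function(n_nodes) {
  if (n_nodes == 13L) {
    data.frame(
      name = c("vACC", "dPCC", "vPCC", "lIPL", "rIPL",
               "lSFG", "rSFG", "lAG", "rAG",
               "lPut", "rPut", "lHipp", "rHipp"),
      network = c(rep("DMN", 5), rep("FPN", 4), rep("SC", 4)),
      stringsAsFactors = FALSE
    )
  } else {
    nets <- rep(c("DMN", "FPN", "SC"), length.out = n_nodes)
    nets <- sort(nets)
    data.frame(name = sprintf("node%02d", seq_len(n_nodes)),
               network = nets, stringsAsFactors = FALSE)
  }
}

# Baseline inter-node correlations: strong within networks, weak between,
# with the DMN-putamen block mildly anticorrelated.
base_correlation <- function(atlas) {
  n <- nrow(atlas)
  R <- matrix(0.05, n, n)
  for (net in unique(atlas$network)) {
    idx <- which(atlas$network == net)
    R[idx, idx] <- if (net == "SC") 0.4 else 0.5
  }
  dmn <- which(atlas$network == "DMN")
  fpn <- which(atlas$network == "FPN")
  R[dmn, fpn] <- R[fpn, dmn] <- 0.15
  put <- grep("Put", atlas$name)
  if (length(put)) R[dmn, put] <- R[put, dmn] <- -0.2
  diag(R) <- 1
  R
}

# Planted connection weights in pair_index() order: positive on
# DMN-hippocampus connections, negative within the DMN, zero elsewhere.
connection_weights <- function(atlas) {
  n <- nrow(atlas)
  pairs <- pair_index(n, atlas$name)
  w <- numeric(nrow(pairs))
  dmn <- which(atlas$network == "DMN")
  hip <- grep("Hipp", atlas$name)
  if (!length(hip)) hip <- which(atlas$network == "SC")
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (i %in% dmn && j %in% dmn) w[k] <- -0.3
    if ((i %in% dmn && j %in% hip) || (i %in% hip && j %in% dmn)) w[k] <- 0.3
  }
  w
}

#' Generate spatially compact, near-independent source maps
#'
#' Each source is a 3-D Gaussian blob (unit maximum, nonnegative) centered
#' at a random voxel; centers are rejected until all pairwise distances
#' exceed five blob SDs, which keeps pairwise spatial correlations well
#' under 0.2.
#'
#' @param config a [sim_config()].
#' @return matrix of `n_sources` rows by `prod(grid_dims)` voxels, with
#'   attributes `centers` (source centers) and `sigma`.
#' @export
generate_sources <- function(config) {
  dims <- config$grid_dims
  k <- config$n_sources
  nv <- prod(dims)
  if (k > nv) stop("grid too small: ", k, " sources requested for ",
                   nv, " voxels")
  sigma <- max(1.5, min(dims) / 10)
  seed <- substream_seed(config$seed, "sources")
  with_local_seed(seed, {
    margin <- pmin(ceiling(sigma), floor((dims - 1) / 2))
    centers <- NULL
    # prefer 5-sigma spacing; relax toward 3 sigma on cramped grids, where
    # the pairwise blob correlation exp(-d^2 / (4 sigma^2)) is still ~0.1
    for (d_min in c(5, 4, 3) * sigma) {
      for (restart in 1:50) {
        centers <- matrix(NA_real_, k, 3)
        ok <- TRUE
        for (s in seq_len(k)) {
          placed <- FALSE
          for (try in 1:200) {
            cand <- vapply(1:3, function(a)
              sample(seq(1 + margin[a], dims[a] - margin[a]), 1), numeric(1))
            if (s == 1 ||
                all(sqrt(colSums((t(centers[seq_len(s - 1), , drop = FALSE]) -
                                 cand)^2)) >= d_min)) {
              centers[s, ] <- cand
              placed <- TRUE
              break
            }
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (ok) break
        centers <- NULL
      }
      if (!is.null(centers)) break
    }
    if (is.null(centers))
      stop("grid too small to place ", k,
           " non-overlapping sources at minimum spacing ", 3 * sigma)
    coords <- as.matrix(expand.grid(x = seq_len(dims[1]),
                                    y = seq_len(dims[2]),
                                    z = seq_len(dims[3])))
    S <- matrix(0, k, nv)
    for (s in seq_len(k)) {
      d2 <- rowSums((coords - matrix(centers[s, ], nv, 3, byrow = TRUE))^2)
      S[s, ] <- exp(-d2 / (2 * sigma^2))
    }
    attr(S, "centers") <- centers
    attr(S, "sigma") <- sigma
    S
  })
}

#' Generate subject PET binding maps from planted sources
#'
#' Applies the generative model maps = loadings x sources + noise. Loadings
#' are standard normal per component; patients additionally receive
#' `group_effect` on the target component, so the planted group-mean
#' difference equals `group_effect` exactly in expectation and the draws are
#' recorded in the returned ground truth.
#'
#' @param sources output of [generate_sources()].
#' @param config a [sim_config()].
#' @return list with `stack` (class `pk_map_stack`: subject x voxel `maps`,
#'   logical `mask`, `grid_meta`, `subject_ids`, `group`) and `truth`
#'   (class `ground_truth`).
#' @export
generate_pk_maps <- function(sources, config) {
  k <- config$n_sources
  stopifnot(nrow(sources) == k)
  n <- config$n_patients + config$n_controls
  group <- factor(rep(c("AD_MCI", "HC"),
                      c(config$n_patients, config$n_controls)),
                  levels = c("AD_MCI", "HC"))
  target <- min(3L, k)
  seed <- substream_seed(config$seed, "pk_maps")
  with_local_seed(seed, {
    loadings <- matrix(stats::rnorm(n * k), n, k)
    loadings[group == "AD_MCI", target] <-
      loadings[group == "AD_MCI", target] + config$group_effect
    maps <- loadings %*% sources
    if (config$map_noise_sd > 0)
      maps <- maps + matrix(stats::rnorm(length(maps),
                                         sd = config$map_noise_sd),
                            nrow(maps), ncol(maps))
    subject_ids <- sprintf("sub-%02d", seq_len(n))
    atlas <- node_atlas(config$n_nodes)
    stack <- structure(list(
      maps = maps,
      mask = rep(TRUE, ncol(sources)),
      grid_meta = list(dims = config$grid_dims,
                       voxel_size = c(2, 2, 2),
                       affine = diag(c(2, 2, 2, 1))),
      subject_ids = subject_ids,
      group = group
    ), class = "pk_map_stack")
    truth <- structure(list(
      true_sources = sources,
      true_loadings = loadings,
      target_component = target,
      true_connection_weights = connection_weights(atlas) * 1.0,
      true_interaction_slope = config$interaction_slope
    ), class = "ground_truth")
    list(stack = stack, truth = truth)
  })
}

#' Generate node time-series with loading-coupled connectivity
#'
#' Each subject's latent inter-node correlation for connection j is
#' base_r(j) + coupling * weight(j) * centered target loading, clipped to
#' (-0.95, 0.95). Time points are i.i.d. draws from a multivariate normal
#' with that correlation matrix (connectivity estimates, not temporal
#' dynamics, are what the downstream analysis consumes). Non-positive-
#' definite matrices after clipping are repaired to the nearest correlation
#' matrix and the repair is logged.
#'
#' @param truth a `ground_truth` from [generate_pk_maps()].
#' @param config a [sim_config()].
#' @return list of per-subject `node_timeseries` objects.
#' @export
generate_timeseries <- function(truth, config) {
  atlas <- node_atlas(config$n_nodes)
  base_R <- base_correlation(atlas)
  pairs <- pair_index(config$n_nodes, atlas$name)
  w <- truth$true_connection_weights
  load_c <- truth$true_loadings[, truth$target_component]
  load_c <- load_c - mean(load_c)
  n <- length(load_c)
  seed <- substream_seed(config$seed, "timeseries")
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      R <- base_R
      r_ij <- R[cbind(pairs$i, pairs$j)] + config$coupling * w * load_c[i]
      r_ij <- pmin(pmax(r_ij, -0.95), 0.95)
      R[cbind(pairs$i, pairs$j)] <- r_ij
      R[cbind(pairs$j, pairs$i)] <- r_ij
      ch <- tryCatch(chol(R), error = function(e) NULL)
      if (is.null(ch)) {
        message("subject ", i,
                ": latent correlation not positive definite; ",
                "applying nearest-correlation repair")
        R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
        ch <- chol(R)
      }
      Z <- matrix(stats::rnorm(config$n_timepoints * config$n_nodes),
                  config$n_timepoints, config$n_nodes)
      X <- Z %*% ch  # time x node
      node_timeseries(t(X), tr = config$tr_seconds, node_names = atlas$name)
    })
  })
}

#' Generate three cognitive test scores from a latent cognition factor
#'
#' The latent factor is baseline minus a fixed patient deficit, plus
#' `interaction_slope` times brain score in patients only, plus Gaussian
#' noise; it is standardized across the sample and observed through three
#' tests (MMSE-, ACE-R- and RAVLT-like scales) with test-specific noise
#' calibrated so the first principal component of the standardized tests
#' carries about 80% of the variance.
#'
#' @param brain_score_truth per-subject brain-score values (typically the
#'   planted target-component loadings).
#' @param group factor with levels `AD_MCI`, `HC`.
#' @param config a [sim_config()].
#' @return data.frame with columns `MMSE`, `ACER`, `RAVLT` and attribute
#'   `latent` (the standardized latent factor).
#' @export
generate_cognition <- function(brain_score_truth, group, config) {
  n <- length(brain_score_truth)
  stopifnot(length(group) == n)
  patient <- as.numeric(group == "AD_MCI")
  bs_c <- brain_score_truth - mean(brain_score_truth)
  seed <- substream_seed(config$seed, "cognition")
  with_local_seed(seed, {
    g <- -1.5 * patient + config$interaction_slope * bs_c * patient +
      stats::rnorm(n, sd = config$cognition_noise_sd)
    g_std <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0
    tau <- config$test_noise_sd
    E <- matrix(stats::rnorm(n * 3), n, 3)
    if (tau > 0 && n >= 8L) {
      # orthogonalize the test noises against the latent factor (and each
      # other) in-sample, so the realized inter-test correlation is exactly
      # 1/(1 + tau^2) and the PC1 variance fraction is exactly its design
      # value rather than fluctuating with the draw
      E <- qr.Q(qr(cbind(1, g_std, E)))[, 3:5, drop = FALSE]
      E <- sweep(E, 2, apply(E, 2, stats::sd), `/`)
    }
    obs <- vapply(1:3, function(j) g_std + tau * E[, j], numeric(n))
    out <- data.frame(
      MMSE  = 27 + 2.0 * obs[, 1],
      ACER  = 85 + 8.0 * obs[, 2],
      RAVLT = 5  + 3.5 * obs[, 3]
    )
    attr(out, "latent") <- g_std
    out
  })
}

#' Simulate a complete multimodal cohort
#'
#' Convenience wrapper chaining [generate_sources()], [generate_pk_maps()],
#' [generate_timeseries()] and [generate_cognition()], and drawing
#' demographic covariates (age, sex, education, motion, total gray matter).
#' Total gray matter declines with the target loading in patients, planting
#' the atrophy association the component-selection rule requires.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `stack`, `truth`, `series`, `cohort`
#'   (the cohort table as a data.frame).
#' @export
simulate_cohort <- function(config = sim_config()) {
  sources <- generate_sources(config)
  pk <- generate_pk_maps(sources, config)
  series <- generate_timeseries(pk$truth, config)
  group <- pk$stack$group
  n <- length(group)
  patient <- as.numeric(group == "AD_MCI")
  load_target <- pk$truth$true_loadings[, pk$truth$target_component]
  cog <- generate_cognition(load_target, group, config)
  seed <- substream_seed(config$seed, "covariates")
  covars <- with_local_seed(seed, {
    age <- ifelse(patient == 1, stats::rnorm(n, 72.7, 8.5),
                  stats::rnorm(n, 68.3, 5.4))
    sex <- ifelse(stats::runif(n) < ifelse(patient == 1, 12 / 28, 8 / 14),
                  "F", "M")
    education <- round(pmax(8, stats::rnorm(n, ifelse(patient == 1,
                                                      12.9, 14.1), 3)))
    motion_rms <- exp(stats::rnorm(n, log(0.15), 0.4))
    load_c <- load_target - mean(load_target)
    total_gm <- 620 - 20 * load_c * patient + stats::rnorm(n, 0, 20)
    data.frame(age = age, sex = sex, education = education,
               motion_rms = motion_rms, total_gm = total_gm)
  })
  cohort <- data.frame(
    subject_id = pk$stack$subject_ids,
    group = as.character(group),
    age = covars$age, sex = covars$sex, education = covars$education,
    MMSE = cog$MMSE, ACER = cog$ACER, RAVLT = cog$RAVLT,
    motion_rms = covars$motion_rms, total_gm = covars$total_gm,
    stringsAsFactors = FALSE
  )
  list(config = config, stack = pk$stack, truth = pk$truth,
       series = series, cohort = cohort)
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI volume per subject map (float32), one TSV per subject
#' time-series (nodes as columns), the cohort table as CSV, planted source
#' maps as NIfTI, and the remaining ground truth as JSON. Re-reading
#' reproduces all arrays within float32 storage precision (the TSV, CSV and
#' JSON round-trip exactly).
#'
#' @param cohort output of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a character vector of all files written.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  map_dir <- file.path(out_dir, "maps")
  ts_dir <- file.path(out_dir, "timeseries")
  dir.create(map_dir, showWarnings = FALSE)
  dir.create(ts_dir, showWarnings = FALSE)
  dims <- cohort$stack$grid_meta$dims
  files <- character(0)
  for (i in seq_along(cohort$stack$subject_ids)) {
    vol <- array(cohort$stack$maps[i, ], dim = dims)
    f <- file.path(map_dir, paste0(cohort$stack$subject_ids[i], "_pk.nii"))
    RNifti::writeNifti(RNifti::asNifti(vol, datatype = "float"), f)
    files <- c(files, f)
  }
  for (i in seq_along(cohort$series)) {
    ts <- cohort$series[[i]]
    df <- as.data.frame(t(ts$values))
    names(df) <- ts$node_names
    f <- file.path(ts_dir, paste0(cohort$stack$subject_ids[i], "_ts.tsv"))
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  f_cohort <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort$cohort, f_cohort, row.names = FALSE)
  for (s in seq_len(nrow(cohort$truth$true_sources))) {
    vol <- array(cohort$truth$true_sources[s, ], dim = dims)
    f <- file.path(out_dir, sprintf("truth_source_%02d.nii", s))
    RNifti::writeNifti(RNifti::asNifti(vol, datatype = "float"), f)
    files <- c(files, f)
  }
  f_truth <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(
    true_loadings = cohort$truth$true_loadings,
    target_component = cohort$truth$target_component,
    true_connection_weights = cohort$truth$true_connection_weights,
    true_interaction_slope = cohort$truth$true_interaction_slope,
    tr_seconds = cohort$config$tr_seconds
  ), f_truth, digits = NA, auto_unbox = TRUE)
  invisible(c(files, f_cohort, f_truth))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param out_dir directory previously passed to [write_cohort()].
#' @return list with `stack`, `series`, `cohort`, `truth` (loadings etc.
#'   from the ground-truth JSON).
#' @export
read_cohort <- function(out_dir) {
  f_cohort <- file.path(out_dir, "cohort.csv")
  if (!file.exists(f_cohort)) stop("no cohort.csv under ", out_dir)
  tab <- utils::read.csv(f_cohort, stringsAsFactors = FALSE)
  map_files <- sort(list.files(file.path(out_dir, "maps"),
                               pattern = "_pk\\.nii$", full.names = TRUE))
  stack <- read_nifti_stack(map_files)
  stack$subject_ids <- sub("_pk\\.nii$", "", basename(map_files))
  stack$group <- factor(tab$group, levels = c("AD_MCI", "HC"))
  truth_file <- file.path(out_dir, "ground_truth.json")
  truth <- if (file.exists(truth_file)) {
    tr <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
    tr$true_loadings <- as.matrix(tr$true_loadings)
    tr
  } else NULL
  ts_files <- sort(list.files(file.path(out_dir, "timeseries"),
                              pattern = "_ts\\.tsv$", full.names = TRUE))
  tr_sec <- if (!is.null(truth)) truth$tr_seconds else NA_real_
  series <- lapply(ts_files, function(f) read_timeseries_tsv(f, tr = tr_sec))
  list(stack = stack, series = series, cohort = tab, truth = truth)
}
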