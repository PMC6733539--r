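#' Node time-series container
#'
#' @param values node x time numeric matrix.
#' @param tr repetition time in seconds.
#' @param node_names optional node labels (defaults to node01, ...).
#' @return object of class `node_timeseries`.
#' @export
node_timeseries <- function(values, tr, node_names = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("time-series contains missing values")
  if (nrow(values) < 2L) stop("need at least 2 nodes")
  if (ncol(values) < 10L) stop("need at least 10 time points")
  if (is.null(node_names)) node_names <- sprintf("node%02d", seq_len(nrow(values)))
  stopifnot(length(node_names) == nrow(values), tr > 0)
  structure(list(values = values, tr = tr, node_names = node_names),
            class = "node_timeseries")
}

# Read a TSV written by write_cohort (nodes as columns, header row).
read_timeseries_tsv <- function(path, tr) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  node_timeseries(t(as.matrix(df)), tr = tr, node_names = names(df))
}

# Read 6-column realignment parameters (whitespace-delimited text,
# translations in mm then rotations in radians, SPM convention).
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion parameter file must have 6 columns, got ",
                          ncol(m))
  unname(m)
}

#' Extract a node time-series as the first principal component of a sphere
#'
#' Voxels within `radius_mm` of the node center are collected and the first
#' right singular vector of the centered voxel x time matrix is returned,
#' sign-oriented to correlate positively with the sphere's mean signal and
#' scaled to unit variance.
#'
#' @param voxel_series voxel x time matrix covering the whole grid, voxel
#'   order fastest-varying first axis.
#' @param node_center length-3 mm coordinates of the node.
#' @param radius_mm sphere radius in mm (default 8, the conventional node
#'   sphere).
#' @param grid_meta list with `dims` (voxel counts) and `voxel_size`
#'   (mm per voxel, length 3); voxel centers are at (index - 0.5) * size.
#' @param node_name label used in error messages.
#' @return numeric time vector, unit variance.
#' @export
extract_node_series <- function(voxel_series, node_center, radius_mm = 8,
                                grid_meta, node_name = "node") {
  dims <- grid_meta$dims
  vs <- grid_meta$voxel_size
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]),
                                  y = seq_len(dims[2]),
                                  z = seq_len(dims[3])))
  mm <- sweep(coords - 0.5, 2, vs, `*`)
  d2 <- rowSums(sweep(mm, 2, node_center, `-`)^2)
  in_sphere <- which(d2 <= radius_mm^2)
  if (!length(in_sphere))
    stop("empty sphere for node '", node_name, "' at radius ", radius_mm,
         " mm")
  V <- voxel_series[in_sphere, , drop = FALSE]  # voxel x time
  mean_sig <- colMeans(V)
  if (nrow(V) == 1L) {
    pc <- as.numeric(V[1, ])
  } else {
    Vc <- V - rowMeans(V)
    sv <- svd(t(Vc), nu = 1, nv = 0)  # time x voxel; u = temporal PC
    pc <- as.numeric(sv$u[, 1])
  }
  if (stats::sd(pc) == 0) stop("degenerate sphere signal for node '",
                               node_name, "'")
  if (stats::cor(pc, mean_sig) < 0) pc <- -pc
  as.numeric(scale(pc))
}

#' Build the nuisance-plus-bandpass design matrix
#'
#' One design for simultaneous nuisance regression and bandpass filtering:
#' intercept, linear trend, the 24-parameter motion expansion (6 realignment
#' parameters, their first differences, and the squares of those 12), white
#' matter and CSF mean signals with their first differences and squares, and
#' a discrete cosine basis restricted to frequencies outside the passband
#' (below the low cut and above the high cut, up to Nyquist) so that
#' regressing the design out removes the stop-band.
#'
#' All-zero blocks (e.g. no motion available) are dropped with a message.
#'
#' @param n_timepoints number of volumes.
#' @param tr repetition time in seconds.
#' @param motion_params optional time x 6 realignment matrix (mm, radians).
#' @param wm_signal,csf_signal optional tissue mean signals.
#' @param passband low/high frequency cut in Hz (default c(0.0078, 0.1)).
#' @return list of class `nuisance_design` with `regressors` (time x
#'   regressor matrix) and `labels`.
#' @export
build_nuisance_design <- function(n_timepoints, tr, motion_params = NULL,
                                  wm_signal = NULL, csf_signal = NULL,
                                  passband = c(0.0078, 0.1)) {
  T <- as.integer(n_timepoints)
  nyquist <- 1 / (2 * tr)
  if (passband[1] <= 0 || passband[2] >= nyquist || passband[1] >= passband[2])
    stop("passband must lie strictly inside (0, Nyquist = ",
         signif(nyquist, 4), " Hz)")
  cols <- list(intercept = rep(1, T),
               trend = seq_len(T) - (T + 1) / 2)
  labels <- c("intercept", "trend")
  add_block <- function(block, label, cols, labels) {
    keep <- apply(block, 2, function(x) any(x != 0))
    if (!all(keep))
      message("dropping ", sum(!keep), " all-zero '", label, "' column(s)")
    if (any(keep)) {
      cols[[length(cols) + 1L]] <- block[, keep, drop = FALSE]
      labels <- c(labels, rep(label, sum(keep)))
    }
    list(cols = cols, labels = labels)
  }
  if (!is.null(motion_params)) {
    mp <- as.matrix(motion_params)
    if (nrow(mp) != T) stop("motion parameters have ", nrow(mp),
                            " rows, expected ", T)
    if (ncol(mp) != 6L) stop("motion parameters must have 6 columns")
    dmp <- rbind(0, diff(mp))
    for (blk in list(list(mp, "motion"), list(dmp, "motion_derivative"),
                     list(mp^2, "motion_quadratic"),
                     list(dmp^2, "motion_quadratic"))) {
      res <- add_block(blk[[1]], blk[[2]], cols, labels)
      cols <- res$cols; labels <- res$labels
    }
  }
  tissue <- cbind(wm = wm_signal, csf = csf_signal)
  if (!is.null(tissue) && ncol(tissue)) {
    if (nrow(tissue) != T) stop("tissue signals have wrong length")
    dt <- rbind(0, diff(tissue))
    for (blk in list(list(tissue, "tissue"), list(dt, "tissue_derivative"),
                     list(tissue^2, "tissue_quadratic"),
                     list(dt^2, "tissue_quadratic"))) {
      res <- add_block(blk[[1]], blk[[2]], cols, labels)
      cols <- res$cols; labels <- res$labels
    }
  }
  dct <- dct_stopband_basis(T, tr, passband)
  if (ncol(dct)) {
    cols[[length(cols) + 1L]] <- dct
    labels <- c(labels, rep("dct", ncol(dct)))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- make.unique(labels, sep = "_")
  structure(list(regressors = X, labels = labels, tr = tr,
                 passband = passband),
            class = "nuisance_design")
}

#' Discrete cosine basis columns outside a passband
#'
#' DCT-II basis function k (k >= 1) over T volumes has frequency
#' f_k = k / (2 * T * TR). Columns with f_k below the low cut or above the
#' high cut are returned; regressing them out implements the bandpass.
#'
#' @inheritParams build_nuisance_design
#' @return time x column matrix (possibly zero columns), with attribute
#'   `frequencies`.
#' @export
dct_stopband_basis <- function(n_timepoints, tr, passband = c(0.0078, 0.1)) {
  T <- as.integer(n_timepoints)
  k <- seq_len(T - 1L)
  f <- k / (2 * T * tr)
  sel <- k[f < passband[1] | f > passband[2]]
  t_idx <- seq_len(T) - 1L
  B <- vapply(sel, function(kk) cos(pi * kk * (2 * t_idx + 1) / (2 * T)),
              numeric(T))
  B <- matrix(B, nrow = T)
  attr(B, "frequencies") <- sel / (2 * T * tr)
  B
}

#' Regress the nuisance design out of every node series
#'
#' A single least-squares regression per node on all design columns
#' (nuisance and stop-band DCT together), returning residuals. Rank-deficient
#' designs are reduced to a maximal independent column set with a message
#' listing dropped labels; residuals are orthogonal to every retained column.
#'
#' @param ts a [node_timeseries()].
#' @param design a `nuisance_design` from [build_nuisance_design()].
#' @return a cleaned `node_timeseries`.
#' @export
clean_timeseries <- function(ts, design) {
  X <- design$regressors
  if (nrow(X) != ncol(ts$values))
    stop("design rows (", nrow(X), ") != time length (", ncol(ts$values), ")")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- design$labels[q$pivot[(q$rank + 1L):ncol(X)]]
    message("rank-deficient design; dropping columns: ",
            paste(unique(dropped), collapse = ", "))
  }
  res <- t(qr.resid(q, t(ts$values)))
  node_timeseries(res, tr = ts$tr, node_names = ts$node_names)
}

#' Root-mean-square volume-to-volume displacement
#'
#' Scalar head-motion summary: per volume pair, the Euclidean displacement
#' combining translation differences (mm) and rotation differences
#' (radians converted to arc length on a 50 mm sphere); the RMS over all
#' pairs is returned.
#'
#' @param motion_params time x 6 matrix, translations (mm) in columns 1-3,
#'   rotations (radians) in columns 4-6.
#' @param radius_mm rotation-to-displacement radius (default 50 mm).
#' @return nonnegative scalar (mm).
#' @export
compute_fd_rms <- function(motion_params, radius_mm = 50) {
  m <- as.matrix(motion_params)
  if (ncol(m) != 6L) stop("motion parameters must have 6 columns, got ",
                          ncol(m))
  if (nrow(m) < 2L) stop("need at least 2 volumes")
  d <- diff(m)
  d[, 4:6] <- d[, 4:6] * radius_mm
  disp <- sqrt(rowSums(d^2))
  sqrt(mean(disp^2))
}

#' Per-subject pairwise Pearson connectivity
#'
#' Upper-triangle correlations in fixed lexicographic pair order
#' ((1,2), (1,3), ..., (2,3), ...).
#'
#' @param ts a cleaned [node_timeseries()].
#' @return object of class `connectivity_vector`: list with `r`,
#'   `pair_index` (data.frame i, j, label), `node_names`.
#' @export
connectivity_vector <- function(ts) {
  v <- ts$values
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0))
    stop("constant node series: ",
         paste(ts$node_names[sds == 0], collapse = ", "))
  C <- stats::cor(t(v))
  pairs <- pair_index(nrow(v), ts$node_names)
  structure(list(r = C[cbind(pairs$i, pairs$j)], pair_index = pairs,
                 node_names = ts$node_names),
            class = "connectivity_vector")
}

# Stack per-subject connectivity vectors into a subject x connection matrix.
connectivity_matrix <- function(vectors) {
  r <- t(vapply(vectors, function(v) v$r, numeric(length(vectors[[1]]$r))))
  colnames(r) <- vectors[[1]]$pair_index$label
  r
}

#' Univariate group connectivity statistics
#'
#' Per connection: the overall mean correlation, and the two-sample pooled t
#' on Fisher z-transformed correlations between groups, with unadjusted and
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param vectors list of per-subject `connectivity_vector`s.
#' @param group_labels factor/character with two levels; the t contrast is
#'   first level minus second level.
#' @return data.frame with one row per connection: `label`, `mean_r`, `t`,
#'   `p`, `p_fdr`.
#' @export
group_connectivity_stats <- function(vectors, group_labels) {
  R <- connectivity_matrix(vectors)
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("need exactly two groups")
  if (any(table(g) < 2L)) stop("each group needs at least 2 subjects")
  Z <- atanh(pmin(pmax(R, -0.999999), 0.999999))
  i1 <- g == levels(g)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  m1 <- colMeans(Z[i1, , drop = FALSE])
  m2 <- colMeans(Z[!i1, , drop = FALSE])
  v1 <- apply(Z[i1, , drop = FALSE], 2, stats::var)
  v2 <- apply(Z[!i1, , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tval[sp2 == 0 & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(tval), n1 + n2 - 2)
  data.frame(label = colnames(R), mean_r = colMeans(R), t = tval, p = p,
             p_fdr = stats::p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Mean signal over voxels of a tissue class
#'
#' Average time-series over voxels whose tissue probability exceeds the
#' threshold (conventionally 0.7 for white matter and CSF nuisance signals).
#'
#' @param voxel_series voxel x time matrix.
#' @param tissue_prob per-voxel probability in [0, 1].
#' @param threshold inclusion threshold (strict).
#' @return numeric time vector.
#' @export
tissue_mean_signal <- function(voxel_series, tissue_prob, threshold = 0.7) {
  stopifnot(length(tissue_prob) == nrow(voxel_series),
            all(tissue_prob >= 0 & tissue_prob <= 1))
  sel <- tissue_prob > threshold
  if (!any(sel)) stop("no voxels above tissue probability ", threshold)
  colMeans(voxel_series[sel, , drop = FALSE])
}
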