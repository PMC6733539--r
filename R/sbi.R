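#' Group gray-matter mask
#'
#' A voxel enters the analysis mask iff the across-subject mean gray-matter
#' probability strictly exceeds the threshold (0.3 by convention). This
#' reconciles per-subject probability maps into one group mask.
#'
#' @param gm_prob_maps subject x voxel matrix of tissue probabilities.
#' @param threshold inclusion threshold on the group mean (strict).
#' @return logical voxel vector.
#' @export
build_group_mask <- function(gm_prob_maps, threshold = 0.3) {
  m <- as.matrix(gm_prob_maps)
  if (any(m < 0 | m > 1)) stop("tissue probabilities must lie in [0, 1]")
  mask <- colMeans(m) > threshold
  if (!any(mask)) stop("empty gray-matter mask at threshold ", threshold)
  mask
}

#' Estimate the number of independent components by MDL
#'
#' Minimum-description-length order selection on the eigenspectrum of the
#' subject-space covariance (the form conventional in group-ICA order
#' selection): for each candidate order k the code length combines the
#' log ratio of geometric to arithmetic mean of the trailing eigenvalues
#' with a parameter-count penalty; the argmin over k = 1..n_subjects-1 is
#' returned.
#'
#' @param stack a `pk_map_stack` (or any subject x voxel matrix).
#' @return integer component count, with attribute `mdl` (the criterion
#'   values).
#' @export
estimate_n_components <- function(stack) {
  X <- if (inherits(stack, "pk_map_stack")) stack$maps else as.matrix(stack)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 subjects")
  v <- ncol(X)
  Xc <- X - rowMeans(X)
  lambda <- sort(eigen(tcrossprod(Xc) / v, symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  eps <- max(lambda[1], 1) * 1e-12
  lambda <- pmax(lambda, eps)
  if (diff(range(lambda)) / lambda[1] < 1e-10) {
    warning("degenerate (flat) eigenspectrum; returning 1 component")
    out <- 1L
    attr(out, "mdl") <- rep(NA_real_, n - 1L)
    return(out)
  }
  ks <- seq_len(n - 1L)
  mdl <- vapply(ks, function(k) {
    tail_l <- lambda[(k + 1):n]
    geo <- mean(log(tail_l))
    ari <- log(mean(tail_l))
    -v * (n - k) * (geo - ari) + 0.5 * k * (2 * n - k + 1) * log(v)
  }, numeric(1))
  out <- which.min(mdl)
  attr(out, "mdl") <- mdl
  out
}

# Fixed-point (logcosh contrast, deflation) ICA on whitened data.
# Z: k x v whitened matrix (unit-variance uncorrelated rows over voxels).
# Returns the orthogonal unmixing matrix W (k x k) with S = W %*% Z.
fastica_deflation <- function(Z, max_iter = 500L, tol = 1e-8) {
  k <- nrow(Z)
  v <- ncol(Z)
  W <- matrix(0, k, k)
  for (comp in seq_len(k)) {
    w <- stats::rnorm(k)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      u <- drop(w %*% Z)
      gu <- tanh(u)
      g1u <- 1 - gu^2
      w_new <- Z %*% gu / v - mean(g1u) * w
      if (comp > 1L) {
        prev <- W[seq_len(comp - 1L), , drop = FALSE]
        w_new <- w_new - t(prev) %*% (prev %*% w_new)
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < 1e-12) { w_new <- stats::rnorm(k); nrm <- sqrt(sum(w_new^2)) }
      w_new <- w_new / nrm
      conv <- abs(abs(sum(w_new * w)) - 1) < tol
      w <- drop(w_new)
      if (conv) break
    }
    if (it == max_iter) return(NULL)  # non-convergence; caller retries
    W[comp, ] <- w
  }
  W
}

#' Source-based inflammetry: spatial ICA of subject binding maps
#'
#' Decomposes the subject x voxel matrix into spatially independent sources
#' and a subject x component mixing (loading) matrix: maps are row-centered,
#' PCA-whitened to `n_components` in subject space, rotated by fixed-point
#' ICA (logcosh contrast, deflation), and loadings are recovered by least
#' squares, so the rank-k reconstruction equals the PCA truncation. Each
#' source is scaled to unit variance over masked voxels and sign-fixed so
#' its skewness is positive (higher loading = higher binding in the
#' source's hot spots). Deterministic given `seed`; on non-convergence two
#' fallback seeds are tried before erroring.
#'
#' @param stack a `pk_map_stack` (masked subject x voxel matrix inside).
#' @param n_components number of sources (< n_subjects); default from
#'   [estimate_n_components()].
#' @param seed RNG seed for the ICA initial vectors.
#' @return object of class `source_decomposition`: `sources` (component x
#'   voxel), `loadings` (subject x component), `n_components`, `row_means`,
#'   `selected` (NULL until [select_component()]).
#' @export
sbi_decompose <- function(stack, n_components = NULL, seed = 1L) {
  X <- if (inherits(stack, "pk_map_stack")) stack$maps else as.matrix(stack)
  n <- nrow(X)
  if (is.null(n_components)) n_components <- as.integer(estimate_n_components(X))
  k <- as.integer(n_components)
  if (k >= n) stop("n_components must be smaller than the number of subjects")
  rmeans <- rowMeans(X)
  Xc <- X - rmeans
  v <- ncol(Xc)
  sv <- svd(Xc, nu = k, nv = 0)
  d <- sv$d[seq_len(k)]
  if (any(d < 1e-10 * max(sv$d)))
    stop("requested more components than the data's effective rank")
  # whitened subject-space projection: rows unit variance over voxels
  Z <- t(sv$u[, seq_len(k), drop = FALSE]) %*% Xc
  Z <- Z / sqrt(rowMeans(Z^2))
  W <- NULL
  for (s_try in c(seed, seed + 1000L, seed + 2000L)) {
    W <- with_local_seed(s_try, fastica_deflation(Z))
    if (!is.null(W)) break
  }
  if (is.null(W)) stop("ICA failed to converge after fallback seeds")
  S <- W %*% Z
  # unit variance + positive skewness per source; loadings by least squares
  sds <- sqrt(rowMeans(S^2) - rowMeans(S)^2)
  S <- S / sds
  sk <- rowMeans((S - rowMeans(S))^3)
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip
  A <- Xc %*% t(S) %*% solve(tcrossprod(S))
  colnames(A) <- rownames(S) <- sprintf("IC%d", seq_len(k))
  structure(list(sources = S, loadings = A, n_components = k,
                 row_means = rmeans, selected = NULL,
                 subject_ids = if (inherits(stack, "pk_map_stack"))
                   stack$subject_ids else rownames(X)),
            class = "source_decomposition")
}

#' Group difference of component loadings (robust permutation test)
#'
#' Per component, a Huber-type robust regression of loading on a patient
#' indicator gives the group t; its two-sided p-value comes from `n_perm`
#' random label shuffles of the robust t. The group contrast is
#' patients minus controls.
#'
#' @param decomp a `source_decomposition`.
#' @param group_labels factor/character; patients are the `AD_MCI` level
#'   (or the first level if no such level exists).
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return data.frame, one row per component: `component`, `group_t`,
#'   `group_p_perm`.
#' @export
test_loading_group_difference <- function(decomp, group_labels,
                                          n_perm = 10000L, seed = 1L) {
  A <- decomp$loadings
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("need exactly two groups")
  if (any(table(g) < 3L)) stop("each group needs at least 3 subjects")
  patient_level <- if ("AD_MCI" %in% levels(g)) "AD_MCI" else levels(g)[1]
  ind <- as.numeric(g == patient_level)
  n <- length(ind)
  X <- cbind(1, ind)
  with_local_seed(seed, {
    res <- lapply(seq_len(ncol(A)), function(j) {
      y <- A[, j]
      if (stats::sd(y) < 1e-12) {
        message("component ", j, ": constant loadings; p set to 1")
        return(list(t = 0, p = 1))
      }
      t_obs <- huber_t(X, y)
      t_perm <- vapply(seq_len(n_perm), function(b)
        huber_t(cbind(1, ind[sample.int(n)]), y), numeric(1))
      list(t = t_obs,
           p = (1 + sum(abs(t_perm) >= abs(t_obs))) / (n_perm + 1))
    })
    data.frame(component = seq_len(ncol(A)),
               group_t = vapply(res, `[[`, numeric(1), "t"),
               group_p_perm = vapply(res, `[[`, numeric(1), "p"))
  })
}

#' Association of component loadings with total gray matter
#'
#' Robust regression of loading on total gray-matter volume in all subjects,
#' patients only and controls only. The reported r-equivalent is
#' sign(slope) * sqrt(t^2 / (t^2 + df)). Strata with fewer than 4 subjects
#' or degenerate gray-matter variance are skipped with a message.
#'
#' @param decomp a `source_decomposition`.
#' @param total_gm per-subject total gray-matter values.
#' @param group_labels factor/character with a patient level `AD_MCI`.
#' @return data.frame, one row per component: `component`, then
#'   `gm_r_all`, `gm_p_all`, `gm_r_patients`, `gm_p_patients`,
#'   `gm_r_controls`, `gm_p_controls` (NA where a stratum was skipped).
#' @export
test_loading_gm_association <- function(decomp, total_gm, group_labels) {
  A <- decomp$loadings
  g <- factor(group_labels)
  stopifnot(length(total_gm) == nrow(A), length(g) == nrow(A))
  patient_level <- if ("AD_MCI" %in% levels(g)) "AD_MCI" else levels(g)[1]
  strata <- list(all = rep(TRUE, nrow(A)),
                 patients = g == patient_level,
                 controls = g != patient_level)
  out <- data.frame(component = seq_len(ncol(A)))
  for (sname in names(strata)) {
    sel <- strata[[sname]]
    r_col <- p_col <- rep(NA_real_, ncol(A))
    if (sum(sel) < 4L) {
      message("stratum '", sname, "' has fewer than 4 subjects; skipped")
    } else if (stats::sd(total_gm[sel]) < 1e-12) {
      message("stratum '", sname, "' has constant gray matter; skipped")
    } else {
      gm <- total_gm[sel]
      X <- cbind(1, gm)
      for (j in seq_len(ncol(A))) {
        f <- huber_lm(X, A[sel, j])
        tv <- f$t[2]
        r_col[j] <- if (is.finite(tv))
          sign(f$coefficients[2]) * sqrt(tv^2 / (tv^2 + f$df))
        else sign(f$coefficients[2])  # exact fit: |r| = 1
        p_col[j] <- f$p[2]
      }
    }
    out[[paste0("gm_r_", sname)]] <- r_col
    out[[paste0("gm_p_", sname)]] <- p_col
  }
  out
}

#' Select the group-differentiating, atrophy-associated component
#'
#' A component qualifies iff its loading group difference is significant at
#' `alpha` and its patient-stratum gray-matter association is significant at
#' `alpha` with negative sign. Exactly one component must qualify; zero
#' raises a `no_selection_error`, several an `ambiguous_selection_error`.
#'
#' @param tests merged component-test table (columns `group_p_perm`,
#'   `gm_p_patients`, `gm_r_patients`), e.g. the merge of
#'   [test_loading_group_difference()] and [test_loading_gm_association()].
#' @param alpha significance level.
#' @return integer component index.
#' @export
select_component <- function(tests, alpha = 0.05) {
  ok <- !is.na(tests$group_p_perm) & tests$group_p_perm < alpha &
    !is.na(tests$gm_p_patients) & tests$gm_p_patients < alpha &
    !is.na(tests$gm_r_patients) & tests$gm_r_patients < 0
  hits <- tests$component[ok]
  if (length(hits) == 0L)
    stop(errorCondition(
      "no component is both group-differentiating and atrophy-associated",
      class = c("no_selection_error", "error", "condition")))
  if (length(hits) > 1L)
    stop(errorCondition(
      paste("multiple qualifying components:",
            paste(hits, collapse = ", ")),
      class = c("ambiguous_selection_error", "error", "condition")))
  hits
}

#' Iterative two-sided Grubbs outlier test
#'
#' At each pass, G = max |x_i - mean| / sd is compared with the
#' t-quantile-based critical value at level `alpha`; the most extreme point
#' is flagged and removed, and the test repeats until no point exceeds the
#' critical value.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level.
#' @return integer vector of flagged indices into `values` (possibly
#'   empty), in flagging order.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  x <- as.numeric(values)
  if (length(x) < 3L) stop("Grubbs test needs at least 3 values")
  if (stats::sd(x) < 1e-12) {
    message("zero variance; no outliers flagged")
    return(integer(0))
  }
  idx <- seq_along(x)
  flagged <- integer(0)
  while (length(x) >= 3L && stats::sd(x) > 1e-12) {
    n <- length(x)
    dev <- abs(x - mean(x)) / stats::sd(x)
    G <- max(dev)
    tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (G <= crit) break
    worst <- which.max(dev)
    flagged <- c(flagged, idx[worst])
    x <- x[-worst]
    idx <- idx[-worst]
  }
  flagged
}
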