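#' Ledoit-Wolf well-conditioned covariance estimator
#'
#' Analytic shrinkage of the sample covariance toward a scaled identity:
#' Sigma* = rho * mu * I + (1 - rho) * S, with mu the mean diagonal of S and
#' rho in [0, 1] chosen to minimize expected Frobenius loss. The result is
#' symmetric positive definite for any n >= 2 and never worse conditioned
#' than S.
#'
#' @param X subject x variable matrix.
#' @param rho optional fixed shrinkage intensity in [0, 1]; by default the
#'   analytic optimum is used.
#' @return list with `sigma` (p x p), `rho`, `mu` and the sample covariance
#'   `sample` (MLE, divisor n).
#' @export
shrinkage_covariance <- function(X, rho = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("need at least 2 subjects")
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  if (is.null(rho)) {
    # squared Frobenius distances scaled by 1/p (Ledoit-Wolf 2004 norms)
    d2 <- sum((S - diag(mu, p))^2) / p
    if (d2 < .Machine$double.eps) {
      rho <- 0
    } else {
      sq_norms <- rowSums(Xc^2)
      b2bar <- (sum(sq_norms^2) / p - n * sum(S^2) / p) / n^2
      rho <- min(b2bar, d2) / d2
    }
  } else {
    stopifnot(rho >= 0, rho <= 1)
  }
  sigma <- (1 - rho) * S + diag(rho * mu, p)
  list(sigma = sigma, rho = rho, mu = mu, sample = S)
}

#' Cross-validation configuration for the first-level model
#'
#' @param k_folds folds per partition (default 5).
#' @param n_repeats random re-partitions (default 1000; the median R over
#'   repeats is the reported statistic).
#' @param seed RNG seed.
#' @param shrinkage "analytic" for the Ledoit-Wolf optimum, or a fixed
#'   value in [0, 1].
#' @return list of class `cv_config`.
#' @export
cv_config <- function(k_folds = 5L, n_repeats = 1000L, seed = 1L,
                      shrinkage = "analytic") {
  stopifnot(k_folds >= 2L, n_repeats >= 1L)
  if (!identical(shrinkage, "analytic"))
    stopifnot(is.numeric(shrinkage), shrinkage >= 0, shrinkage <= 1)
  structure(list(k_folds = as.integer(k_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), shrinkage = shrinkage),
            class = "cv_config")
}

rho_arg <- function(shrinkage) if (identical(shrinkage, "analytic")) NULL else shrinkage

# Drop constant connectivity columns with a message; returns kept indices.
nonconstant_columns <- function(X) {
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    labs <- colnames(X)[sds == 0]
    if (is.null(labs)) labs <- which(sds == 0)
    message("dropping constant connection column(s): ",
            paste(labs, collapse = ", "))
  }
  which(sds > 0)
}

#' First-level shrinkage-regularized multiple linear regression
#'
#' Regresses the selected-component loadings on whole-brain connectivity:
#' connections are z-scored across subjects, the regression weights are
#' (regularized covariance)^-1 times the predictor-loading cross-covariance,
#' brain scores are the fitted linear combination of connections, and each
#' connection's structure coefficient is its Pearson correlation with the
#' brain scores.
#'
#' @param fc subject x connection matrix.
#' @param loadings per-subject component loadings (the response).
#' @param config a [cv_config()] (only the `shrinkage` field is used here).
#' @return object of class `crossmodal_result` with `coefficients`,
#'   `structure_coefficients`, `brain_scores`, `insample_r`, `rho`,
#'   `kept_connections`; CV fields are filled by [cross_validate()].
#' @export
fit_shrinkage_mlr <- function(fc, loadings, config = cv_config()) {
  X <- as.matrix(fc)
  y <- as.numeric(loadings)
  stopifnot(nrow(X) == length(y))
  keep <- nonconstant_columns(X)
  X <- X[, keep, drop = FALSE]
  n <- nrow(X)
  Xs <- scale(X)
  sc <- shrinkage_covariance(Xs, rho = rho_arg(config$shrinkage))
  cxy <- crossprod(Xs, y - mean(y)) / n
  w <- solve(sc$sigma, cxy)
  scores <- drop(Xs %*% w)
  struct <- drop(stats::cor(X, scores))
  coefs <- drop(w)
  names(coefs) <- names(struct) <- colnames(X)
  structure(list(coefficients = coefs, structure_coefficients = struct,
                 brain_scores = scores,
                 insample_r = stats::cor(scores, y),
                 rho = sc$rho, kept_connections = keep,
                 cv_r_distribution = NULL, cv_r_median = NULL,
                 model_p = NULL, significant_connections = NULL),
            class = "crossmodal_result")
}

# Precompute, for every (repeat, fold), the linear map from training
# responses to held-out predictions. Out-of-fold predictions are linear in
# y because the Ledoit-Wolf covariance of the predictors does not involve
# the response; this is what makes matched-repeats permutation tests cheap.
cv_hat_blocks <- function(X, k_folds, n_repeats, seed, shrinkage) {
  n <- nrow(X)
  if (n < 2L * k_folds) {
    sizes <- table(rep(seq_len(k_folds), length.out = n))
    if (any(sizes < 2L)) stop("a fold would have fewer than 2 subjects")
  }
  with_local_seed(seed, {
    lapply(seq_len(n_repeats), function(rep_i) {
      fold_of <- sample(rep(seq_len(k_folds), length.out = n))
      lapply(seq_len(k_folds), function(f) {
        te <- which(fold_of == f)
        tr <- which(fold_of != f)
        if (length(te) < 2L || length(tr) < 2L)
          stop("a fold would have fewer than 2 subjects")
        mu <- colMeans(X[tr, , drop = FALSE])
        sds <- apply(X[tr, , drop = FALSE], 2, stats::sd)
        sds[sds == 0] <- 1  # constant-in-fold column carries no signal
        Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sds, `/`)
        Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sds, `/`)
        sc <- shrinkage_covariance(Xtr, rho = rho_arg(shrinkage))
        H <- Xte %*% solve(sc$sigma, t(Xtr)) / length(tr)
        list(test = te, train = tr, H = H)
      })
    })
  })
}

# R (Pearson r of pooled out-of-fold predictions vs observed) for each
# column of Y, for each repeat. Returns n_repeats x ncol(Y).
cv_r_matrix <- function(blocks, Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  res <- vapply(blocks, function(rep_blocks) {
    P <- matrix(0, n, ncol(Y))
    for (b in rep_blocks) {
      ytr <- Y[b$train, , drop = FALSE]
      ytr <- sweep(ytr, 2, colMeans(ytr))
      P[b$test, ] <- b$H %*% ytr
    }
    diag_cor(P, Y)
  }, numeric(ncol(Y)))
  if (ncol(Y) == 1L) matrix(res, ncol = 1L) else t(res)
}

# columnwise cor(P[,j], Y[,j]) without forming the full cross matrix
diag_cor <- function(P, Y) {
  Pc <- sweep(P, 2, colMeans(P))
  Yc <- sweep(Y, 2, colMeans(Y))
  num <- colSums(Pc * Yc)
  den <- sqrt(colSums(Pc^2) * colSums(Yc^2))
  out <- num / den
  out[den == 0] <- 0
  out
}

#' Repeated k-fold cross-validation of the first-level model
#'
#' For each repetition the subjects are randomly partitioned into k folds;
#' per fold the model is fitted on the training subjects only (including
#' the standardization parameters), the held-out subjects are predicted,
#' and R is the Pearson correlation between the pooled out-of-fold
#' predictions and the observed loadings. The distribution over repetitions
#' and its median are returned; deterministic given the seed.
#'
#' @inheritParams fit_shrinkage_mlr
#' @param config a [cv_config()].
#' @return list with `cv_r_distribution` (length `n_repeats`) and
#'   `cv_r_median`.
#' @export
cross_validate <- function(fc, loadings, config = cv_config()) {
  X <- as.matrix(fc)
  y <- as.numeric(loadings)
  keep <- nonconstant_columns(X)
  X <- X[, keep, drop = FALSE]
  blocks <- cv_hat_blocks(X, config$k_folds, config$n_repeats,
                          config$seed, config$shrinkage)
  r <- drop(cv_r_matrix(blocks, matrix(y, ncol = 1)))
  list(cv_r_distribution = r, cv_r_median = stats::median(r))
}

#' Permutation significance of the first-level model and connection map
#'
#' Model-level p: the observed cross-validated median R is compared with its
#' distribution under `n_perm` random shuffles of the loadings, each shuffle
#' re-cross-validated with the same fold partitions and number of repeats
#' (one-sided: larger R is more significant). Connection-level p: each
#' structure coefficient is compared two-sidedly with its permutation
#' distribution from the full-sample fit, then Benjamini-Hochberg corrected
#' across connections at `alpha`.
#'
#' @inheritParams fit_shrinkage_mlr
#' @param n_perm number of label permutations (a warning is logged below
#'   100).
#' @param alpha FDR level for the connection map.
#' @param seed RNG seed for the permutations.
#' @return a completed `crossmodal_result` (fields `cv_r_distribution`,
#'   `cv_r_median`, `model_p`, `structure_p`, `structure_p_fdr`,
#'   `significant_connections`).
#' @export
significance_and_thresholding <- function(fc, loadings,
                                          config = cv_config(),
                                          n_perm = 5000L, alpha = 0.05,
                                          seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse permutation p")
  X <- as.matrix(fc)
  y <- as.numeric(loadings)
  fit <- fit_shrinkage_mlr(X, y, config)
  X <- X[, fit$kept_connections, drop = FALSE]
  n <- nrow(X)
  blocks <- cv_hat_blocks(X, config$k_folds, config$n_repeats,
                          config$seed, config$shrinkage)
  Yperm <- with_local_seed(seed,
    vapply(seq_len(n_perm), function(b) y[sample.int(n)], numeric(n)))
  r_obs <- drop(cv_r_matrix(blocks, matrix(y, ncol = 1)))
  cv_med <- stats::median(r_obs)
  r_perm <- cv_r_matrix(blocks, Yperm)           # n_repeats x n_perm
  med_perm <- apply(r_perm, 2, stats::median)
  model_p <- (1 + sum(med_perm >= cv_med)) / (n_perm + 1)
  # permutation distribution of structure coefficients (full-sample fit)
  Xs <- scale(X)
  sc <- shrinkage_covariance(Xs, rho = rho_arg(config$shrinkage))
  G <- Xs %*% solve(sc$sigma, t(Xs)) / n          # scores = G %*% centered y
  Pscore <- G %*% sweep(Yperm, 2, colMeans(Yperm))
  struct_perm <- stats::cor(X, Pscore)            # p x n_perm
  s_obs <- fit$structure_coefficients
  struct_p <- vapply(seq_along(s_obs), function(j)
    (1 + sum(abs(struct_perm[j, ]) >= abs(s_obs[j]))) / (n_perm + 1),
    numeric(1))
  p_fdr <- stats::p.adjust(struct_p, "BH")
  fit$cv_r_distribution <- r_obs
  fit$cv_r_median <- cv_med
  fit$model_p <- model_p
  fit$structure_p <- struct_p
  fit$structure_p_fdr <- p_fdr
  fit$significant_connections <- which(p_fdr < alpha)
  fit
}

# Residualize columns of M on covariates (with intercept); returns the
# residual matrix. Used when covariates of no interest are removed before
# the first-level fit.
residualize <- function(M, covariates) {
  M <- as.matrix(M)
  C <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  q <- qr(C)
  qr.resid(q, M)
}

#' Full first-level analysis: outlier screen, covariates, fit, CV, inference
#'
#' Applies the Grubbs outlier screen to the loadings (flagged subjects are
#' excluded with a message), optionally residualizes both connectivity and
#' loadings on covariates of no interest, then runs [fit_shrinkage_mlr()],
#' [cross_validate()] and [significance_and_thresholding()].
#'
#' @inheritParams significance_and_thresholding
#' @param covariates optional data.frame of covariates of no interest
#'   (regressed out of predictors and response before the fit).
#' @param grubbs_alpha level for the outlier screen (NULL disables it).
#' @return a `crossmodal_result` with additional fields `excluded_subjects`
#'   and `included` (logical index into the input rows).
#' @export
crossmodal_analysis <- function(fc, loadings, covariates = NULL,
                                config = cv_config(), n_perm = 5000L,
                                alpha = 0.05, grubbs_alpha = 0.05,
                                seed = 1L) {
  X <- as.matrix(fc)
  y <- as.numeric(loadings)
  excluded <- integer(0)
  if (!is.null(grubbs_alpha)) {
    excluded <- grubbs_test(y, alpha = grubbs_alpha)
    if (length(excluded))
      message("excluding outlying loading(s) at subject index: ",
              paste(excluded, collapse = ", "))
  }
  included <- setdiff(seq_along(y), excluded)
  X <- X[included, , drop = FALSE]
  y <- y[included]
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)[included, , drop = FALSE]
    X <- residualize(X, cv)
    y <- drop(residualize(matrix(y, ncol = 1), cv))
  }
  res <- significance_and_thresholding(X, y, config = config,
                                       n_perm = n_perm, alpha = alpha,
                                       seed = seed)
  res$excluded_subjects <- excluded
  res$included <- included
  res
}
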