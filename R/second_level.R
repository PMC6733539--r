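#' Cognitive composite: first principal component of three test scores
#'
#' PCA on z-scored MMSE, ACE-R and RAVLT columns. The first component is
#' returned with its sign fixed so all three loadings are nonnegative
#' (higher composite = better cognition), together with the fraction of
#' variance it explains.
#'
#' @param scores subject x 3 data.frame or matrix (MMSE, ACER, RAVLT order
#'   assumed if unnamed).
#' @return object of class `cognitive_composite`: `pc1_scores`,
#'   `loadings` (unit norm), `variance_explained`.
#' @export
cognitive_pca <- function(scores) {
  M <- as.matrix(scores)
  stopifnot(ncol(M) == 3L)
  if (nrow(M) < 4L) stop("need at least 4 subjects")
  if (anyNA(M)) stop("missing values in cognitive scores")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(M)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant cognitive test: ", paste(nm, collapse = ", "))
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  if (sum(load1) < 0) load1 <- -load1
  if (any(load1 < -1e-8))
    warning("first-component loadings are not all of one sign; ",
            "sign fixed by the loading sum")
  scores1 <- drop(scale(M) %*% load1)
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  structure(list(pc1_scores = scores1, loadings = load1,
                 variance_explained = ve,
                 all_variances = pc$sdev^2 / sum(pc$sdev^2)),
            class = "cognitive_composite")
}

#' Second-level brain-score x group interaction model
#'
#' Robust (Huber IRLS) regression of the cognitive composite on centered
#' brain scores, a patient indicator, their interaction, and covariates of
#' no interest (age, sex, motion, total gray matter). Brain scores are
#' centered before forming the interaction so the main effect and
#' interaction are decorrelated; group is coded patients = 1, controls = 0.
#'
#' @param composite per-subject cognitive composite (e.g.
#'   `cognitive_pca(...)$pc1_scores`).
#' @param brain_scores per-subject first-level brain scores.
#' @param group factor/character; patients are level `AD_MCI` (or the first
#'   level).
#' @param covariates optional data.frame (numeric columns and/or factors).
#' @param robust logical; FALSE gives ordinary least squares.
#' @return object of class `second_level_result`: data.frame `terms` with
#'   estimate, se, t, p per term, plus `df` and the fit object.
#' @export
fit_interaction_model <- function(composite, brain_scores, group,
                                  covariates = NULL, robust = TRUE) {
  y <- as.numeric(composite)
  bs <- as.numeric(brain_scores)
  g <- factor(group)
  stopifnot(length(y) == length(bs), length(y) == length(g))
  if (nlevels(g) != 2L) stop("both groups must be represented")
  patient_level <- if ("AD_MCI" %in% levels(g)) "AD_MCI" else levels(g)[1]
  ind <- as.numeric(g == patient_level)
  bs_c <- bs - mean(bs)
  X <- cbind(intercept = 1, brain_score = bs_c, group = ind,
             `brain_score:group` = bs_c * ind)
  if (!is.null(covariates)) {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                    drop = FALSE]
    X <- cbind(X, C)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("perfectly collinear design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  fit <- if (robust) huber_lm(X, y) else {
    f <- stats::lm.fit(X, y)
    res <- y - X %*% f$coefficients
    df <- length(y) - ncol(X)
    s2 <- sum(res^2) / df
    se <- sqrt(s2 * diag(chol2inv(chol(crossprod(X)))))
    tv <- f$coefficients / se
    list(coefficients = f$coefficients, se = se, t = tv,
         p = 2 * stats::pt(-abs(tv), df), df = df,
         residuals = as.numeric(res))
  }
  terms <- data.frame(term = colnames(X),
                      estimate = fit$coefficients, se = fit$se,
                      t = fit$t, p = fit$p, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, df = fit$df, robust = robust, fit = fit),
            class = "second_level_result")
}

#' Within-group correlations between composite and brain scores
#'
#' Pearson r and two-sided p within each group; groups with fewer than 4
#' subjects raise an error, degenerate variance skips the group with a
#' message.
#'
#' @inheritParams fit_interaction_model
#' @return data.frame with one row per group: `group`, `n`, `r`, `p`.
#' @export
within_group_correlations <- function(composite, brain_scores, group) {
  y <- as.numeric(composite)
  bs <- as.numeric(brain_scores)
  g <- factor(group)
  out <- lapply(levels(g), function(lev) {
    sel <- g == lev
    n <- sum(sel)
    if (n < 4L) stop("group '", lev, "' has fewer than 4 subjects")
    if (stats::sd(y[sel]) < 1e-12 || stats::sd(bs[sel]) < 1e-12) {
      message("group '", lev, "': degenerate variance; skipped")
      return(data.frame(group = lev, n = n, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(bs[sel], y[sel])
    data.frame(group = lev, n = n, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}

#' Amyloid PET positivity from cortical ROI SUVR values
#'
#' Positive iff the mean standardized uptake value ratio across the
#' supplied cortical ROIs strictly exceeds 1.5.
#'
#' @param roi_suvr numeric vector of ROI SUVR values (all > 0).
#' @param threshold positivity threshold (default 1.5, strict).
#' @return "positive" or "negative".
#' @export
amyloid_status <- function(roi_suvr, threshold = 1.5) {
  if (!length(roi_suvr)) stop("no ROI SUVR values supplied")
  stopifnot(all(roi_suvr > 0))
  if (mean(roi_suvr) > threshold) "positive" else "negative"
}

#' Cohort summary table with group tests
#'
#' Per continuous variable: group means, SDs and ranges plus the
#' pooled-variance two-sample t and p; per categorical variable: a
#' chi-squared test. The same pooled t is available directly from published
#' summary statistics via [pooled_t_summary()].
#'
#' @param table cohort data.frame with a `group` column.
#' @param continuous,categorical variable names; defaults cover the
#'   standard cohort table.
#' @return data.frame with one row per variable.
#' @export
cohort_summary <- function(table,
                           continuous = intersect(
                             c("age", "education", "MMSE", "ACER", "RAVLT",
                               "motion_rms", "total_gm"), names(table)),
                           categorical = intersect("sex", names(table))) {
  g <- factor(table$group)
  if (nlevels(g) != 2L) stop("need two groups")
  if (any(table(g) < 2L)) stop("each group needs at least 2 subjects")
  lev <- levels(g)
  rows <- lapply(continuous, function(v) {
    x1 <- table[[v]][g == lev[1]]
    x2 <- table[[v]][g == lev[2]]
    tt <- pooled_t_summary(mean(x1), stats::sd(x1), length(x1),
                           mean(x2), stats::sd(x2), length(x2))
    data.frame(variable = v, test = "t",
               group1 = sprintf("%.1f (±%.1f, %.1f–%.1f)", mean(x1),
                                stats::sd(x1), min(x1), max(x1)),
               group2 = sprintf("%.1f (±%.1f, %.1f–%.1f)", mean(x2),
                                stats::sd(x2), min(x2), max(x2)),
               statistic = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  cat_rows <- lapply(categorical, function(v) {
    tab <- table(table[[v]], g)
    ct <- suppressWarnings(stats::chisq.test(tab))
    data.frame(variable = v, test = "chisq",
               group1 = paste(tab[, 1], collapse = "/"),
               group2 = paste(tab[, 2], collapse = "/"),
               statistic = unname(ct$statistic), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, cat_rows))
  attr(out, "groups") <- lev
  out
}
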