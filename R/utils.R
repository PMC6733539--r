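#' Derive a per-stage substream seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed. Each stage
#' draws from its own substream whose seed is a deterministic hash of the
#' master seed and the stage name, so adding or reordering stages never
#' perturbs another stage's stream.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name (e.g. "simulate", "sbi").
#' @return an integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  # djb2-style rolling hash over the stage name, folded with the master
  # seed; all arithmetic kept under 2^53 so doubles stay exact
  h <- 5381
  for (b in utf8ToInt(stage)) h <- (h * 33 + b) %% 2147483647
  as.integer((h + as.numeric(master_seed) %% 2147483647 * 48271) %%
               2147483647)
}

# Evaluate expr under a local RNG stream seeded with `seed`, restoring the
# caller's global RNG state afterwards. Keeps stages off the global stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Pooled-variance two-sample t statistic from summary statistics
#'
#' Computes the independent-samples t statistic (equal-variance pooling)
#' directly from group means, standard deviations and sizes, so published
#' summary tables can be checked without raw data.
#'
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations.
#' @param n1,n2 group sizes (each >= 2).
#' @return list with `t`, `df` and two-sided `p`.
#' @examples
#' pooled_t_summary(91.6, 5.3, 14, 78.9, 7.7, 28)$t  # ~5.5
#' @export
pooled_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (mean1 - mean2) / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Match estimated components to reference components
#'
#' Exact assignment maximizing the total absolute correlation between
#' estimated and reference components (brute force over permutations for
#' k <= 8, greedy beyond), used to align ICA output with planted sources.
#'
#' @param abs_cor k x k matrix of absolute correlations, rows = estimated,
#'   columns = reference.
#' @return integer vector: `out[i]` is the reference column assigned to
#'   estimated component i.
#' @export
match_components <- function(abs_cor) {
  k <- nrow(abs_cor)
  stopifnot(ncol(abs_cor) == k)
  if (k <= 8L) {
    perms <- permutations_of(k)
    best <- NULL
    best_sum <- -Inf
    for (i in seq_len(nrow(perms))) {
      p <- perms[i, ]
      s <- sum(abs_cor[cbind(seq_len(k), p)])
      if (s > best_sum) {
        best_sum <- s
        best <- p
      }
    }
    best
  } else {
    # greedy fallback: repeatedly take the largest remaining entry
    assign <- integer(k)
    m <- abs_cor
    for (step in seq_len(k)) {
      ij <- arrayInd(which.max(m), dim(m))
      assign[ij[1]] <- ij[2]
      m[ij[1], ] <- -Inf
      m[, ij[2]] <- -Inf
    }
    assign
  }
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  idx <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      out[idx, ] <- append(sub[i, ], k, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

# Upper-triangle pair index in fixed lexicographic order by node index:
# (1,2), (1,3), ..., (1,n), (2,3), ...
pair_index <- function(n_nodes, node_names = NULL) {
  pairs <- t(utils::combn(n_nodes, 2))
  colnames(pairs) <- c("i", "j")
  if (is.null(node_names)) node_names <- paste0("node", seq_len(n_nodes))
  data.frame(
    i = pairs[, 1], j = pairs[, 2],
    label = paste0(node_names[pairs[, 1]], "—", node_names[pairs[, 2]]),
    stringsAsFactors = FALSE
  )
}
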