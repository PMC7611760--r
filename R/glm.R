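#' Permutation-tested linear models of motif scores on covariates
#'
#' An ordinary-least-squares model relates one outcome per fit (e.g. the
#' scores of one shape motif) to an intercept plus z-transformed covariates
#' (e.g. cycle amplitude, cycle duration, movement speed). Significance of
#' each covariate is assessed nonparametrically: the covariate of interest
#' is row-shuffled on its own, holding the rest of the design fixed, the
#' model refitted, and the observed |t| compared to the permuted |t| null.
#'
#' @name shape-glm
NULL

#' Build an intercept-plus-z-scored design matrix
#'
#' Covariates are z-transformed with the population (1/n) standard
#' deviation.
#'
#' @param covariates Named list (or data frame) of equal-length numeric
#'   vectors, each with nonzero variance.
#' @return A numeric matrix `n x (1 + length(covariates))` with an
#'   `intercept` column of ones followed by the z-scored covariates.
#' @export
build_design <- function(covariates) {
  covariates <- as.list(covariates)
  stopifnot(length(covariates) >= 1L, !is.null(names(covariates)))
  n <- length(covariates[[1L]])
  cols <- lapply(names(covariates), function(nm) {
    v <- as.numeric(covariates[[nm]])
    if (length(v) != n) stop("covariate lengths differ")
    if (anyNA(v)) stop("missing values in covariate '", nm, "'")
    s <- sqrt(mean((v - mean(v))^2))
    if (s < .Machine$double.eps * 100) {
      stop("zero-variance covariate '", nm, "'")
    }
    (v - mean(v)) / s
  })
  out <- cbind(1, do.call(cbind, cols))
  colnames(out) <- c("intercept", names(covariates))
  out
}

#' Ordinary least squares fit with t statistics
#'
#' @param design Design matrix (first column intercept), `n x p`, `n > p`.
#' @param y Outcome vector.
#' @return A list with `betas` and `t_stats` (named by design column);
#'   residual variance uses `n - p` degrees of freedom.
#' @export
fit_glm <- function(design, y) {
  x <- as.matrix(design)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(y) == n, n > p)
  qr_x <- qr(x)
  if (qr_x$rank < p) stop("rank-deficient design matrix")
  beta <- qr.coef(qr_x, y)
  res <- y - x %*% beta
  sigma2 <- sum(res^2) / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(xtx_inv))
  t_stats <- as.numeric(beta) / se
  names(t_stats) <- colnames(x)
  list(betas = stats::setNames(as.numeric(beta), colnames(x)), t_stats = t_stats)
}

#' Row-shuffle permutation test for each covariate
#'
#' For every non-intercept column, the model is refitted `n_perm` times
#' with only that column's rows shuffled (covariate structure otherwise
#' intact); the null is the distribution of permuted |t| and the two-tailed
#' p-value is `(1 + #(null >= |t_obs|)) / (1 + n_perm)` (never exactly 0).
#'
#' @param design Design matrix from [build_design()].
#' @param y Outcome vector.
#' @param n_perm Number of permutations (default 5000; fewer than 100
#'   triggers a warning).
#' @param alpha Significance level (default 0.01).
#' @param seed Integer seed, or `NULL`.
#' @return A list with `betas`, `t_stats`, `perm_null` (list of |t| null
#'   vectors per covariate), `p_values`, `significant` and `alpha`.
#' @export
permutation_test <- function(design, y, n_perm = 5000L, alpha = 0.01,
                             seed = NULL) {
  if (n_perm < 100L) warning("n_perm < 100: permutation p-values are coarse")
  x <- as.matrix(design)
  obs <- fit_glm(x, y)
  regs <- setdiff(seq_len(ncol(x)), 1L)
  nulls <- vector("list", length(regs))
  names(nulls) <- colnames(x)[regs]
  with_seed(seed, {
    for (k in seq_along(regs)) {
      j <- regs[k]
      null_t <- numeric(n_perm)
      xp <- x
      for (b in seq_len(n_perm)) {
        xp[, j] <- x[sample.int(nrow(x)), j]
        null_t[b] <- abs(fit_glm(xp, y)$t_stats[j])
      }
      nulls[[k]] <- null_t
    }
  })
  p_values <- vapply(
    seq_along(regs),
    function(k) (1 + sum(nulls[[k]] >= abs(obs$t_stats[regs[k]]))) / (1 + n_perm),
    numeric(1)
  )
  names(p_values) <- names(nulls)
  list(
    betas = obs$betas,
    t_stats = obs$t_stats,
    perm_null = nulls,
    p_values = p_values,
    significant = p_values < alpha,
    alpha = alpha
  )
}
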