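#' Covariate-controlled (partial) Pearson correlation
#'
#' Correlates the OLS residuals of `x` and `y` after regressing each on
#' an intercept plus the covariates `z`; with no covariates this is the
#' plain Pearson correlation. Two-tailed p from
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - ncol(z)`.
#'
#' @param x,y Aligned numeric vectors.
#' @param z Covariate matrix/data.frame (possibly with zero columns).
#' @return List with `r`, `df`, `p`, `n`.
#' @export
partial_pearson <- function(x, y, z = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(z) || NCOL(z) == 0L) {
    zz <- matrix(1, n, 1L)
  } else {
    z <- as.matrix(z)
    stopifnot(nrow(z) == n)
    zz <- cbind(1, z)
  }
  k <- ncol(zz) - 1L
  if (n <= k + 2L) stop("need n > n_covariates + 2", call. = FALSE)
  if (qr(zz)$rank < ncol(zz)) {
    stop("covariate matrix is rank deficient", call. = FALSE)
  }
  h <- zz %*% (chol2inv(chol(crossprod(zz))) %*% t(zz))
  rx <- x - h %*% x
  ry <- y - h %*% y
  r <- as.numeric(stats::cor(rx, ry))
  df <- n - 2L - k
  p <- if (abs(r) >= 1) 0 else {
    t0 <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(t0), df)
  }
  list(r = r, df = df, p = p, n = n)
}

#' Scan clinical scores against network indices (patients only)
#'
#' Covariate-controlled Pearson correlation between every network index
#' (e.g. global metric AUCs and any significant nodal/block values) and
#' every clinical score, with Benjamini-Hochberg FDR across the full
#' scan. Rows with a missing score are dropped pairwise and the
#' per-pair n is reported.
#'
#' @param indices data.frame/matrix of network indices, patients in
#'   rows.
#' @param scores data.frame of clinical scores (may contain NA).
#' @param covariates Covariate matrix/data.frame aligned to the rows.
#' @return data.frame with `index`, `score`, `n`, `r`, `df`, `p`,
#'   `q_fdr`.
#' @export
assoc_scan <- function(indices, scores, covariates) {
  indices <- as.data.frame(indices)
  scores <- as.data.frame(scores)
  covariates <- as.matrix(covariates)
  grid <- expand.grid(index = names(indices), score = names(scores),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    xv <- indices[[grid$index[k]]]
    yv <- scores[[grid$score[k]]]
    ok <- stats::complete.cases(xv, yv, covariates)
    zz <- covariates[ok, , drop = FALSE]
    # a covariate constant over the analysed rows carries no information
    keep <- apply(zz, 2L, function(v) stats::sd(v) > 0)
    pr <- partial_pearson(xv[ok], yv[ok], zz[, keep, drop = FALSE])
    data.frame(index = grid$index[k], score = grid$score[k],
               n = sum(ok), r = pr$r, df = pr$df, p = pr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- bh_fdr(out$p)
  out
}
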