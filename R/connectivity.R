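#' Ridge-regularized precision matrix of a parcel time series
#'
#' Columns are standardized to zero mean and unit variance, the sample
#' correlation matrix `R` is formed, and the Tikhonov (ridge) inverse
#' `(R + lambda I)^-1` is returned. For `lambda > 0` this is always
#' symmetric positive definite, also when `T < N`; `lambda = 0` requires
#' a non-singular `R`.
#'
#' @param ts An `fc_timeseries`, or a plain timepoints x parcels matrix.
#' @param lambda Ridge penalty, `>= 0`.
#' @return N x N precision matrix.
#' @export
ridge_precision <- function(ts, lambda = 1) {
  x <- if (inherits(ts, "fc_timeseries")) ts$data else as.matrix(ts)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  r <- stats::cor(x)
  n <- ncol(r)
  rl <- r + diag(lambda, n)
  if (lambda == 0) {
    ev_min <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < .Machine$double.eps * n) {
      stop("sample correlation matrix is singular (T <= N or collinear ",
           "columns); use lambda > 0", call. = FALSE)
    }
  }
  theta <- chol2inv(chol(rl))
  (theta + t(theta)) / 2
}

#' Partial correlations from a precision matrix
#'
#' Standard map `p_ij = -theta_ij / sqrt(theta_ii * theta_jj)`, with the
#' diagonal set to 0.
#'
#' @param theta Symmetric precision matrix with positive diagonal.
#' @return N x N partial-correlation matrix in `[-1, 1]`.
#' @export
partial_corr_from_precision <- function(theta) {
  d <- diag(theta)
  if (any(d <= 0)) {
    stop("precision matrix has non-positive diagonal entries",
         call. = FALSE)
  }
  s <- 1 / sqrt(d)
  p <- -theta * tcrossprod(s)
  diag(p) <- 0
  pmin(pmax(p, -1), 1)
}

#' Fisher r-to-z transform with clipping
#'
#' `z = atanh(r)` after clipping `|r|` at `1 - 1e-7`, so outputs are
#' always finite; the diagonal is fixed at 0.
#'
#' @param r Correlation matrix (or vector) with `|r| <= 1`.
#' @return Matrix (or vector) of z-values.
#' @export
fisher_z <- function(r) {
  z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
  if (is.matrix(z)) diag(z) <- 0
  z
}

#' Build a per-subject Fisher-z connectivity matrix
#'
#' For `method = "tikhonov_partial"` (the default): ridge precision of
#' the standardized series, precision-to-partial-correlation map, then
#' Fisher z. For `method = "pearson"`: plain correlation, then Fisher z.
#'
#' @param ts An `fc_timeseries`.
#' @param method `"tikhonov_partial"` or `"pearson"`.
#' @param lambda Ridge penalty (ignored for `"pearson"`).
#' @return An `fc_matrix` object: list with `subject_id`, `z` (symmetric
#'   zero-diagonal matrix), `method`, `lambda`.
#' @export
build_fc_matrix <- function(ts, method = c("tikhonov_partial", "pearson"),
                            lambda = 1) {
  method <- match.arg(method)
  if (method == "tikhonov_partial") {
    r <- partial_corr_from_precision(ridge_precision(ts, lambda))
  } else {
    r <- stats::cor(ts$data)
    lambda <- 0
  }
  z <- fisher_z(r)
  z <- (z + t(z)) / 2
  structure(list(subject_id = ts$subject_id, z = z, method = method,
                 lambda = lambda),
            class = "fc_matrix")
}

#' Build connectivity matrices for a whole cohort
#'
#' @param ts_list Named list of `fc_timeseries`.
#' @inheritParams build_fc_matrix
#' @return Named list of `fc_matrix`, same order as `ts_list`.
#' @export
build_fc_stack <- function(ts_list, method = "tikhonov_partial",
                           lambda = 1) {
  out <- lapply(ts_list, build_fc_matrix, method = method, lambda = lambda)
  names(out) <- names(ts_list)
  out
}

#' Edge index table for an N-node network
#'
#' Upper-triangular node pairs `(i, j)`, `i < j`, in ascending
#' lexicographic order; this ordering is the single source of truth for
#' edge vectors throughout the package.
#'
#' @param n Number of nodes.
#' @return Two-column integer matrix with `n (n - 1) / 2` rows.
#' @export
edge_index <- function(n) {
  j <- sequence((n - 1L):1L, from = 2:n)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  cbind(i = i, j = j)
}

#' Stack connectivity matrices into a subjects x edges matrix
#'
#' @param fc_list List of `fc_matrix`.
#' @return Numeric matrix, one row per subject, columns in
#'   [edge_index()] order; attribute `"edges"` carries the index table.
#' @export
fc_edge_matrix <- function(fc_list) {
  n <- nrow(fc_list[[1L]]$z)
  ei <- edge_index(n)
  y <- t(vapply(fc_list, function(fc) fc$z[ei], numeric(nrow(ei))))
  rownames(y) <- vapply(fc_list, `[[`, character(1L), "subject_id")
  attr(y, "edges") <- ei
  y
}
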