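#' Build the group-contrast design matrix
#'
#' Columns: intercept, group indicator (patient = 1), age, sex, mean
#' framewise displacement and cortex volume. The group column is the
#' tested contrast; the remaining columns are nuisance covariates.
#'
#' @param pheno Validated phenotype data.frame (see [as_phenotypes()]).
#' @param covariates Character vector of covariate columns to include.
#' @return Numeric matrix with attribute `"contrast"` naming the tested
#'   column.
#' @export
design_matrix <- function(pheno,
                          covariates = c("age", "sex", "mean_fd",
                                         "cortex_volume")) {
  x <- cbind(intercept = 1,
             group = as.numeric(pheno$group == "patient"))
  for (cv in covariates) x <- cbind(x, pheno[[cv]])
  colnames(x) <- c("intercept", "group", covariates)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  attr(x, "contrast") <- "group"
  x
}

#' OLS t-statistics for many outcomes at once
#'
#' Fits the same linear model to every column of `y` and returns the
#' t-statistic of the contrast coefficient. Outcomes with zero residual
#' variance get t = 0.
#'
#' @param y Outcome matrix (subjects x outcomes) or vector.
#' @param x Design matrix (see [design_matrix()]).
#' @param contrast Name or index of the tested column.
#' @return List with `t`, two-sided parametric `p`, and residual `df`.
#' @export
glm_tstats <- function(y, x, contrast = attr(x, "contrast") %||% "group") {
  y <- as.matrix(y)
  if (nrow(y) != nrow(x)) stop("y and design rows do not align",
                               call. = FALSE)
  j <- if (is.character(contrast)) match(contrast, colnames(x)) else contrast
  if (is.na(j)) stop("contrast column not found", call. = FALSE)
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(x))), error = function(e) {
    stop("design matrix is rank deficient", call. = FALSE)
  })
  beta <- xtx_inv %*% crossprod(x, y)
  res <- y - x %*% beta
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * xtx_inv[j, j])
  t <- as.numeric(beta[j, ]) / se
  # outcomes with (numerically) zero residual variance carry no signal
  tol <- .Machine$double.eps^0.75 * (colMeans(y * y) + 1)
  t[!is.finite(t) | sigma2 <= tol] <- 0
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' @rdname glm_tstats
#' @export
glm_tstat <- function(y, x, contrast = attr(x, "contrast") %||% "group") {
  glm_tstats(matrix(y, ncol = 1L), x, contrast)$t
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Freedman-Lane ingredients: residualize Y on the nuisance part of X.
fl_parts <- function(y, x, contrast) {
  j <- if (is.character(contrast)) match(contrast, colnames(x)) else contrast
  z <- x[, -j, drop = FALSE]
  gz <- chol2inv(chol(crossprod(z))) %*% crossprod(z, y)
  fit <- z %*% gz
  list(resid = y - fit, fit = fit)
}

#' Freedman-Lane permutation null t-statistics
#'
#' Residualizes the outcomes on the nuisance covariates, permutes the
#' residual rows, adds the nuisance fit back, and refits the full model,
#' giving a permutation null for the contrast t-statistic that respects
#' the covariate structure. With no covariates this reduces exactly to
#' simple group-label permutation.
#'
#' @param y Outcomes (subjects x outcomes).
#' @param x Design matrix.
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed.
#' @param contrast Tested column.
#' @return `n_perm` x `n_outcomes` matrix of null t-statistics.
#' @export
freedman_lane_permute <- function(y, x, n_perm, seed,
                                  contrast = attr(x, "contrast") %||%
                                    "group") {
  y <- as.matrix(y)
  set.seed(seed)
  parts <- fl_parts(y, x, contrast)
  n <- nrow(y)
  out <- matrix(NA_real_, n_perm, ncol(y))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    ystar <- parts$resid[idx, , drop = FALSE] + parts$fit
    out[b, ] <- glm_tstats(ystar, x, contrast)$t
  }
  colnames(out) <- colnames(y)
  out
}

#' Apply a function to each Freedman-Lane permutation
#'
#' Memory-light variant of [freedman_lane_permute()] for large outcome
#' families (e.g. all connectome edges): `fun(t, p, df)` is called with
#' the permuted-statistics vector for each permutation and its results
#' are collected in a list.
#'
#' @inheritParams freedman_lane_permute
#' @param fun Function of the per-permutation `t`, `p`, `df`.
#' @return List of length `n_perm` with `fun`'s results.
#' @export
freedman_lane_apply <- function(y, x, n_perm, seed, fun,
                                contrast = attr(x, "contrast") %||%
                                  "group") {
  y <- as.matrix(y)
  set.seed(seed)
  parts <- fl_parts(y, x, contrast)
  n <- nrow(y)
  out <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    ystar <- parts$resid[idx, , drop = FALSE] + parts$fit
    st <- glm_tstats(ystar, x, contrast)
    out[[b]] <- fun(st$t, st$p, st$df)
  }
  out
}

#' Max-statistic and uncorrected permutation p-values
#'
#' For each outcome: uncorrected p = (1 + #{|t_null| >= |t_obs|}) /
#' (n_perm + 1); family-wise corrected p compares |t_obs| with the
#' permutation distribution of the maximum |t| over the family.
#' Outcomes with non-finite observed statistics (e.g. assortativity on a
#' degree-regular graph) are dropped from the family with a warning.
#' Benjamini-Hochberg q-values over the uncorrected p complete the
#' result.
#'
#' @param t_obs Observed t-statistics (named vector).
#' @param t_null Permutation null matrix (`n_perm` x outcomes).
#' @return data.frame with `outcome`, `t`, `p_uncorrected`, `p_maxstat`,
#'   `q_fdr`; attribute `"n_perm"`.
#' @export
maxstat_pvalues <- function(t_obs, t_null) {
  stopifnot(length(t_obs) == ncol(t_null))
  nm <- names(t_obs) %||% colnames(t_null) %||%
    paste0("outcome", seq_along(t_obs))
  ok <- is.finite(t_obs) & apply(t_null, 2L, function(v) all(is.finite(v)))
  if (!all(ok)) {
    warning(sum(!ok), " outcome(s) with non-finite statistics dropped ",
            "from the permutation family", call. = FALSE)
  }
  to <- abs(t_obs[ok])
  tn <- abs(t_null[, ok, drop = FALSE])
  n_perm <- nrow(tn)
  maxnull <- apply(tn, 1L, max)
  p_unc <- vapply(seq_along(to), function(i) {
    (1 + sum(tn[, i] >= to[i])) / (n_perm + 1)
  }, numeric(1L))
  p_max <- vapply(to, function(t0) {
    (1 + sum(maxnull >= t0)) / (n_perm + 1)
  }, numeric(1L))
  out <- data.frame(outcome = nm[ok], t = t_obs[ok],
                    p_uncorrected = p_unc,
                    p_maxstat = pmax(p_max, p_unc),
                    q_fdr = bh_fdr(p_unc),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "dropped") <- nm[!ok]
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Monotone q-values (`stats::p.adjust` method `"BH"`).
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Covariate-adjusted permutation test of metric AUC group differences
#'
#' Runs the max-statistic Freedman-Lane engine on the family of 8 global
#' AUC metrics and, when nodal AUCs are supplied, on each nodal metric's
#' N-node family separately (degree, betweenness, efficiency), matching
#' the reporting granularity of density-integrated connectome studies.
#'
#' @param metrics Output of [cohort_metrics()].
#' @param pheno Phenotype table aligned to the metric rows.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param atlas Optional `fc_atlas` used to annotate nodal rows with
#'   parcel names and Yeo networks.
#' @return List with data.frames `global` and (if available) `nodal`.
#' @export
metric_group_test <- function(metrics, pheno, n_perm = 10000L, seed = 1L,
                              atlas = NULL) {
  x <- design_matrix(pheno)
  ga <- metrics$global_auc
  y <- as.matrix(ga[, setdiff(names(ga), "subject_id")])
  obs <- glm_tstats(y, x)
  null <- freedman_lane_permute(y, x, n_perm, seed)
  res_global <- maxstat_pvalues(stats::setNames(obs$t, colnames(y)), null)
  out <- list(global = res_global)
  if (!is.null(metrics$nodal_auc)) {
    arr <- metrics$nodal_auc
    nodal <- lapply(dimnames(arr)[[3L]], function(m) {
      ym <- arr[, , m]
      colnames(ym) <- paste0("node", seq_len(ncol(ym)))
      obs_m <- glm_tstats(ym, x)
      null_m <- freedman_lane_permute(ym, x, n_perm, seed)
      r <- maxstat_pvalues(stats::setNames(obs_m$t, colnames(ym)), null_m)
      r$metric <- m
      r$node <- match(r$outcome, colnames(ym))
      r
    })
    nodal <- do.call(rbind, nodal)
    if (!is.null(atlas)) {
      nodal$parcel_name <- atlas$parcel_name[nodal$node]
      nodal$network <- atlas$network[nodal$node]
    }
    out$nodal <- nodal
  }
  out
}
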