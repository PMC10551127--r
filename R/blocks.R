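block_labels <- function() {
  within <- paste(yeo7_networks, yeo7_networks, sep = "-")
  between <- apply(utils::combn(yeo7_networks, 2L), 2L,
                   paste, collapse = "-")
  c(within, between)
}

# Edge -> block membership matrix (edges x 28), entries 1/block size,
# so y_edges %*% M yields per-subject block means in one product.
block_weight_matrix <- function(atlas) {
  net <- atlas$network
  ei <- edge_index(nrow(atlas))
  a <- net[ei[, 1L]]
  b <- net[ei[, 2L]]
  lab <- ifelse(match(a, yeo7_networks) <= match(b, yeo7_networks),
                paste(a, b, sep = "-"), paste(b, a, sep = "-"))
  labs <- block_labels()
  m <- matrix(0, nrow(ei), length(labs), dimnames = list(NULL, labs))
  idx <- match(lab, labs)
  m[cbind(seq_len(nrow(ei)), idx)] <- 1
  sweep(m, 2L, colSums(m), "/")
}

#' Average connectivity within and between Yeo-7 networks
#'
#' Signed average of the Fisher-z values over all unordered parcel pairs
#' inside each network (7 within-network values, excluding the diagonal)
#' and across each network pair (21 between-network values); negative
#' and positive z contribute as they are, not folded.
#'
#' @param fc An `fc_matrix` (or plain symmetric z matrix).
#' @param atlas The `fc_atlas`.
#' @return Named numeric vector of 28 block means, within-network blocks
#'   first.
#' @export
block_average <- function(fc, atlas) {
  z <- if (inherits(fc, "fc_matrix")) fc$z else fc
  ei <- edge_index(nrow(atlas))
  drop(z[ei] %*% block_weight_matrix(atlas))[block_labels()]
}

#' Block-average table for a whole cohort
#'
#' @param fc_list List of `fc_matrix`.
#' @param atlas The `fc_atlas`.
#' @return Subjects x 28 matrix of block means (row names = subject
#'   ids).
#' @export
block_average_stack <- function(fc_list, atlas) {
  y <- fc_edge_matrix(fc_list)
  out <- y %*% block_weight_matrix(atlas)
  out[, block_labels(), drop = FALSE]
}

#' Permutation group test of the 28 network-block FC values
#'
#' Covariate-adjusted Freedman-Lane permutation p per block (uncorrected)
#' followed by Benjamini-Hochberg FDR over the single 28-outcome family.
#'
#' @param blocks Subjects x 28 block matrix ([block_average_stack()]).
#' @param pheno Phenotype table aligned to the rows.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `table` (data.frame: block, t, p_perm, q_fdr,
#'   significant) and the permutation count.
#' @export
block_group_test <- function(blocks, pheno, n_perm = 10000L, seed = 1L) {
  x <- design_matrix(pheno)
  obs <- glm_tstats(blocks, x)
  null <- freedman_lane_permute(blocks, x, n_perm, seed)
  p <- vapply(seq_len(ncol(blocks)), function(j) {
    (1 + sum(abs(null[, j]) >= abs(obs$t[j]))) / (n_perm + 1)
  }, numeric(1L))
  q <- bh_fdr(p)
  list(table = data.frame(block = colnames(blocks), t = obs$t,
                          p_perm = p, q_fdr = q,
                          significant = q < 0.05,
                          row.names = NULL, stringsAsFactors = FALSE),
       n_perm = n_perm)
}
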