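#' Canonical Yeo 7-network labels
#'
#' The seven large-scale cortical systems used to label parcels: visual
#' (VN), somatomotor (SMN), dorsal attention (DAN), ventral attention
#' (VAN), limbic (LN), frontoparietal control (FPN) and default mode
#' (DMN).
#'
#' @format Character vector of length 7.
#' @export
yeo7_networks <- c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN")

#' Construct and validate a parcellation atlas
#'
#' An atlas defines the node set of every downstream network: one row per
#' cortical parcel, in the order that parcels appear as columns of the
#' time-series matrices and as rows/columns of connectivity matrices.
#'
#' @param parcels A data.frame with columns `parcel_id` (consecutive
#'   1-based integers), `parcel_name`, `hemisphere` (`"L"`/`"R"`) and
#'   `network` (one of [yeo7_networks]); optional numeric columns
#'   `x`, `y`, `z` give template-space coordinates in mm.
#' @return An object of class `fc_atlas` (a validated data.frame).
#' @export
as_atlas <- function(parcels) {
  parcels <- as.data.frame(parcels, stringsAsFactors = FALSE)
  required <- c("parcel_id", "parcel_name", "hemisphere", "network")
  missing_cols <- setdiff(required, names(parcels))
  if (length(missing_cols) > 0L) {
    stop("atlas is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(parcels)
  ids <- parcels$parcel_id
  if (anyDuplicated(ids)) {
    stop("duplicate parcel_id at row(s): ",
         paste(which(duplicated(ids)), collapse = ", "), call. = FALSE)
  }
  if (!isTRUE(all.equal(as.numeric(ids), as.numeric(seq_len(n))))) {
    stop("parcel_id must be consecutive 1-based integers 1..", n,
         call. = FALSE)
  }
  bad_net <- which(!parcels$network %in% yeo7_networks)
  if (length(bad_net) > 0L) {
    stop(sprintf("unknown network label '%s' at atlas row %d (allowed: %s)",
                 parcels$network[bad_net[1L]], bad_net[1L],
                 paste(yeo7_networks, collapse = ", ")), call. = FALSE)
  }
  bad_hemi <- which(!parcels$hemisphere %in% c("L", "R"))
  if (length(bad_hemi) > 0L) {
    stop(sprintf("hemisphere must be 'L' or 'R' (atlas row %d)",
                 bad_hemi[1L]), call. = FALSE)
  }
  counts <- table(factor(parcels$network, levels = yeo7_networks))
  if (any(counts < 2L)) {
    stop("every network needs at least 2 parcels for block statistics; ",
         "deficient: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  parcels$parcel_id <- as.integer(ids)
  class(parcels) <- c("fc_atlas", "data.frame")
  parcels
}

#' Read an atlas from a TSV file
#'
#' @param path Path to a tab-separated file with a header row and the
#'   columns described in [as_atlas()].
#' @return An `fc_atlas` object. Row order defines node order everywhere
#'   downstream.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_atlas(tab)
}

#' Write an atlas to a TSV file
#' @param atlas An `fc_atlas`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a synthetic atlas with balanced Yeo-7 labels
#'
#' Convenience constructor used by the cohort simulator and the test
#' suite: `n_parcels` parcels assigned to the seven networks in contiguous
#' blocks, as evenly as possible, alternating hemispheres.
#'
#' @param n_parcels Total number of parcels (at least 14).
#' @return An `fc_atlas`.
#' @export
synthetic_atlas <- function(n_parcels = 400L) {
  n_parcels <- as.integer(n_parcels)
  if (n_parcels < 14L) stop("need at least 14 parcels (2 per network)",
                            call. = FALSE)
  base <- n_parcels %/% 7L
  sizes <- rep(base, 7L)
  extra <- n_parcels - 7L * base
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  network <- rep(yeo7_networks, times = sizes)
  as_atlas(data.frame(
    parcel_id = seq_len(n_parcels),
    parcel_name = sprintf("%s_parcel%03d", network, seq_len(n_parcels)),
    hemisphere = rep_len(c("L", "R"), n_parcels),
    network = network,
    stringsAsFactors = FALSE
  ))
}
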