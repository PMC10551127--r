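#' Configuration for the Network-Based Statistic
#'
#' @param primary_alpha Two-tailed edge-level p threshold forming the
#'   supra-threshold graph (default 0.001).
#' @param n_perm Number of permutations for the maximum component-size
#'   null (default 10,000).
#' @param component_alpha One-tailed significance threshold per contrast
#'   direction (default 0.025).
#' @param seed Integer seed.
#' @return An `nbs_config` list.
#' @export
nbs_config <- function(primary_alpha = 0.001, n_perm = 10000L,
                       component_alpha = 0.025, seed = 1L) {
  stopifnot(primary_alpha > 0, primary_alpha < 1, component_alpha <= 0.5,
            component_alpha > 0, n_perm >= 1L)
  structure(list(primary_alpha = primary_alpha,
                 n_perm = as.integer(n_perm),
                 component_alpha = component_alpha,
                 seed = as.integer(seed)),
            class = "nbs_config")
}

#' Edge-wise covariate-adjusted group t-statistics
#'
#' One linear model per upper-triangular edge of the connectome
#' (`N(N-1)/2` tests), with parametric two-tailed p-values used only for
#' the NBS primary threshold.
#'
#' @param y_edges Subjects x edges matrix (see [fc_edge_matrix()]), or a
#'   list of `fc_matrix`.
#' @param x Design matrix.
#' @return List with `t`, `p`, `df` and the `edges` index table.
#' @export
edge_tstats <- function(y_edges, x) {
  if (is.list(y_edges) && inherits(y_edges[[1L]], "fc_matrix")) {
    y_edges <- fc_edge_matrix(y_edges)
  }
  st <- glm_tstats(y_edges, x)
  st$edges <- attr(y_edges, "edges")
  st
}

# Connected components of a set of kept edges; size = edge count.
component_list <- function(edges_kept, t_kept, n_nodes) {
  if (nrow(edges_kept) == 0L) return(list())
  g <- igraph::add_edges(
    igraph::make_empty_graph(n_nodes, directed = FALSE), t(edges_kept))
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[edges_kept[, 1L]]
  comps <- lapply(sort(unique(comp_of_edge)), function(cid) {
    sel <- comp_of_edge == cid
    e <- edges_kept[sel, , drop = FALSE]
    list(nodes = sort(unique(as.vector(e))),
         edges = data.frame(node_i = e[, 1L], node_j = e[, 2L],
                            t = t_kept[sel]),
         size = sum(sel))
  })
  comps[order(-vapply(comps, `[[`, numeric(1L), "size"))]
}

#' Supra-threshold connected components in one contrast direction
#'
#' Keeps edges with `p < primary_alpha` whose t-statistic sign matches
#' the direction (`"greater"`: patients > controls), and returns the
#' connected components of the kept graph, largest first. Component
#' size is the edge count ("extent").
#'
#' @param stats Output of [edge_tstats()].
#' @param direction `"greater"` or `"less"`.
#' @param primary_alpha Edge-level two-tailed p threshold.
#' @param n_nodes Number of nodes in the network.
#' @return List of components (possibly empty), each with `nodes`,
#'   `edges` and `size`.
#' @export
suprathreshold_components <- function(stats, direction = c("greater",
                                                           "less"),
                                      primary_alpha = 0.001,
                                      n_nodes = max(stats$edges)) {
  direction <- match.arg(direction)
  sgn <- if (direction == "greater") stats$t > 0 else stats$t < 0
  keep <- which(stats$p < primary_alpha & sgn)
  component_list(stats$edges[keep, , drop = FALSE], stats$t[keep],
                 n_nodes)
}

max_component_size <- function(t, p, edges, direction, primary_alpha,
                               n_nodes) {
  sgn <- if (direction == "greater") t > 0 else t < 0
  keep <- which(p < primary_alpha & sgn)
  if (length(keep) == 0L) return(0L)
  e <- edges[keep, , drop = FALSE]
  g <- igraph::add_edges(
    igraph::make_empty_graph(n_nodes, directed = FALSE), t(e))
  memb <- igraph::components(g)$membership
  max(tabulate(memb[e[, 1L]]))
}

#' Tally supra-threshold edges by Yeo network pair
#'
#' Counts the significant-component edges falling in each of the 28
#' network pairs, split by direction (hypo = patients < controls, hyper
#' = patients > controls), together with the ratio of the count to the
#' total number of possible connections for that pair.
#'
#' @param edge_table data.frame with `node_i`, `node_j`, `direction`.
#' @param atlas The `fc_atlas`.
#' @return data.frame with `network_a`, `network_b`, `n_hypo`,
#'   `n_hyper`, `ratio_hypo`, `ratio_hyper`.
#' @export
network_pair_tally <- function(edge_table, atlas) {
  net <- atlas$network
  sizes <- table(factor(net, levels = yeo7_networks))
  pairs <- rbind(cbind(yeo7_networks, yeo7_networks),
                 t(utils::combn(yeo7_networks, 2L)))
  out <- data.frame(network_a = pairs[, 1L], network_b = pairs[, 2L],
                    n_hypo = 0L, n_hyper = 0L, total_possible = 0L,
                    stringsAsFactors = FALSE)
  sa <- as.integer(sizes[out$network_a])
  sb <- as.integer(sizes[out$network_b])
  out$total_possible <- ifelse(out$network_a == out$network_b,
                               as.integer(choose(sa, 2L)), sa * sb)
  key <- function(a, b) {
    ifelse(match(a, yeo7_networks) <= match(b, yeo7_networks),
           paste(a, b), paste(b, a))
  }
  out_key <- key(out$network_a, out$network_b)
  if (nrow(edge_table) > 0L) {
    ek <- key(net[edge_table$node_i], net[edge_table$node_j])
    for (d in c("hypo", "hyper")) {
      counts <- table(ek[edge_table$direction == d])
      idx <- match(names(counts), out_key)
      out[[paste0("n_", d)]][idx] <- as.integer(counts)
    }
  }
  out$ratio_hypo <- out$n_hypo / out$total_possible
  out$ratio_hyper <- out$n_hyper / out$total_possible
  out
}

#' Network-Based Statistic group comparison
#'
#' Edge-wise covariate-adjusted t-tests, supra-threshold components per
#' direction, and a Freedman-Lane permutation null of the maximum
#' component size per direction. The corrected p of each observed
#' component is `(1 + #{null max size >= observed size}) / (n_perm + 1)`
#' (one-tailed per direction); components with `p < component_alpha`
#' are flagged significant.
#'
#' @param fc_list List of `fc_matrix` (or a subjects x edges matrix).
#' @param pheno Phenotype table aligned to the subjects.
#' @param config An [nbs_config()].
#' @param atlas Optional `fc_atlas` for the network-pair tally of
#'   significant-component edges.
#' @return An `nbs_result` list: per direction the component list with
#'   corrected p-values and significance flags, the null maxima, and
#'   (with an atlas) the hypo/hyper network-pair tally plus a merged
#'   union summary (`n_nodes`, `n_edges`, `n_hypo`, `n_hyper`).
#' @export
nbs_test <- function(fc_list, pheno, config = nbs_config(),
                     atlas = NULL) {
  y <- if (is.matrix(fc_list)) fc_list else fc_edge_matrix(fc_list)
  x <- design_matrix(pheno)
  edges <- attr(y, "edges")
  n_nodes <- max(edges)
  obs <- glm_tstats(y, x)
  obs$edges <- edges
  comps <- list(
    greater = suprathreshold_components(obs, "greater",
                                        config$primary_alpha, n_nodes),
    less = suprathreshold_components(obs, "less",
                                     config$primary_alpha, n_nodes))
  null_max <- freedman_lane_apply(
    y, x, config$n_perm, config$seed,
    function(t, p, df) {
      c(greater = max_component_size(t, p, edges, "greater",
                                     config$primary_alpha, n_nodes),
        less = max_component_size(t, p, edges, "less",
                                  config$primary_alpha, n_nodes))
    })
  null_max <- do.call(rbind, null_max)
  for (dir in c("greater", "less")) {
    for (k in seq_along(comps[[dir]])) {
      sz <- comps[[dir]][[k]]$size
      p <- (1 + sum(null_max[, dir] >= sz)) / (config$n_perm + 1)
      comps[[dir]][[k]]$p_corrected <- p
      comps[[dir]][[k]]$significant <- p < config$component_alpha
    }
  }
  res <- list(components = comps, null_max = null_max, config = config,
              n_nodes = n_nodes)
  sig_edges <- nbs_significant_edges(res)
  res$summary <- data.frame(
    n_nodes = length(unique(c(sig_edges$node_i, sig_edges$node_j))),
    n_edges = nrow(sig_edges),
    n_hypo = sum(sig_edges$direction == "hypo"),
    n_hyper = sum(sig_edges$direction == "hyper"))
  if (!is.null(atlas)) {
    res$tally <- network_pair_tally(sig_edges, atlas)
  }
  class(res) <- "nbs_result"
  res
}

# Edges belonging to significant components, both directions merged.
nbs_significant_edges <- function(res) {
  rows <- list()
  for (dir in c("greater", "less")) {
    lab <- if (dir == "greater") "hyper" else "hypo"
    for (k in seq_along(res$components[[dir]])) {
      cp <- res$components[[dir]][[k]]
      if (isTRUE(cp$significant)) {
        e <- cp$edges
        e$direction <- lab
        e$component_id <- paste0(substr(lab, 1L, 2L), k)
        e$component_p <- cp$p_corrected
        rows[[length(rows) + 1L]] <- e
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(node_i = integer(), node_j = integer(),
                      t = numeric(), direction = character(),
                      component_id = character(),
                      component_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Flat edge table of an NBS result (all components, both directions)
#' @param res An `nbs_result`.
#' @return data.frame with columns `node1`, `node2`, `t`, `direction`,
#'   `component_id`, `component_p` (header-only when nothing passes).
#' @export
nbs_edge_table <- function(res) {
  e <- nbs_significant_edges(res)
  data.frame(node1 = e$node_i, node2 = e$node_j, t = e$t,
             direction = e$direction, component_id = e$component_id,
             component_p = e$component_p, stringsAsFactors = FALSE)
}
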