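#' The default proportional-density grid
#'
#' Sparsity fractions from `from` to `to` in steps of `by`; the default
#' is 10% to 34% in 1% steps (25 values), stored as exact hundredths to
#' avoid floating-point drift.
#'
#' @param from,to,by Grid limits and step.
#' @return Strictly increasing numeric vector of densities.
#' @export
density_grid <- function(from = 0.10, to = 0.34, by = 0.01) {
  d <- round(seq(round(from * 100), round(to * 100), by = round(by * 100))) / 100
  if (length(d) < 1L || any(diff(d) <= 0)) {
    stop("density grid must be strictly increasing", call. = FALSE)
  }
  d
}

# Edge rows kept at a proportional density: the k = round(density * E)
# largest signed z, ties broken by ascending lexicographic edge index
# (order() is stable).
binarize_edges <- function(z, density, ei = edge_index(nrow(z))) {
  vals <- z[ei]
  k <- round(density * nrow(ei))
  if (k < 1L) stop("density ", density, " keeps zero edges", call. = FALSE)
  ei[order(-vals)[seq_len(k)], , drop = FALSE]
}

#' Threshold a connectivity matrix into a binary graph
#'
#' Keeps the `k = round(density * N(N-1)/2)` edges with the largest
#' signed z-value; ties are broken by ascending `(i, j)` lexicographic
#' edge order, so the graph is a deterministic function of the matrix.
#'
#' @param z Symmetric connectivity matrix (or an `fc_matrix`).
#' @param density Fraction of possible edges to keep, in `(0, 1)`.
#' @return An undirected `igraph` graph with `N` vertices.
#' @export
binarize_at_density <- function(z, density) {
  if (inherits(z, "fc_matrix")) z <- z$z
  keep <- binarize_edges(z, density)
  igraph::add_edges(igraph::make_empty_graph(nrow(z), directed = FALSE),
                    t(keep))
}

graph_edgelist <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  el
}

#' Global graph metrics of one binary graph
#'
#' Computes the mean clustering coefficient (`Cp`; local value 0 for
#' degree < 2), characteristic path length over pairs in the largest
#' connected component (`Lp`), global efficiency (`Eglob`; unreachable
#' pairs contribute 0), local efficiency (`Eloc`; mean over nodes of the
#' global efficiency of the neighbour-induced subgraph) and degree
#' assortativity (Pearson correlation of degrees over edge endpoints;
#' `NaN` on degree-regular graphs).
#'
#' @param g An undirected `igraph` graph.
#' @return Named numeric vector `c(Cp, Lp, Eglob, Eloc, assortativity)`.
#' @export
global_metrics <- function(g) {
  m <- graph_metrics_cpp(graph_edgelist(g), igraph::vcount(g),
                         include_nodal = FALSE)
  c(Cp = m$Cp, Lp = m$Lp, Eglob = m$Eglob, Eloc = m$Eloc,
    assortativity = m$assortativity)
}

#' Nodal graph metrics of one binary graph
#'
#' Per node: degree, unnormalized shortest-path betweenness (exact
#' Brandes counting), and nodal efficiency
#' `(1/(N-1)) * sum_j 1/d(i, j)` (unreachable nodes contribute 0).
#'
#' @param g An undirected `igraph` graph.
#' @return N x 3 matrix with columns `degree`, `betweenness`,
#'   `efficiency`.
#' @export
nodal_metrics <- function(g) {
  m <- graph_metrics_cpp(graph_edgelist(g), igraph::vcount(g),
                         include_nodal = TRUE)
  cbind(degree = m$degree, betweenness = m$betweenness,
        efficiency = m$nodal_efficiency)
}

#' Degree-preserving random-graph reference metrics
#'
#' Generates `n_null` Maslov-Sneppen rewired versions of `g` (double
#' edge swaps preserving the degree sequence; `10 |E|` successful swaps
#' per null) and returns the mean clustering coefficient and
#' characteristic path length across them, for the gamma/lambda/sigma
#' normalizations. Graphs whose degree sequence admits no rewiring
#' (e.g. complete graphs) come back unchanged, so gamma = lambda = 1
#' there. Draws from R's RNG, so call `set.seed()` for reproducibility.
#'
#' @param g An undirected `igraph` graph with at least 2 edges.
#' @param n_null Number of rewired null graphs.
#' @return Named vector `c(Cp_rand, Lp_rand)`.
#' @export
random_null_metrics <- function(g, n_null = 100L) {
  el <- graph_edgelist(g)
  if (nrow(el) < 2L) stop("null model needs at least 2 edges",
                          call. = FALSE)
  m <- null_metrics_cpp(el, igraph::vcount(g), n_null,
                        n_swaps = 10L * nrow(el))
  c(Cp_rand = m$Cp_rand, Lp_rand = m$Lp_rand)
}

#' Area under a metric curve over the density grid
#'
#' Trapezoidal integral of metric values against density (the default),
#' or the "sum times step" convention of some connectome toolboxes
#' (`method = "step_sum"`), which differs from the trapezoid by a
#' constant factor on a uniform grid. Densities with non-finite values
#' are dropped pairwise (with a warning); at least two finite points are
#' required.
#'
#' @param values Metric value per density.
#' @param densities Density grid (same length).
#' @param method `"trapezoid"` or `"step_sum"`.
#' @return Scalar AUC.
#' @export
auc_over_densities <- function(values, densities,
                               method = c("trapezoid", "step_sum")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(densities))
  ok <- is.finite(values)
  if (sum(ok) < 2L) {
    stop("AUC needs at least two finite metric values", call. = FALSE)
  }
  if (!all(ok)) {
    warning(sum(!ok), " non-finite metric value(s) dropped from AUC",
            call. = FALSE)
  }
  if (method == "step_sum") {
    return(sum(values[ok]) * mean(diff(densities[ok])))
  }
  pracma::trapz(densities[ok], values[ok])
}

metric_names_global <- c("Cp", "Lp", "gamma", "lambda", "sigma",
                         "Eglob", "Eloc", "assortativity")
metric_names_nodal <- c("degree", "betweenness", "efficiency")

#' Metric curves and AUC summaries for one subject
#'
#' Binarizes the z-matrix at every grid density and computes the eight
#' global metrics (Cp, Lp, gamma, lambda, sigma, Eglob, Eloc,
#' assortativity) and, optionally, the three nodal metrics per parcel.
#' gamma = Cp / Cp_rand and lambda = Lp / Lp_rand use `n_null` rewired
#' graphs per density; sigma = gamma / lambda.
#'
#' @param z Symmetric connectivity matrix or `fc_matrix`.
#' @param densities Density grid (see [density_grid()]).
#' @param n_null Rewired null graphs per density.
#' @param include_nodal Compute nodal metrics too?
#' @return List with `global` (densities x 8 matrix), `global_auc`
#'   (length-8 vector), and when requested `nodal` (densities x N x 3
#'   array) and `nodal_auc` (N x 3 matrix).
#' @export
metric_curves <- function(z, densities = density_grid(), n_null = 100L,
                          include_nodal = TRUE) {
  if (inherits(z, "fc_matrix")) z <- z$z
  n <- nrow(z)
  ei <- edge_index(n)
  nd <- length(densities)
  glob <- matrix(NA_real_, nd, length(metric_names_global),
                 dimnames = list(NULL, metric_names_global))
  nodal <- if (include_nodal) {
    array(NA_real_, c(nd, n, length(metric_names_nodal)),
          dimnames = list(NULL, NULL, metric_names_nodal))
  }
  for (k in seq_len(nd)) {
    kept <- binarize_edges(z, densities[k], ei)
    m <- graph_metrics_cpp(kept, n, include_nodal = include_nodal)
    nulls <- null_metrics_cpp(kept, n, n_null,
                              n_swaps = 10L * nrow(kept))
    gamma <- m$Cp / nulls$Cp_rand
    lam <- m$Lp / nulls$Lp_rand
    glob[k, ] <- c(m$Cp, m$Lp, gamma, lam, gamma / lam, m$Eglob,
                   m$Eloc,
                   if (is.null(m$assortativity)) NaN else m$assortativity)
    if (include_nodal) {
      nodal[k, , ] <- cbind(m$degree, m$betweenness,
                            m$nodal_efficiency)
    }
  }
  safe_auc <- function(v) {
    tryCatch(suppressWarnings(auc_over_densities(v, densities)),
             error = function(e) NaN)
  }
  out <- list(global = glob, global_auc = apply(glob, 2L, safe_auc))
  if (include_nodal) {
    out$nodal <- nodal
    out$nodal_auc <- apply(nodal, c(2L, 3L), safe_auc)
  }
  out
}

#' Graph-metric AUC tables for a whole cohort
#'
#' @param fc_list Named list of `fc_matrix`.
#' @param densities Density grid.
#' @param n_null Rewired null graphs per subject and density.
#' @param include_nodal Compute nodal metrics too?
#' @param seed Optional seed set once before the (stochastic) null-model
#'   draws.
#' @return List with `global_auc` (data.frame, one row per subject, 8
#'   metric columns) and, when requested, `nodal_auc` (subjects x N x 3
#'   array).
#' @export
cohort_metrics <- function(fc_list, densities = density_grid(),
                           n_null = 100L, include_nodal = TRUE,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(fc_list, function(fc) {
    metric_curves(fc, densities = densities, n_null = n_null,
                  include_nodal = include_nodal)
  })
  ga <- do.call(rbind, lapply(res, `[[`, "global_auc"))
  global_auc <- data.frame(
    subject_id = vapply(fc_list, `[[`, character(1L), "subject_id"),
    ga, row.names = NULL, stringsAsFactors = FALSE)
  out <- list(global_auc = global_auc)
  if (include_nodal) {
    n <- nrow(res[[1L]]$nodal_auc)
    arr <- array(NA_real_, c(length(res), n, 3L),
                 dimnames = list(global_auc$subject_id, NULL,
                                 metric_names_nodal))
    for (s in seq_along(res)) arr[s, , ] <- res[[s]]$nodal_auc
    out$nodal_auc <- arr
  }
  out
}
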