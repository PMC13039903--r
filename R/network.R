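#' Build a co-occurrence network under the dual threshold
#'
#' Retains taxon pairs with q < `edge_q` AND |rho| > `edge_r` (the printed
#' criterion q < 0.005 and |r| > 0.5 by default); nodes are the endpoints of
#' retained edges. Set `q_matrix = NULL` to threshold on |rho| alone (used
#' by the bootstrap fast path).
#'
#' @param estimate a `sparcc_estimate` (or a plain correlation matrix).
#' @param q_matrix matching q-value matrix, or NULL.
#' @param edge_q,edge_r thresholds (defaults 0.005 and 0.5).
#' @return list of class `correlation_network`: `nodes`, `edges` (data.frame
#'   taxon_i, taxon_j, r, q, sign), `thresholds`, `taxa` (full taxon set).
#' @export
build_network <- function(estimate, q_matrix, edge_q = 0.005, edge_r = 0.5) {
  rho <- if (inherits(estimate, "sparcc_estimate")) estimate$rho else as.matrix(estimate)
  taxa <- colnames(rho) %||% paste0("T", seq_len(ncol(rho)))
  keep <- abs(rho) > edge_r
  if (!is.null(q_matrix)) {
    stopifnot(all(dim(q_matrix) == dim(rho)))
    keep <- keep & (q_matrix < edge_q)
  }
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    taxon_i = taxa[idx[, 1]], taxon_j = taxa[idx[, 2]],
    r = rho[idx],
    q = if (is.null(q_matrix)) rep(NA_real_, nrow(idx)) else q_matrix[idx],
    sign = ifelse(rho[idx] > 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  if (nrow(edges) == 0) warning("network has no edges under the thresholds")
  structure(
    list(nodes = sort(unique(c(edges$taxon_i, edges$taxon_j))),
         edges = edges,
         thresholds = list(edge_q = if (is.null(q_matrix)) NA else edge_q,
                           edge_r = edge_r),
         taxa = taxa),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("correlation_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$sign == "+"), "positive )\n")
  invisible(x)
}

network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("taxon_i", "taxon_j", "r")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
}

#' Community detection on the positive-edge subgraph
#'
#' Greedy modularity maximization (fast-greedy) on the subgraph of positive
#' edges weighted by |r|; modularity Q is computed on that subgraph. Module
#' count includes only communities with >= 2 vertices.
#'
#' @param network a `correlation_network` with >= 1 edge.
#' @return list `membership` (named), `Q`, `n_modules`.
#' @export
detect_modules <- function(network) {
  pos <- network$edges[network$edges$sign == "+", , drop = FALSE]
  if (nrow(pos) == 0) {
    return(list(membership = NULL, Q = NA_real_, n_modules = 0L, flag = "no positive edges"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = pos$taxon_i, to = pos$taxon_j, weight = abs(pos$r)),
    directed = FALSE)
  cm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cm)
  sizes <- table(memb)
  list(membership = memb,
       Q = igraph::modularity(g, memb, weights = igraph::E(g)$weight),
       n_modules = sum(sizes >= 2))
}

#' Topology summary of a co-occurrence network
#'
#' Edge/vertex counts, average degree 2E/V, average unweighted shortest path
#' length over connected ordered pairs, global transitivity, Freeman
#' normalized degree centralization (with the unnormalized maximum-degree
#' variant reported alongside, since the published variant is ambiguous),
#' modularity and module count from [detect_modules()].
#'
#' @param network a `correlation_network`.
#' @return one-row data.frame of class `topology_summary`.
#' @export
topology_summary <- function(network) {
  e <- network$edges
  if (nrow(e) == 0) {
    out <- data.frame(n_edges = 0L, n_positive = 0L, n_negative = 0L,
                      n_vertices = 0L, average_degree = 0, average_path_length = 0,
                      clustering_coefficient = 0, degree_centralization = 0,
                      max_degree = 0, modularity = 0, n_modules = 0L,
                      empty = TRUE)
    class(out) <- c("topology_summary", "data.frame")
    return(out)
  }
  g <- network_igraph(network)
  V <- igraph::vcount(g); E <- igraph::ecount(g)
  deg <- igraph::degree(g)
  sp <- igraph::distances(g, weights = NA)
  finite_off <- sp[is.finite(sp) & sp > 0]
  apl <- if (length(finite_off)) mean(finite_off) else 0
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  centr <- if (V > 2) sum(max(deg) - deg) / ((V - 1) * (V - 2)) else 0
  mods <- detect_modules(network)
  out <- data.frame(
    n_edges = as.integer(E),
    n_positive = sum(e$sign == "+"),
    n_negative = sum(e$sign == "-"),
    n_vertices = as.integer(V),
    average_degree = 2 * E / V,
    average_path_length = apl,
    clustering_coefficient = trans,
    degree_centralization = centr,
    max_degree = max(deg),
    modularity = if (is.na(mods$Q)) 0 else mods$Q,
    n_modules = mods$n_modules,
    empty = FALSE
  )
  class(out) <- c("topology_summary", "data.frame")
  out
}

#' Fast metric subset from an adjacency representation
#'
#' Matrix-based computation of the bootstrap metric subset (edge counts,
#' vertices, average degree, clustering coefficient); agrees with
#' [topology_summary()] and is cheap enough for thousands of bootstrap
#' resamples.
#'
#' @param rho correlation matrix.
#' @param edge_r absolute-correlation edge threshold.
#' @return named numeric vector.
#' @keywords internal
fast_topology_metrics <- function(rho, edge_r = 0.5) {
  A <- (abs(rho) > edge_r) * 1
  diag(A) <- 0
  deg <- rowSums(A)
  keep <- deg > 0
  Epos <- sum(rho > edge_r & upper.tri(rho))
  Eneg <- sum(rho < -edge_r & upper.tri(rho))
  E <- Epos + Eneg
  V <- sum(keep)
  if (V == 0) {
    return(c(n_edges = 0, n_positive = 0, n_negative = 0, n_vertices = 0,
             average_degree = 0, clustering_coefficient = 0))
  }
  Ak <- A[keep, keep, drop = FALSE]
  A2 <- Ak %*% Ak
  triangles <- sum(diag(A2 %*% Ak)) / 6
  dk <- rowSums(Ak)
  triples <- sum(dk * (dk - 1)) / 2
  cc <- if (triples > 0) 3 * triangles / triples else 0
  c(n_edges = E, n_positive = Epos, n_negative = Eneg, n_vertices = V,
    average_degree = 2 * E / V, clustering_coefficient = cc)
}
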