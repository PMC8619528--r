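# Node-level topology metrics in the Cytoscape NetworkAnalyzer convention
# (sign-agnostic, undirected, unweighted): degree, neighborhood connectivity
# (mean degree of the neighbors) and closeness centrality (reciprocal of the
# mean shortest-path length to the reachable nodes; degree-0 nodes score 0).
# Plus between-network comparisons of metric distributions (Mann-Whitney U).

adjacency_list <- function(network) {
  nodes <- network$nodes$genus
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  ed <- network$edges
  for (k in seq_len(nrow(ed))) {
    a <- ed$source[k]; b <- ed$target[k]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

bfs_distances <- function(adj, start) {
  dist <- stats::setNames(rep(NA_real_, length(adj)), names(adj))
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

check_node <- function(network, node) {
  if (!all(node %in% network$nodes$genus)) {
    stop("unknown node '", setdiff(node, network$nodes$genus)[1L], "'")
  }
}

#' Node degree (DG)
#' @param network a `taxon_network`.
#' @param node node name(s); default all nodes.
#' @return named integer vector of incident-edge counts (sign-agnostic).
#' @export
node_degree <- function(network, node = NULL) {
  adj <- adjacency_list(network)
  if (is.null(node)) node <- names(adj) else check_node(network, node)
  vapply(adj[node], length, integer(1))
}

#' Neighborhood connectivity (NC)
#'
#' Mean degree of a node's neighbors; 0 for degree-0 nodes by convention.
#'
#' @inheritParams node_degree
#' @return named numeric vector.
#' @export
neighborhood_connectivity <- function(network, node = NULL) {
  adj <- adjacency_list(network)
  deg <- vapply(adj, length, integer(1))
  if (is.null(node)) node <- names(adj) else check_node(network, node)
  vapply(node, function(v) {
    if (deg[[v]] == 0L) 0 else mean(deg[adj[[v]]])
  }, numeric(1))
}

#' Closeness centrality (CC)
#'
#' Cytoscape NetworkAnalyzer convention: CC(n) = 1 / mean(shortest-path
#' length from n to every node reachable from n); unreachable nodes are
#' excluded from the mean and degree-0 nodes score 0.
#'
#' @inheritParams node_degree
#' @return named numeric vector in [0, 1].
#' @export
closeness_centrality <- function(network, node = NULL) {
  adj <- adjacency_list(network)
  if (is.null(node)) node <- names(adj) else check_node(network, node)
  vapply(node, function(v) {
    if (!length(adj[[v]])) return(0)
    d <- bfs_distances(adj, v)
    d <- d[names(d) != v & !is.na(d)]
    if (!length(d)) 0 else 1 / mean(d)
  }, numeric(1))
}

#' All topology metrics of one network
#' @param network a `taxon_network`.
#' @return data.frame section, dose_ppb, genus, degree,
#'   neighborhood_connectivity, closeness_centrality.
#' @export
network_topology <- function(network) {
  data.frame(section = network$section, dose_ppb = network$dose_ppb,
             genus = network$nodes$genus,
             degree = unname(node_degree(network)),
             neighborhood_connectivity = unname(neighborhood_connectivity(network)),
             closeness_centrality = unname(closeness_centrality(network)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Mann-Whitney U, two-sided, normal approximation with tie correction
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  p <- if (v <= 0) 1 else 2 * stats::pnorm(-abs((u1 - mu) / sqrt(v)))
  list(U = u1, p = min(1, p))
}

#' Compare a topology metric between two networks
#'
#' Two-sided Mann-Whitney U on the per-node metric distributions, normal
#' approximation with tie correction; the direction is reported as the
#' difference of medians (A minus B).
#'
#' @param topo_a,topo_b [network_topology()] rows of the two networks
#'   (>= 3 nodes each).
#' @param metric `"degree"`, `"neighborhood_connectivity"` or
#'   `"closeness_centrality"`.
#' @return list: U_stat, p_two_sided, median_a, median_b, median_diff.
#' @export
compare_networks <- function(topo_a, topo_b,
                             metric = c("degree", "neighborhood_connectivity",
                                        "closeness_centrality")) {
  metric <- match.arg(metric)
  if (nrow(topo_a) < 3L || nrow(topo_b) < 3L) {
    stop("compare_networks: need at least 3 nodes per network")
  }
  x <- topo_a[[metric]]; y <- topo_b[[metric]]
  mw <- mann_whitney_u(x, y)
  list(metric = metric, U_stat = mw$U, p_two_sided = mw$p,
       median_a = stats::median(x), median_b = stats::median(y),
       median_diff = stats::median(x) - stats::median(y))
}

#' Topology comparison grid across a network set
#'
#' Within each gut section, compares every exposed network against the
#' control and every exposed pair, for each metric. No multiplicity
#' correction is applied by default; `adjust = "BH"` adds an adjusted column.
#'
#' @param nets a `taxon_network_set`.
#' @param control_ppb control dose (default 0).
#' @param adjust `"none"` (default) or `"BH"` across the whole grid.
#' @return data.frame section, dose_a, dose_b, metric, U_stat, p (and p_adj).
#' @export
compare_all_networks <- function(nets, control_ppb = 0, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  topo <- lapply(nets, network_topology)
  info <- data.frame(name = names(nets),
                     section = vapply(nets, function(n) n$section, character(1)),
                     dose = vapply(nets, function(n) n$dose_ppb, numeric(1)),
                     stringsAsFactors = FALSE)
  rows <- list()
  for (s in unique(info$section)) {
    sub <- info[info$section == s, ]
    doses <- sort(sub$dose)
    if (length(doses) < 2L) next
    prs <- utils::combn(doses, 2L)
    for (k in seq_len(ncol(prs))) {
      a <- sub$name[sub$dose == prs[2L, k]]  # higher dose as A
      b <- sub$name[sub$dose == prs[1L, k]]
      for (metric in c("degree", "neighborhood_connectivity",
                       "closeness_centrality")) {
        cm <- compare_networks(topo[[a]], topo[[b]], metric)
        rows[[length(rows) + 1L]] <- data.frame(
          section = s, dose_a = prs[2L, k], dose_b = prs[1L, k],
          metric = metric, U_stat = cm$U_stat, p = cm$p_two_sided,
          median_diff = cm$median_diff, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
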