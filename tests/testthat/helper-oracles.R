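# Shared fixtures and independent oracles, built in code at test time.

# --- graph fixtures -------------------------------------------------------

# build a taxon_network from a character edge list, e.g. c("A-B", "B-C")
make_net <- function(edge_spec, nodes = NULL, section = "midgut", dose = 0,
                     rho = 0.9) {
  ed <- if (length(edge_spec)) {
    parts <- strsplit(edge_spec, "-", fixed = TRUE)
    data.frame(source = vapply(parts, `[`, "", 1L),
               target = vapply(parts, `[`, "", 2L),
               rho = rho, p_fdr = 1e-4, p_bonf = 1e-3,
               sign = ifelse(rho >= 0, "+", "-"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(0), target = character(0), rho = numeric(0),
               p_fdr = numeric(0), p_bonf = numeric(0), sign = character(0))
  }
  if (is.null(nodes)) nodes <- sort(unique(c(ed$source, ed$target)))
  taxon_network(data.frame(genus = nodes, total_activity = 1,
                           occurrence = 10L, class = "noncore",
                           stringsAsFactors = FALSE),
                ed, section, dose)
}

# Erdos-Renyi taxon_network on n nodes
random_net <- function(n, p = 0.2) {
  nodes <- sprintf("g%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  make_net(paste(pairs[keep, 1L], pairs[keep, 2L], sep = "-"), nodes = nodes)
}

# --- brute-force topology oracle (adjacency matrix + Floyd-Warshall) ------

oracle_topology <- function(net) {
  nodes <- net$nodes$genus
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(net$edges))) {
    A[net$edges$source[k], net$edges$target[k]] <- 1
    A[net$edges$target[k], net$edges$source[k]] <- 1
  }
  deg <- rowSums(A)
  nc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (!length(nb)) 0 else mean(deg[nb])
  }, numeric(1))
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  cc <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]; d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / mean(d)
  }, numeric(1))
  data.frame(genus = nodes, degree = deg, nc = nc, cc = cc,
             row.names = NULL, stringsAsFactors = FALSE)
}

# --- rank-walk LCA oracle -------------------------------------------------

oracle_lca <- function(lins) {
  m <- do.call(rbind, lapply(lins, unclass))
  out <- stats::setNames(rep("", 7L), colnames(m))
  for (i in 1:7) {
    if (length(unique(m[, i])) == 1L && m[1L, i] != "") out[i] <- m[1L, i]
    else break
  }
  out
}

# --- Monte-Carlo Spearman permutation oracle ------------------------------

oracle_spearman_perm <- function(x, y, n_perm) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (abs(stats::cor(rx, ry[sample.int(length(y))])) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  (1 + hits) / (n_perm + 1)
}

# --- per-subject expansion of a survival ledger (for survival:: oracle) ---

ledger_to_subjects <- function(ledger) {
  rows <- list()
  for (i in seq_len(nrow(ledger))) {
    d <- ledger$day[i]
    if (ledger$deaths[i] > 0) {
      rows[[length(rows) + 1L]] <- data.frame(time = d, status = 1L,
                                              n = ledger$deaths[i])
    }
    if (ledger$censored[i] > 0) {
      rows[[length(rows) + 1L]] <- data.frame(time = d, status = 0L,
                                              n = ledger$censored[i])
    }
  }
  # survivors at the horizon are censored there
  last <- max(ledger$day)
  agg <- stats::aggregate(cbind(n_at_risk = ledger$n_at_risk,
                                deaths = ledger$deaths,
                                censored = ledger$censored),
                          by = list(day = ledger$day), FUN = sum)
  final_alive <- agg$n_at_risk[agg$day == last] - agg$deaths[agg$day == last] -
    agg$censored[agg$day == last]
  if (final_alive > 0) {
    rows[[length(rows) + 1L]] <- data.frame(time = last, status = 0L,
                                            n = final_alive)
  }
  df <- do.call(rbind, rows)
  data.frame(time = rep(df$time, df$n), status = rep(df$status, df$n))
}

# small genus matrix with named rows of samples
sample_matrix <- function(data, samples, taxa) {
  matrix(data, nrow = length(samples), byrow = TRUE,
         dimnames = list(samples, taxa))
}
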