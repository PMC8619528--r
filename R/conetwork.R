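# The core procedure: per condition (gut section x dose), build the
# genus-level co-abundance network from Spearman correlations of relative
# activities, with dual multiple-testing control (Benjamini-Hochberg AND
# Bonferroni) and the |rho| >= 0.4 rule; genera must occur in more than 70%
# of the condition's samples (n > 7 of 10 in the full design) to enter.

#' Aggregate an ASV table to the genus level
#'
#' Counts are summed over ASVs sharing a genus. ASVs whose deepest assigned
#' rank is above genus are grouped under `unassigned_<rank>_<name>` buckets
#' (never merged into a named genus); fully unassigned ASVs fall into
#' `unassigned`. Output columns are ordered by descending total activity,
#' ties lexicographic.
#'
#' @param table ASV-level `activity_table`.
#' @param lineages data.frame asv_id + the seven rank columns, covering every
#'   ASV in `table`.
#' @return genus-level `activity_table`.
#' @export
aggregate_genus <- function(table, lineages) {
  m <- unclass(as.matrix(table))
  idx <- match(colnames(m), lineages$asv_id)
  if (anyNA(idx)) stop("aggregate_genus: no lineage for ASV '",
                       colnames(m)[which(is.na(idx))[1L]], "'")
  lin <- lineages[idx, , drop = FALSE]
  ranks_above_genus <- c("superkingdom", "phylum", "class", "order", "family")
  label <- vapply(seq_len(nrow(lin)), function(i) {
    if (!is.na(lin$genus[i]) && lin$genus[i] != "") return(lin$genus[i])
    named <- ranks_above_genus[vapply(ranks_above_genus, function(r) {
      !is.na(lin[[r]][i]) && lin[[r]][i] != ""
    }, logical(1))]
    if (!length(named)) return("unassigned")
    deepest <- named[length(named)]
    paste("unassigned", deepest, lin[[deepest]][i], sep = "_")
  }, character(1))
  agg <- t(rowsum(t(m), group = label))
  ord <- order(-colSums(agg), colnames(agg))
  agg <- agg[, ord, drop = FALSE]
  gnd_log("network", "aggregated %d ASVs into %d genus-level taxa",
          ncol(m), ncol(agg))
  activity_table(agg)
}

#' Occurrence filter for one condition subset
#'
#' A genus is retained iff it is present (count > 0) in strictly more than
#' `min_frac` of the subset's samples — 8 of 10 under the full design (the
#' "n > 7 on 10 samples" rule), generalized as strict > 0.7 N elsewhere.
#'
#' @param table genus-level `activity_table` restricted to one condition.
#' @param min_frac occurrence fraction that must be exceeded (default 0.7).
#' @return character vector of retained genus names.
#' @export
occurrence_filter <- function(table, min_frac = 0.7) {
  m <- unclass(as.matrix(table))
  if (nrow(m) < 4L) stop("occurrence_filter: fewer than 4 samples; ",
                         "correlations would be meaningless")
  occ <- colSums(m > 0)
  keep <- occ > min_frac * nrow(m)
  gnd_log("network", "occurrence filter kept %d of %d genera (> %.1f of %d samples)",
          sum(keep), ncol(m), min_frac * nrow(m), nrow(m))
  colnames(m)[keep]
}

#' Spearman correlation screen for one condition subset
#'
#' Computes Spearman's rho (average-rank ties) on per-sample relative
#' activities for every unordered genus pair, with two-sided p values from
#' the t approximation t = rho sqrt((n-2)/(1-rho^2)), df = n-2 (p = 0 at
#' |rho| = 1), or from Monte-Carlo permutations. BH and Bonferroni
#' adjustments run across the g(g-1)/2 upper-triangle family; genera that are
#' constant across the subset produce NaN correlations and are removed from
#' the family (logged), so p_bonf = min(1, m p_raw) with m the non-NaN pair
#' count.
#'
#' @param table genus-level `activity_table` restricted to one condition
#'   (>= 4 samples, >= 2 genera).
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutations (permutation mode).
#' @param relative correlate per-sample proportions (default TRUE; rank-based,
#'   so this only matters when sequencing depths differ).
#' @return data.frame of class `correlation_screen` (genus_a, genus_b, rho,
#'   p_raw, p_bh, p_bonf) with attributes `n_samples`, `m_family`,
#'   `dropped_constant`.
#' @export
spearman_screen <- function(table, p_method = c("t", "permutation"),
                            n_perm = 10000L, relative = TRUE) {
  p_method <- match.arg(p_method)
  m <- unclass(as.matrix(table))
  n <- nrow(m)
  if (n < 4L) stop("spearman_screen: need at least 4 samples")
  if (ncol(m) < 2L) stop("spearman_screen: need at least 2 genera")
  if (relative) m <- m / rowSums(m)
  constant <- apply(m, 2L, function(x) length(unique(x)) == 1L)
  dropped <- colnames(m)[constant]
  if (length(dropped)) {
    gnd_log("network", "dropping %d constant genus(era) from the family: %s",
            length(dropped), paste(dropped, collapse = ", "))
    m <- m[, !constant, drop = FALSE]
  }
  g <- ncol(m)
  rk <- apply(m, 2L, rank)
  R <- stats::cor(rk)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  rho <- R[ut]
  rho <- pmin(1, pmax(-1, rho))
  if (p_method == "t") {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p_raw <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p_raw[abs(rho) >= 1 - 1e-12] <- 0
  } else {
    p_raw <- vapply(seq_len(nrow(ut)), function(k) {
      ri <- rk[, ut[k, 1L]]; rj <- rk[, ut[k, 2L]]
      obs <- abs(stats::cor(ri, rj))
      perm <- vapply(seq_len(n_perm), function(b)
        abs(stats::cor(ri, rj[sample.int(n)])), numeric(1))
      (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
    }, numeric(1))
  }
  out <- data.frame(genus_a = colnames(m)[ut[, 1L]],
                    genus_b = colnames(m)[ut[, 2L]],
                    rho = rho, p_raw = p_raw,
                    p_bh = stats::p.adjust(p_raw, "BH"),
                    p_bonf = stats::p.adjust(p_raw, "bonferroni"),
                    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- n
  attr(out, "m_family") <- nrow(out)
  attr(out, "dropped_constant") <- dropped
  class(out) <- c("correlation_screen", "data.frame")
  out
}

#' Construct a validated taxon network
#' @param nodes data.frame genus, total_activity, occurrence, class.
#' @param edges data.frame source, target, rho, p_fdr, p_bonf, sign.
#' @param section,dose_ppb condition labels.
#' @return list of class `taxon_network`.
#' @export
taxon_network <- function(nodes, edges, section, dose_ppb) {
  stopifnot(all(c("genus") %in% names(nodes)),
            all(c("source", "target", "rho", "sign") %in% names(edges)) ||
              nrow(edges) == 0L)
  if (nrow(edges)) {
    if (any(edges$source == edges$target)) stop("taxon_network: self-edge")
    if (!all(c(edges$source, edges$target) %in% nodes$genus)) {
      stop("taxon_network: edge endpoint missing from node table")
    }
  }
  structure(list(section = section, dose_ppb = dose_ppb,
                 nodes = nodes, edges = edges),
            class = "taxon_network")
}

#' @export
print.taxon_network <- function(x, ...) {
  cat(sprintf("taxon_network [%s, %s ppb]: %d nodes, %d edges (%d +, %d -)\n",
              x$section, dose_label(x$dose_ppb), nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  invisible(x)
}

#' Build the co-abundance network from a correlation screen
#'
#' An edge is kept iff |rho| >= `rho_min` AND p_BH < `alpha` AND (by default)
#' p_Bonferroni < `alpha`; its sign is the sign of rho. Retained genera
#' without any significant partner stay as degree-0 nodes.
#'
#' @param screen a `correlation_screen` computed on the retained genera.
#' @param nodes data.frame genus, total_activity, occurrence, class for the
#'   retained genera.
#' @param section,dose_ppb condition labels.
#' @param rho_min absolute-correlation threshold (default 0.4).
#' @param alpha significance level for both corrected p values (default 0.05).
#' @param require_bonferroni enforce the Bonferroni clause (default TRUE;
#'   FALSE relaxes to BH-only).
#' @return a `taxon_network`.
#' @export
build_network <- function(screen, nodes, section, dose_ppb, rho_min = 0.4,
                          alpha = 0.05, require_bonferroni = TRUE) {
  keep <- abs(screen$rho) >= rho_min & screen$p_bh < alpha
  if (require_bonferroni) keep <- keep & screen$p_bonf < alpha
  ed <- screen[keep, , drop = FALSE]
  edges <- data.frame(source = ed$genus_a, target = ed$genus_b, rho = ed$rho,
                      p_fdr = ed$p_bh, p_bonf = ed$p_bonf,
                      sign = ifelse(ed$rho >= 0, "+", "-"),
                      row.names = NULL, stringsAsFactors = FALSE)
  taxon_network(nodes, edges, section, dose_ppb)
}

#' Build one condition's network from a genus table and metadata
#'
#' Runs the full per-condition chain: sample subsetting, occurrence filter,
#' taxon classification ([classify_taxa()]), Spearman screen on the retained
#' genera, and edge-rule application.
#'
#' @param genus_table genus-level `activity_table` (all samples).
#' @param meta matching `sample_meta`.
#' @param section,dose_ppb the condition.
#' @param core_genera passed to [classify_taxa()].
#' @param ... passed to [build_network()] / [spearman_screen()].
#' @param min_frac occurrence threshold fraction (default 0.7).
#' @return a `taxon_network`.
#' @export
condition_network <- function(genus_table, meta, section, dose_ppb,
                              core_genera = CORE_GENERA, min_frac = 0.7, ...) {
  meta <- as.data.frame(meta)
  ids <- meta$sample_id[meta$gut_section == section & meta$dose_ppb == dose_ppb]
  ids <- intersect(ids, rownames(genus_table))
  if (!length(ids)) stop("condition_network: no samples for ", section, " at ",
                         dose_label(dose_ppb), " ppb")
  sub <- unclass(as.matrix(genus_table))[ids, , drop = FALSE]
  retained <- occurrence_filter(sub, min_frac = min_frac)
  cls <- classify_taxa(sub, core_genera = core_genera)
  rel <- sub / rowSums(sub)
  screen <- spearman_screen(sub[, retained, drop = FALSE], ...)
  nodes <- data.frame(genus = retained,
                      total_activity = colSums(rel[, retained, drop = FALSE]),
                      occurrence = colSums(sub[, retained, drop = FALSE] > 0),
                      class = cls[retained],
                      row.names = NULL, stringsAsFactors = FALSE)
  build_network(screen, nodes, section, dose_ppb)
}

#' Build every condition's network
#'
#' One network per gut section x dose cell of the design (12 under the full
#' study). Missing cells are a hard error listing the absent conditions.
#'
#' @param genus_table,meta,... as in [condition_network()].
#' @param sections,doses_ppb design cells expected (defaults: the full design).
#' @return named list of `taxon_network` (class `taxon_network_set`).
#' @export
run_all_conditions <- function(genus_table, meta,
                               sections = GUT_SECTIONS, doses_ppb = DOSES_PPB,
                               ...) {
  meta <- as.data.frame(meta)
  cells <- expand.grid(section = sections, dose_ppb = doses_ppb,
                       stringsAsFactors = FALSE)
  have <- mapply(function(s, d) any(meta$gut_section == s & meta$dose_ppb == d),
                 cells$section, cells$dose_ppb)
  if (!all(have)) {
    miss <- cells[!have, ]
    stop("run_all_conditions: no samples for condition(s): ",
         paste(sprintf("%s/%s ppb", miss$section, dose_label(miss$dose_ppb)),
               collapse = ", "))
  }
  ord <- order(match(cells$section, sections), match(cells$dose_ppb, doses_ppb))
  cells <- cells[ord, ]
  nets <- mapply(function(s, d) condition_network(genus_table, meta, s, d, ...),
                 cells$section, cells$dose_ppb, SIMPLIFY = FALSE)
  names(nets) <- sprintf("%s_d%s", cells$section, dose_label(cells$dose_ppb))
  class(nets) <- "taxon_network_set"
  nets
}

#' Per-condition node and signed-edge tallies
#' @param nets a `taxon_network_set` (or list of `taxon_network`).
#' @return data.frame condition, section, dose_ppb, nodes, pos_edges, neg_edges.
#' @export
network_summary <- function(nets) {
  out <- do.call(rbind, lapply(names(nets), function(nm) {
    nt <- nets[[nm]]
    data.frame(condition = nm, section = nt$section, dose_ppb = nt$dose_ppb,
               nodes = nrow(nt$nodes),
               pos_edges = sum(nt$edges$sign == "+"),
               neg_edges = sum(nt$edges$sign == "-"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
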