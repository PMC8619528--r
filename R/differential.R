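# Differential activity of ASVs per section and dose vs control: a fully
# specified median-of-ratios + Wilcoxon stand-in producing signed log2 fold
# changes with BH-adjusted p values. Deliberately simple: the scientific
# readout downstream is the dysbiosis signature, not the DE engine.

#' Median-of-ratios size factors
#'
#' factor_j = median over taxa of count_ij / geometric-mean_i(count_i.),
#' medians over taxa with all-positive counts, factors normalized to
#' geometric mean 1. When no taxon is positive in every sample, the
#' "poscounts" fallback takes geometric means over positive entries only.
#'
#' @param table `activity_table` or matrix, samples in rows.
#' @param fallback `"poscounts"` (default) or `"error"`.
#' @return named numeric vector of per-sample scale factors.
#' @export
size_factors <- function(table, fallback = c("poscounts", "error")) {
  fallback <- match.arg(fallback)
  m <- unclass(as.matrix(table))
  if (nrow(m) < 2L) stop("size_factors: need at least two samples")
  all_pos <- colSums(m > 0) == nrow(m)
  if (any(all_pos)) {
    sub <- m[, all_pos, drop = FALSE]
    ref <- exp(colMeans(log(sub)))
    sf <- apply(sweep(sub, 2L, ref, "/"), 1L, stats::median)
  } else if (fallback == "poscounts") {
    gnd_log("diff", "no all-positive taxon; poscounts fallback")
    lg <- log(m); lg[!is.finite(lg)] <- NA
    ref <- exp(colMeans(lg, na.rm = TRUE))
    keep <- is.finite(ref) & ref > 0
    if (!any(keep)) stop("size_factors: no usable taxon")
    sf <- vapply(seq_len(nrow(m)), function(i) {
      r <- m[i, keep] / ref[keep]
      stats::median(r[m[i, keep] > 0])
    }, numeric(1))
  } else {
    stop("size_factors: no taxon with all-positive counts and fallback disabled")
  }
  if (anyNA(sf) || any(sf <= 0)) stop("size_factors: undefined factor for sample '",
                                      rownames(m)[which(is.na(sf) | sf <= 0)[1L]], "'")
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- rownames(m)
  sf
}

#' Differential activity, one section and dose vs control
#'
#' Subsets the two arms within a gut section, normalizes by [size_factors()]
#' computed on that two-arm subset, and reports per ASV the signed log2 fold
#' change log2((mean_exposed + c) / (mean_control + c)) with pseudocount
#' c = 0.5 normalized counts, a two-sided Wilcoxon rank-sum p value on the
#' normalized counts, and BH adjustment across the ASV family. ASVs absent
#' from both arms are suppressed. Swapping the arm labels negates every fold
#' change and leaves p values unchanged; per-sample depth rescaling leaves
#' fold changes unchanged up to the pseudocount perturbation.
#'
#' @param table ASV-level `activity_table` of raw counts.
#' @param meta matching `sample_meta`.
#' @param section gut section to analyze.
#' @param dose_ppb exposed dose.
#' @param control_ppb control dose (default 0).
#' @param pseudocount c above (default 0.5).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame of class `diff_result`: asv_id, section, dose_ppb,
#'   base_mean_control, base_mean_exposed, log2fc, p_raw, p_adj, direction,
#'   significant.
#' @export
diff_activity <- function(table, meta, section, dose_ppb, control_ppb = 0,
                          pseudocount = 0.5, alpha = 0.05) {
  m <- unclass(as.matrix(table))
  meta <- as.data.frame(meta)
  pick <- function(dose) meta$sample_id[meta$gut_section == section &
                                          meta$dose_ppb == dose]
  ctrl_ids <- intersect(pick(control_ppb), rownames(m))
  expo_ids <- intersect(pick(dose_ppb), rownames(m))
  if (length(ctrl_ids) < 3L || length(expo_ids) < 3L) {
    stop("diff_activity: fewer than 3 samples per arm for ", section, " at ",
         dose_label(if (length(ctrl_ids) < 3L) control_ppb else dose_ppb),
         " ppb")
  }
  sub <- m[c(ctrl_ids, expo_ids), , drop = FALSE]
  norm <- sub / size_factors(sub)
  present <- colSums(norm) > 0
  gnd_log("diff", "%s %s ppb vs %s ppb: %d of %d ASVs present",
          section, dose_label(dose_ppb), dose_label(control_ppb),
          sum(present), ncol(norm))
  norm <- norm[, present, drop = FALSE]
  mean_c <- colMeans(norm[ctrl_ids, , drop = FALSE])
  mean_e <- colMeans(norm[expo_ids, , drop = FALSE])
  log2fc <- log2((mean_e + pseudocount) / (mean_c + pseudocount))
  p_raw <- vapply(colnames(norm), function(a) {
    suppressWarnings(stats::wilcox.test(norm[expo_ids, a], norm[ctrl_ids, a],
                                        exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  p_raw[!is.finite(p_raw)] <- 1  # constant-everywhere ASVs carry no signal
  p_adj <- stats::p.adjust(p_raw, "BH")
  out <- data.frame(asv_id = colnames(norm), section = section,
                    dose_ppb = dose_ppb,
                    base_mean_control = unname(mean_c),
                    base_mean_exposed = unname(mean_e),
                    log2fc = unname(log2fc), p_raw = unname(p_raw),
                    p_adj = unname(p_adj),
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    significant = unname(p_adj < alpha),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Differential activity across every section and exposed dose
#' @param table,meta as in [diff_activity()].
#' @param ... passed to [diff_activity()].
#' @return row-bound `diff_result` across all section x dose cells.
#' @export
diff_activity_all <- function(table, meta, ...) {
  meta <- as.data.frame(meta)
  sections <- unique(meta$gut_section)
  doses <- setdiff(sort(unique(meta$dose_ppb)), 0)
  out <- do.call(rbind, lapply(sections, function(s) {
    do.call(rbind, lapply(doses, function(d) diff_activity(table, meta, s, d, ...)))
  }))
  class(out) <- c("diff_result", "data.frame")
  out
}
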