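# Alpha diversity per sample (Chao1 richness, Shannon diversity in nats)
# and the nonparametric group-comparison chain:
# Kruskal-Wallis -> Dunn's post hoc z tests -> Benjamini-Hochberg.

#' Chao1 bias-corrected richness estimator
#'
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)) with F1 singletons and F2 doubletons.
#' Defined on raw integer counts only (undefined on normalized data); an
#' all-zero sample has richness 0.
#'
#' @param counts one sample's non-negative integer taxon counts.
#' @return estimated richness [taxa].
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("chao1: negative counts")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("chao1: non-integer counts (Chao1 is undefined on normalized data)")
  }
  s_obs <- sum(counts > 0)
  if (s_obs == 0L) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over taxa with p_i > 0.
#'
#' @param counts one sample's non-negative taxon counts, sum > 0.
#' @return diversity [nats].
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("shannon: negative counts")
  tot <- sum(counts)
  if (tot <= 0) stop("shannon: zero-sum sample")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Per-sample alpha diversity of an activity table
#' @param table an `activity_table` of raw counts.
#' @return data.frame sample_id, observed, chao1, shannon.
#' @export
alpha_diversity <- function(table) {
  m <- unclass(as.matrix(table))
  data.frame(sample_id = rownames(m),
             observed = apply(m, 1L, function(x) sum(x > 0)),
             chao1 = apply(m, 1L, chao1),
             shannon = apply(m, 1L, shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H over all groups, then pairwise Dunn z
#' statistics on the pooled ranks,
#' z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)) with tie
#' correction T = sum(t^3 - t) / (12 (N - 1)), two-sided normal p values,
#' Benjamini-Hochberg adjusted across the pairwise family. With two groups
#' the single Dunn p equals the Kruskal-Wallis p (z^2 = H).
#'
#' @param values numeric response.
#' @param groups group labels, same length; >= 2 groups of >= 2 values each.
#' @return list of class `kw_dunn`: `H`, `df`, `p_kw` and a `comparisons`
#'   data.frame (group_a, group_b, dunn_z, p_raw, p_bh).
#' @export
kw_dunn <- function(values, groups) {
  groups <- factor(groups)
  n_g <- table(groups)
  if (nlevels(groups) < 2L) stop("kw_dunn: need at least two groups")
  if (any(n_g < 2L)) {
    stop("kw_dunn: group '", names(n_g)[n_g < 2L][1L], "' has fewer than 2 values")
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  comparisons <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                            dunn_z = z, p_raw = p_raw,
                            p_bh = stats::p.adjust(p_raw, "BH"),
                            stringsAsFactors = FALSE)
  structure(list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p_kw = kw$p.value, comparisons = comparisons),
            class = "kw_dunn")
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g (df = %d), p = %.4g\n",
              x$H, x$df, x$p_kw))
  print(x$comparisons)
  invisible(x)
}

#' Alpha-diversity group comparisons of an activity table
#'
#' Computes per-sample Chao1 and Shannon and compares them across doses with
#' [kw_dunn()], either pooling gut sections (default, matching the pooled
#' "all gut sections" readout) or stratified per section.
#'
#' @param table `activity_table` of raw ASV counts.
#' @param meta matching `sample_meta`.
#' @param stratify_section run one comparison chain per gut section.
#' @return list with `diversity` (per-sample table) and `tests` (data.frame
#'   of metric, section, group_a, group_b, H_stat, dunn_z, p_raw, p_bh).
#' @export
diversity_analysis <- function(table, meta, stratify_section = FALSE) {
  div <- alpha_diversity(table)
  div <- merge(div, as.data.frame(meta)[, c("sample_id", "gut_section", "dose_ppb")],
               by = "sample_id", sort = FALSE)
  strata <- if (stratify_section) split(div, div$gut_section) else list(all = div)
  tests <- do.call(rbind, lapply(names(strata), function(s) {
    d <- strata[[s]]
    do.call(rbind, lapply(c("chao1", "shannon"), function(metric) {
      res <- kw_dunn(d[[metric]], dose_label(d$dose_ppb))
      cbind(metric = metric, section = s, H_stat = res$H, res$comparisons)
    }))
  }))
  rownames(tests) <- NULL
  list(diversity = div, tests = tests)
}
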