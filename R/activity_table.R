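# The ActivityTable: a samples x taxa matrix of non-negative transcript-derived
# counts (or normalized activities). Rows are samples, columns are ASVs or
# genera. Stored as a plain numeric matrix with class "activity_table";
# integrality is enforced only when ingesting raw count tables.

#' Construct a validated activity table
#'
#' An activity table holds one row per sample and one column per taxon (ASV or
#' genus) of non-negative activity values. Samples whose row sum is zero carry
#' no information for any downstream stage and are dropped with a warning.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids,taxon_ids identifiers; default to the dimnames of `counts`.
#' @param integer_counts require integer values (raw transcript counts).
#' @param drop_empty drop samples whose counts sum to zero (with a warning).
#' @return a matrix of class `activity_table`.
#' @export
activity_table <- function(counts, sample_ids = rownames(counts),
                           taxon_ids = colnames(counts),
                           integer_counts = FALSE, drop_empty = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(taxon_ids)) {
    stop("activity_table: sample and taxon identifiers are required")
  }
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (nrow(counts) != length(sample_ids) || ncol(counts) != length(taxon_ids)) {
    stop("activity_table: dimensions inconsistent with id lists")
  }
  if (anyDuplicated(sample_ids)) {
    stop("activity_table: duplicate sample id '",
         sample_ids[duplicated(sample_ids)][1L], "'")
  }
  if (anyDuplicated(taxon_ids)) {
    stop("activity_table: duplicate taxon id '",
         taxon_ids[duplicated(taxon_ids)][1L], "'")
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1L, ]
    stop("activity_table: non-numeric count at sample '", sample_ids[bad[1L]],
         "', taxon '", taxon_ids[bad[2L]], "'")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("activity_table: negative count ", counts[bad[1L], bad[2L]],
         " at sample '", sample_ids[bad[1L]], "', taxon '",
         taxon_ids[bad[2L]], "'")
  }
  if (integer_counts && any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop("activity_table: non-integer count ", counts[bad[1L], bad[2L]],
         " at sample '", sample_ids[bad[1L]], "', taxon '",
         taxon_ids[bad[2L]], "'")
  }
  dimnames(counts) <- list(sample_ids, taxon_ids)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    if (!drop_empty) stop("activity_table: sample '",
                          sample_ids[empty][1L], "' has all-zero counts")
    warning("activity_table: dropping ", sum(empty),
            " all-zero sample(s): ", paste(sample_ids[empty], collapse = ", "))
    gnd_log("ingest", "dropped %d all-zero sample(s)", sum(empty))
    counts <- counts[!empty, , drop = FALSE]
  }
  structure(counts, class = c("activity_table", class(counts)))
}

#' @export
print.activity_table <- function(x, ...) {
  cat("activity_table:", nrow(x), "samples x", ncol(x), "taxa; total activity",
      format(sum(x)), "\n")
  invisible(x)
}

#' Per-sample relative activity
#'
#' Divides each sample's counts by the sample total, so every row sums to one.
#'
#' @param x an `activity_table` or numeric matrix with samples in rows.
#' @return matrix of per-sample proportions.
#' @export
relative_activity <- function(x) {
  m <- unclass(as.matrix(x))
  sweep(m, 1L, rowSums(m), "/")
}
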