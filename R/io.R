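# Readers and writers: activity tables (TSV, dense BIOM JSON), sample
# metadata, and network exports (SIF / GraphML / edge TSV) that Cytoscape
# can open directly.

#' Read an activity table
#'
#' TSV dialect: header row; first column holds sample ids, remaining columns
#' taxon ids, tab-separated. Dense BIOM-style JSON is read through the
#' `biomformat` package (observations x samples, transposed on ingestion).
#' Orientation is fixed as samples-in-rows; the transpose is auto-detected
#' only when `meta` is supplied and the column ids (not the row ids) match its
#' sample list — silent transposition is the classic microbiome-pipeline bug.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom_json"`.
#' @param meta optional `sample_meta` table used for orientation checking.
#' @param integer_counts enforce integrality (default TRUE: raw counts).
#' @return an `activity_table`.
#' @export
read_activity_table <- function(path, format = c("tsv", "biom_json"),
                                meta = NULL, integer_counts = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_activity_table: no such file: ", path)
  if (format == "biom_json") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("read_activity_table: the 'biomformat' package is required for biom_json input")
    }
    b <- biomformat::read_biom(path)
    m <- t(as(biomformat::biom_data(b), "matrix"))  # -> samples x taxa
    return(activity_table(m, integer_counts = integer_counts))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("read_activity_table: malformed header in ", path,
                          " (need sample_id plus at least one taxon column)")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("read_activity_table: non-numeric count at sample '", ids[bad[1L]],
           "', taxon '", colnames(m)[bad[2L]], "'")
    }
  }
  rownames(m) <- ids
  if (!is.null(meta)) {
    known <- as.character(meta$sample_id)
    rows_match <- all(rownames(m) %in% known)
    cols_match <- all(colnames(m) %in% known)
    if (!rows_match && cols_match) {
      gnd_log("ingest", "taxon ids match the metadata sample list; transposing")
      m <- t(m)
    } else if (!rows_match && !cols_match) {
      stop("read_activity_table: neither rows nor columns of ", path,
           " match the metadata sample list")
    }
  }
  gnd_log("ingest", "read %d samples x %d taxa from %s", nrow(m), ncol(m), path)
  activity_table(m, integer_counts = integer_counts)
}

#' Write an activity table as TSV (samples in rows)
#' @param x an `activity_table`.
#' @param path output file.
#' @export
write_activity_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(as.matrix(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample metadata table
#'
#' Required columns: `sample_id`, `cage`, `gut_section`, `dose_ppb`,
#' `replicate`, `timepoint_day`. Sections outside midgut/ileum/rectum and
#' doses outside 0/0.1/1/10 ppb are rejected (the study design analyzed
#' exactly those cells); duplicated sample ids are a hard error.
#'
#' @param path TSV file.
#' @return data.frame of class `sample_meta`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_sample_meta(df)
}

#' Validate a data.frame of sample metadata
#' @param df data.frame with the columns listed under [read_metadata()].
#' @return data.frame of class `sample_meta`.
#' @export
as_sample_meta <- function(df) {
  required <- c("sample_id", "cage", "gut_section", "dose_ppb",
                "replicate", "timepoint_day")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sample metadata: missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("sample metadata: duplicated sample_id '",
         df$sample_id[duplicated(df$sample_id)][1L], "'")
  }
  bad_sec <- setdiff(unique(df$gut_section), GUT_SECTIONS)
  if (length(bad_sec)) {
    stop("sample metadata: unknown gut_section '", bad_sec[1L],
         "' (expected midgut, ileum or rectum)")
  }
  bad_dose <- setdiff(unique(df$dose_ppb), DOSES_PPB)
  if (length(bad_dose)) {
    stop("sample metadata: unknown dose_ppb ", bad_dose[1L],
         " (expected 0, 0.1, 1 or 10)")
  }
  df$dose_ppb <- as.numeric(df$dose_ppb)
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Write sample metadata as TSV
#' @param meta `sample_meta` table.
#' @param path output file.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 6)

#' Export a co-abundance network
#'
#' Formats: `edge_tsv` (columns source, target, rho, p_fdr, p_bonf, sign —
#' re-reading reconstructs the edge set), `sif` (Cytoscape simple interaction
#' format, relation `pp` for positive and `pn` for negative edges; degree-0
#' nodes are written as single-column lines), and `graphml` (node attributes
#' activity and class, edge attributes rho and sign; written through igraph).
#'
#' @param network a `taxon_network`.
#' @param path output file.
#' @param format one of `"edge_tsv"`, `"sif"`, `"graphml"`.
#' @export
write_network <- function(network, path, format = c("edge_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "taxon_network"))
  ed <- network$edges
  if (format == "edge_tsv") {
    out <- data.frame(source = ed$source, target = ed$target,
                      rho = fmt_num(ed$rho), p_fdr = fmt_num(ed$p_fdr),
                      p_bonf = fmt_num(ed$p_bonf), sign = ed$sign)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- character(0)
    if (nrow(ed)) {
      rel <- ifelse(ed$sign == "+", "pp", "pn")
      lines <- paste(ed$source, rel, ed$target, sep = "\t")
    }
    isolated <- setdiff(network$nodes$genus, c(ed$source, ed$target))
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(lines, isolated), con)
  } else {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(ed)) ed[, c("source", "target", "rho", "sign")] else
        data.frame(source = character(0), target = character(0),
                   rho = numeric(0), sign = character(0)),
      directed = FALSE,
      vertices = data.frame(name = network$nodes$genus,
                            activity = network$nodes$total_activity,
                            class = network$nodes$class))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge TSV written by [write_network()]
#' @param path edge TSV file.
#' @return data.frame with columns source, target, rho, p_fdr, p_bonf, sign.
#' @export
read_edge_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "numeric", "character"))
  names(df) <- c("source", "target", "rho", "p_fdr", "p_bonf", "sign")
  df
}
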