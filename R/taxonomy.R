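# Taxonomic assignment from BLAST tabular hits: best-hit assignment above an
# identity threshold, lowest-common-ancestor (LCA) over the top 50 hits
# otherwise. Lineages are seven-rank (superkingdom..species) vectors filled
# top-down without gaps.

LINEAGE_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                   "genus", "species")

#' Construct a seven-rank lineage
#'
#' Ranks are filled from the top down; an unranked or missing intermediate
#' rank below a named ancestor inherits the parent's name with an
#' `unclassified_` prefix so rank-walks never gap. An all-empty lineage is the
#' "unassigned" sentinel.
#'
#' @param superkingdom,phylum,class,order,family,genus,species rank names
#'   (empty string for absent ranks).
#' @return named character vector of class `lineage`.
#' @export
lineage <- function(superkingdom = "", phylum = "", class = "", order = "",
                    family = "", genus = "", species = "") {
  r <- c(superkingdom = superkingdom, phylum = phylum, class = class,
         order = order, family = family, genus = genus, species = species)
  r[is.na(r)] <- ""
  for (i in 2:7) {
    if (r[i] == "" && any(r[seq(i + 1, 8)[seq_len(7 - i)]] != "")) {
      r[i] <- paste0("unclassified_", r[i - 1])
    }
  }
  structure(r, class = "lineage")
}

#' The unassigned-lineage sentinel
#' @return an all-empty `lineage`.
#' @export
unassigned_lineage <- function() lineage()

#' @export
print.lineage <- function(x, ...) {
  if (is_unassigned(x)) cat("<unassigned lineage>\n")
  else cat(paste(x[x != ""], collapse = "; "), "\n")
  invisible(x)
}

#' Is a lineage the unassigned sentinel?
#' @param lin a `lineage`.
#' @export
is_unassigned <- function(lin) all(lin == "")

#' Deepest non-empty rank of a lineage
#' @param lin a `lineage`.
#' @return rank name, or `NA` for the unassigned sentinel.
#' @export
assigned_rank <- function(lin) {
  nz <- which(lin != "")
  if (!length(nz)) return(NA_character_)
  LINEAGE_RANKS[max(nz)]
}

#' Lowest common ancestor of a set of lineages
#'
#' Walks superkingdom to species and keeps the deepest prefix on which all
#' input lineages agree; disagreement already at superkingdom yields the
#' unassigned sentinel. Commutative and associative over its input set;
#' adding a lineage can never deepen the result.
#'
#' @param lineages non-empty list of `lineage` objects.
#' @return a `lineage`.
#' @export
lca <- function(lineages) {
  if (!length(lineages)) stop("lca: empty lineage list")
  m <- do.call(rbind, lapply(lineages, unclass))
  out <- rep("", 7L)
  for (i in 1:7) {
    vals <- unique(m[, i])
    if (length(vals) == 1L && vals != "") out[i] <- vals else break
  }
  names(out) <- LINEAGE_RANKS
  structure(out, class = "lineage")
}

#' Assign a lineage to one query from its BLAST hits
#'
#' If the best hit (highest bitscore, input order on ties) exceeds the
#' identity threshold, its full lineage is assigned; otherwise the LCA of the
#' lineages of the top `top_n` hits is taken. Hits whose taxid is absent from
#' the lookup are dropped with a warning; no usable hits yield the unassigned
#' sentinel.
#'
#' @param hits data.frame with columns `query_id`, `subject_taxid`,
#'   `percent_identity`, `bitscore` for a single query.
#' @param lineage_lookup data.frame `taxid` + the seven rank columns.
#' @param identity_threshold assign the top hit when its identity is strictly
#'   above this value (default 98, percent).
#' @param top_n number of top hits entering the LCA fallback (default 50).
#' @return a `lineage`.
#' @export
assign_taxon <- function(hits, lineage_lookup, identity_threshold = 98,
                         top_n = 50L) {
  if (is.null(hits) || nrow(hits) == 0L) return(unassigned_lineage())
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop("assign_taxon: percent_identity outside [0, 100]")
  }
  hits <- hits[order(-hits$bitscore), , drop = FALSE]  # stable on ties
  known <- hits$subject_taxid %in% lineage_lookup$taxid
  if (any(!known)) {
    warning("assign_taxon: dropping ", sum(!known),
            " hit(s) with taxid(s) absent from the lineage lookup")
    hits <- hits[known, , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(unassigned_lineage())
  lin_of <- function(taxid) {
    row <- lineage_lookup[match(taxid, lineage_lookup$taxid), ]
    do.call(lineage, as.list(vapply(LINEAGE_RANKS, function(r)
      as.character(row[[r]] %||% ""), character(1))))
  }
  if (hits$percent_identity[1L] > identity_threshold) {
    return(lin_of(hits$subject_taxid[1L]))
  }
  top <- hits[seq_len(min(top_n, nrow(hits))), , drop = FALSE]
  lca(lapply(top$subject_taxid, lin_of))
}

#' Read BLAST tabular hits (outfmt 6 plus staxids)
#'
#' Expects the standard 12 outfmt-6 columns with subject taxids appended as
#' column 13; only query id, subject taxid, percent identity and bitscore are
#' retained.
#'
#' @param path BLAST tabular file (no header).
#' @return data.frame with columns query_id, subject_taxid,
#'   percent_identity, bitscore.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore", "staxids")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 13L) stop("read_blast_hits: expected 13 columns ",
                           "(outfmt 6 + staxids), got ", ncol(df))
  names(df)[1:13] <- cols
  data.frame(query_id = as.character(df$qseqid),
             subject_taxid = as.character(df$staxids),
             percent_identity = as.numeric(df$pident),
             bitscore = as.numeric(df$bitscore),
             stringsAsFactors = FALSE)
}

#' Read a taxid-to-lineage lookup table
#' @param path TSV with columns `taxid` + the seven ranks.
#' @return data.frame.
#' @export
read_lineage_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(c("taxid", LINEAGE_RANKS), names(df))
  if (length(missing)) stop("read_lineage_table: missing column(s): ",
                            paste(missing, collapse = ", "))
  df
}

#' Assign lineages to every query in a BLAST hit table
#' @param hits data.frame as returned by [read_blast_hits()] (any queries).
#' @param lineage_lookup data.frame `taxid` + rank columns.
#' @param ... passed to [assign_taxon()].
#' @return data.frame asv_id + the seven ranks + assigned_rank.
#' @export
assign_all_taxa <- function(hits, lineage_lookup, ...) {
  per_query <- split(hits, hits$query_id)
  rows <- lapply(names(per_query), function(q) {
    lin <- assign_taxon(per_query[[q]], lineage_lookup, ...)
    c(asv_id = q, unclass(lin), assigned_rank = assigned_rank(lin))
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
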