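# End-to-end orchestration: simulate (or ingest) -> genus aggregation ->
# diversity -> differential activity -> per-condition networks -> topology ->
# dysbiosis signatures -> survival & feeding, with a deterministic run
# manifest of file digests.

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) fmt_num(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> aggregate -> diversity -> differential -> network ->
#' topology -> signature -> survival/feeding and writes every artifact (TSV,
#' SIF, GraphML) plus a JSON run manifest with MD5 digests of all outputs.
#' Re-running with the same config and seed reproduces identical digests.
#'
#' @param config a [synth_config()]; its seed drives every stage.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory artifacts (design, table,
#'   nets, summaries, ...) and the manifest path.
#' @export
run_pipeline <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "synth_config"))
  if (!(0 %in% config$doses_ppb) || length(config$doses_ppb) < 2L) {
    stop("run_pipeline: the design needs the 0 ppb control plus at least ",
         "one exposed dose")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nets_dir <- file.path(out_dir, "nets")
  dir.create(nets_dir, showWarnings = FALSE)

  gnd_log("pipeline", "simulating design seed=%d", config$seed)
  design <- generate_design(config)
  table <- generate_activity(design, config)
  lineages <- synth_lineages(table)
  ledger <- generate_survival(config)
  feeding <- generate_feeding(config, ledger)

  write_metadata(design, file.path(out_dir, "metadata.tsv"))
  write_activity_table(table, file.path(out_dir, "counts.tsv"))
  write_tsv(lineages, file.path(out_dir, "taxa.tsv"))
  write_tsv(ledger, file.path(out_dir, "survival_ledger.tsv"))
  write_tsv(feeding, file.path(out_dir, "feeding_ledger.tsv"))

  div <- diversity_analysis(table, design)
  write_tsv(div$diversity, file.path(out_dir, "diversity.tsv"))
  write_tsv(div$tests, file.path(out_dir, "diversity_tests.tsv"))

  diff <- diff_activity_all(table, design)
  write_tsv(as.data.frame(diff), file.path(out_dir, "differential.tsv"))

  genus_tab <- aggregate_genus(table, lineages)
  nets <- run_all_conditions(genus_tab, design,
                             sections = config$sections,
                             doses_ppb = config$doses_ppb)
  for (nm in names(nets)) {
    write_network(nets[[nm]], file.path(nets_dir, paste0(nm, ".edges.tsv")),
                  "edge_tsv")
    write_network(nets[[nm]], file.path(nets_dir, paste0(nm, ".sif")), "sif")
    write_network(nets[[nm]], file.path(nets_dir, paste0(nm, ".graphml")),
                  "graphml")
  }
  summ <- network_summary(nets)
  write_tsv(summ, file.path(out_dir, "network_summary.tsv"))

  topo <- do.call(rbind, lapply(nets, network_topology))
  rownames(topo) <- NULL
  write_tsv(topo, file.path(out_dir, "topology.tsv"))
  topo_cmp <- compare_all_networks(nets)
  write_tsv(topo_cmp, file.path(out_dir, "topology_comparisons.tsv"))

  sigs <- all_signatures(nets)
  sig_rows <- do.call(rbind, lapply(names(sigs), function(nm) {
    s <- sigs[[nm]]
    cbind(section = s$section, dose_ppb = s$dose_ppb,
          nodes_control = s$nodes_control, nodes_exposed = s$nodes_exposed,
          pos_edges_control = s$pos_edges_control,
          pos_edges_exposed = s$pos_edges_exposed,
          neg_edges_control = s$neg_edges_control,
          neg_edges_exposed = s$neg_edges_exposed, s$per_genus)
  }))
  write_tsv(sig_rows, file.path(out_dir, "signatures.tsv"))

  km <- do.call(rbind, lapply(config$doses_ppb, function(d) {
    cbind(group = dose_label(d), kaplan_meier(ledger, d))
  }))
  write_tsv(km, file.path(out_dir, "survival_km.tsv"))
  lr <- do.call(rbind, lapply(setdiff(config$doses_ppb, 0), function(d) {
    r <- logrank(ledger, d, 0)
    data.frame(group = dose_label(d), chi2 = r$chi2, p = r$p)
  }))
  write_tsv(lr, file.path(out_dir, "survival_tests.tsv"))

  rates <- feeding_rate(feeding)
  write_tsv(rates, file.path(out_dir, "feeding_rates.tsv"))
  fc <- feeding_comparisons(rates)
  write_tsv(fc$vs_control, file.path(out_dir, "feeding_tests.tsv"))

  manifest <- run_manifest(config, out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  gnd_log("pipeline", "wrote %d artifacts to %s", length(manifest$files), out_dir)
  invisible(list(design = design, table = table, ledger = ledger,
                 feeding = feeding, diversity = div, differential = diff,
                 nets = nets, network_summary = summ, topology = topo,
                 signatures = sigs, km = km,
                 manifest_path = file.path(out_dir, "manifest.json")))
}

# manifest: config digest, seed, package version, per-file MD5 digests
run_manifest <- function(config, out_dir) {
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  writeLines(deparse(unclass(config)), cfg_file)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  list(package = "gutnetdys",
       version = as.character(utils::packageVersion("gutnetdys")),
       seed = config$seed,
       config_md5 = unname(tools::md5sum(cfg_file)),
       files = digests)
}
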