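# Condition-vs-control dysbiosis signatures: edge/node tallies, gained and
# lost correlation partners per genus, activity directions, core /
# low-activity classification and keystone flags.

#' Default core members of the honeybee gut microbiota
#' @export
CORE_GENERA <- c("Lactobacillus", "Bifidobacterium", "Gilliamella",
                 "Snodgrassella", "Frischella")

#' Classify genera within one condition subset
#'
#' `core` iff the genus is in `core_genera`; otherwise `low_activity` iff its
#' summed relative activity is below `low_activity_frac` of the subset total
#' AND it occurs in fewer than `occ_frac` of the samples (n < 3 of 10 under
#' the full design); otherwise `noncore`.
#'
#' @param table genus-level counts of one condition subset (samples x genera).
#' @param core_genera configurable core list.
#' @param low_activity_frac relative-activity ceiling (default 1e-4, i.e.
#'   <0.01% of the condition's total activity).
#' @param occ_frac occurrence fraction below which a genus counts as sparse
#'   (strict <, default 0.3).
#' @return named character vector genus -> class.
#' @export
classify_taxa <- function(table, core_genera = CORE_GENERA,
                          low_activity_frac = 1e-4, occ_frac = 0.3) {
  m <- unclass(as.matrix(table))
  rel <- m / rowSums(m)
  share <- colSums(rel) / nrow(m)
  occ <- colSums(m > 0)
  cls <- ifelse(colnames(m) %in% core_genera, "core",
                ifelse(share < low_activity_frac & occ < occ_frac * nrow(m),
                       "low_activity", "noncore"))
  stats::setNames(cls, colnames(m))
}

#' Keystone flags from topology rows
#'
#' A genus is flagged keystone iff its degree AND neighborhood connectivity
#' both lie in the top quartile of the network's nonzero-degree nodes. The
#' quantile threshold is configurable; isolated nodes are never keystone.
#'
#' @param topo [network_topology()] rows of one network.
#' @param prob quantile defining "top" (default 0.75).
#' @return named logical vector genus -> keystone.
#' @export
keystone_flags <- function(topo, prob = 0.75) {
  flags <- stats::setNames(rep(FALSE, nrow(topo)), topo$genus)
  nz <- topo$degree > 0
  if (any(nz)) {
    qd <- stats::quantile(topo$degree[nz], prob, names = FALSE)
    qn <- stats::quantile(topo$neighborhood_connectivity[nz], prob, names = FALSE)
    flags[nz] <- topo$degree[nz] >= qd &
      topo$neighborhood_connectivity[nz] >= qn
  }
  flags
}

neighbor_sets <- function(network) {
  adj <- adjacency_list(network)
  lapply(adj, sort)
}

#' Dysbiosis signature of an exposed condition vs its control
#'
#' Tallies nodes and signed edges in both networks and, per genus (union of
#' both node sets), the correlation partners gained (present only in the
#' exposed network) and lost (only in the control network), the activity
#' direction (change in summed relative activity with a +/-10% stability
#' band), the taxon class and the keystone flag of the exposed network.
#' `signature(X, X)` is the neutral signature.
#'
#' @param control_net,exposed_net `taxon_network`s from the same gut section.
#' @param stability_band relative-change band within which activity counts as
#'   stable (default 0.10).
#' @param keystone_prob passed to [keystone_flags()].
#' @return list of class `dysbiosis_signature`: section, dose_ppb,
#'   nodes_control, nodes_exposed, pos/neg edge counts, and `per_genus`
#'   data.frame (genus, class, activity_direction, partners_gained,
#'   partners_lost, n_gained, n_lost, keystone).
#' @export
dysbiosis_signature <- function(control_net, exposed_net,
                                stability_band = 0.10, keystone_prob = 0.75) {
  if (!identical(control_net$section, exposed_net$section)) {
    stop("dysbiosis_signature: networks come from different gut sections (",
         control_net$section, " vs ", exposed_net$section, ")")
  }
  nb_c <- neighbor_sets(control_net)
  nb_e <- neighbor_sets(exposed_net)
  act_c <- stats::setNames(control_net$nodes$total_activity, control_net$nodes$genus)
  act_e <- stats::setNames(exposed_net$nodes$total_activity, exposed_net$nodes$genus)
  cls_e <- stats::setNames(exposed_net$nodes$class, exposed_net$nodes$genus)
  cls_c <- stats::setNames(control_net$nodes$class, control_net$nodes$genus)
  ks <- keystone_flags(network_topology(exposed_net), prob = keystone_prob)
  genera <- sort(union(names(nb_c), names(nb_e)))
  per <- do.call(rbind, lapply(genera, function(g) {
    gained <- setdiff(nb_e[[g]] %||% character(0), nb_c[[g]] %||% character(0))
    lost <- setdiff(nb_c[[g]] %||% character(0), nb_e[[g]] %||% character(0))
    a_c <- act_c[g]; a_e <- act_e[g]
    a_c <- if (is.na(a_c)) 0 else a_c
    a_e <- if (is.na(a_e)) 0 else a_e
    dir <- if (a_c == 0 && a_e == 0) "stable"
      else if (a_c == 0) "up"
      else if (a_e == 0) "down"
      else {
        ratio <- a_e / a_c
        if (ratio > 1 + stability_band) "up"
        else if (ratio < 1 - stability_band) "down" else "stable"
      }
    data.frame(genus = g,
               class = unname(cls_e[g] %||% NA_character_) %||% NA_character_,
               activity_direction = dir,
               partners_gained = paste(gained, collapse = ","),
               partners_lost = paste(lost, collapse = ","),
               n_gained = length(gained), n_lost = length(lost),
               keystone = isTRUE(ks[g]),
               stringsAsFactors = FALSE)
  }))
  per$class[is.na(per$class)] <- unname(cls_c[per$genus[is.na(per$class)]])
  rownames(per) <- NULL
  structure(list(
    section = control_net$section, dose_ppb = exposed_net$dose_ppb,
    nodes_control = nrow(control_net$nodes),
    nodes_exposed = nrow(exposed_net$nodes),
    pos_edges_control = sum(control_net$edges$sign == "+"),
    pos_edges_exposed = sum(exposed_net$edges$sign == "+"),
    neg_edges_control = sum(control_net$edges$sign == "-"),
    neg_edges_exposed = sum(exposed_net$edges$sign == "-"),
    per_genus = per), class = "dysbiosis_signature")
}

#' @export
print.dysbiosis_signature <- function(x, ...) {
  cat(sprintf(paste0("dysbiosis_signature [%s, %s ppb vs control]: nodes %d -> %d, ",
                     "+edges %d -> %d, -edges %d -> %d\n"),
              x$section, dose_label(x$dose_ppb), x$nodes_control,
              x$nodes_exposed, x$pos_edges_control, x$pos_edges_exposed,
              x$neg_edges_control, x$neg_edges_exposed))
  invisible(x)
}

#' Signatures of every exposed condition in a network set
#' @param nets a `taxon_network_set` containing the control of each section.
#' @param control_ppb control dose (default 0).
#' @param ... passed to [dysbiosis_signature()].
#' @return list of `dysbiosis_signature` keyed like the exposed networks.
#' @export
all_signatures <- function(nets, control_ppb = 0, ...) {
  info <- data.frame(name = names(nets),
                     section = vapply(nets, function(n) n$section, character(1)),
                     dose = vapply(nets, function(n) n$dose_ppb, numeric(1)),
                     stringsAsFactors = FALSE)
  out <- list()
  for (s in unique(info$section)) {
    ctrl <- info$name[info$section == s & info$dose == control_ppb]
    if (!length(ctrl)) stop("all_signatures: no control network for ", s)
    for (nm in info$name[info$section == s & info$dose != control_ppb]) {
      out[[nm]] <- dysbiosis_signature(nets[[ctrl]], nets[[nm]], ...)
    }
  }
  out
}
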