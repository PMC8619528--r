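# Synthetic study generator. Emulates the caged-bee design: 2 replicates x
# 5 cages x 3 gut sections x 4 clothianidin doses (0, 0.1, 1, 10 ppb) = 120
# RNA samples at day 7, genus-structured activity compositions dominated by
# the bee core taxa, planted inter-genus rank correlations (Gaussian copula,
# so Spearman targets survive the marginal transform by construction),
# dose-dependent activity shifts, low-activity rare genera, and survival /
# feeding ledgers for 4000 bees over 28 days.

default_genus_profiles <- function() {
  # mean log relative intensity per genus and gut section (natural log of an
  # unnormalized weight; only ratios matter). Lactobacillus dominates the
  # rectum, Gilliamella/Snodgrassella/Frischella peak in the ileum.
  g <- c("Lactobacillus", "Gilliamella", "Snodgrassella", "Bifidobacterium",
         "Frischella", "Bartonella", "Bombella", "Parasaccharibacter",
         "Pediococcus", "unassigned")
  m <- rbind(
    Lactobacillus      = c(3.4, 3.2, 4.4),
    Gilliamella        = c(3.0, 3.8, 2.6),
    Snodgrassella      = c(2.6, 3.6, 2.2),
    Bifidobacterium    = c(2.8, 2.4, 3.6),
    Frischella         = c(2.2, 3.0, 1.8),
    Bartonella         = c(2.0, 1.6, 2.4),
    Bombella           = c(1.6, 1.4, 1.2),
    Parasaccharibacter = c(1.4, 1.2, 1.0),
    Pediococcus        = c(1.2, 1.0, 1.4),
    unassigned         = c(4.8, 4.8, 4.8))
  colnames(m) <- GUT_SECTIONS
  m[g, , drop = FALSE]
}

default_genus_sdlog <- function() {
  # per-genus lognormal sd of activity. The large "unassigned" pool varies
  # little, which keeps each sample's total activity nearly constant: on
  # proportions (the screen's input) planted rank correlations then survive
  # the compositional closure, per the copula design.
  c(Lactobacillus = 0.6, Gilliamella = 0.6, Snodgrassella = 0.6,
    Bifidobacterium = 0.6, Frischella = 0.6, Bartonella = 0.6,
    Bombella = 0.6, Parasaccharibacter = 0.6, Pediococcus = 0.6,
    unassigned = 0.15)
}

default_dose_effects <- function(genera) {
  # log2 multiplicative shifts of mean activity per nonzero dose. Frischella
  # activity falls at every exposure; Bifidobacterium rises; Gilliamella is
  # dose-dependent (mild fall, strong fall, rise); Snodgrassella falls.
  m <- matrix(0, nrow = length(genera), ncol = length(DOSES_PPB),
              dimnames = list(genera, dose_label(DOSES_PPB)))
  set_if <- function(g, d, v) if (g %in% genera) m[g, dose_label(d)] <<- v
  for (d in c(0.1, 1, 10)) {
    set_if("Frischella", d, -1.0)
    set_if("Bifidobacterium", d, 0.8)
    set_if("Snodgrassella", d, -0.5)
    # dominant unassigned pool recedes under exposure, so exposed
    # communities are more even (higher alpha diversity)
    set_if("unassigned", d, -0.5)
  }
  set_if("Gilliamella", 0.1, -0.2)
  set_if("Gilliamella", 1, -1.6)
  set_if("Gilliamella", 10, 0.7)
  m
}

default_planted_edges <- function() {
  # disjoint genus pairs keep the planted correlation matrix positive
  # definite without repair; control keeps four positive associations, every
  # exposed condition keeps one positive and gains one negative association.
  data.frame(
    genus_a = c("Lactobacillus", "Gilliamella", "Bartonella", "Frischella",
                "Gilliamella"),
    genus_b = c("Bifidobacterium", "Snodgrassella", "Bombella", "Pediococcus",
                "Frischella"),
    rho = c(0.9, 0.95, 0.95, 0.9, -0.8),
    doses = c("all", "0", "0", "0", "0.1,1,10"),
    sections = "all",
    stringsAsFactors = FALSE)
}

# plausible 16S lineages for the genera the generator plants (species empty:
# genus-level assignment); the synthetic "unassigned" genus is the all-empty
# sentinel.
bee_genus_lineages <- function(genera) {
  lut <- list(
    Lactobacillus      = c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae"),
    Pediococcus        = c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae"),
    Bifidobacterium    = c("Bacteria", "Actinobacteria", "Actinomycetia", "Bifidobacteriales", "Bifidobacteriaceae"),
    Gilliamella        = c("Bacteria", "Proteobacteria", "Gammaproteobacteria", "Orbales", "Orbaceae"),
    Frischella         = c("Bacteria", "Proteobacteria", "Gammaproteobacteria", "Orbales", "Orbaceae"),
    Snodgrassella      = c("Bacteria", "Proteobacteria", "Betaproteobacteria", "Neisseriales", "Neisseriaceae"),
    Bartonella         = c("Bacteria", "Proteobacteria", "Alphaproteobacteria", "Hyphomicrobiales", "Bartonellaceae"),
    Bombella           = c("Bacteria", "Proteobacteria", "Alphaproteobacteria", "Rhodospirillales", "Acetobacteraceae"),
    Parasaccharibacter = c("Bacteria", "Proteobacteria", "Alphaproteobacteria", "Rhodospirillales", "Acetobacteraceae"),
    Ralstonia          = c("Bacteria", "Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae"),
    Devosia            = c("Bacteria", "Proteobacteria", "Alphaproteobacteria", "Hyphomicrobiales", "Devosiaceae"),
    Leifsonia          = c("Bacteria", "Actinobacteria", "Actinomycetia", "Micrococcales", "Microbacteriaceae"),
    Flavobacterium     = c("Bacteria", "Bacteroidota", "Flavobacteriia", "Flavobacteriales", "Flavobacteriaceae"),
    Moraxella          = c("Bacteria", "Proteobacteria", "Gammaproteobacteria", "Moraxellales", "Moraxellaceae"),
    Pseudomonas        = c("Bacteria", "Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Pseudomonadaceae"))
  out <- data.frame(genus = genera, superkingdom = "", phylum = "", class = "",
                    order = "", family = "", species = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(genera)) {
    g <- genera[i]
    if (g %in% names(lut)) {
      out[i, c("superkingdom", "phylum", "class", "order", "family")] <- lut[[g]]
    } else if (g != "unassigned") {
      out[i, c("superkingdom", "phylum", "class", "order", "family")] <-
        c("Bacteria", "", "", "", "")
    }
  }
  out$genus_name <- ifelse(out$genus == "unassigned", "", out$genus)
  out
}

#' Configuration of the synthetic study generator
#'
#' Defaults encode the cage experiment the pipeline analyzes: 3 gut sections
#' x 4 doses (0/0.1/1/10 ppb) x 5 cages x 2 replicates = 120 samples taken at
#' day 7, 200 bees per cage (4000 in total) followed for 28 days with 20 bees
#' sampled per cage on days 7/14/21/28 (treated as right-censored). Per-dose
#' daily hazards solve (1-h)^t = 1/2 at the observed 50%-mortality days
#' (16, 20, 22, 22 for 0.1, 1, 0, 10 ppb), so mortality ranks
#' 0.1 > 1 > 10 ~ control; per-bee syrup intake peaks at 1 ppb.
#'
#' @param seed integer master seed; every stage derives a child seed from it.
#' @param sections,doses_ppb design cells (defaults: the full study).
#' @param cages_per_group,replicates_per_cage,bees_per_cage,horizon_days design sizes.
#' @param sampling_days,bees_sampled_per_cage weekly removals, right-censored.
#' @param timepoint_day RNA sampling day.
#' @param genus_profiles genus x section mean log relative intensity.
#' @param genus_sdlog lognormal sd of per-genus activity on the log scale;
#'   a scalar or a named per-genus vector. The default gives the dominant
#'   unassigned pool a small sd so each sample's total activity is nearly
#'   constant and planted rank correlations survive the closure to
#'   proportions.
#' @param planted_edges data.frame(genus_a, genus_b, rho, doses, sections)
#'   of target Spearman correlations; `doses`/`sections` are `"all"` or a
#'   comma-separated list of labels.
#' @param dose_effects genus x dose matrix of log2 activity shifts.
#' @param depth_mean,depth_dispersion negative-binomial sequencing-depth model.
#' @param rare_genera low-activity genera injected in at most
#'   `rare_max_occurrence` samples per condition.
#' @param rare_fraction relative activity of a rare genus within a sample.
#' @param rare_max_occurrence samples per condition carrying each rare genus.
#' @param max_asvs_per_genus each genus is split into 1..this many ASVs.
#' @param hazard named per-dose daily death probability.
#' @param intake_g named per-dose mean syrup intake [g/bee/day].
#' @param feeding_noise_sd cage-level Gaussian noise on daily syrup mass [g].
#' @param corr_repair_tol max allowed drift of planted correlations after
#'   nearest-positive-definite repair.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         sections = GUT_SECTIONS,
                         doses_ppb = DOSES_PPB,
                         cages_per_group = 5L,
                         replicates_per_cage = 2L,
                         bees_per_cage = 200L,
                         horizon_days = 28L,
                         sampling_days = c(7L, 14L, 21L, 28L),
                         bees_sampled_per_cage = 20L,
                         timepoint_day = 7L,
                         genus_profiles = default_genus_profiles(),
                         genus_sdlog = default_genus_sdlog(),
                         planted_edges = default_planted_edges(),
                         dose_effects = NULL,
                         depth_mean = 25000,
                         depth_dispersion = 5,
                         rare_genera = c("Ralstonia", "Devosia", "Leifsonia"),
                         rare_fraction = 2e-5,
                         rare_max_occurrence = 2L,
                         max_asvs_per_genus = 4L,
                         hazard = c(`0` = 0.031, `0.1` = 0.0425,
                                    `1` = 0.034, `10` = 0.0315),
                         intake_g = c(`0` = 0.050, `0.1` = 0.046,
                                      `1` = 0.062, `10` = 0.048),
                         feeding_noise_sd = 0.3,
                         corr_repair_tol = 0.05) {
  if (is.null(dose_effects)) dose_effects <- default_dose_effects(rownames(genus_profiles))
  stopifnot(all(sections %in% GUT_SECTIONS), all(doses_ppb %in% DOSES_PPB),
            all(abs(planted_edges$rho) <= 1),
            all(hazard >= 0 & hazard <= 1),
            all(dose_label(doses_ppb) %in% names(hazard)),
            all(dose_label(doses_ppb) %in% names(intake_g)))
  if (!all(c(planted_edges$genus_a, planted_edges$genus_b) %in%
           rownames(genus_profiles))) {
    stop("synth_config: planted_edges name genera absent from genus_profiles")
  }
  structure(list(
    seed = as.integer(seed), sections = sections, doses_ppb = doses_ppb,
    cages_per_group = as.integer(cages_per_group),
    replicates_per_cage = as.integer(replicates_per_cage),
    bees_per_cage = as.integer(bees_per_cage),
    horizon_days = as.integer(horizon_days),
    sampling_days = as.integer(sampling_days),
    bees_sampled_per_cage = as.integer(bees_sampled_per_cage),
    timepoint_day = as.integer(timepoint_day),
    genus_profiles = genus_profiles, genus_sdlog = genus_sdlog,
    planted_edges = planted_edges, dose_effects = dose_effects,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    rare_genera = rare_genera, rare_fraction = rare_fraction,
    rare_max_occurrence = as.integer(rare_max_occurrence),
    max_asvs_per_genus = as.integer(max_asvs_per_genus),
    hazard = hazard, intake_g = intake_g,
    feeding_noise_sd = feeding_noise_sd,
    corr_repair_tol = corr_repair_tol), class = "synth_config")
}

#' Generate the sample design (metadata) of the synthetic study
#'
#' One metadata row per section x dose x cage x replicate, all at the RNA
#' sampling day. Deterministic (no random draws).
#'
#' @param config a [synth_config()].
#' @return a `sample_meta` data.frame (120 rows under the default design).
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  grid <- expand.grid(replicate = seq_len(config$replicates_per_cage),
                      cage_i = seq_len(config$cages_per_group),
                      dose_ppb = config$doses_ppb,
                      gut_section = config$sections,
                      stringsAsFactors = FALSE)
  # order: section, dose, cage, replicate
  grid <- grid[order(match(grid$gut_section, config$sections),
                     match(grid$dose_ppb, config$doses_ppb),
                     grid$cage_i, grid$replicate), ]
  dl <- dose_label(grid$dose_ppb)
  df <- data.frame(
    sample_id = sprintf("%s_d%s_c%d_r%d", grid$gut_section, dl, grid$cage_i,
                        grid$replicate),
    cage = sprintf("cage_d%s_%d", dl, grid$cage_i),
    gut_section = grid$gut_section,
    dose_ppb = grid$dose_ppb,
    replicate = grid$replicate,
    timepoint_day = config$timepoint_day,
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  as_sample_meta(df)
}

planted_active <- function(edge, section, dose) {
  in_list <- function(spec, value) {
    spec == "all" || value %in% strsplit(spec, ",", fixed = TRUE)[[1L]]
  }
  in_list(edge$sections, section) && in_list(edge$doses, dose_label(dose))
}

# target Spearman matrix for one condition -> latent Pearson matrix (with
# nearest-PD repair if needed); errors if repair drifts beyond tolerance
latent_corr_matrix <- function(config, section, dose) {
  genera <- rownames(config$genus_profiles)
  S <- diag(length(genera)); dimnames(S) <- list(genera, genera)
  pe <- config$planted_edges
  for (i in seq_len(nrow(pe))) {
    if (planted_active(pe[i, ], section, dose)) {
      S[pe$genus_a[i], pe$genus_b[i]] <- S[pe$genus_b[i], pe$genus_a[i]] <- pe$rho[i]
    }
  }
  R <- 2 * sin(pi * S / 6)  # Spearman -> Pearson for the Gaussian copula
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    Rr <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    achieved <- (6 / pi) * asin(Rr / 2)
    dev <- max(abs((achieved - S)[upper.tri(S)]))
    if (dev > config$corr_repair_tol) {
      stop("generate_activity: planted correlation matrix for ", section, "/",
           dose_label(dose), " ppb is not positive definite and repair moves ",
           "targets by ", format(dev), " (> ", config$corr_repair_tol,
           "); use weaker rho_targets")
    }
    gnd_log("simulate", "nearPD repair of %s/%s ppb targets (max drift %.4f)",
            section, dose_label(dose), dev)
    R <- Rr
  }
  R
}

#' Generate the ASV-level activity table of the synthetic study
#'
#' Per condition (section x dose): latent Gaussian vectors with the planted
#' correlation structure are mapped through per-genus lognormal marginals
#' (section profile shifted by the dose effect), each genus is split into 1-4
#' ASVs by fixed Dirichlet weights, rare genera are injected at trace
#' relative activity in at most `rare_max_occurrence` samples, and each
#' sample is scaled to a negative-binomial sequencing depth and rounded to
#' integer counts. Spearman correlations between genus sums equal the planted
#' targets up to sampling/rounding noise because the marginal map is monotone.
#'
#' @param design output of [generate_design()].
#' @param config the matching [synth_config()].
#' @return an `activity_table` (samples x ASVs) with the ASV lineage table
#'   attached as attribute `"lineages"` (see [synth_lineages()]).
#' @export
generate_activity <- function(design, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stage_seed(config$seed, 1L))
  genera <- rownames(config$genus_profiles)
  rare <- config$rare_genera
  all_genera <- c(genera, rare)

  n_asv <- c(sample(seq_len(config$max_asvs_per_genus), length(genera),
                    replace = TRUE),
             rep(1L, length(rare)))
  names(n_asv) <- all_genera
  asv_genus <- rep(all_genera, n_asv)
  asv_ids <- sprintf("ASV%03d", seq_along(asv_genus))
  weights <- unlist(lapply(n_asv, function(k) {
    w <- stats::rgamma(k, shape = 2); w / sum(w)
  }), use.names = FALSE)

  counts <- matrix(0, nrow = nrow(design), ncol = length(asv_ids),
                   dimnames = list(design$sample_id, asv_ids))
  for (section in config$sections) {
    for (dose in config$doses_ppb) {
      sel <- which(design$gut_section == section & design$dose_ppb == dose)
      if (!length(sel)) next
      n <- length(sel)
      R <- latent_corr_matrix(config, section, dose)
      meanlog <- config$genus_profiles[, section] +
        log(2) * config$dose_effects[genera, dose_label(dose)]
      Z <- matrix(stats::rnorm(n * length(genera)), n) %*% chol(R)
      V <- matrix(0, n, length(all_genera),
                  dimnames = list(NULL, all_genera))
      sdlog <- if (length(config$genus_sdlog) == 1L) {
        rep(unname(config$genus_sdlog), length(genera))
      } else config$genus_sdlog[genera]
      if (anyNA(sdlog)) stop("generate_activity: genus_sdlog misses genera")
      V[, genera] <- stats::qlnorm(stats::pnorm(Z), meanlog = rep(meanlog, each = n),
                                   sdlog = rep(sdlog, each = n))
      main_tot <- rowSums(V)
      for (g in rare) {
        k <- sample(seq_len(config$rare_max_occurrence), 1L)
        rows <- sample.int(n, k)
        V[rows, g] <- config$rare_fraction * main_tot[rows] * stats::runif(k, 0.3, 1)
      }
      A <- V[, asv_genus, drop = FALSE] *
        matrix(weights, n, length(asv_ids), byrow = TRUE)
      P <- A / rowSums(A)
      depth <- pmax(stats::rnbinom(n, size = config$depth_dispersion,
                                   mu = config$depth_mean), 2000)
      C <- round(P * depth)
      # keep injected rare presences visible after rounding
      present <- V[, asv_genus, drop = FALSE] > 0 & A > 0
      rare_cols <- asv_genus %in% rare
      C[, rare_cols][present[, rare_cols] & C[, rare_cols] == 0] <- 1
      counts[sel, ] <- C
    }
  }
  tab <- activity_table(counts, integer_counts = TRUE)
  lin <- bee_genus_lineages(asv_genus)
  lineages <- data.frame(asv_id = asv_ids,
                         superkingdom = lin$superkingdom, phylum = lin$phylum,
                         class = lin$class, order = lin$order,
                         family = lin$family, genus = lin$genus_name,
                         species = lin$species, stringsAsFactors = FALSE)
  attr(tab, "lineages") <- lineages
  gnd_log("simulate", "activity table: %d samples x %d ASVs (%d genera)",
          nrow(tab), ncol(tab), length(all_genera))
  tab
}

#' ASV lineage table attached to a synthetic activity table
#' @param table output of [generate_activity()].
#' @return data.frame asv_id + seven taxonomic ranks.
#' @export
synth_lineages <- function(table) {
  lin <- attr(table, "lineages")
  if (is.null(lin)) stop("synth_lineages: no lineage attribute on this table")
  lin
}

#' Generate the daily survival ledger of the cage experiment
#'
#' Binomial daily deaths per cage under the per-dose hazard; the weekly
#' 20-bee samplings are recorded as right-censored on the sampling day
#' (removed from the risk set after that day's deaths).
#'
#' @param config a [synth_config()].
#' @return data.frame of class `survival_ledger` with columns
#'   group (dose_ppb), cage, day, n_at_risk, deaths, censored.
#' @export
generate_survival <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stage_seed(config$seed, 2L))
  rows <- vector("list", 0L)
  for (dose in config$doses_ppb) {
    h <- config$hazard[[dose_label(dose)]]
    for (cage_i in seq_len(config$cages_per_group)) {
      cage <- sprintf("cage_d%s_%d", dose_label(dose), cage_i)
      alive <- config$bees_per_cage
      for (day in seq_len(config$horizon_days)) {
        deaths <- stats::rbinom(1L, alive, h)
        cens <- if (day %in% config$sampling_days) {
          min(config$bees_sampled_per_cage, alive - deaths)
        } else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          group = dose, cage = cage, day = day, n_at_risk = alive,
          deaths = deaths, censored = cens, stringsAsFactors = FALSE)
        alive <- alive - deaths - cens
        if (alive == 0L) break
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("survival_ledger", "data.frame")
  out
}

#' Generate the daily feeding ledger
#'
#' Per cage and day, syrup mass = per-bee intake(dose) x mean(alive at day
#' start, alive at day end) + Gaussian noise, truncated at zero. With
#' `feeding_noise_sd = 0` the configured intake is recovered exactly by
#' [feeding_rate()].
#'
#' @param config a [synth_config()].
#' @param ledger the matching [generate_survival()] output.
#' @return data.frame of class `feeding_ledger` with columns group, cage,
#'   day, syrup_consumed, alive_prev, alive_now.
#' @export
generate_feeding <- function(config, ledger) {
  stopifnot(inherits(config, "synth_config"),
            inherits(ledger, "survival_ledger"))
  set.seed(stage_seed(config$seed, 3L))
  alive_prev <- ledger$n_at_risk
  alive_now <- ledger$n_at_risk - ledger$deaths - ledger$censored
  intake <- config$intake_g[dose_label(ledger$group)]
  mass <- intake * (alive_prev + alive_now) / 2
  if (config$feeding_noise_sd > 0) {
    mass <- pmax(0, mass + stats::rnorm(length(mass), 0, config$feeding_noise_sd))
  }
  mass[alive_prev + alive_now == 0] <- 0
  out <- data.frame(group = ledger$group, cage = ledger$cage,
                    day = ledger$day, syrup_consumed = mass,
                    alive_prev = alive_prev, alive_now = alive_now,
                    stringsAsFactors = FALSE)
  class(out) <- c("feeding_ledger", "data.frame")
  out
}
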