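#' Default genus panel of the simulated oral community
#'
#' Fourteen oral genera with full lineages, baseline mean fractional
#' abundances and group effects (log2, group 1 vs group 2). The panel mirrors
#' the biology of a dysbiotic vs commensal oral community: periopathogen
#' genera (Fretibacterium, Porphyromonas, Treponema, Tannerella,
#' Desulfobulbus, Olsenella) enriched in group 1, commensals (Lautropia,
#' Neisseria, Streptococcus, Cardiobacterium, Leptotrichia) enriched in
#' group 2, and Actinomyces dominant throughout. Names are data, not logic.
#'
#' @return Tibble with columns `genus`, `phylum`, `class`, `order`, `family`,
#'   `base_mean_fraction`, `log2_effect_g1_vs_g2`.
#' @export
default_genus_panel <- function() {
  tibble::tribble(
    ~genus, ~phylum, ~class, ~order, ~family, ~base_mean_fraction, ~log2_effect_g1_vs_g2,
    "Actinomyces", "Actinobacteria", "Actinomycetia", "Actinomycetales", "Actinomycetaceae", 0.28, 0,
    "Olsenella", "Actinobacteria", "Coriobacteriia", "Coriobacteriales", "Atopobiaceae", 0.07, 1.5,
    "Fretibacterium", "Synergistetes", "Synergistia", "Synergistales", "Synergistaceae", 0.06, 2.0,
    "Porphyromonas", "Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae", 0.05, 1.5,
    "Treponema", "Spirochaetes", "Spirochaetia", "Spirochaetales", "Treponemataceae", 0.04, 1.5,
    "Tannerella", "Bacteroidetes", "Bacteroidia", "Bacteroidales", "Tannerellaceae", 0.04, 1.0,
    "Desulfobulbus", "Proteobacteria", "Deltaproteobacteria", "Desulfobacterales", "Desulfobulbaceae", 0.03, 1.0,
    "Lautropia", "Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae", 0.06, -2.0,
    "Neisseria", "Proteobacteria", "Betaproteobacteria", "Neisseriales", "Neisseriaceae", 0.07, -1.5,
    "Streptococcus", "Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae", 0.10, -1.5,
    "Cardiobacterium", "Proteobacteria", "Gammaproteobacteria", "Cardiobacteriales", "Cardiobacteriaceae", 0.04, -1.0,
    "Leptotrichia", "Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Leptotrichiaceae", 0.05, -1.0,
    "Capnocytophaga", "Bacteroidetes", "Flavobacteriia", "Flavobacteriales", "Flavobacteriaceae", 0.05, 0,
    "Haemophilus", "Proteobacteria", "Gammaproteobacteria", "Pasteurellales", "Pasteurellaceae", 0.06, 0
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic dataset generator. Defaults are
#' the study conditions the pipeline is designed for: a 16 vs 6 two-group
#' sample design, the [default_genus_panel()] community with |log2| effects
#' of 1-2, uneven bacteria-dominated PSM counts of at least 1000 per stratum,
#' a 20% decoy share with normal score mixtures in which target scores
#' stochastically dominate decoy scores, log2-scale lognormal LFQ noise,
#' completely-at-random missingness, and 10% of bacterial accessions whose
#' lineage stops above genus (matching a ~90% genus-level assignment rate).
#'
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @param n_samples_g1,n_samples_g2 Samples per group.
#' @param genera Genus panel tibble, see [default_genus_panel()].
#' @param proteins_per_genus Bacterial accessions per genus.
#' @param human_protein_count,other_protein_count Accessions in the host and
#'   "other" (archaeal/dietary) pools.
#' @param n_psms Named integer vector of PSM counts per stratum.
#' @param decoy_fraction Fraction of PSM rows that are reverse-database hits.
#' @param target_score_location,target_score_scale,decoy_score_location,decoy_score_scale
#'   Normal score model parameters; target location must exceed decoy
#'   location.
#' @param lfq_log2_sd Protein-level lognormal LFQ noise (log2 sd); together
#'   with missingness this is the generator's source of within-group
#'   variation.
#' @param bio_log2_sd Optional extra per-sample genus-level variation
#'   (log2 sd) on top of the group effect; off (0) by default — per the
#'   generator contract, sample fractions are the base fractions perturbed by
#'   the group effect and renormalized, with stochastic noise entering at the
#'   protein LFQ level.
#' @param missing_rate Fraction of LFQ cells missing completely at random.
#' @param genus_unresolvable_fraction Fraction of bacterial accessions whose
#'   lineage is truncated above genus.
#' @param multi_accession_fraction Fraction of bacterial groups built from
#'   two same-genus accessions rather than one.
#' @return Object of class `sim_config` (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_samples_g1 = 16L, n_samples_g2 = 6L,
                       genera = default_genus_panel(),
                       proteins_per_genus = 8L,
                       human_protein_count = 30L,
                       other_protein_count = 9L,
                       n_psms = c(bacteria = 3000L, human = 1500L,
                                  other = 1000L),
                       decoy_fraction = 0.2,
                       target_score_location = 80, target_score_scale = 15,
                       decoy_score_location = 40, decoy_score_scale = 10,
                       lfq_log2_sd = 0.8, bio_log2_sd = 0,
                       missing_rate = 0.15,
                       genus_unresolvable_fraction = 0.1,
                       multi_accession_fraction = 0.15) {
  cfg <- list(seed = as.integer(seed), n_samples_g1 = n_samples_g1,
              n_samples_g2 = n_samples_g2, genera = genera,
              proteins_per_genus = proteins_per_genus,
              human_protein_count = human_protein_count,
              other_protein_count = other_protein_count,
              n_psms = n_psms, decoy_fraction = decoy_fraction,
              target_score_location = target_score_location,
              target_score_scale = target_score_scale,
              decoy_score_location = decoy_score_location,
              decoy_score_scale = decoy_score_scale,
              lfq_log2_sd = lfq_log2_sd, bio_log2_sd = bio_log2_sd,
              missing_rate = missing_rate,
              genus_unresolvable_fraction = genus_unresolvable_fraction,
              multi_accession_fraction = multi_accession_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!all(c("genus", "base_mean_fraction",
             "log2_effect_g1_vs_g2") %in% names(cfg$genera))) {
    abort("genera must carry genus, base_mean_fraction, log2_effect_g1_vs_g2")
  }
  if (all(cfg$genera$base_mean_fraction <= 0)) {
    abort("infeasible config: all genus base fractions are zero")
  }
  if (any(cfg$genera$base_mean_fraction < 0)) {
    abort("genus base fractions must be non-negative")
  }
  if (!all(is.finite(cfg$genera$log2_effect_g1_vs_g2))) {
    abort("genus effects must be finite")
  }
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction >= 1) {
    abort("decoy_fraction must lie in [0, 1)")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)")
  }
  if (cfg$target_score_location <= cfg$decoy_score_location) {
    abort("target score location must exceed decoy score location")
  }
  if (cfg$genus_unresolvable_fraction < 0 ||
      cfg$genus_unresolvable_fraction >= 1) {
    abort("genus_unresolvable_fraction must lie in [0, 1)")
  }
  invisible(cfg)
}

#' Override one genus's group effect
#'
#' Returns a copy of the configuration with the named genus's log2 effect
#' replaced — the building block for spike-in differential scenarios.
#'
#' @param config A [sim_config()].
#' @param genus Genus name present in the panel.
#' @param log2_effect New log2 effect (group 1 vs group 2).
#' @return Modified `sim_config`.
#' @export
spike_effect <- function(config, genus, log2_effect) {
  idx <- which(config$genera$genus == genus)
  if (length(idx) != 1L) {
    abort(sprintf("genus '%s' is not in the simulation panel", genus))
  }
  config$genera$log2_effect_g1_vs_g2[idx] <- log2_effect
  validate_sim_config(config)
  config
}

#' Null configuration for type-I error studies
#'
#' A panel of `n_genera` equally abundant genera with zero effects, all other
#' parameters at their defaults.
#'
#' @param n_genera Number of genera.
#' @param ... Passed to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(n_genera = 60L, ...) {
  panel <- tibble(
    genus = sprintf("Genus%03d", seq_len(n_genera)),
    phylum = "Firmicutes", class = "Bacilli", order = "Lactobacillales",
    family = sprintf("Family%03d", seq_len(n_genera)),
    base_mean_fraction = 1 / n_genera, log2_effect_g1_vs_g2 = 0
  )
  sim_config(genera = panel, proteins_per_genus = 4L, ...)
}

random_peptide <- function(n, len_range = c(9L, 16L)) {
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  map_chr(lens, ~ paste(sample(AA_ALPHABET, .x, replace = TRUE),
                        collapse = ""))
}

# Lineage rows for one accession given its taxonomy columns (NA = absent).
lineage_rows <- function(accession, superkingdom, phylum = NA, class = NA,
                         order = NA, parvorder = NA, family = NA,
                         genus = NA, species = NA) {
  tibble(accession = accession,
         rank = c("superkingdom", "phylum", "class", "order", "parvorder",
                  "family", "genus", "species"),
         taxon = c(superkingdom, phylum, class, order, parvorder, family,
                   genus, species)) %>%
    filter(!is.na(.data$taxon))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Produces the three input tables the pipeline consumes — peptide-level
#' PSMs with decoys, a long protein-group table with razor + unique counts
#' and LFQ intensities, and a lineage table — plus ground-truth tables
#' (sample group labels, true per-sample genus fractions, per-PSM
#' true/false/decoy status). Deterministic given the seed.
#'
#' The community model: per sample, each genus's log2 fraction is its log2
#' baseline plus half the group effect (positive for group 1, negative for
#' group 2), optionally plus N(0, `bio_log2_sd`) extra biological noise;
#' fractions are then renormalized to sum to 1. Protein LFQ values are lognormal around the
#' product of sample depth, genus fraction and a fixed within-genus protein
#' weight. Forward PSMs are a mixture of correct identifications (target
#' score distribution) and false identifications (decoy score distribution,
#' one per decoy row, the target-decoy symmetry assumption); decoy rows point
#' at reverse-prefixed accessions.
#'
#' @param config A [sim_config()].
#' @return List with tibbles `peptides`, `protein_groups`, `lineages` and a
#'   `truth` list (`sample_groups`, `genus_fractions`, `psm_status`,
#'   `accessions`, `config`).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 42))
#' names(sim)
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  samples <- sprintf("sample_%02d", seq_len(cfg$n_samples_g1 +
                                              cfg$n_samples_g2))
  sample_groups <- tibble(
    raw_file = samples,
    group = rep(c("G1", "G2"), c(cfg$n_samples_g1, cfg$n_samples_g2))
  )

  ## ---- accession pools and lineages -------------------------------------
  panel <- cfg$genera
  bact <- panel %>%
    mutate(accessions = map(.data$genus, function(g) {
      sprintf("BAC_%s_%02d", toupper(gsub("[^A-Za-z0-9]", "", g)),
              seq_len(cfg$proteins_per_genus))
    })) %>%
    select("genus", "phylum", "class", "order", "family", "accessions") %>%
    unnest("accessions") %>%
    rename(accession = "accessions") %>%
    mutate(species = paste(.data$genus,
                           rep_len(c("sp. A", "sp. B"), dplyr::n())))
  n_bact <- nrow(bact)
  n_trunc <- round(cfg$genus_unresolvable_fraction * n_bact)
  trunc_idx <- sample.int(n_bact, n_trunc)
  bact$truncated <- seq_len(n_bact) %in% trunc_idx
  bact_lineages <- pmap(bact, function(genus, phylum, class, order, family,
                                       accession, species, truncated) {
    if (truncated) {
      lineage_rows(accession, "Bacteria", phylum, class, order,
                   family = family)
    } else {
      lineage_rows(accession, "Bacteria", phylum, class, order,
                   family = family, genus = genus, species = species)
    }
  }) %>% list_rbind()

  hum_acc <- sprintf("HUM_%03d", seq_len(cfg$human_protein_count))
  hum_lineages <- map(hum_acc, lineage_rows, superkingdom = "Eukaryota",
                      phylum = "Chordata", class = "Mammalia",
                      order = "Primates", parvorder = "Catarrhini",
                      family = "Hominidae", genus = "Homo",
                      species = "Homo sapiens") %>% list_rbind()

  n_other <- cfg$other_protein_count
  n_arc <- max(1L, n_other - 4L)
  arc_acc <- sprintf("ARC_%03d", seq_len(n_arc))
  diet_acc <- c("DIET_BOS_001", "DIET_BOS_002", "DIET_AVENA_001")
  prim_acc <- "PRIM_001"
  other_acc <- c(arc_acc, diet_acc, prim_acc)
  other_lineages <- bind_rows(
    map(arc_acc, lineage_rows, superkingdom = "Archaea",
        phylum = "Euryarchaeota", class = "Methanobacteria",
        order = "Methanobacteriales", family = "Methanobacteriaceae",
        genus = "Methanobrevibacter",
        species = "Methanobrevibacter oralis") %>% list_rbind(),
    map(diet_acc[1:2], lineage_rows, superkingdom = "Eukaryota",
        phylum = "Chordata", class = "Mammalia", order = "Artiodactyla",
        family = "Bovidae", genus = "Bos", species = "Bos taurus") %>%
      list_rbind(),
    lineage_rows(diet_acc[3], "Eukaryota", "Streptophyta", "Magnoliopsida",
                 order = "Poales", family = "Poaceae", genus = "Avena",
                 species = "Avena sativa"),
    lineage_rows(prim_acc, "Eukaryota", "Chordata", "Mammalia", "Primates",
                 parvorder = "Catarrhini", family = "Cercopithecidae",
                 genus = "Macaca", species = "Macaca mulatta")
  )
  lineages <- bind_rows(bact_lineages, hum_lineages, other_lineages)

  ## ---- protein groups ---------------------------------------------------
  group_list <- list()
  add_group <- function(ids, annotation, stratum, genus = NA_character_,
                        is_contaminant = FALSE, is_decoy_group = FALSE) {
    group_list[[length(group_list) + 1L]] <<-
      tibble(protein_ids = join_ids(ids),
             majority_protein_ids = join_ids(ids),
             annotation = annotation, stratum = stratum, genus = genus,
             is_contaminant = is_contaminant,
             is_decoy_group = is_decoy_group)
  }
  for (g in unique(bact$genus)) {
    accs <- bact$accession[bact$genus == g]
    i <- 1L
    while (i <= length(accs)) {
      if (i < length(accs) && runif(1) < cfg$multi_accession_fraction) {
        add_group(accs[i:(i + 1L)], paste("protein", accs[i]), "bacteria", g)
        i <- i + 2L
      } else {
        add_group(accs[i], paste("protein", accs[i]), "bacteria", g)
        i <- i + 1L
      }
    }
  }
  for (a in hum_acc[-(1:2)]) add_group(a, paste("protein", a), "human")
  # two host groups sharing peptides with an old-world monkey homolog:
  # the LCA lands on the parvorder and the override must pull them to human
  add_group(c(hum_acc[1L], prim_acc), "immunoglobulin heavy constant", "human")
  add_group(c(hum_acc[2L], prim_acc), "serum albumin homolog", "human")
  for (a in arc_acc) add_group(a, paste("protein", a), "other")
  add_group(diet_acc[1L], "beta-lactoglobulin", "other")
  # dietary group carrying a host accession: other-stratum with a human
  # accession, the second branch of the override
  add_group(c(diet_acc[2L], hum_acc[3L]), "serum albumin precursor", "other")
  add_group(diet_acc[3L], "12S seed storage globulin", "other")
  add_group("CON__TRYP_PIG", "trypsin (contaminant)", "other",
            is_contaminant = TRUE)
  add_group("HUM_KRT_001", "Keratin, type II cytoskeletal 1", "human")
  add_group("REV__BAC_DECOY_01", "reverse hit", "bacteria",
            is_decoy_group = TRUE)
  groups_meta <- list_rbind(group_list) %>%
    mutate(group_id = seq_len(dplyr::n()), .before = 1L)

  ## ---- true genus fractions and LFQ -------------------------------------
  half <- panel$log2_effect_g1_vs_g2 / 2
  genus_fracs <- map(seq_along(samples), function(si) {
    sgn <- if (sample_groups$group[si] == "G1") 1 else -1
    lg <- log2(pmax(panel$base_mean_fraction, 1e-12)) + sgn * half +
      rnorm(nrow(panel), 0, cfg$bio_log2_sd)
    w <- 2^lg
    w[panel$base_mean_fraction == 0] <- 0
    tibble(raw_file = samples[si], genus = panel$genus, fraction = w / sum(w))
  }) %>% list_rbind()

  # fixed within-genus protein weights (per accession), normalized per genus
  bact <- bact %>%
    mutate(weight = 2^rnorm(dplyr::n(), 0, 1)) %>%
    mutate(weight = .data$weight / sum(.data$weight), .by = "genus")
  acc_weight <- setNames(bact$weight, bact$accession)
  depth <- setNames(1e10 * 2^rnorm(length(samples), 0, 0.5), samples)
  hum_share <- 0.08
  other_share <- 0.01

  quant <- tidyr::crossing(group_id = groups_meta$group_id,
                           raw_file = samples) %>%
    left_join(select(groups_meta, "group_id", "protein_ids", "stratum",
                     "genus"),
              by = "group_id") %>%
    left_join(genus_fracs, by = c("raw_file", "genus")) %>%
    mutate(
      base = dplyr::case_when(
        .data$stratum == "bacteria" & !is.na(.data$fraction) ~
          .data$fraction *
          map_dbl(.data$protein_ids,
                  ~ sum(acc_weight[split_ids(.x)], na.rm = TRUE)),
        .data$stratum == "human" ~ hum_share / 40,
        TRUE ~ other_share / 10
      ),
      lfq = depth[.data$raw_file] * .data$base *
        2^rnorm(dplyr::n(), 0, cfg$lfq_log2_sd),
      lfq = ifelse(runif(dplyr::n()) < cfg$missing_rate, NA_real_,
                   .data$lfq),
      razor_unique = ifelse(is.na(.data$lfq),
                            rbinom(dplyr::n(), 1L, 0.3),
                            2L + rpois(dplyr::n(), 2L))
    ) %>%
    select("group_id", "raw_file", "razor_unique", "lfq")

  protein_groups <- groups_meta %>%
    select("group_id", "protein_ids", "majority_protein_ids", "annotation",
           "is_contaminant", "is_decoy_group") %>%
    inner_join(quant, by = "group_id") %>%
    arrange(.data$group_id, .data$raw_file)

  ## ---- peptide-level PSMs ------------------------------------------------
  pools <- list(
    bacteria = filter(groups_meta, .data$stratum == "bacteria",
                      !.data$is_decoy_group),
    human = filter(groups_meta, .data$stratum == "human"),
    other = filter(groups_meta, .data$stratum == "other",
                   !.data$is_contaminant)
  )
  empty_psms <- tibble(sequence = character(), score = numeric(),
                       stratum = character(),
                       leading_razor_protein = character(),
                       proteins = character(), raw_file = character(),
                       is_decoy = logical(), status = character())
  psm_tables <- imap(pools, function(pool, stratum) {
    n <- cfg$n_psms[[stratum]]
    if (n == 0L) return(empty_psms)
    n_decoy <- rbinom(1L, n, cfg$decoy_fraction)
    n_false <- min(n_decoy, n - n_decoy)
    n_true <- n - n_decoy - n_false
    pick <- sample.int(nrow(pool), n_true + n_false + n_decoy,
                       replace = TRUE)
    lead_acc <- map_chr(pool$protein_ids[pick],
                        ~ split_ids(.x)[1L])
    status <- rep(c("true", "false", "decoy"), c(n_true, n_false, n_decoy))
    score <- c(rnorm(n_true, cfg$target_score_location,
                     cfg$target_score_scale),
               rnorm(n_false + n_decoy, cfg$decoy_score_location,
                     cfg$decoy_score_scale))
    is_decoy <- status == "decoy"
    proteins <- pool$protein_ids[pick]
    # most decoy rows have an empty Proteins cell; a third keep a (spurious)
    # valid entry so the razor-decoy QC filter has work to do
    decoy_valid <- is_decoy & runif(n) < 1 / 3
    proteins[is_decoy & !decoy_valid] <- NA_character_
    proteins[decoy_valid] <- paste0("REV__", lead_acc[decoy_valid])
    tibble(
      sequence = random_peptide(n),
      score = round(score, 3L),
      stratum = stratum,
      leading_razor_protein = ifelse(is_decoy,
                                     paste0("REV__", lead_acc), lead_acc),
      proteins = proteins,
      raw_file = sample(samples, n, replace = TRUE),
      is_decoy = is_decoy,
      status = status
    )
  })
  peptides_full <- list_rbind(psm_tables) %>%
    mutate(psm_id = seq_len(dplyr::n()))
  psm_status <- select(peptides_full, "psm_id", "status")
  peptides <- select(peptides_full, -"status")

  list(
    peptides = peptides,
    protein_groups = protein_groups,
    lineages = lineages,
    truth = list(
      sample_groups = sample_groups,
      genus_fractions = genus_fracs,
      psm_status = psm_status,
      accessions = select(bact, "accession", "genus", "species",
                          "truncated", "weight"),
      config = cfg
    )
  )
}

#' Write a simulated dataset to a directory
#'
#' Writes `peptides.tsv`, `protein_groups.tsv` and `lineages.tsv` (the
#' pipeline's inputs) plus a `ground_truth/` subdirectory with the sample
#' groups, true genus fractions and per-PSM status.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_peptide_table(sim$peptides, file.path(dir, "peptides.tsv"))
  write_protein_groups(sim$protein_groups,
                       file.path(dir, "protein_groups.tsv"))
  write_lineage_table(sim$lineages, file.path(dir, "lineages.tsv"))
  gt <- file.path(dir, "ground_truth")
  dir.create(gt, showWarnings = FALSE)
  readr::write_tsv(sim$truth$sample_groups,
                   file.path(gt, "sample_groups.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$genus_fractions,
                   file.path(gt, "genus_fractions.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$psm_status,
                   file.path(gt, "psm_status.tsv"), progress = FALSE)
  invisible(dir)
}
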