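read_stage_input <- function(dir, file, stage) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    abort(sprintf("%s stage: required input '%s' not found in %s",
                  stage, file, dir))
  }
  path
}

#' Pipeline stage: stratified FDR
#'
#' Reads `peptides.tsv` from `input_dir`, controls FDR within each stratum
#' at `config$fdr$q` and writes `accepted_peptides.tsv` and
#' `fdr_summary.tsv` to `output_dir`.
#'
#' @param input_dir Directory holding the pipeline inputs.
#' @param output_dir Directory stage outputs are written to.
#' @param config Configuration list, see [default_config()].
#' @return Invisibly, the per-stratum summary tibble.
#' @export
stage_fdr <- function(input_dir, output_dir, config = default_config()) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  peptides <- read_peptide_table(
    read_stage_input(input_dir, "peptides.tsv", "fdr"),
    decoy_prefix = config$io$decoy_prefix)
  res <- stratified_fdr(peptides, q = config$fdr$q)
  write_peptide_table(res$accepted,
                      file.path(output_dir, "accepted_peptides.tsv"))
  readr::write_tsv(res$summary, file.path(output_dir, "fdr_summary.tsv"),
                   progress = FALSE)
  message(sprintf("fdr: accepted %d forward peptides of %d input rows",
                  nrow(res$accepted), nrow(peptides)))
  invisible(res$summary)
}

#' Pipeline stage: peptide QC and protein-group filtering
#'
#' Reads the FDR-accepted peptides (from `output_dir`) and
#' `protein_groups.tsv` (from `input_dir`); drops razor-decoy peptides, maps
#' groups by leading razor accession, applies the minimum razor + unique
#' filter and the contaminant/excluded-annotation filter. Writes
#' `qc_peptides.tsv`, `filtered_groups.tsv` and `filter_audit.tsv`.
#'
#' @inheritParams stage_fdr
#' @return Invisibly, the filtered protein-group tibble.
#' @export
stage_filter <- function(input_dir, output_dir, config = default_config()) {
  peptides <- read_peptide_table(
    read_stage_input(output_dir, "accepted_peptides.tsv", "filter"),
    decoy_prefix = config$io$decoy_prefix)
  groups <- read_protein_groups(
    read_stage_input(input_dir, "protein_groups.tsv", "filter"))
  qc <- drop_razor_decoy_peptides(peptides)
  mapped <- map_groups_by_leading_razor(groups, qc)
  counted <- min_peptides_filter(mapped, config$filter$min_razor_unique,
                                 config$filter$whole_group)
  clean <- drop_contaminants_and_excluded(counted,
                                          config$filter$excluded_patterns)
  audit <- bind_rows(
    filter_audit(groups, mapped, "no_surviving_leading_razor"),
    filter_audit(mapped, counted, "below_min_razor_unique"),
    filter_audit(counted, clean, "contaminant_or_excluded")
  )
  write_peptide_table(qc, file.path(output_dir, "qc_peptides.tsv"))
  write_protein_groups(clean, file.path(output_dir, "filtered_groups.tsv"))
  readr::write_tsv(audit, file.path(output_dir, "filter_audit.tsv"),
                   progress = FALSE)
  message(sprintf(
    "filter: %d -> %d peptides; %d -> %d protein groups (%d removals logged)",
    nrow(peptides), nrow(qc), dplyr::n_distinct(groups$group_id),
    dplyr::n_distinct(clean$group_id), nrow(audit)))
  invisible(clean)
}

#' Pipeline stage: LCA taxonomic assignment
#'
#' Reads the filtered groups and QC'd peptides (from `output_dir`) and
#' `lineages.tsv` (from `input_dir`), assigns each group its lowest common
#' ancestor with the primate override, and writes `lca_assignments.tsv`
#' (with the genus-level taxon flattened out for downstream use).
#'
#' @inheritParams stage_fdr
#' @return Invisibly, the assignment tibble.
#' @export
stage_lca <- function(input_dir, output_dir, config = default_config()) {
  groups <- read_protein_groups(
    read_stage_input(output_dir, "filtered_groups.tsv", "taxonomy"))
  peptides <- read_peptide_table(
    read_stage_input(output_dir, "qc_peptides.tsv", "taxonomy"),
    decoy_prefix = config$io$decoy_prefix)
  lineages <- read_lineage_table(
    read_stage_input(input_dir, "lineages.tsv", "taxonomy"),
    ladder = config$taxonomy$rank_ladder)
  asg <- assign_taxonomy(groups, peptides, lineages,
                         ladder = config$taxonomy$rank_ladder,
                         human_trigger_taxa = config$taxonomy$human_trigger_taxa,
                         human_taxon = config$taxonomy$human_taxon)
  flat <- asg %>%
    mutate(genus = map_chr(.data$lca_path, taxon_at_rank, rank = "genus")) %>%
    select(-"lca_path")
  readr::write_tsv(flat, file.path(output_dir, "lca_assignments.tsv"),
                   na = "", progress = FALSE)
  message(sprintf("taxonomy: %d groups assigned; %.1f%% of bacterial groups at genus level",
                  nrow(asg), 100 * genus_assignment_rate(asg,
                                                         config$taxonomy$rank_ladder)))
  invisible(asg)
}

#' Pipeline stage: genus-level quantitation
#'
#' Computes genus fractional abundances from the filtered groups and the LCA
#' assignments; writes the long table (`genus_fractions.tsv`), the
#' samples-as-columns matrix (`genus_fraction_matrix.tsv`), the unassigned
#' remainders (`unassigned_fractions.tsv`) and the top-N bar-chart table
#' (`top_genera.tsv`).
#'
#' @inheritParams stage_fdr
#' @return Invisibly, the `genus_fractions` tibble.
#' @export
stage_quant <- function(input_dir, output_dir, config = default_config()) {
  asg <- stage_lca_reload(input_dir, output_dir, config)
  groups <- read_protein_groups(
    read_stage_input(output_dir, "filtered_groups.tsv", "quant"))
  gf <- genus_fractions(groups, asg, rank = config$quant$rank)
  readr::write_tsv(as_tibble(gf), file.path(output_dir,
                                            "genus_fractions.tsv"),
                   progress = FALSE)
  mat <- fraction_matrix(gf)
  mat_tbl <- as_tibble(t(mat), rownames = "genus")
  readr::write_tsv(mat_tbl, file.path(output_dir,
                                      "genus_fraction_matrix.tsv"),
                   progress = FALSE)
  readr::write_tsv(attr(gf, "unassigned"),
                   file.path(output_dir, "unassigned_fractions.tsv"),
                   progress = FALSE)
  readr::write_tsv(top_genera(gf, config$quant$top_n),
                   file.path(output_dir, "top_genera.tsv"), progress = FALSE)
  message(sprintf("quant: %d genera quantified across %d samples",
                  dplyr::n_distinct(gf$genus),
                  dplyr::n_distinct(gf$raw_file)))
  invisible(gf)
}

# Re-run the LCA assignment in memory (stages are pure, so recomputing from
# the stage files is cheaper than serializing list-columns).
stage_lca_reload <- function(input_dir, output_dir, config) {
  groups <- read_protein_groups(
    read_stage_input(output_dir, "filtered_groups.tsv", "quant"))
  peptides <- read_peptide_table(
    read_stage_input(output_dir, "qc_peptides.tsv", "quant"),
    decoy_prefix = config$io$decoy_prefix)
  lineages <- read_lineage_table(
    read_stage_input(input_dir, "lineages.tsv", "quant"),
    ladder = config$taxonomy$rank_ladder)
  assign_taxonomy(groups, peptides, lineages,
                  ladder = config$taxonomy$rank_ladder,
                  human_trigger_taxa = config$taxonomy$human_trigger_taxa,
                  human_taxon = config$taxonomy$human_taxon)
}

#' Pipeline stage: community statistics
#'
#' Clusters the samples on the min-half-filtered, log2-median-normalized
#' protein LFQ matrix (Pearson distance), cuts the tree into
#' `config$stats$k_groups` flat groups (labelled `G1`, `G2`, ... by
#' decreasing size), runs the two-group differential genus t-test between
#' the first two groups, and computes the Bray-Curtis dissimilarity matrix
#' on the integer-scaled percent abundances. Writes `cluster_labels.tsv`,
#' `linkage.tsv`, `volcano.tsv` and `bray_curtis.tsv`.
#'
#' @inheritParams stage_fdr
#' @return Invisibly, a list with the clustering, the differential test and
#'   the dissimilarity matrix.
#' @export
stage_stats <- function(input_dir, output_dir, config = default_config()) {
  groups <- read_protein_groups(
    read_stage_input(output_dir, "filtered_groups.tsv", "stats"))
  gf_tbl <- readr::read_tsv(
    read_stage_input(output_dir, "genus_fractions.tsv", "stats"),
    col_types = readr::cols(raw_file = "c", genus = "c", .default = "d"),
    progress = FALSE)
  mat <- lfq_matrix(groups) %>%
    min_half_filter() %>%
    log2_median_normalize()
  cl <- hierarchical_cluster(mat, linkage = config$stats$linkage,
                             k = config$stats$k_groups)
  sizes <- sort(table(cl$groups), decreasing = TRUE)
  relabel <- setNames(paste0("G", seq_along(sizes)), names(sizes))
  labels <- tibble(raw_file = names(cl$groups),
                   group = unname(relabel[as.character(cl$groups)]))
  readr::write_tsv(labels, file.path(output_dir, "cluster_labels.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(cl), file.path(output_dir, "linkage.tsv"),
                   progress = FALSE)
  lab12 <- filter(labels, .data$group %in% c("G1", "G2"))
  diff <- two_group_t_test(gf_tbl, setNames(lab12$group, lab12$raw_file),
                           alpha = config$stats$alpha,
                           var_equal = config$stats$test_variant == "student")
  volcano <- diff %>%
    as_tibble() %>%
    mutate(minus_log10_p = -log10(.data$p_value))
  readr::write_tsv(volcano, file.path(output_dir, "volcano.tsv"), na = "",
                   progress = FALSE)
  counts <- gf_tbl %>%
    select("raw_file", "genus", "fraction") %>%
    pivot_wider(names_from = "genus", values_from = "fraction",
                values_fill = 0)
  cmat <- scale_percent_to_counts(
    100 * as.matrix(counts[, -1L, drop = FALSE]))
  rownames(cmat) <- counts$raw_file
  bc <- bray_curtis(cmat)
  readr::write_tsv(as_tibble(bc, rownames = "raw_file"),
                   file.path(output_dir, "bray_curtis.tsv"),
                   progress = FALSE)
  message(sprintf("stats: %d/%d genera significant between %s",
                  sum(diff$significant), sum(diff$tested),
                  paste(attr(diff, "groups"), collapse = " and ")))
  invisible(list(clustering = cl, differential = diff, bray_curtis = bc))
}

#' Pipeline stage: dietary peptide discrimination
#'
#' Digests the reference proteins of `diet_references.fasta` pairwise and
#' writes the peptide species-uniqueness classes to `diet_peptides.tsv`.
#' The first two records are compared (further records participate through
#' [classify_observed_peptide()] downstream).
#'
#' @inheritParams stage_fdr
#' @return Invisibly, the `diet_discrimination` tibble.
#' @export
stage_diet <- function(input_dir, output_dir, config = default_config()) {
  fasta <- read_fasta(
    read_stage_input(input_dir, "diet_references.fasta", "diet"))
  if (nrow(fasta) < 2L) abort("diet stage: need at least two references")
  disc <- discriminating_peptides(
    fasta$sequence[1L], fasta$sequence[2L],
    max_missed = config$diet$max_missed,
    deamidation_aware = config$diet$deamidation_aware,
    q_e = config$diet$q_e_equivalence,
    len_min = config$diet$len_min, len_max = config$diet$len_max)
  out <- disc %>%
    as_tibble() %>%
    mutate(reference = ifelse(.data$reference == "a", fasta$seq_id[1L],
                              fasta$seq_id[2L]))
  readr::write_tsv(out, file.path(output_dir, "diet_peptides.tsv"),
                   progress = FALSE)
  message(sprintf("diet: %d discriminating tryptic peptide loci between %s and %s",
                  count_discriminating(disc), fasta$seq_id[1L],
                  fasta$seq_id[2L]))
  invisible(disc)
}

#' Run the full post-processing pipeline
#'
#' Executes the stages in the fixed order FDR -> QC/group filtering -> LCA ->
#' quantitation -> statistics (plus dietary discrimination when
#' `diet_references.fasta` is present in `input_dir`), each stage a pure
#' file-to-file transformation, and writes `manifest.tsv` listing every
#' artifact with its row count. Running the stage functions individually in
#' the same order produces identical outputs.
#'
#' @param input_dir Directory with `peptides.tsv`, `protein_groups.tsv`,
#'   `lineages.tsv` (e.g. from [write_simulated_dataset()]) and optionally
#'   `diet_references.fasta`.
#' @param output_dir Directory for all stage outputs.
#' @param config Configuration list, see [default_config()] /
#'   [read_config()].
#' @return Invisibly, the manifest tibble.
#' @export
run_pipeline <- function(input_dir, output_dir, config = default_config()) {
  stage_fdr(input_dir, output_dir, config)
  stage_filter(input_dir, output_dir, config)
  stage_lca(input_dir, output_dir, config)
  stage_quant(input_dir, output_dir, config)
  stage_stats(input_dir, output_dir, config)
  if (file.exists(file.path(input_dir, "diet_references.fasta"))) {
    stage_diet(input_dir, output_dir, config)
  }
  artifacts <- setdiff(list.files(output_dir, pattern = "\\.tsv$"),
                       "manifest.tsv")
  manifest <- tibble(
    file = artifacts,
    n_rows = map_int(artifacts, function(f) {
      nrow(readr::read_tsv(file.path(output_dir, f),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE))
    })
  )
  readr::write_tsv(manifest, file.path(output_dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(manifest)
}
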