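# Small in-code fixture builders shared across test files.

make_peptides <- function(sequence, score = 50, stratum = "bacteria",
                          leading = "ACC1", proteins = leading,
                          raw_file = "s1") {
  tibble::tibble(
    sequence = sequence, score = score, stratum = stratum,
    leading_razor_protein = leading, proteins = proteins,
    raw_file = raw_file,
    is_decoy = startsWith(leading, "REV__")
  )
}

# Long-format protein-group rows from a compact spec:
# groups = list(list(id=, ids=, counts=c(s1=..), lfq=c(s1=..), ...))
make_groups <- function(groups, raw_files = NULL) {
  if (is.null(raw_files)) {
    raw_files <- unique(unlist(lapply(groups, function(g) names(g$counts))))
  }
  purrr::map(groups, function(g) {
    counts <- if (is.null(g$counts)) rep(2L, length(raw_files)) else {
      v <- unname(g$counts[raw_files]); v[is.na(v)] <- 0L; as.integer(v)
    }
    lfq <- if (is.null(g$lfq)) rep(NA_real_, length(raw_files)) else {
      as.numeric(unname(g$lfq[raw_files]))
    }
    tibble::tibble(
      group_id = g$id,
      protein_ids = paste(g$ids, collapse = ";"),
      majority_protein_ids = paste(g$majority %||% g$ids, collapse = ";"),
      annotation = g$annotation %||% "",
      is_contaminant = isTRUE(g$contaminant),
      is_decoy_group = isTRUE(g$decoy),
      raw_file = raw_files,
      razor_unique = counts,
      lfq = lfq
    )
  }) |> purrr::list_rbind()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Lineage rows from "rank=taxon" strings.
make_lineage <- function(accession, ...) {
  pairs <- c(...)
  tibble::tibble(accession = accession,
                 rank = names(pairs), taxon = unname(pairs))
}

strep_sanguinis <- function(acc = "STR_SANG") {
  make_lineage(acc, superkingdom = "Bacteria", phylum = "Firmicutes",
               class = "Bacilli", order = "Lactobacillales",
               family = "Streptococcaceae", genus = "Streptococcus",
               species = "Streptococcus sanguinis")
}

strep_mutans <- function(acc = "STR_MUT") {
  make_lineage(acc, superkingdom = "Bacteria", phylum = "Firmicutes",
               class = "Bacilli", order = "Lactobacillales",
               family = "Streptococcaceae", genus = "Streptococcus",
               species = "Streptococcus mutans")
}

human_lineage <- function(acc = "HUM_1") {
  make_lineage(acc, superkingdom = "Eukaryota", phylum = "Chordata",
               class = "Mammalia", order = "Primates",
               parvorder = "Catarrhini", family = "Hominidae",
               genus = "Homo", species = "Homo sapiens")
}

# Hand-built assignment row (so quantitation can be tested in isolation).
make_assignment <- function(group_id, taxon, rank, stratum,
                            path = NULL) {
  if (is.null(path)) {
    path <- tibble::tibble(rank = rank, taxon = taxon)
  }
  tibble::tibble(group_id = group_id, representatives = "",
                 lca_taxon = taxon, lca_rank = rank,
                 effective_stratum = stratum, lca_path = list(path))
}

# Recovered genus fractions for a simulated dataset (full quant path).
sim_fractions <- function(sim) {
  asg <- assign_taxonomy(sim$protein_groups, sim$peptides, sim$lineages)
  genus_fractions(sim$protein_groups, asg)
}
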