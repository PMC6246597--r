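rank_depth <- function(rank, ladder) match(rank, ladder)

#' Count peptide associations per accession
#'
#' A peptide is associated with every accession listed in its `proteins`
#' cell; the association count of an accession is the number of distinct
#' peptide sequences associated with it. These counts drive representative
#' selection for the lowest-common-ancestor assignment.
#'
#' @param peptides Peptide tibble (post-FDR, post-QC).
#' @return Tibble with columns `accession`, `n_peptides`.
#' @export
peptide_association_counts <- function(peptides) {
  peptides %>%
    filter(!is.na(.data$proteins)) %>%
    distinct(.data$sequence, .data$proteins) %>%
    mutate(accession = map(.data$proteins, split_ids)) %>%
    select("sequence", "accession") %>%
    unnest("accession") %>%
    distinct() %>%
    count(.data$accession, name = "n_peptides")
}

#' Select representative accessions of a protein group
#'
#' From the group's majority protein IDs, keeps every accession attaining the
#' maximum peptide-association count (ties all retained; accessions with no
#' recorded associations count 0).
#'
#' @param majority_ids Character vector of majority protein accessions.
#' @param counts Named numeric vector of peptide-association counts.
#' @return Character vector of representative accessions.
#' @export
select_representatives <- function(majority_ids, counts) {
  if (length(majority_ids) == 0L) {
    abort("protein group has an empty majority protein ID list")
  }
  n <- unname(counts[majority_ids])
  n[is.na(n)] <- 0
  majority_ids[n == max(n)]
}

#' Lowest common ancestor of a set of lineages
#'
#' Intersects the `(rank, taxon)` pairs of all input lineage paths (pairs, so
#' homonymous taxon names at different ranks never collide) and returns the
#' intersecting taxon of the most specific rank. An empty intersection yields
#' `("unassigned", "unassigned")`. The operation is permutation-invariant and
#' idempotent, and adding a lineage can only move the result to a less
#' specific rank.
#'
#' @param lineages Long lineage tibble (`accession`, `rank`, `taxon`)
#'   covering the accessions to intersect; accessions present in the
#'   `accessions` argument but absent from the table contribute empty paths.
#' @param accessions Character vector of accessions to intersect; default all
#'   accessions present in `lineages`.
#' @param ladder Ordered rank ladder, root first.
#' @return List with `taxon`, `rank`, and `path` (tibble of the shared
#'   `(rank, taxon)` pairs, root to leaf).
#' @export
lca <- function(lineages, accessions = unique(lineages$accession),
                ladder = default_config()$taxonomy$rank_ladder) {
  if (length(accessions) == 0L) abort("lca needs at least one accession")
  paths <- lapply(accessions, function(acc) {
    p <- lineages[lineages$accession == acc, c("rank", "taxon")]
    paste(p$rank, p$taxon, sep = "\r")
  })
  shared <- Reduce(intersect, paths)
  empty <- list(taxon = "unassigned", rank = "unassigned",
                path = tibble(rank = character(), taxon = character()))
  if (length(shared) == 0L) return(empty)
  parts <- str_split(shared, "\r", n = 2L)
  path <- tibble(rank = map_chr(parts, 1L), taxon = map_chr(parts, 2L)) %>%
    mutate(depth = rank_depth(.data$rank, ladder)) %>%
    arrange(.data$depth)
  leaf <- tail(path, 1L)
  list(taxon = leaf$taxon, rank = leaf$rank,
       path = select(path, "rank", "taxon"))
}

taxon_at_rank <- function(path, rank) {
  hit <- path$taxon[path$rank == rank]
  if (length(hit) == 1L) hit else NA_character_
}

#' Assign protein groups a lowest-common-ancestor taxon
#'
#' For every protein group, selects the majority accessions with the most
#' peptide associations ([select_representatives()]), intersects their
#' lineages ([lca()]), derives the effective stratum from the shared
#' superkingdom (Bacteria -> `bacteria`, Homo sapiens -> `human`, everything
#' else -> `other`), and applies the primate override
#' ([apply_human_override()]).
#'
#' @param groups Long protein-group tibble.
#' @param peptides Surviving peptide tibble (for association counts).
#' @param lineages Long lineage tibble.
#' @param ladder Ordered rank ladder.
#' @param human_trigger_taxa LCA taxa coerced to human (default the primate
#'   parvorder Catarrhini).
#' @param human_taxon Species name of the host (default `"Homo sapiens"`).
#' @return Tibble with columns `group_id`, `representatives`, `lca_taxon`,
#'   `lca_rank`, `effective_stratum` and a list-column `lca_path`.
#' @export
assign_taxonomy <- function(groups, peptides, lineages,
                            ladder = default_config()$taxonomy$rank_ladder,
                            human_trigger_taxa = "Catarrhini",
                            human_taxon = "Homo sapiens") {
  counts_tbl <- peptide_association_counts(peptides)
  counts <- setNames(counts_tbl$n_peptides, counts_tbl$accession)
  meta <- distinct(groups, .data$group_id, .data$protein_ids,
                   .data$majority_protein_ids)
  assignments <- pmap(meta, function(group_id, protein_ids,
                                     majority_protein_ids) {
    reps <- select_representatives(split_ids(majority_protein_ids), counts)
    res <- lca(lineages, reps, ladder)
    stratum <- if (identical(taxon_at_rank(res$path, "superkingdom"),
                             "Bacteria")) {
      "bacteria"
    } else if (identical(res$taxon, human_taxon)) {
      "human"
    } else {
      "other"
    }
    tibble(group_id = group_id,
           representatives = join_ids(reps),
           lca_taxon = res$taxon, lca_rank = res$rank,
           effective_stratum = stratum, lca_path = list(res$path))
  }) %>% list_rbind()
  apply_human_override(assignments, groups, lineages,
                       human_trigger_taxa = human_trigger_taxa,
                       human_taxon = human_taxon, ladder = ladder)
}

#' Coerce primate-level assignments to human
#'
#' Ancient host proteins often resolve only to the primate parvorder
#' Catarrhini because homologous ape sequences share all observed peptides.
#' This override sets any assignment whose LCA is a configured trigger taxon
#' to Homo sapiens at species rank, and likewise promotes `other`-stratum
#' groups that contain a human accession anywhere in their protein IDs.
#'
#' @param assignments Assignment tibble from [assign_taxonomy()].
#' @param groups Long protein-group tibble (for the human-accession rule).
#' @param lineages Long lineage tibble (defines which accessions are human).
#' @param human_trigger_taxa Taxa triggering the override.
#' @param human_taxon Host species name.
#' @param ladder Ordered rank ladder.
#' @return Assignment tibble with the override applied.
#' @export
apply_human_override <- function(assignments, groups, lineages,
                                 human_trigger_taxa = "Catarrhini",
                                 human_taxon = "Homo sapiens",
                                 ladder = default_config()$taxonomy$rank_ladder) {
  human_accessions <- lineages %>%
    filter(.data$rank == "species", .data$taxon == human_taxon) %>%
    pull("accession")
  has_human <- groups %>%
    distinct(.data$group_id, .data$protein_ids) %>%
    mutate(has_human = map_lgl(.data$protein_ids,
                               ~ any(split_ids(.x) %in% human_accessions))) %>%
    select("group_id", "has_human")
  human_path <- lineages %>%
    filter(.data$accession %in% human_accessions) %>%
    distinct(.data$rank, .data$taxon)
  if (nrow(human_path) == 0L) {
    human_path <- tibble(rank = "species", taxon = human_taxon)
  }
  assignments %>%
    left_join(has_human, by = "group_id") %>%
    mutate(
      trigger = .data$lca_taxon %in% human_trigger_taxa |
        (.data$effective_stratum == "other" &
           dplyr::coalesce(.data$has_human, FALSE)),
      lca_taxon = ifelse(.data$trigger, human_taxon, .data$lca_taxon),
      lca_rank = ifelse(.data$trigger, "species", .data$lca_rank),
      effective_stratum = ifelse(.data$trigger, "human",
                                 .data$effective_stratum),
      lca_path = map2(.data$trigger, .data$lca_path,
                      ~ if (.x) human_path else .y)
    ) %>%
    select(-"trigger", -"has_human")
}

#' Genus-level assignment rate among bacterial groups
#'
#' Fraction of bacteria-stratum protein groups whose LCA rank is genus or
#' more specific.
#'
#' @param assignments Assignment tibble from [assign_taxonomy()].
#' @param ladder Ordered rank ladder.
#' @return A single fraction in \[0, 1\].
#' @export
genus_assignment_rate <- function(assignments,
                                  ladder = default_config()$taxonomy$rank_ladder) {
  bact <- filter(assignments, .data$effective_stratum == "bacteria")
  if (nrow(bact) == 0L) {
    abort("genus assignment rate is undefined: no bacterial groups")
  }
  genus_depth <- rank_depth("genus", ladder)
  depth <- rank_depth(bact$lca_rank, ladder)
  mean(!is.na(depth) & depth >= genus_depth)
}
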