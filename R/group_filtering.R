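#' Drop peptides whose leading razor protein is a decoy
#'
#' Quality-control filter applied after FDR acceptance: a peptide row is
#' removed if and only if its leading razor protein is a reverse-database hit
#' AND its `proteins` cell holds a valid (non-missing) entry. Decoy-leading
#' rows with a missing `proteins` cell are retained.
#'
#' @param peptides Peptide tibble.
#' @return Filtered peptide tibble.
#' @export
drop_razor_decoy_peptides <- function(peptides) {
  filter(peptides, !(.data$is_decoy & !is.na(.data$proteins)))
}

#' Map surviving peptides onto protein groups
#'
#' Retains a protein group if and only if at least one surviving peptide's
#' leading razor accession is a member of the group's `protein_ids`.
#'
#' @param groups Long protein-group tibble (see [read_protein_groups()]).
#' @param peptides Post-FDR, post-QC peptide tibble.
#' @return Filtered protein-group tibble.
#' @export
map_groups_by_leading_razor <- function(groups, peptides) {
  leading <- unique(peptides$leading_razor_protein)
  keep <- groups %>%
    distinct(.data$group_id, .data$protein_ids) %>%
    filter(map_lgl(.data$protein_ids,
                   ~ any(split_ids(.x) %in% leading))) %>%
    pull("group_id")
  filter(groups, .data$group_id %in% keep)
}

#' Minimum razor + unique peptides filter
#'
#' Per raw file, a group's LFQ value is masked to missing where its razor +
#' unique peptide count falls below `min_count`; groups masked in every raw
#' file are removed. With `whole_group = TRUE` the stricter reading is used:
#' any raw file below the threshold removes the whole group.
#'
#' @param groups Long protein-group tibble.
#' @param min_count Minimum razor + unique peptides per raw file (default 2).
#' @param whole_group If `TRUE`, drop the entire group when any raw file is
#'   below `min_count`.
#' @return Filtered protein-group tibble with masked `lfq` cells set `NA`.
#' @export
min_peptides_filter <- function(groups, min_count = 2L, whole_group = FALSE) {
  stopifnot(min_count >= 1L)
  masked <- groups %>%
    mutate(.masked = .data$razor_unique < min_count,
           lfq = ifelse(.data$.masked, NA_real_, .data$lfq))
  drop <- masked %>%
    summarise(all_masked = all(.data$.masked),
              any_masked = any(.data$.masked), .by = "group_id")
  drop_ids <- if (whole_group) {
    drop$group_id[drop$any_masked]
  } else {
    drop$group_id[drop$all_masked]
  }
  masked %>%
    filter(!.data$group_id %in% drop_ids) %>%
    select(-".masked")
}

#' Drop contaminant, decoy and excluded protein groups
#'
#' Removes groups flagged as contaminants or decoy groups, and groups whose
#' annotation matches any excluded pattern (case-insensitive substring;
#' default collagen and keratin, which dominate skeletal samples and would
#' swamp the microbial signal).
#'
#' @param groups Long protein-group tibble.
#' @param excluded_patterns Character vector of substrings.
#' @return Filtered protein-group tibble.
#' @export
drop_contaminants_and_excluded <- function(groups,
                                           excluded_patterns = c("collagen",
                                                                 "keratin")) {
  pattern_hit <- function(ann) {
    if (length(excluded_patterns) == 0L) return(rep(FALSE, length(ann)))
    Reduce(`|`, lapply(excluded_patterns, function(p) {
      str_detect(stringr::str_to_lower(dplyr::coalesce(ann, "")),
                 fixed(stringr::str_to_lower(p)))
    }))
  }
  filter(groups, !.data$is_contaminant, !.data$is_decoy_group,
         !pattern_hit(.data$annotation))
}

#' Count unique peptide sequences
#'
#' Counts distinct peptide sequences per stratum and raw file (the unique
#' sequence string is the counting key; charge states or modifications do not
#' multiply counts).
#'
#' @param peptides Peptide tibble (post-filter).
#' @return Tibble with columns `stratum`, `raw_file`, `n_peptides`.
#' @export
count_unique_peptides <- function(peptides) {
  peptides %>%
    distinct(.data$stratum, .data$raw_file, .data$sequence) %>%
    count(.data$stratum, .data$raw_file, name = "n_peptides")
}

#' Filter audit log
#'
#' Compares a protein-group table before and after a filtering stage and
#' records each removed group with the stage name, for the pipeline's audit
#' TSV.
#'
#' @param before,after Long protein-group tibbles.
#' @param reason Stage name recorded for each removal.
#' @return Tibble with columns `group_id`, `protein_ids`, `reason`.
#' @export
filter_audit <- function(before, after, reason) {
  before %>%
    distinct(.data$group_id, .data$protein_ids) %>%
    filter(!.data$group_id %in% unique(after$group_id)) %>%
    mutate(reason = reason)
}
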