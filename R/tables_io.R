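#' Column dialects for peptide tables
#'
#' A dialect maps the canonical column names used throughout this package to
#' the column headers found in a particular file flavour. [dialect_canonical()]
#' is the identity mapping used by the synthetic tables;
#' [dialect_maxquant()] matches the headers of a `peptides.txt` export from a
#' MaxQuant-style search (the `stratum` column is not part of such exports and
#' is optional on read).
#'
#' @return Named character vector, names canonical, values file headers.
#' @export
dialect_canonical <- function() {
  c(sequence = "sequence", score = "score",
    leading_razor_protein = "leading_razor_protein",
    proteins = "proteins", raw_file = "raw_file", stratum = "stratum")
}

#' @rdname dialect_canonical
#' @export
dialect_maxquant <- function() {
  c(sequence = "Sequence", score = "Score",
    leading_razor_protein = "Leading razor protein",
    proteins = "Proteins", raw_file = "Raw file", stratum = "Taxonomic group")
}

peptide_columns <- c("sequence", "score", "stratum",
                     "leading_razor_protein", "proteins", "raw_file",
                     "is_decoy")

#' Read a peptide identification table
#'
#' Reads a tab-separated peptide-level identification table (the shape of a
#' search engine's peptide export) into a tibble with one row per identified
#' peptide. The decoy flag is derived from the configured decoy prefix on the
#' leading razor protein; a missing `proteins` cell is kept as `NA` (an
#' explicit missing marker, distinct from an empty list).
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect Named character vector mapping canonical column names to the
#'   file's headers; see [dialect_canonical()].
#' @param decoy_prefix Accession prefix marking reverse-database hits.
#' @return Tibble with columns `sequence`, `score`, `stratum`,
#'   `leading_razor_protein`, `proteins`, `raw_file`, `is_decoy`.
#' @export
read_peptide_table <- function(path, dialect = dialect_canonical(),
                               decoy_prefix = "REV__") {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  required <- c("sequence", "score", "leading_razor_protein", "proteins",
                "raw_file")
  for (col in required) {
    if (!dialect[[col]] %in% names(raw)) {
      abort(sprintf("peptide table is missing required column '%s' (canonical '%s')",
                    dialect[[col]], col))
    }
  }
  out <- tibble(
    sequence = raw[[dialect[["sequence"]]]],
    score_chr = raw[[dialect[["score"]]]],
    stratum = if (dialect[["stratum"]] %in% names(raw))
      raw[[dialect[["stratum"]]]] else NA_character_,
    leading_razor_protein = raw[[dialect[["leading_razor_protein"]]]],
    proteins = dplyr::na_if(raw[[dialect[["proteins"]]]], ""),
    raw_file = raw[[dialect[["raw_file"]]]]
  )
  score <- suppressWarnings(as.numeric(out$score_chr))
  bad <- which(is.na(score) & nzchar(out$score_chr))
  if (length(bad) > 0L) {
    abort(sprintf("unparseable score '%s' in peptide table row %d",
                  out$score_chr[bad[1L]], bad[1L]))
  }
  out %>%
    mutate(score = score,
           is_decoy = str_starts(.data$leading_razor_protein,
                                 fixed(decoy_prefix))) %>%
    select(all_of(peptide_columns))
}

#' Write a peptide table
#'
#' Inverse of [read_peptide_table()]: writes the canonical TSV dialect.
#' Missing `proteins` cells are written as empty strings; the derived
#' `is_decoy` column is not written (it is a pure function of the prefix).
#'
#' @param peptides Peptide tibble as returned by [read_peptide_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  peptides %>%
    select(all_of(setdiff(peptide_columns, "is_decoy"))) %>%
    mutate(proteins = dplyr::coalesce(.data$proteins, "")) %>%
    readr::write_tsv(path, na = "", progress = FALSE)
  invisible(path)
}

razor_col <- function(raw) paste0("Razor + unique peptides ", raw)
lfq_col <- function(raw) paste0("LFQ intensity ", raw)

group_meta_columns <- c("group_id", "protein_ids", "majority_protein_ids",
                        "annotation", "is_contaminant", "is_decoy_group")

#' Read a protein-group table
#'
#' Reads a MaxQuant-style protein-group TSV (wide: one pair of
#' `Razor + unique peptides <raw file>` / `LFQ intensity <raw file>` columns
#' per raw file) into tidy long form with one row per group and raw file.
#' Empty LFQ cells become `NA` ("not quantified"), never 0.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `group_id`, `protein_ids`,
#'   `majority_protein_ids`, `annotation`, `is_contaminant`,
#'   `is_decoy_group`, `raw_file`, `razor_unique`, `lfq`.
#' @export
read_protein_groups <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  for (col in c("group_id", "protein_ids", "majority_protein_ids")) {
    if (!col %in% names(raw)) {
      abort(sprintf("protein-group table is missing required column '%s'", col))
    }
  }
  raw_files <- names(raw) %>%
    purrr::keep(~ str_starts(.x, fixed("Razor + unique peptides "))) %>%
    str_remove(fixed("Razor + unique peptides "))
  if (length(raw_files) == 0L) {
    abort("protein-group table has no 'Razor + unique peptides <raw file>' columns")
  }
  meta <- tibble(
    group_id = as.integer(raw$group_id),
    protein_ids = raw$protein_ids,
    majority_protein_ids = raw$majority_protein_ids,
    annotation = if ("annotation" %in% names(raw)) raw$annotation else "",
    is_contaminant = if ("is_contaminant" %in% names(raw))
      raw$is_contaminant == "TRUE" else FALSE,
    is_decoy_group = if ("is_decoy_group" %in% names(raw))
      raw$is_decoy_group == "TRUE" else FALSE
  )
  quant <- purrr::map(raw_files, function(rf) {
    tibble(
      group_id = meta$group_id,
      raw_file = rf,
      razor_unique = as.integer(dplyr::na_if(raw[[razor_col(rf)]], "")),
      lfq = as.numeric(dplyr::na_if(raw[[lfq_col(rf)]], ""))
    )
  }) %>% list_rbind()
  meta %>%
    inner_join(quant, by = "group_id") %>%
    mutate(razor_unique = dplyr::coalesce(.data$razor_unique, 0L),
           raw_file = factor(.data$raw_file, levels = raw_files)) %>%
    arrange(.data$group_id, .data$raw_file) %>%
    mutate(raw_file = as.character(.data$raw_file))
}

#' Write a protein-group table
#'
#' Inverse of [read_protein_groups()]: spreads the long quantitation rows to
#' MaxQuant-style wide columns. Missing LFQ values are written as empty cells.
#'
#' @param groups Long protein-group tibble as from [read_protein_groups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(groups, path) {
  raw_files <- unique(groups$raw_file)
  meta <- groups %>% distinct(across(all_of(group_meta_columns)))
  wide <- meta
  for (rf in raw_files) {
    sub <- groups %>% filter(.data$raw_file == rf)
    sub <- sub[match(meta$group_id, sub$group_id), ]
    wide[[razor_col(rf)]] <- sub$razor_unique
    wide[[lfq_col(rf)]] <- sub$lfq
  }
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a taxonomy lineage table
#'
#' Reads a wide TSV (`accession` plus one column per rank, in ladder order;
#' empty cells mean the rank is absent from that accession's lineage) into a
#' tidy long tibble of `(accession, rank, taxon)` rows ordered root to leaf.
#'
#' @param path Path to a TSV file.
#' @param ladder Ordered character vector of ranks, root first.
#' @return Tibble with columns `accession`, `rank`, `taxon`.
#' @export
read_lineage_table <- function(path,
                               ladder = default_config()$taxonomy$rank_ladder) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  if (!"accession" %in% names(raw)) {
    abort("lineage table is missing required column 'accession'")
  }
  if (anyDuplicated(raw$accession)) {
    dup <- raw$accession[duplicated(raw$accession)][1L]
    abort(sprintf("duplicate accession '%s' in lineage table", dup))
  }
  ranks <- intersect(ladder, names(raw))
  raw %>%
    select(all_of(c("accession", ranks))) %>%
    pivot_longer(all_of(ranks), names_to = "rank", values_to = "taxon") %>%
    filter(nzchar(.data$taxon)) %>%
    mutate(rank = factor(.data$rank, levels = ladder)) %>%
    arrange(.data$accession, .data$rank) %>%
    mutate(rank = as.character(.data$rank))
}

#' Write a taxonomy lineage table
#'
#' Inverse of [read_lineage_table()]: one row per accession, one column per
#' rank of the ladder, absent ranks as empty cells.
#'
#' @param lineages Long lineage tibble (`accession`, `rank`, `taxon`).
#' @param path Output path.
#' @param ladder Ordered character vector of ranks, root first.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(lineages, path,
                                ladder = default_config()$taxonomy$rank_ladder) {
  wide <- lineages %>%
    mutate(rank = factor(.data$rank, levels = ladder)) %>%
    arrange(.data$accession, .data$rank) %>%
    pivot_wider(names_from = "rank", values_from = "taxon",
                values_fill = "") %>%
    select(all_of(c("accession", intersect(ladder, unique(lineages$rank)))))
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read amino-acid FASTA references
#'
#' Reads a FASTA file of protein sequences. Headers are tokenized at the
#' first whitespace; sequences are uppercased (so lowercase soft-masked
#' residues compare equal to their uppercase forms).
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `seq_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) abort("FASTA file contains no records")
  seqs <- str_to_upper(as.character(set))
  if (any(!nzchar(seqs))) abort("FASTA file contains an empty record")
  ids <- map_chr(str_split(names(set), "\\s+"), 1L)
  tibble(seq_id = ids, sequence = unname(seqs))
}
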