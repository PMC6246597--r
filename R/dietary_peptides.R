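AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

check_protein_sequence <- function(sequence) {
  residues <- strsplit(str_to_upper(sequence), "")[[1L]]
  bad <- setdiff(residues, AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf("invalid residue(s) in sequence: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  paste(residues, collapse = "")
}

#' In-silico tryptic digestion
#'
#' Cleaves after lysine (K) or arginine (R) except when the next residue is
#' proline (P) — the classical trypsin rule; set `proline_rule = FALSE` for
#' the trypsin/P behaviour of some search engines — and enumerates all
#' peptides carrying 0 to `max_missed` missed cleavages, ordered by
#' `(start, end)`. The zero-missed peptides tile the parent exactly.
#'
#' @param sequence Amino-acid string.
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @param parent_id Identifier recorded in the output (default `NA`).
#' @param proline_rule If `TRUE` (default), no cleavage before proline.
#' @return Tibble with columns `sequence`, `start`, `end` (0-based,
#'   half-open), `missed_cleavages`, `parent_id`.
#' @export
#' @examples
#' tryptic_digest("AKRP", max_missed = 0)
tryptic_digest <- function(sequence, max_missed = 2L, parent_id = NA_character_,
                           proline_rule = TRUE) {
  stopifnot(max_missed >= 0L)
  sequence <- check_protein_sequence(sequence)
  res <- strsplit(sequence, "")[[1L]]
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (proline_rule) cut_after <- cut_after[res[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)  # fragment boundaries, 0-based
  n_frag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(n_frag)) {
    for (m in 0:min(max_missed, n_frag - i)) {
      s <- bounds[i]; e <- bounds[i + 1L + m]
      out[[length(out) + 1L]] <- tibble(
        sequence = substr(sequence, s + 1L, e),
        start = s, end = e, missed_cleavages = m, parent_id = parent_id)
    }
  }
  list_rbind(out) %>% arrange(.data$start, .data$end)
}

#' Deamidation-aware peptide equivalence
#'
#' During protein aging, asparagine (N) spontaneously deamidates to aspartate
#' (D) (and glutamine (Q) to glutamate (E)), so an observed D cannot be told
#' apart from an aged N. Two equal-length peptides are deamidation-equivalent
#' when they match position-wise under the equivalence class N = D (and
#' Q = E when enabled) and exactly elsewhere. Symmetric; peptides of unequal
#' length are never equivalent.
#'
#' @param pep_a,pep_b Peptide strings.
#' @param q_e If `TRUE`, also treat Q and E as equivalent (default `FALSE`).
#' @return Logical scalar.
#' @export
#' @examples
#' deamidation_equivalent("PTPEGDLEILLQK", "PTPEGNLEILLQK")
deamidation_equivalent <- function(pep_a, pep_b, q_e = FALSE) {
  if (nchar(pep_a) != nchar(pep_b)) return(FALSE)
  canon <- function(p) {
    p <- chartr("N", "D", p)
    if (q_e) p <- chartr("Q", "E", p)
    p
  }
  canon(pep_a) == canon(pep_b)
}

deamidation_key <- function(p, q_e = FALSE) {
  p <- chartr("N", "D", p)
  if (q_e) p <- chartr("Q", "E", p)
  p
}

#' Species-discriminating tryptic peptides of two reference proteins
#'
#' Digests both references, classifies every digest peptide as `shared`
#' (sequence present in both digests), `unique_a`/`unique_b` (present in one
#' only), or — when `deamidation_aware` — `ambiguous` where a nominally
#' unique peptide has a deamidation-equivalent counterpart in the other
#' digest and so cannot support a species call in aged samples. Length
#' bounds, when given, are applied after the uniqueness logic.
#'
#' @param ref_a,ref_b Amino-acid reference sequences (mature proteins; signal
#'   peptides are assumed pre-removed).
#' @param max_missed Maximum missed cleavages (default 2).
#' @param deamidation_aware Move deamidation-confusable peptides to
#'   `ambiguous` (default `TRUE`).
#' @param q_e Extend the equivalence to Q = E (default `FALSE`).
#' @param len_min,len_max Optional reported peptide length bounds.
#' @param proline_rule Passed to [tryptic_digest()].
#' @return Object of class `diet_discrimination`: tibble with `reference`
#'   (`"a"`/`"b"`), `sequence`, `start`, `end`, `missed_cleavages`, `class`.
#' @export
discriminating_peptides <- function(ref_a, ref_b, max_missed = 2L,
                                    deamidation_aware = TRUE, q_e = FALSE,
                                    len_min = NULL, len_max = NULL,
                                    proline_rule = TRUE) {
  dig_a <- tryptic_digest(ref_a, max_missed, "a", proline_rule)
  dig_b <- tryptic_digest(ref_b, max_missed, "b", proline_rule)
  classify_side <- function(mine, other) {
    cls <- ifelse(mine$sequence %in% other$sequence, "shared", "unique")
    if (deamidation_aware) {
      other_keys <- unique(deamidation_key(other$sequence, q_e))
      confusable <- deamidation_key(mine$sequence, q_e) %in% other_keys
      cls[cls == "unique" & confusable] <- "ambiguous"
    }
    cls
  }
  out <- bind_rows(
    dig_a %>% mutate(reference = "a",
                     class = classify_side(dig_a, dig_b)),
    dig_b %>% mutate(reference = "b",
                     class = classify_side(dig_b, dig_a))
  ) %>%
    mutate(class = ifelse(.data$class == "unique",
                          paste0("unique_", .data$reference), .data$class)) %>%
    select("reference", "sequence", "start", "end", "missed_cleavages",
           "class")
  if (!is.null(len_min)) out <- filter(out, nchar(.data$sequence) >= len_min)
  if (!is.null(len_max)) out <- filter(out, nchar(.data$sequence) <= len_max)
  structure(out, class = c("diet_discrimination", class(out)),
            deamidation_aware = deamidation_aware)
}

#' @method glance diet_discrimination
#' @export
glance.diet_discrimination <- function(x, ...) {
  fully <- filter(x, .data$missed_cleavages == 0L)
  loci <- fully %>%
    filter(str_starts(.data$class, "unique")) %>%
    distinct(.data$start, .data$end)
  tibble(
    n_unique_a = sum(fully$class == "unique_a"),
    n_unique_b = sum(fully$class == "unique_b"),
    n_ambiguous = sum(fully$class == "ambiguous") / 2L,
    n_discriminating = nrow(loci),
    deamidation_aware = attr(x, "deamidation_aware")
  )
}

#' Count discriminating tryptic peptide loci
#'
#' The number of distinct fully cleaved peptide positions (`start`, `end`
#' coordinate pairs) at which the two references differ without being
#' deamidation-confusable — "N tryptic peptides uniquely discriminate"
#' between the two species.
#'
#' @param discrimination A `diet_discrimination` tibble.
#' @return Integer count.
#' @export
count_discriminating <- function(discrimination) {
  glance(discrimination)$n_discriminating
}

#' Synthetic beta-lactoglobulin reference set
#'
#' Loads the constructed stand-in references shipped with the package
#' (`inst/extdata/blg_synthetic.fasta`): bovine-, caprine- and ovine-like
#' mature beta-lactoglobulin sequences. They are synthetic — built to carry
#' the documented polymorphism structure of the real homologs (an N/D site
#' in the PTPEGDLEILLQK marker peptide, bovine D versus caprine/ovine N,
#' plus three non-deamidation discriminating tryptic peptide loci between
#' the bovine-like and caprine-like chains) — not database sequences. The
#' marker peptide sits at the mature N-terminus so that it is recoverable
#' under the no-cleavage-before-proline trypsin rule.
#'
#' @return Tibble with columns `seq_id`, `sequence`.
#' @export
blg_synthetic_references <- function() {
  read_fasta(system.file("extdata", "blg_synthetic.fasta",
                         package = "calculomics", mustWork = TRUE))
}

#' Classify an observed peptide against species references
#'
#' Returns the set of species whose tryptic digest contains the observed
#' peptide exactly or — when `deamidation_aware` — up to deamidation
#' equivalence. A set of size > 1 means the peptide cannot support a species
#' identification in aged samples; an empty set means unmatched.
#'
#' @param pep Observed peptide string.
#' @param references Named character vector (or tibble with `seq_id`,
#'   `sequence` as from [read_fasta()]) of mature reference proteins keyed by
#'   species.
#' @param max_missed Maximum missed cleavages used to digest the references.
#' @param deamidation_aware Match up to N = D equivalence (default `TRUE`).
#' @param q_e Extend the equivalence to Q = E (default `FALSE`).
#' @param proline_rule Passed to [tryptic_digest()].
#' @return Character vector of matching species names (possibly empty).
#' @export
classify_observed_peptide <- function(pep, references, max_missed = 2L,
                                      deamidation_aware = TRUE, q_e = FALSE,
                                      proline_rule = TRUE) {
  if (is.data.frame(references)) {
    references <- setNames(references$sequence, references$seq_id)
  }
  pep <- check_protein_sequence(pep)
  hits <- map_lgl(references, function(ref) {
    dig <- tryptic_digest(ref, max_missed, proline_rule = proline_rule)
    if (pep %in% dig$sequence) return(TRUE)
    if (deamidation_aware) {
      return(deamidation_key(pep, q_e) %in%
               deamidation_key(dig$sequence, q_e))
    }
    FALSE
  })
  names(references)[hits]
}
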