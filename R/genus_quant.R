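#' Genus-level fractional abundances from LFQ intensities
#'
#' Per sample (raw file), sums the LFQ intensities of bacterial protein
#' groups resolved to genus level or better — species-level assignments roll
#' up to their genus — and divides by the total LFQ intensity of ALL
#' bacterial groups in that sample, including those whose LCA stopped above
#' genus. Fractions therefore sum to at most 1 per sample; the remainder is
#' the genus-unassigned bacterial fraction, reported alongside. Masked or
#' missing LFQ cells contribute nothing to either sum.
#'
#' @param groups Long protein-group tibble (post-filtering).
#' @param assignments Assignment tibble from [assign_taxonomy()].
#' @param rank Taxonomic rank to aggregate at (default `"genus"`; use
#'   `"species"` for a species-level table).
#' @return Object of class `genus_fractions`: a tibble with columns
#'   `raw_file`, `genus`, `fraction` (and `lfq_sum`), carrying an
#'   `unassigned` attribute tibble (`raw_file`, `unassigned_fraction`,
#'   `total_bacterial_lfq`). Samples with zero bacterial intensity are
#'   flagged in the `undefined_samples` attribute.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1))
#' asg <- assign_taxonomy(sim$protein_groups, sim$peptides, sim$lineages)
#' gf <- genus_fractions(sim$protein_groups, asg)
#' head(gf)
genus_fractions <- function(groups, assignments, rank = "genus") {
  taxon_col <- assignments %>%
    mutate(taxon = map_chr(.data$lca_path, taxon_at_rank, rank = rank)) %>%
    select("group_id", "effective_stratum", "taxon")
  bact <- groups %>%
    inner_join(taxon_col, by = "group_id") %>%
    filter(.data$effective_stratum == "bacteria")
  totals <- bact %>%
    summarise(total_bacterial_lfq = sum(.data$lfq, na.rm = TRUE),
              .by = "raw_file")
  undefined <- totals$raw_file[totals$total_bacterial_lfq <= 0]
  if (length(undefined) > 0L) {
    warning(sprintf("sample(s) with zero bacterial LFQ intensity: %s",
                    paste(undefined, collapse = ", ")), call. = FALSE)
  }
  fr <- bact %>%
    filter(!is.na(.data$taxon)) %>%
    summarise(lfq_sum = sum(.data$lfq, na.rm = TRUE),
              .by = c("raw_file", "taxon")) %>%
    rename(genus = "taxon") %>%
    left_join(totals, by = "raw_file") %>%
    mutate(fraction = ifelse(.data$total_bacterial_lfq > 0,
                             .data$lfq_sum / .data$total_bacterial_lfq,
                             NA_real_)) %>%
    select("raw_file", "genus", "lfq_sum", "fraction") %>%
    arrange(.data$raw_file, desc(.data$fraction))
  unassigned <- fr %>%
    summarise(assigned = sum(.data$fraction), .by = "raw_file") %>%
    right_join(totals, by = "raw_file") %>%
    mutate(unassigned_fraction = ifelse(.data$total_bacterial_lfq > 0,
                                        1 - dplyr::coalesce(.data$assigned, 0),
                                        NA_real_)) %>%
    select("raw_file", "unassigned_fraction", "total_bacterial_lfq")
  structure(fr, class = c("genus_fractions", class(fr)),
            unassigned = unassigned, undefined_samples = undefined,
            rank = rank)
}

#' @method glance genus_fractions
#' @export
glance.genus_fractions <- function(x, ...) {
  tibble(n_samples = dplyr::n_distinct(x$raw_file),
         n_taxa = dplyr::n_distinct(x$genus),
         rank = attr(x, "rank"),
         max_unassigned_fraction =
           max(attr(x, "unassigned")$unassigned_fraction, na.rm = TRUE))
}

#' Spread genus fractions to a samples-by-genera matrix
#'
#' @param fractions A `genus_fractions` tibble.
#' @param fill Value for genus/sample combinations never observed (default 0:
#'   an absent genus has zero bacterial LFQ intensity in that sample).
#' @return Numeric matrix, rows = samples (raw files), columns = genera.
#' @export
fraction_matrix <- function(fractions, fill = 0) {
  wide <- fractions %>%
    select("raw_file", "genus", "fraction") %>%
    pivot_wider(names_from = "genus", values_from = "fraction",
                values_fill = fill)
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$raw_file
  m
}

#' Log2 transform and median-normalize an intensity matrix
#'
#' Per sample column, each present intensity becomes `log2(value)` minus the
#' median of that column's log2 values; missing entries stay missing and
#' every column has median 0 afterwards (all-missing columns pass through).
#'
#' @param mat Numeric matrix, rows = entries (e.g. protein groups),
#'   columns = samples; entries positive or `NA`.
#' @return Normalized matrix of the same shape.
#' @export
log2_median_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat <= 0, na.rm = TRUE)) {
    abort("intensities must be strictly positive where present")
  }
  lg <- log2(mat)
  med <- apply(lg, 2L, median, na.rm = TRUE)
  med[is.na(med)] <- 0  # all-missing column: leave untouched
  sweep(lg, 2L, med, `-`)
}

#' Minimum-observations ("min half") row filter
#'
#' Keeps matrix rows observed (non-missing) in at least `ceiling(n/2)` of the
#' given sample subset, the filter applied before hierarchical clustering
#' (11 of 22 samples at the default design).
#'
#' @param mat Numeric matrix, columns = samples.
#' @param sample_subset Column names defining the subset the threshold is
#'   computed on; default all columns.
#' @return The filtered matrix.
#' @export
min_half_filter <- function(mat, sample_subset = colnames(mat)) {
  if (length(sample_subset) == 0L) abort("sample_subset must be nonempty")
  stopifnot(all(sample_subset %in% colnames(mat)))
  threshold <- ceiling(length(sample_subset) / 2)
  present <- rowSums(!is.na(mat[, sample_subset, drop = FALSE]))
  mat[present >= threshold, , drop = FALSE]
}

#' LFQ intensity matrix from a long protein-group table
#'
#' @param groups Long protein-group tibble.
#' @return Numeric matrix, rows = group IDs, columns = raw files, `NA` where
#'   not quantified.
#' @export
lfq_matrix <- function(groups) {
  wide <- groups %>%
    select("group_id", "raw_file", "lfq") %>%
    pivot_wider(names_from = "raw_file", values_from = "lfq")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- as.character(wide$group_id)
  m
}

#' Top-N abundance table for the genus bar chart
#'
#' Orders genera by mean fractional abundance across samples and keeps the
#' top N (default 20), the layout of a stacked genus distribution bar chart.
#'
#' @param fractions A `genus_fractions` tibble.
#' @param top_n Number of genera to keep.
#' @return Tibble with `raw_file`, `genus`, `fraction`, genera ordered by
#'   decreasing mean abundance.
#' @export
top_genera <- function(fractions, top_n = 20L) {
  means <- fractions %>%
    summarise(mean_fraction = mean(.data$fraction, na.rm = TRUE),
              .by = "genus") %>%
    arrange(desc(.data$mean_fraction)) %>%
    head(top_n)
  fractions %>%
    as_tibble() %>%
    filter(.data$genus %in% means$genus) %>%
    mutate(genus = factor(.data$genus, levels = means$genus)) %>%
    arrange(.data$raw_file, .data$genus) %>%
    select("raw_file", "genus", "fraction")
}
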