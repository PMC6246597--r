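#' Split peptides by taxonomic stratum
#'
#' Partitions a peptide table into the three search-space strata (`human`,
#' `bacteria`, `other`) within which target-decoy FDR is controlled
#' independently. The union of the outputs equals the input and row order is
#' preserved within each stratum; strata with no records yield empty tibbles.
#'
#' @param peptides Peptide tibble (see [read_peptide_table()]).
#' @param strata Character vector of admissible stratum labels.
#' @return Named list of peptide tibbles, one per stratum.
#' @export
split_by_stratum <- function(peptides,
                             strata = c("human", "bacteria", "other")) {
  bad <- setdiff(unique(peptides$stratum), strata)
  if (length(bad) > 0L) {
    abort(sprintf("unknown stratum label(s): %s", paste(bad, collapse = ", ")))
  }
  setNames(lapply(strata, function(s) filter(peptides, .data$stratum == s)),
           strata)
}

#' Accept peptides at a target-decoy FDR threshold
#'
#' Implements score-accumulation FDR control within one stratum: all records
#' (forward and reverse hits together) are sorted by identification score in
#' descending order and the accepted set is the longest prefix whose ratio of
#' reverse to forward hits does not exceed `q`. Records tied at the boundary
#' score are admitted or rejected as a block, so the cutoff is a pure score
#' threshold. Reverse hits are discarded from the accepted output.
#'
#' The ratio convention is reverse/forward with 0/0 treated as 0; a prefix
#' with forward = 0 and reverse > 0 never qualifies.
#'
#' @param peptides Peptide tibble from a single stratum.
#' @param q FDR threshold in (0, 1); default 0.01.
#' @return Object of class `fdr_result`: a list with `summary` (one-row
#'   tibble: `q_threshold`, `cutoff_score`, `n_forward_accepted`,
#'   `n_reverse_in_prefix`, `estimated_fdr`) and `accepted` (the forward
#'   records of the accepted prefix).
#' @export
#' @examples
#' peps <- simulate_dataset(sim_config(seed = 1))$peptides
#' res <- accept_at_fdr(dplyr::filter(peps, stratum == "bacteria"), q = 0.01)
#' tidy(res)
accept_at_fdr <- function(peptides, q = 0.01) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    abort("q must be a single number strictly between 0 and 1")
  }
  ord <- arrange(peptides, desc(.data$score))
  n <- nrow(ord)
  accepted_len <- 0L
  if (n > 0L) {
    cum_rev <- cumsum(ord$is_decoy)
    cum_fwd <- seq_len(n) - cum_rev
    ratio <- ifelse(cum_fwd == 0L, ifelse(cum_rev == 0L, 0, Inf),
                    cum_rev / cum_fwd)
    # tie blocks: a prefix may only end where the score changes
    block_end <- c(ord$score[-n] != ord$score[-1L], TRUE)
    qualifying <- which(block_end & ratio <= q)
    if (length(qualifying) > 0L) accepted_len <- max(qualifying)
  }
  prefix <- head(ord, accepted_len)
  n_rev <- sum(prefix$is_decoy)
  n_fwd <- accepted_len - n_rev
  summary <- tibble(
    q_threshold = q,
    cutoff_score = if (accepted_len > 0L) ord$score[accepted_len] else NA_real_,
    n_forward_accepted = n_fwd,
    n_reverse_in_prefix = n_rev,
    estimated_fdr = if (n_fwd > 0L) n_rev / n_fwd else 0
  )
  structure(list(summary = summary,
                 accepted = filter(prefix, !.data$is_decoy)),
            class = "fdr_result")
}

#' @method tidy fdr_result
#' @export
tidy.fdr_result <- function(x, ...) x$summary

#' @method glance fdr_result
#' @export
glance.fdr_result <- function(x, ...) {
  mutate(x$summary, n_input = .data$n_forward_accepted +
           .data$n_reverse_in_prefix)
}

#' @method print fdr_result
#' @export
print.fdr_result <- function(x, ...) {
  cat("Target-decoy FDR result\n")
  print(x$summary)
  invisible(x)
}

#' Stratified FDR control across all strata
#'
#' Applies [accept_at_fdr()] independently within each stratum at the same
#' threshold `q` and binds the surviving forward peptides back together.
#'
#' @param peptides Peptide tibble with a `stratum` column.
#' @param q FDR threshold in (0, 1), applied to each stratum.
#' @param strata Admissible stratum labels.
#' @return List with `summary` (one row per stratum: stratum, q, cutoff,
#'   counts, estimated FDR) and `accepted` (forward records from all strata).
#' @export
stratified_fdr <- function(peptides, q = 0.01,
                           strata = c("human", "bacteria", "other")) {
  parts <- split_by_stratum(peptides, strata)
  results <- imap(parts, function(part, name) {
    res <- accept_at_fdr(part, q)
    list(summary = mutate(res$summary, stratum = name, .before = 1L),
         accepted = res$accepted)
  })
  list(
    summary = list_rbind(map(results, "summary")),
    accepted = list_rbind(map(results, "accepted"))
  )
}

#' Accepted-count curve over a grid of FDR thresholds
#'
#' Diagnostic around the single working threshold: reruns [accept_at_fdr()]
#' at each `q` of a grid and reports how many forward identifications each
#' threshold admits. Counts are non-decreasing in `q`.
#'
#' @param peptides Peptide tibble from a single stratum.
#' @param q_grid Numeric vector of thresholds in (0, 1).
#' @return Tibble with columns `q`, `n_accepted`, `cutoff_score`.
#' @export
estimated_fdr_curve <- function(peptides, q_grid) {
  if (length(q_grid) == 0L) abort("q_grid must be nonempty")
  map(sort(q_grid), function(q) {
    s <- accept_at_fdr(peptides, q)$summary
    tibble(q = q, n_accepted = s$n_forward_accepted,
           cutoff_score = s$cutoff_score)
  }) %>% list_rbind()
}
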