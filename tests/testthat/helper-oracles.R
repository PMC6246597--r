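# Independent brute-force oracles the implementation is checked against.

# Longest qualifying prefix by exhaustive scan over every score-tie-respecting
# prefix length; returns (accepted length, forward, reverse, cutoff score).
oracle_accept <- function(scores, is_decoy, q) {
  ord <- order(-scores)
  s <- scores[ord]
  d <- is_decoy[ord]
  best <- 0L
  for (len in seq_along(s)) {
    if (len < length(s) && s[len] == s[len + 1L]) next  # inside a tie block
    n_rev <- sum(d[seq_len(len)])
    n_fwd <- len - n_rev
    ratio <- if (n_fwd == 0L) (if (n_rev == 0L) 0 else Inf) else n_rev / n_fwd
    if (ratio <= q) best <- len
  }
  n_rev <- if (best > 0L) sum(d[seq_len(best)]) else 0L
  list(len = best, n_forward = best - n_rev, n_reverse = n_rev,
       cutoff = if (best > 0L) s[best] else NA_real_)
}

# LCA by leaf-to-root scan of the first path: the deepest (rank, taxon) pair
# of path 1 that appears in every other path.
oracle_lca <- function(lineages, accessions, ladder) {
  get_path <- function(a) {
    p <- lineages[lineages$accession == a, ]
    p <- p[order(match(p$rank, ladder)), ]
    paste(p$rank, p$taxon, sep = "|")
  }
  first <- get_path(accessions[1L])
  others <- lapply(accessions[-1L], get_path)
  for (pair in rev(first)) {
    if (all(vapply(others, function(o) pair %in% o, logical(1)))) {
      parts <- strsplit(pair, "|", fixed = TRUE)[[1L]]
      return(list(taxon = parts[2L], rank = parts[1L]))
    }
  }
  list(taxon = "unassigned", rank = "unassigned")
}

# Bray-Curtis by the textbook double loop.
oracle_bray_curtis <- function(counts) {
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 2 * sum(pmin(counts[i, ], counts[j, ]))
      den <- sum(counts[i, ]) + sum(counts[j, ])
      d[i, j] <- 1 - num / den
    }
  }
  d
}
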