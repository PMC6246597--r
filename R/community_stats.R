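#' Two-group differential genus test
#'
#' Two-tailed two-sample t-test per genus on log2-transformed fractional
#' abundances between two sample groups, with Benjamini-Hochberg adjustment
#' across the tested genera. Zero fractions are treated as missing (no
#' pseudo-count is fabricated); a genus needs at least two present values in
#' each group to be tested, otherwise it is reported untested.
#'
#' @param fractions A `genus_fractions` tibble (or any tibble with
#'   `raw_file`, `genus`, `fraction`).
#' @param labels Named character vector or two-column tibble
#'   (`raw_file`, `group`) assigning each sample to one of two groups.
#' @param alpha Significance level for the adjusted p-values (default 0.05).
#' @param var_equal `TRUE` (default) for Student's pooled-variance t,
#'   `FALSE` for Welch.
#' @return Object of class `genus_diff` (a tibble): `genus`, `log2_ratio`
#'   (group1 minus group2 mean log2 fraction), `t_statistic`, `p_value`,
#'   `adjusted_p`, `significant`, `n1`, `n2`, `tested`. Group 1 is the first
#'   group label in sorted order unless `labels` is a factor.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1))
#' asg <- assign_taxonomy(sim$protein_groups, sim$peptides, sim$lineages)
#' gf <- genus_fractions(sim$protein_groups, asg)
#' res <- two_group_t_test(gf, sim$truth$sample_groups)
#' dplyr::filter(res, significant)
two_group_t_test <- function(fractions, labels, alpha = 0.05,
                             var_equal = TRUE) {
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels$group), labels$raw_file)
  }
  groups_present <- if (is.factor(labels)) levels(labels) else
    sort(unique(as.character(labels)))
  if (length(groups_present) != 2L) {
    abort("labels must define exactly two groups")
  }
  g1 <- groups_present[1L]; g2 <- groups_present[2L]
  if (sum(labels == g1) < 2L || sum(labels == g2) < 2L) {
    abort("each group needs at least two samples")
  }
  dat <- fractions %>%
    as_tibble() %>%
    filter(.data$raw_file %in% names(labels)) %>%
    mutate(log2_fraction = ifelse(.data$fraction > 0,
                                  log2(.data$fraction), NA_real_),
           group = unname(labels[.data$raw_file]))
  if (nrow(dat) == 0L) {
    abort("no genus abundances overlap the labelled samples")
  }
  res <- dat %>%
    summarise(x = list(.data$log2_fraction[.data$group == g1 &
                                             !is.na(.data$log2_fraction)]),
              y = list(.data$log2_fraction[.data$group == g2 &
                                             !is.na(.data$log2_fraction)]),
              .by = "genus") %>%
    mutate(n1 = map_int(.data$x, length), n2 = map_int(.data$y, length),
           tested = .data$n1 >= 2L & .data$n2 >= 2L)
  stats_tbl <- pmap(res, function(genus, x, y, n1, n2, tested) {
    if (!tested) {
      return(tibble(log2_ratio = NA_real_, t_statistic = NA_real_,
                    p_value = NA_real_))
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate: constant within both groups, t.test would refuse
      delta <- mean(x) - mean(y)
      return(tibble(log2_ratio = delta,
                    t_statistic = if (delta == 0) 0 else sign(delta) * Inf,
                    p_value = if (delta == 0) 1 else 0))
    }
    tt <- t.test(x, y, var.equal = var_equal)
    tibble(log2_ratio = mean(x) - mean(y),
           t_statistic = unname(tt$statistic), p_value = tt$p.value)
  }) %>% list_rbind()
  out <- bind_cols(select(res, "genus", "n1", "n2", "tested"), stats_tbl)
  adj <- rep(NA_real_, nrow(out))
  adj[out$tested] <- p.adjust(out$p_value[out$tested], method = "BH")
  out <- out %>%
    mutate(adjusted_p = adj,
           significant = dplyr::coalesce(.data$adjusted_p <= alpha, FALSE)) %>%
    select("genus", "log2_ratio", "t_statistic", "p_value", "adjusted_p",
           "significant", "n1", "n2", "tested")
  structure(out, class = c("genus_diff", class(out)),
            groups = c(g1, g2), alpha = alpha)
}

#' @method glance genus_diff
#' @export
glance.genus_diff <- function(x, ...) {
  tibble(n_genera = nrow(x), n_tested = sum(x$tested),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha"),
         group1 = attr(x, "groups")[1L], group2 = attr(x, "groups")[2L])
}

#' Hierarchical clustering with Pearson correlation distance
#'
#' Agglomerative clustering of samples using distance `1 - r`, where `r` is
#' the Pearson correlation of two sample columns over their pairwise-present
#' entries. Sample pairs sharing fewer than 3 present entries cannot support
#' a correlation; such pairs are flagged and their distance imputed as the
#' maximum observed distance.
#'
#' @param mat Numeric matrix, rows = entries (pre-filtered with
#'   [min_half_filter()] and normalized with [log2_median_normalize()]),
#'   columns = samples.
#' @param linkage Agglomeration method (`"average"` default, or
#'   `"complete"`/`"single"`).
#' @param k Number of flat groups to cut the tree into (default 2).
#' @return Object of class `calc_hclust`: list with `tree` (an
#'   [stats::hclust] object), `dist` (full symmetric distance matrix),
#'   `groups` (named integer vector of flat labels), and `flagged_pairs`
#'   (tibble of imputed pairs).
#' @export
hierarchical_cluster <- function(mat, linkage = "average", k = 2L) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) abort("need at least two samples to cluster")
  shared <- crossprod(!is.na(mat))
  r <- suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
  d <- 1 - r
  bad <- shared < 3L & upper.tri(shared)
  flagged <- tibble(
    sample_a = rownames(shared)[row(shared)[bad]],
    sample_b = colnames(shared)[col(shared)[bad]]
  )
  d[shared < 3L] <- NA
  diag(d) <- 0
  if (any(is.na(d))) {
    d_max <- max(d, na.rm = TRUE)
    d[is.na(d)] <- d_max
    warning(sprintf("%d sample pair(s) share < 3 entries; distance imputed as max observed (%.3f)",
                    nrow(flagged), d_max), call. = FALSE)
  }
  tree <- hclust(as.dist(d), method = linkage)
  groups <- cutree(tree, k = k)
  structure(list(tree = tree, dist = d, groups = groups,
                 flagged_pairs = flagged, linkage = linkage, k = k),
            class = "calc_hclust")
}

#' @method tidy calc_hclust
#' @export
tidy.calc_hclust <- function(x, ...) {
  tibble(merge_step = seq_len(nrow(x$tree$merge)),
         height = x$tree$height,
         member_a = x$tree$merge[, 1L], member_b = x$tree$merge[, 2L])
}

#' @method glance calc_hclust
#' @export
glance.calc_hclust <- function(x, ...) {
  tibble(n_samples = length(x$groups), k = x$k, linkage = x$linkage,
         n_flagged_pairs = nrow(x$flagged_pairs),
         max_height = max(x$tree$height))
}

#' @method print calc_hclust
#' @export
print.calc_hclust <- function(x, ...) {
  cat(sprintf("Hierarchical clustering of %d samples (Pearson distance, %s linkage)\n",
              length(x$groups), x$linkage))
  print(table(x$groups))
  invisible(x)
}

#' Scale percent abundances to integer counts
#'
#' Multiplies percent values by 10^6 and truncates the decimals (toward
#' zero), turning fractional percentages into the integer counts a
#' count-based dissimilarity expects.
#'
#' @param percents Numeric matrix or vector of percent values (>= 0).
#' @return Integer-valued object of the same shape.
#' @export
scale_percent_to_counts <- function(percents) {
  if (any(percents < 0, na.rm = TRUE)) {
    abort("percent values must be non-negative")
  }
  trunc(percents * 1e6)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i, j) = 1 - 2 * sum_g min(x_ig, x_jg) / (sum_g x_ig + sum_g x_jg)` on
#' non-negative counts; symmetric with zero diagonal and values in \[0, 1\].
#' Pairs involving an all-zero sample are undefined and returned as `NA`
#' with a warning.
#'
#' @param counts Numeric matrix of non-negative counts, rows = samples.
#' @return Symmetric dissimilarity matrix with the samples' names.
#' @export
bray_curtis <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) abort("counts must be non-negative")
  zero <- rowSums(counts) == 0
  d <- matrix(NA_real_, nrow(counts), nrow(counts),
              dimnames = list(rownames(counts), rownames(counts)))
  ok <- !zero
  if (sum(ok) >= 2L) {
    d[ok, ok] <- as.matrix(vegan::vegdist(counts[ok, , drop = FALSE],
                                          method = "bray"))
  }
  diag(d)[ok] <- 0
  if (any(zero)) {
    warning(sprintf("all-zero sample(s): %s; their dissimilarities are undefined",
                    paste(rownames(counts)[zero], collapse = ", ")),
            call. = FALSE)
  }
  d
}
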