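#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters as a nested list. Values follow
#' the conventions of MaxQuant-style search output (decoy prefix `REV__`,
#' contaminant prefix `CON__`) and the defaults used throughout the pipeline:
#' peptide FDR `q = 0.01` within each taxonomic stratum, a minimum of two
#' razor + unique peptides per raw file for quantitation, collagen/keratin
#' exclusion, an eight-rank taxonomic ladder (with `parvorder` between order
#' and family so the primate override has a home), and trypsin digestion with
#' up to two missed cleavages for dietary marker work.
#'
#' @return Nested named list with sections `io`, `fdr`, `filter`, `taxonomy`,
#'   `quant`, `stats` and `diet`.
#' @export
#' @examples
#' default_config()$fdr$q
default_config <- function() {
  list(
    io = list(
      decoy_prefix = "REV__",
      contaminant_prefix = "CON__"
    ),
    fdr = list(
      q = 0.01
    ),
    filter = list(
      min_razor_unique = 2L,
      whole_group = FALSE,
      excluded_patterns = c("collagen", "keratin")
    ),
    taxonomy = list(
      rank_ladder = c("superkingdom", "phylum", "class", "order",
                      "parvorder", "family", "genus", "species"),
      human_trigger_taxa = "Catarrhini",
      human_taxon = "Homo sapiens"
    ),
    quant = list(
      rank = "genus",
      top_n = 20L
    ),
    stats = list(
      alpha = 0.05,
      test_variant = "student",
      linkage = "average",
      k_groups = 2L
    ),
    diet = list(
      max_missed = 2L,
      len_min = 7L,
      len_max = 30L,
      deamidation_aware = TRUE,
      q_e_equivalence = FALSE
    )
  )
}

#' Read a pipeline configuration file
#'
#' Reads a flat YAML key-value file and merges it over [default_config()].
#' Keys may be nested (`fdr: {q: 0.05}`) or dotted (`fdr.q: 0.05`).
#'
#' @param path Path to a YAML configuration file.
#' @return Nested configuration list as in [default_config()].
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (is.null(user)) return(cfg)
  # expand dotted keys into nested lists
  for (key in names(user)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    node <- user[[key]]
    if (length(parts) == 2L) {
      cfg[[parts[1L]]][[parts[2L]]] <- node
    } else if (is.list(node)) {
      for (sub in names(node)) cfg[[key]][[sub]] <- node[[sub]]
    } else {
      cfg[[key]] <- node
    }
  }
  cfg
}
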