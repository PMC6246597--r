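test_that("representative selection keeps all maximal-count accessions", {
  counts <- c(A = 5, B = 5, C = 2)
  expect_setequal(select_representatives(c("A", "B", "C"), counts),
                  c("A", "B"))
  expect_equal(select_representatives("Z", counts), "Z")  # absent counts as 0
  expect_setequal(select_representatives(c("A", "B"), c(A = 3, B = 3)),
                  c("A", "B"))
  expect_error(select_representatives(character(0), counts), "empty majority")
})

test_that("lca intersects lineages and returns the lowest shared rank", {
  lin <- dplyr::bind_rows(strep_sanguinis(), strep_mutans(), human_lineage())

  one <- lca(lin, "STR_SANG")
  expect_equal(one$taxon, "Streptococcus sanguinis")
  expect_equal(one$rank, "species")

  two <- lca(lin, c("STR_SANG", "STR_MUT"))
  expect_equal(two$taxon, "Streptococcus")
  expect_equal(two$rank, "genus")

  cross <- lca(lin, c("STR_SANG", "HUM_1"))
  expect_equal(cross$taxon, "unassigned")

  # permutation invariance and idempotence
  expect_equal(lca(lin, c("STR_MUT", "STR_SANG")), two)
  expect_equal(lca(lin, c("STR_SANG", "STR_SANG")), one)

  # the result taxon appears in every input path
  expect_true(all(c("STR_SANG", "STR_MUT") %in%
                    lin$accession[lin$taxon == two$taxon]))
})

test_that("adding a lineage never makes the LCA more specific", {
  sim <- simulate_dataset(sim_config(seed = 9))
  lin <- sim$lineages
  ladder <- default_config()$taxonomy$rank_ladder
  accs <- unique(lin$accession)
  set.seed(90)
  for (i in 1:20) {
    base <- sample(accs, sample(1:4, 1))
    grown <- c(base, sample(accs, 1))
    d_base <- match(lca(lin, base)$rank, ladder)
    d_grown <- match(lca(lin, grown)$rank, ladder)
    expect_true(is.na(d_grown) || (!is.na(d_base) && d_grown <= d_base))
  }
})

test_that("lca equals the leaf-to-root scan oracle on random lineage sets", {
  sim <- simulate_dataset(sim_config(seed = 21))
  lin <- sim$lineages
  ladder <- default_config()$taxonomy$rank_ladder
  accs <- unique(lin$accession)
  set.seed(22)
  for (i in 1:30) {
    subset <- sample(accs, sample(1:20, 1))
    got <- lca(lin, subset, ladder)
    want <- oracle_lca(lin, subset, ladder)
    expect_equal(got$taxon, want$taxon)
    expect_equal(got$rank, want$rank)
  }
})

test_that("the primate override coerces assignments to human", {
  lin <- dplyr::bind_rows(
    human_lineage("HUM_1"),
    make_lineage("MAC_1", superkingdom = "Eukaryota", phylum = "Chordata",
                 class = "Mammalia", order = "Primates",
                 parvorder = "Catarrhini", family = "Cercopithecidae",
                 genus = "Macaca", species = "Macaca mulatta"),
    make_lineage("BOS_1", superkingdom = "Eukaryota", phylum = "Chordata",
                 class = "Mammalia", order = "Artiodactyla",
                 family = "Bovidae", genus = "Bos", species = "Bos taurus"),
    strep_sanguinis()
  )
  groups <- make_groups(list(
    list(id = 1L, ids = c("HUM_1", "MAC_1"), counts = c(s1 = 2)),
    list(id = 2L, ids = c("BOS_1", "HUM_1"), counts = c(s1 = 2)),
    list(id = 3L, ids = "STR_SANG", counts = c(s1 = 2))
  ))
  peps <- dplyr::bind_rows(
    make_peptides("AK", leading = "HUM_1", proteins = "HUM_1;MAC_1"),
    make_peptides("CK", leading = "BOS_1", proteins = "BOS_1;HUM_1"),
    make_peptides("DK", leading = "STR_SANG", proteins = "STR_SANG")
  )
  asg <- assign_taxonomy(groups, peps, lin)

  # LCA of human + macaque is the parvorder -> coerced to Homo sapiens
  a1 <- dplyr::filter(asg, group_id == 1L)
  expect_equal(a1$lca_taxon, "Homo sapiens")
  expect_equal(a1$lca_rank, "species")
  expect_equal(a1$effective_stratum, "human")

  # other-stratum group containing a human accession -> human
  a2 <- dplyr::filter(asg, group_id == 2L)
  expect_equal(a2$effective_stratum, "human")

  # bacterial assignment untouched
  a3 <- dplyr::filter(asg, group_id == 3L)
  expect_equal(a3$lca_taxon, "Streptococcus sanguinis")
  expect_equal(a3$effective_stratum, "bacteria")
})

test_that("genus assignment rate counts genus-or-better bacterial groups", {
  asg <- dplyr::bind_rows(
    make_assignment(1L, "Streptococcus sanguinis", "species", "bacteria"),
    make_assignment(2L, "Streptococcus", "genus", "bacteria"),
    make_assignment(3L, "Neisseria", "genus", "bacteria"),
    make_assignment(4L, "Streptococcaceae", "family", "bacteria"),
    make_assignment(5L, "Homo sapiens", "species", "human")
  )
  expect_equal(genus_assignment_rate(asg), 0.75)
  all_species <- dplyr::filter(asg, lca_rank == "species",
                               effective_stratum == "bacteria")
  expect_equal(genus_assignment_rate(all_species), 1.0)
  expect_error(genus_assignment_rate(dplyr::filter(asg, group_id == 5L)),
               "undefined")
})

test_that("generator genus-resolvability carries through to the measured rate", {
  rates <- vapply(1:5, function(seed) {
    sim <- simulate_dataset(sim_config(seed = seed))
    asg <- assign_taxonomy(sim$protein_groups, sim$peptides, sim$lineages)
    genus_assignment_rate(asg)
  }, numeric(1))
  # 10% of accessions are genus-unresolvable; groups mixing a truncated and a
  # full lineage also stall above genus, so expect roughly 0.9
  expect_gt(mean(rates), 0.82)
  expect_lt(mean(rates), 0.95)
})
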