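two_sample_quant_fixture <- function() {
  groups <- make_groups(list(
    list(id = 1L, ids = "X1", counts = c(s1 = 3), lfq = c(s1 = 3e9)),
    list(id = 2L, ids = "Y1", counts = c(s1 = 3), lfq = c(s1 = 1e9)),
    list(id = 3L, ids = "U1", counts = c(s1 = 3), lfq = c(s1 = 1e9)),
    list(id = 4L, ids = "H1", counts = c(s1 = 3), lfq = c(s1 = 5e9))
  ))
  strep_path <- tibble::tibble(
    rank = c("superkingdom", "genus"), taxon = c("Bacteria", "GenusX"))
  neis_path <- tibble::tibble(
    rank = c("superkingdom", "genus", "species"),
    taxon = c("Bacteria", "GenusY", "GenusY speciesis"))
  fam_path <- tibble::tibble(
    rank = c("superkingdom", "family"), taxon = c("Bacteria", "FamilyU"))
  asg <- dplyr::bind_rows(
    make_assignment(1L, "GenusX", "genus", "bacteria", strep_path),
    make_assignment(2L, "GenusY speciesis", "species", "bacteria", neis_path),
    make_assignment(3L, "FamilyU", "family", "bacteria", fam_path),
    make_assignment(4L, "Homo sapiens", "species", "human")
  )
  list(groups = groups, asg = asg)
}

test_that("genus fractions divide genus sums by total bacterial intensity", {
  fx <- two_sample_quant_fixture()
  gf <- genus_fractions(fx$groups, fx$asg)
  x <- dplyr::filter(gf, genus == "GenusX")
  y <- dplyr::filter(gf, genus == "GenusY")  # species rolled up to genus
  expect_equal(x$fraction, 0.6)
  expect_equal(y$fraction, 0.2)
  expect_false("FamilyU" %in% gf$genus)
  una <- attr(gf, "unassigned")
  expect_equal(una$unassigned_fraction, 0.2)
  # the human group's 5e9 must not appear anywhere
  expect_equal(una$total_bacterial_lfq, 5e9)
})

test_that("fractions are scale-invariant per sample and conserve mass", {
  sim <- simulate_dataset(sim_config(seed = 17))
  asg <- assign_taxonomy(sim$protein_groups, sim$peptides, sim$lineages)
  gf <- genus_fractions(sim$protein_groups, asg)

  sums <- dplyr::summarise(tibble::as_tibble(gf),
                           s = sum(fraction), .by = raw_file)
  una <- attr(gf, "unassigned")
  total <- sums$s + una$unassigned_fraction[match(sums$raw_file,
                                                  una$raw_file)]
  expect_true(all(abs(total - 1) < 1e-9))

  scaled <- sim$protein_groups |>
    dplyr::mutate(lfq = ifelse(raw_file == "sample_01", lfq * 7.5, lfq))
  gf2 <- genus_fractions(scaled, asg)
  s1 <- dplyr::filter(tibble::as_tibble(gf), raw_file == "sample_01")
  s2 <- dplyr::filter(tibble::as_tibble(gf2), raw_file == "sample_01")
  expect_equal(dplyr::arrange(s2, genus)$fraction,
               dplyr::arrange(s1, genus)$fraction)
})

test_that("recovered fractions approach ground truth as LFQ noise shrinks", {
  mae <- function(noise_sd) {
    sim <- simulate_dataset(sim_config(seed = 31, lfq_log2_sd = noise_sd,
                                       missing_rate = 0,
                                       genus_unresolvable_fraction = 0))
    gf <- sim_fractions(sim)
    joined <- dplyr::inner_join(tibble::as_tibble(gf),
                                sim$truth$genus_fractions,
                                by = c("raw_file", "genus"),
                                suffix = c("_est", "_true"))
    median(abs(joined$fraction_est - joined$fraction_true))
  }
  expect_lt(mae(0.05), mae(1.5))
  expect_lt(mae(0.05), 0.02)
})

test_that("log2 median normalization centers each sample at zero", {
  m <- matrix(c(4, 16, 8, NA), nrow = 2,
              dimnames = list(NULL, c("s1", "s2")))
  norm <- log2_median_normalize(m)
  expect_equal(unname(norm[, "s1"]), c(-1, 1))
  expect_true(is.na(norm[2, "s2"]))
  expect_equal(unname(norm[1, "s2"]), 0)

  sim <- simulate_dataset(sim_config(seed = 2))
  big <- log2_median_normalize(lfq_matrix(sim$protein_groups))
  meds <- apply(big, 2, median, na.rm = TRUE)
  expect_true(all(abs(meds) < 1e-12))

  all_na <- matrix(NA_real_, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_true(all(is.na(log2_median_normalize(all_na))))
  expect_error(log2_median_normalize(matrix(c(-1, 2), 1)),
               "strictly positive")
})

test_that("min-half filter keeps rows present in at least ceil(n/2) samples", {
  m <- matrix(NA_real_, nrow = 3, ncol = 22,
              dimnames = list(c("r10", "r11", "r22"), sprintf("s%02d", 1:22)))
  m["r10", 1:10] <- 1
  m["r11", 1:11] <- 1
  m["r22", ] <- 1
  out <- min_half_filter(m)
  expect_setequal(rownames(out), c("r11", "r22"))  # threshold 11 of 22

  m7 <- matrix(NA_real_, nrow = 2, ncol = 7,
               dimnames = list(c("r3", "r4"), sprintf("s%d", 1:7)))
  m7["r3", 1:3] <- 1
  m7["r4", 1:4] <- 1
  expect_equal(rownames(min_half_filter(m7)), "r4")  # ceil(7/2) = 4
  expect_error(min_half_filter(m7, character(0)), "nonempty")
})
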