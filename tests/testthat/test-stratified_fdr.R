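test_that("stratum splitting is a conservative partition", {
  peps <- make_peptides(c("AK", "BK", "CK"),
                        stratum = c("human", "bacteria", "bacteria"))
  parts <- split_by_stratum(peps)
  expect_equal(vapply(parts, nrow, integer(1)),
               c(human = 1L, bacteria = 2L, other = 0L))

  empty <- split_by_stratum(peps[0, ])
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))

  expect_error(split_by_stratum(make_peptides("AK", stratum = "fungi")),
               "unknown stratum")

  sim <- simulate_dataset(sim_config(seed = 3))
  parts <- split_by_stratum(sim$peptides)
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(sim$peptides))
  expect_equal(dplyr::bind_rows(parts) |> dplyr::arrange(psm_id),
               dplyr::arrange(sim$peptides, psm_id))
})

test_that("accumulation acceptance handles the canonical cases", {
  # no decoys: everything is accepted, estimated FDR 0
  fwd <- make_peptides(sprintf("P%03dK", 1:200), score = 200:1)
  res <- accept_at_fdr(fwd, q = 0.01)
  expect_equal(res$summary$n_forward_accepted, 200L)
  expect_equal(res$summary$estimated_fdr, 0)

  # decoys at ranks 10 and 120 of 200 distinct scores: the longest prefix
  # with reverse/forward <= 1% stops just before the second decoy
  leading <- rep("ACC1", 200); leading[c(10, 120)] <- "REV__X"
  mixed <- make_peptides(sprintf("P%03dK", 1:200), score = 200:1,
                         leading = leading)
  res <- accept_at_fdr(mixed, q = 0.01)
  expect_equal(res$summary$n_forward_accepted, 118L)
  expect_equal(res$summary$n_reverse_in_prefix, 1L)
  expect_equal(res$summary$estimated_fdr, 1 / 118, tolerance = 1e-12)
  expect_false(any(res$accepted$is_decoy))

  # all-decoy input: nothing accepted, no error
  dec <- make_peptides(c("AK", "CK"), score = c(9, 8), leading = "REV__X")
  expect_equal(accept_at_fdr(dec, 0.01)$summary$n_forward_accepted, 0L)

  expect_error(accept_at_fdr(fwd, q = 0), "between 0 and 1")
  expect_error(accept_at_fdr(fwd, q = 1.2), "between 0 and 1")
})

test_that("records tied at the boundary score move as a block", {
  # scores: 10 (fwd), 9 9 9 (fwd, fwd, decoy)
  peps <- make_peptides(sprintf("P%dK", 1:4), score = c(10, 9, 9, 9),
                        leading = c("A", "A", "A", "REV__X"))
  # at q = 0.4 the 9-block qualifies as a whole (1 rev / 3 fwd)
  res <- accept_at_fdr(peps, q = 0.4)
  expect_equal(res$summary$n_forward_accepted, 3L)
  expect_equal(res$summary$cutoff_score, 9)
  # at q = 0.3 the 9-block fails as a whole (1/3 > 0.3); it is never split
  # even though its first two members alone would qualify
  res <- accept_at_fdr(peps, q = 0.3)
  expect_equal(res$summary$n_forward_accepted, 1L)
  expect_equal(res$summary$cutoff_score, 10)
  # ...and a later qualifying prefix can resume past a failing block
  resumed <- dplyr::bind_rows(peps,
                              make_peptides(sprintf("Q%dK", 1:4),
                                            score = c(8, 7, 6, 5),
                                            leading = "A"))
  res <- accept_at_fdr(resumed, q = 0.2)
  expect_equal(res$summary$n_forward_accepted, 7L)
  expect_equal(res$summary$cutoff_score, 5)
})

test_that("acceptance equals the exhaustive prefix-scan oracle", {
  set.seed(401)
  for (rep in 1:25) {
    n <- sample(10:500, 1)
    scores <- round(runif(n, 0, 100), sample(c(0, 1, 3), 1))  # induce ties
    decoy <- runif(n) < runif(1, 0.05, 0.5)
    q <- sample(c(0.01, 0.05, 0.2), 1)
    leading <- ifelse(decoy, "REV__X", "ACC1")
    peps <- make_peptides(sprintf("P%04dK", seq_len(n)), score = scores,
                          leading = leading)
    got <- accept_at_fdr(peps, q)$summary
    want <- oracle_accept(scores, decoy, q)
    expect_equal(got$n_forward_accepted, want$n_forward)
    expect_equal(got$n_reverse_in_prefix, want$n_reverse)
    expect_equal(got$cutoff_score, want$cutoff)
  }
})

test_that("accepted counts are monotone in q and curves behave", {
  fwd <- make_peptides("AK", score = 5)
  expect_equal(estimated_fdr_curve(fwd, c(0.001, 0.5))$n_accepted, c(1L, 1L))
  expect_error(estimated_fdr_curve(fwd, numeric(0)), "nonempty")

  sim <- simulate_dataset(sim_config(seed = 5))
  bact <- dplyr::filter(sim$peptides, stratum == "bacteria")
  curve <- estimated_fdr_curve(bact, c(0.001, 0.01, 0.05, 0.2))
  expect_true(all(diff(curve$n_accepted) >= 0))
  # each grid point matches an individual call
  for (i in seq_len(nrow(curve))) {
    expect_equal(curve$n_accepted[i],
                 accept_at_fdr(bact, curve$q[i])$summary$n_forward_accepted)
  }
})

test_that("realized false-accept fraction is of the order of q", {
  q <- 0.01
  fdp <- vapply(1:20, function(seed) {
    sim <- simulate_dataset(sim_config(seed = seed))
    bact <- dplyr::filter(sim$peptides, stratum == "bacteria")
    res <- accept_at_fdr(bact, q)
    status <- sim$truth$psm_status
    acc_status <- status$status[match(res$accepted$psm_id, status$psm_id)]
    mean(acc_status == "false")
  }, numeric(1))
  expect_lt(mean(fdp), 2.5 * q)
  expect_gt(mean(fdp), 0)  # decoy model does generate false accepts
})
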