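# brute-force inclusion-exclusion: sum over all non-empty subsets
brute_force_pg <- function(p) {
  n <- length(p)
  total <- 0
  for (mask in seq_len(2^n - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    total <- total + (-1)^(length(s) - 1) * prod(p[s])
  }
  total
}

test_that("complement product equals the inclusion-exclusion expansion", {
  expect_equal(fraction_genomes(0.3), 0.3)
  expect_equal(fraction_genomes(c(0.1, 0.2)), 0.28)
  expect_equal(fraction_genomes(c(0.1, 0.2)), 0.1 + 0.2 - 0.02)
  expect_equal(fraction_genomes(numeric(0)), 0)

  set.seed(8)
  for (n in c(3, 8, 12)) {
    p <- runif(n, 0.001, 0.3)
    expect_equal(fraction_genomes(p), brute_force_pg(p), tolerance = 1e-12)
  }
  expect_error(fraction_genomes(c(0.2, 1.2)), "0, 1")
})

test_that("P(G) is order-invariant, monotone and bounded", {
  set.seed(5)
  p <- runif(10, 0.001, 0.2)
  expect_equal(fraction_genomes(p), fraction_genomes(rev(p)))
  expect_equal(fraction_genomes(p), fraction_genomes(sample(p)))
  partial <- vapply(seq_along(p),
                    function(k) fraction_genomes(p[1:k]), numeric(1))
  expect_true(all(diff(partial) >= 0))
  expect_lte(fraction_genomes(p), min(1, sum(p)))
})

test_that("cell fractions follow the ploidy assumptions", {
  expect_equal(fraction_cells(0.004, "two_hit"), 0.004)
  expect_equal(fraction_cells(0.004, "one_hit"), 0.008)
  expect_equal(fraction_cells(0.6, "one_hit"), 1)
  expect_equal(fraction_cells(0.004, "hemizygous_male_X"), 0.004)
})

test_that("half-up rounding drives driver counts", {
  expect_equal(round_half_up(c(0.4, 0.5, 1.5, 2.5, -0.5)),
               c(0L, 1L, 2L, 3L, -1L))
})

test_that("driver selection takes the top-VAF mutations deterministically", {
  sel <- tibble::tibble(
    gene = "G", mclass = c("missense", "truncating"), scope = "S1",
    observed = c(5L, 3L), expected = c(3, 1),
    dnds = c(5 / 3, 3), ci_low = c(0.8, 0.9), ci_high = c(3, 7),
    p_value = 0.1, driver_excess = c(2, 2), driver_fraction = 0.5
  )
  muts <- tibble::tibble(
    sample_id = "S1", donor_id = "D1", chrom = "c",
    pos = c(5L, 9L, 2L, 7L, 1L),
    ref = "A", alt = "T", mut_type = "SNV",
    vaf_duplex = c(.01, .03, .02, .03, .005),
    vaf_all_molecules = c(.01, .03, .02, .03, .005),
    gene = "G",
    consequence = c("missense", "missense", "nonsense", "missense",
                    "essential_splice"),
    protein_pos = NA_integer_
  )
  drv <- select_drivers(muts, sel, "G", "S1")
  expect_equal(attr(drv, "n_expected"), 4L)
  expect_equal(nrow(drv), 4)
  # top VAF 0.03 tie broken by ascending position: pos 7 before pos 9
  expect_equal(drv$pos[1:2], c(7L, 9L))
  # stable under shuffling of input rows
  set.seed(2)
  drv2 <- select_drivers(muts[sample(5), ], sel, "G", "S1")
  expect_equal(drv2$pos, drv$pos)

  # zero excess -> empty set
  sel0 <- dplyr::mutate(sel, driver_excess = 0, ci_low = 1, ci_high = 1,
                        dnds = 1)
  expect_equal(nrow(select_drivers(muts, sel0, "G", "S1")), 0)

  # excess above available mutations is capped and flagged
  sel_big <- dplyr::mutate(sel, driver_excess = 10)
  drv_big <- select_drivers(muts, sel_big, "G", "S1")
  expect_equal(nrow(drv_big), 5)
  expect_true(attr(drv_big, "capped"))
})

test_that("estimated genome fractions track planted clones of known size", {
  # plant driver clones of known fraction w in the detectable range, measure
  # their VAF as sampled molecules / depth, and compare estimated P(G) with
  # the true clone mass across 30 samples (driver counts given as correct)
  set.seed(77)
  d <- 3000
  samples <- sprintf("S%02d", 1:30)
  rows <- purrr::map_dfr(samples, function(s) {
    n_drv <- sample(2:6, 1)
    w <- exp(runif(n_drv, log(0.002), log(0.2)))
    k <- rbinom(n_drv, d, w)
    k[k == 0] <- 1
    tibble::tibble(
      sample_id = s, donor_id = s, chrom = "c",
      pos = seq_len(n_drv) * 10L, ref = "A", alt = "T", mut_type = "SNV",
      vaf_duplex = k / d, vaf_all_molecules = k / d, gene = "G",
      consequence = "missense", protein_pos = NA_integer_, w_truth = w
    )
  })
  sel <- purrr::map_dfr(samples, function(s) {
    n <- sum(rows$sample_id == s)
    tibble::tibble(gene = "G", mclass = "missense", scope = s,
                   observed = n, expected = 1e-9, dnds = n / 1e-9,
                   ci_low = n / 1e-9, ci_high = n / 1e-9, p_value = 0,
                   driver_excess = n, driver_fraction = 1)
  })
  cf <- clone_fractions(rows, sel, genes = "G", samples = samples)
  truth <- purrr::map_dbl(samples, function(s) {
    fraction_genomes(pmin(rows$w_truth[rows$sample_id == s], 1))
  })
  expect_equal(cf$n_drivers_selected,
               as.integer(table(rows$sample_id)[cf$sample_id]),
               ignore_attr = TRUE)
  expect_gt(cor(cf$fraction_genomes, truth), 0.9)
})

test_that("end-to-end clone fractions are well-formed on a synthetic cohort", {
  co <- shared_cohort()
  ps <- per_sample_omega(co$mutations, co$panel, co$depth,
                         exclude = co$whitelist)
  cf <- clone_fractions(co$mutations, ps$results, genes = "POSGENE")
  expect_true(all(cf$fraction_genomes >= 0 & cf$fraction_genomes <= 1))
  expect_true(all(cf$fraction_low <= cf$fraction_high + 1e-12))
  expect_true(all(cf$fraction_cells == cf$fraction_genomes))  # two-hit default
  # positively selected gene: most samples carry at least one driver
  expect_gt(mean(cf$n_drivers_selected > 0), 0.8)
  # the latent truth is positively associated with the estimate
  truth <- purrr::map_dbl(cf$sample_id, function(s) {
    drv <- select_drivers(co$mutations, ps$results, "POSGENE", s)
    fraction_genomes(pmin(drv$w_truth, 1))
  })
  expect_gt(cor(cf$fraction_genomes, truth, method = "spearman"), 0.3)
})
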