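uniform_spectrum <- function(rate) {
  spec <- tibble::tibble(
    channel = all_channels(), count = 1L, opportunity = 1 / rate,
    rate = rate, probability = 1 / 96
  )
  class(spec) <- c("trinuc_spectrum", class(spec))
  spec
}

test_that("expected counts follow the closed form under uniform rate and depth", {
  panel <- tiny_panel("+")
  r <- 2e-5
  d <- 300
  spec <- uniform_spectrum(r)
  depth <- panel$sites[, c("chrom", "pos")]
  depth$S1 <- d
  ec <- expected_counts(panel, tibble::as_tibble(depth), spec, "TINY")
  sa <- panel$site_alts
  n_mis <- sum(sa$consequence == "missense")
  n_trunc <- sum(sa$consequence %in% c("nonsense", "essential_splice"))
  expect_equal(ec$expected[ec$mclass == "missense"], r * d * n_mis)
  expect_equal(ec$expected[ec$mclass == "truncating"], r * d * n_trunc)

  # doubling depth doubles every expectation
  depth2 <- depth
  depth2$S1 <- 2 * d
  ec2 <- expected_counts(panel, tibble::as_tibble(depth2), spec, "TINY")
  expect_equal(ec2$expected, 2 * ec$expected)

  # absent gene is fatal
  expect_error(expected_counts(panel, tibble::as_tibble(depth), spec, "NOPE"),
               "absent")
})

test_that("cohort expectation equals the sum of per-sample expectations", {
  co <- shared_cohort()
  spec <- shared_spectrum()
  genes <- unique(co$config$genes$gene)
  coh <- expected_counts(co$panel, co$depth, spec, genes)
  samples <- setdiff(names(co$depth), c("chrom", "pos"))
  per <- purrr::map(samples, function(s) {
    expected_counts(co$panel, co$depth, spec, genes, scope = s)$expected
  })
  tot <- Reduce(`+`, per)
  expect_equal(tot, coh$expected, tolerance = 1e-9)
})

test_that("dN/dS arithmetic, CI and p-value match the Poisson contract", {
  row <- deepdnds:::selection_row("G", "missense", "cohort", 20, 2)
  expect_equal(row$dnds, 10)
  expect_equal(row$driver_excess, 18)
  expect_equal(row$driver_fraction, 0.9)
  expect_equal(row$ci_low, qgamma(0.025, 20) / 2)
  expect_equal(row$ci_high, qgamma(0.975, 21) / 2)
  expect_equal(row$p_value,
               min(1, 2 * min(ppois(20, 2), 1 - ppois(19, 2))))
  expect_true(row$ci_low <= row$dnds && row$dnds <= row$ci_high)

  # zero observed: negative-selection direction, dnds 0
  row0 <- deepdnds:::selection_row("G", "truncating", "cohort", 0, 2)
  expect_equal(row0$dnds, 0)
  expect_equal(row0$ci_low, 0)
  expect_equal(row0$driver_excess, 0)

  # zero expectation: suppressed with NA statistics
  rowe <- deepdnds:::selection_row("G", "missense", "cohort", 3, 0)
  expect_true(is.na(rowe$dnds))
})

test_that("injected selection coefficients are recovered on a synthetic cohort", {
  co <- shared_cohort()
  om <- fit_omega(co$mutations, co$panel, co$depth,
                  spectrum = shared_spectrum())
  res <- tidy(om)
  pos_tr <- res[res$gene == "POSGENE" & res$mclass == "truncating", ]
  neg_tr <- res[res$gene == "NEGGENE" & res$mclass == "truncating", ]
  neu_mis <- res[res$gene == "NEUGENE" & res$mclass == "missense", ]
  expect_gt(pos_tr$dnds, 5)
  expect_lt(pos_tr$p_value, 1e-6)
  expect_lt(neg_tr$dnds, 1)
  expect_gt(neu_mis$ci_high, 1)
  expect_lt(neu_mis$ci_low, 1.3)
})

test_that("promoter activation selection calibrates on non-activating sites", {
  co <- shared_cohort()
  pt <- dnds_ptert(co$mutations, co$panel, co$depth, co$whitelist,
                   spectrum = shared_spectrum())
  expect_equal(pt$mclass, "activating_pTERT")
  expect_gt(pt$dnds, 1)
  expect_lt(pt$p_value, 0.05)

  # empty whitelist is fatal
  expect_error(dnds_ptert(co$mutations, co$panel, co$depth,
                          co$whitelist[0, ]), "empty")
  # whitelist outside the promoter is fatal
  bad <- co$whitelist
  bad$pos <- bad$pos + 10000L
  expect_error(dnds_ptert(co$mutations, co$panel, co$depth, bad), "outside")
})

test_that("whitelist with no observed hits yields dnds 0", {
  co <- shared_cohort()
  m_key <- paste(co$mutations$chrom, co$mutations$pos, co$mutations$alt)
  prom <- co$panel$site_alts[co$panel$site_alts$region_class == "promoter", ]
  free <- prom[!(paste(prom$chrom, prom$pos, prom$alt) %in% m_key), ]
  wl <- free[1:4, c("chrom", "pos", "alt")]
  pt <- dnds_ptert(co$mutations, co$panel, co$depth, wl,
                   spectrum = shared_spectrum())
  expect_equal(pt$observed, 0L)
  expect_equal(pt$dnds, 0)
})

test_that("frameshift-indel enrichment uses a leave-one-out background", {
  co <- shared_cohort()
  ie <- indel_enrichment(co$mutations, co$panel, co$depth)
  expect_setequal(ie$gene, co$config$genes$gene)
  pos <- ie[ie$gene == "POSGENE", ]
  expect_gt(pos$dnds, 1)
  # upper-tail Poisson p
  expect_equal(pos$p_value,
               1 - ppois(pos$observed - 1, pos$expected))

  # leave-one-out: adding indels to a gene raises its observed count but
  # leaves its own expectation untouched (it never enters its own background)
  fs_sites <- co$panel$sites[co$panel$sites$gene == "NEUGENE" &
                               co$panel$sites$region_class == "coding", ]
  extra <- tibble::tibble(
    sample_id = co$covariates$sample_id[1], donor_id = "D01",
    chrom = fs_sites$chrom[1:5], pos = fs_sites$pos[1:5],
    ref = "AT", alt = "A", mut_type = "deletion",
    vaf_duplex = 0.001, vaf_all_molecules = 0.001, gene = "NEUGENE",
    consequence = "frameshift_indel", protein_pos = NA_integer_,
    w_truth = NA_real_
  )
  ie2 <- indel_enrichment(dplyr::bind_rows(co$mutations, extra),
                          co$panel, co$depth)
  neu1 <- ie[ie$gene == "NEUGENE", ]
  neu2 <- ie2[ie2$gene == "NEUGENE", ]
  expect_equal(neu2$observed, neu1$observed + 5L)
  expect_equal(neu2$expected, neu1$expected, tolerance = 1e-12)
  expect_gt(neu2$dnds, neu1$dnds)
  # every other gene's background (hence expectation) grows
  other1 <- ie[ie$gene != "NEUGENE", ]
  other2 <- ie2[ie2$gene != "NEUGENE", ]
  expect_true(all(other2$expected > other1$expected))
})

test_that("hand-computed indel example: obs 8, E 1", {
  row <- deepdnds:::selection_row("G", "frameshift_indel", "cohort", 8, 1)
  expect_equal(row$dnds, 8)
  expect_equal(deepdnds::poisson_p_upper(8, 1), 1 - ppois(7, 1))
})

test_that("eligibility boundary flips exactly at the 80% rule", {
  expect_false(eligible_column(63, 79))
  expect_true(eligible_column(64, 79))
  expect_true(eligible_column(80, 100))
  expect_false(eligible_column(79, 100))
})

test_that("per-sample matrix marks zero-depth samples missing and flags eligibility", {
  co <- shared_cohort()
  depth <- co$depth
  samples <- setdiff(names(depth), c("chrom", "pos"))
  # zero out one sample's depth on POSGENE
  s0 <- samples[1]
  pos_sites <- co$panel$sites$gene == "POSGENE"
  key <- paste(co$panel$sites$chrom, co$panel$sites$pos)[pos_sites]
  hit <- paste(depth$chrom, depth$pos) %in% key
  depth[[s0]][hit] <- 0
  muts <- co$mutations[!(co$mutations$sample_id == s0 &
                           co$mutations$gene == "POSGENE"), ]
  ps <- per_sample_omega(muts, co$panel, depth, exclude = co$whitelist)
  row <- ps$results[ps$results$gene == "POSGENE" & ps$results$scope == s0, ]
  expect_true(all(is.na(row$dnds)))
  el <- ps$eligibility
  n <- length(samples)
  expect_equal(el$n_non_missing[el$gene == "POSGENE" &
                                  el$mclass == "missense"], n - 1L)
  expect_equal(el$eligible, el$n_non_missing / el$n_samples >= 0.8)
})
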