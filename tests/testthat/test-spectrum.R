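# a minimal hand-built scenario: one gene, uniform depth, catalog placed on
# known channels
uniform_depth <- function(panel, d, samples = c("S1", "S2")) {
  out <- panel$sites[, c("chrom", "pos")]
  for (s in samples) out[[s]] <- d
  tibble::as_tibble(out)
}

test_that("single-channel toy rate: count over opportunity", {
  panel <- tiny_panel("+")
  depth <- uniform_depth(panel, 500, "S1")
  sa <- panel$site_alts
  syn <- sa[sa$consequence == "synonymous", ]
  ch <- syn$channel[1]
  picks <- syn[syn$channel == ch, ][1, ]
  muts <- tibble::tibble(
    sample_id = "S1", donor_id = "D1", chrom = picks$chrom,
    pos = picks$pos, ref = picks$ref, alt = picks$alt, mut_type = "SNV",
    vaf_duplex = 0.002, vaf_all_molecules = 0.002, gene = picks$gene,
    consequence = picks$consequence, protein_pos = picks$protein_pos
  )[rep(1, 10), ]
  spec <- fit_neutral_spectrum(muts, panel, depth,
                               neutral_classes = "synonymous",
                               pseudocount = 0)
  row <- spec[spec$channel == ch, ]
  n_sites_ch <- sum(sa$consequence == "synonymous" & sa$channel == ch)
  expect_equal(row$count, 10L)
  expect_equal(row$opportunity, n_sites_ch * 500)
  expect_equal(row$rate, 10 / (n_sites_ch * 500))
})

test_that("counts proportional to opportunity give a uniform probability vector", {
  panel <- tiny_panel("+")
  depth <- uniform_depth(panel, 100, "S1")
  sa <- panel$site_alts[panel$site_alts$consequence == "noncoding", ]
  # one mutation per noncoding (site, alt): counts exactly proportional to
  # uniform-depth opportunity in every occupied channel
  muts <- tibble::tibble(
    sample_id = "S1", donor_id = "D1", chrom = sa$chrom, pos = sa$pos,
    ref = sa$ref, alt = sa$alt, mut_type = "SNV",
    vaf_duplex = 0.01, vaf_all_molecules = 0.01, gene = sa$gene,
    consequence = sa$consequence, protein_pos = NA_integer_
  )
  spec <- fit_neutral_spectrum(muts, panel, depth,
                               neutral_classes = "noncoding", pseudocount = 0)
  occupied <- spec[spec$opportunity > 0 & spec$count > 0, ]
  expect_true(all(abs(occupied$rate - occupied$rate[1]) < 1e-12))
})

test_that("fitted spectrum recovers the generating mixture (total variation)", {
  # wide non-coding flanks give > 5,000 neutral mutations; a fixed mixture
  # (no age loading) makes the generating channel distribution exactly known
  genes <- test_gene_table()
  genes$cds_length <- 1500
  genes$omega_missense <- 1
  genes$omega_truncating <- 1
  genes$omega_indel <- 1
  genes <- dplyr::bind_rows(genes, dplyr::mutate(genes[1, ], gene = "GENE4"))
  cfg <- scaled_config(seed = 31, genes = genes, flank_length = 2500,
                       n_donors = 45,
                       covariate_effects = no_covariate_effects(),
                       ageing_age_slope = 0, density_age_beta = 0,
                       selection_frailty_sd = 0)
  co <- generate_cohort(cfg)
  spec <- fit_neutral_spectrum(co$mutations, co$panel, co$depth,
                               exclude = co$whitelist)
  expect_gt(sum(spec$count), 5000)
  profiles <- deepdnds:::signature_profiles()
  w <- cfg$signature_weights / sum(cfg$signature_weights)
  mix <- as.numeric(profiles %*% w)
  names(mix) <- rownames(profiles)
  # generator probability of a neutral mutation landing in channel c is
  # mix_c x opportunity_c (up to scale)
  p_true <- mix[spec$channel] * spec$opportunity
  p_true <- p_true / sum(p_true)
  p_fit <- spec$count / sum(spec$count)
  tv <- 0.5 * sum(abs(p_true - p_fit))
  expect_lt(tv, 0.05)
})

test_that("zero neutral mutations is fatal with guidance", {
  panel <- tiny_panel("+")
  depth <- uniform_depth(panel, 100, "S1")
  muts <- tibble::tibble(
    sample_id = character(), donor_id = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    mut_type = character(), vaf_duplex = numeric(),
    vaf_all_molecules = numeric(), gene = character(),
    consequence = character(), protein_pos = integer()
  )
  expect_error(fit_neutral_spectrum(muts, panel, depth),
               "widen `neutral_classes`")
})

test_that("genome-composition correction conserves totals and matches hand arithmetic", {
  spec <- shared_spectrum()
  gcomp <- tibble::tibble(trinuc = all_trinucs(), count = 1000L)
  corr <- correct_to_genome(spec, gcomp, total_observed = 4321)
  expect_equal(sum(corr$corrected_count), 4321, tolerance = 1e-9)

  # two-channel hand oracle: rates (1e-5, 1e-5), genome counts (100, 300),
  # total 40 -> corrected (10, 30)
  toy <- tibble::tibble(channel = c("A[C>A]A", "A[C>G]C"),
                        count = c(5L, 5L), opportunity = c(5e5, 5e5),
                        rate = c(1e-5, 1e-5), probability = c(0.5, 0.5))
  class(toy) <- c("trinuc_spectrum", class(toy))
  gc2 <- tibble::tibble(trinuc = all_trinucs(), count = 1L)
  gc2$count[gc2$trinuc == "ACA"] <- 100L
  gc2$count[gc2$trinuc == "ACC"] <- 300L
  corr2 <- correct_to_genome(toy, gc2, 40)
  expect_equal(corr2$corrected_count, c(10, 30))

  # panel trinucleotide composition exactly proportional to the genome's
  # (promoter-only panel, uniform depth) -> corrected counts == observed
  set.seed(14)
  seq <- paste0("AA", paste0(sample(c("A", "C", "G", "T"), 400,
                                    replace = TRUE), collapse = ""), "AA")
  reg <- tibble::tibble(chrom = "chr_U", start = 2L, end = 402L, gene = "U",
                        region_class = "promoter", strand = "+",
                        frame_anchor = NA_integer_)
  up <- build_panel(reg, c(chr_U = seq))
  du <- uniform_depth(up, 50, "S1")
  sa_u <- up$site_alts
  pick <- sa_u[sample(nrow(sa_u), 200, replace = TRUE), ]
  mu <- tibble::tibble(
    sample_id = "S1", donor_id = "D1", chrom = pick$chrom, pos = pick$pos,
    ref = pick$ref, alt = pick$alt, mut_type = "SNV",
    vaf_duplex = 0.02, vaf_all_molecules = 0.02, gene = pick$gene,
    consequence = "noncoding", protein_pos = NA_integer_
  )
  spec_u <- fit_neutral_spectrum(mu, up, du, neutral_classes = "noncoding",
                                 pseudocount = 0)
  tri_counts <- table(up$sites$trinuc[!up$sites$excluded])
  gprop <- tibble::tibble(trinuc = all_trinucs(), count = 1e-6)
  gprop$count[match(names(tri_counts), gprop$trinuc)] <- as.numeric(tri_counts)
  corr3 <- correct_to_genome(spec_u, gprop, sum(spec_u$count))
  expect_equal(corr3$corrected_count[spec_u$opportunity > 0 &
                                       spec_u$count > 0],
               spec_u$count[spec_u$opportunity > 0 & spec_u$count > 0],
               tolerance = 1e-9)
})

test_that("probability vectors are scale-invariant in depth", {
  co <- shared_cohort()
  spec1 <- shared_spectrum()
  depth2 <- co$depth
  for (s in setdiff(names(depth2), c("chrom", "pos"))) {
    depth2[[s]] <- depth2[[s]] * 7
  }
  spec2 <- fit_neutral_spectrum(co$mutations, co$panel, depth2,
                                exclude = co$whitelist)
  expect_equal(spec2$probability, spec1$probability, tolerance = 1e-12)
  expect_equal(sum(spec1$probability, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("the shipped synthetic genome composition is usable", {
  path <- system.file("extdata", "genome_trinuc_synthetic.tsv",
                      package = "deepdnds")
  gcomp <- read_genome_composition(path)
  expect_setequal(gcomp$trinuc, all_trinucs())
  expect_true(all(gcomp$count > 0))
  corr <- correct_to_genome(shared_spectrum(), gcomp, 1000)
  expect_equal(sum(corr$corrected_count), 1000, tolerance = 1e-9)
})
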