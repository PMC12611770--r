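make_raw <- function(panel, n = 6, sample_id = "S1") {
  sa <- panel$site_alts[panel$site_alts$region_class == "coding", ]
  pick <- sa[unique(round(seq(1, nrow(sa), length.out = n))), ]
  tibble::tibble(
    sample_id = sample_id, donor_id = "D1",
    chrom = pick$chrom, pos = pick$pos, ref = pick$ref, alt = pick$alt,
    mut_type = "SNV", vaf_duplex = 0.01, vaf_all_molecules = 0.01
  )
}

test_that("annotation fills consequence from the panel and rejects bad rows", {
  panel <- tiny_panel("+")
  raw <- make_raw(panel, 9)
  # one out-of-panel row and one invalid VAF
  raw$pos[1] <- 1000L
  raw$vaf_duplex[2] <- 0
  ann <- suppressMessages(annotate_mutations(raw, panel))
  expect_equal(nrow(ann), 7)
  expect_equal(attr(ann, "n_rejected"), 2)
  idx <- match(paste(ann$pos, ann$alt),
               paste(panel$site_alts$pos, panel$site_alts$alt))
  expect_equal(ann$consequence, panel$site_alts$consequence[idx])
  expect_equal(ann$protein_pos, panel$site_alts$protein_pos[idx])
})

test_that("unknown sample ids are fatal when a sample list is supplied", {
  panel <- tiny_panel("+")
  raw <- make_raw(panel, 3, sample_id = "GHOST")
  expect_error(annotate_mutations(raw, panel, samples = c("S1", "S2")),
               "unknown sample")
})

test_that("indels follow the mod-3 rule inside coding regions", {
  panel <- tiny_panel("+")
  raw <- tibble::tibble(
    sample_id = "S1", donor_id = "D1", chrom = "chr_T",
    pos = c(15L, 15L, 4L),
    ref = c("TGC", "TGCG", "ACG"),
    alt = c("T", "T", "A"),
    mut_type = NA_character_,
    vaf_duplex = 0.01, vaf_all_molecules = 0.01
  )
  ann <- annotate_mutations(raw, panel)
  expect_equal(ann$mut_type, c("deletion", "deletion", "deletion"))
  expect_equal(ann$consequence,
               c("frameshift_indel", "inframe_indel", "noncoding"))
})

test_that("MNVs take the worst constituent consequence", {
  panel <- tiny_panel("+")
  sa <- panel$site_alts
  # any nonsense alt with a coding neighbour: the MNV must inherit the worst
  non <- sa[sa$consequence == "nonsense" & sa$pos < max(sa$pos), ][1, ]
  neighbour <- sa[sa$pos == non$pos + 1, ][1, ]
  ref2 <- paste0(non$ref, neighbour$ref)
  alt2 <- paste0(non$alt, neighbour$alt)
  raw <- tibble::tibble(
    sample_id = "S1", donor_id = "D1", chrom = "chr_T", pos = non$pos,
    ref = ref2, alt = alt2, mut_type = "MNV",
    vaf_duplex = 0.01, vaf_all_molecules = 0.01
  )
  ann <- annotate_mutations(raw, panel)
  expect_equal(ann$consequence, "nonsense")
  # a purely synonymous pair stays synonymous
  syn <- sa[sa$consequence == "synonymous", ]
  adj <- syn[match(syn$pos + 1, syn$pos), ]
  ok <- which(!is.na(adj$pos))[1]
  skip_if(is.na(ok))
  raw2 <- tibble::tibble(
    sample_id = "S1", donor_id = "D1", chrom = "chr_T", pos = syn$pos[ok],
    ref = paste0(syn$ref[ok], adj$ref[ok]),
    alt = paste0(syn$alt[ok], adj$alt[ok]), mut_type = "MNV",
    vaf_duplex = 0.01, vaf_all_molecules = 0.01
  )
  expect_equal(annotate_mutations(raw2, panel)$consequence, "synonymous")
})

test_that("catalog TSV round-trips through write and read", {
  co <- shared_cohort()
  f <- tempfile(fileext = ".tsv")
  write_mutations(co$mutations, f)
  back <- read_mutations(f, co$panel, samples = co$covariates$sample_id)
  expect_equal(nrow(back), nrow(co$mutations))
  expect_equal(back$pos, co$mutations$pos)
  expect_equal(back$vaf_duplex, co$mutations$vaf_duplex)
  expect_equal(back$consequence, co$mutations$consequence)
})

test_that("residue tallies match worked arithmetic and edge cases", {
  # synthetic gene with 394 protein positions (1,182-bp CDS incl. stop)
  set.seed(3)
  gc <- Biostrings::GENETIC_CODE
  cds <- paste0("ATG",
                paste0(sample(names(gc)[gc != "*"], 392, replace = TRUE),
                       collapse = ""), "TAA")
  seq <- paste0(strrep("A", 5), cds, strrep("A", 5))
  regions <- tibble::tibble(chrom = "chr_P", start = 5L,
                            end = 5L + 1182L, gene = "P53LIKE",
                            region_class = "coding", strand = "+",
                            frame_anchor = 0L)
  panel <- build_panel(regions, c(chr_P = seq))
  sa <- panel$site_alts[panel$site_alts$consequence %in%
                          c("missense", "nonsense"), ]
  residues <- unique(sa$protein_pos)
  expect_equal(length(unique(panel$site_alts$protein_pos)), 394)

  hit_res <- sort(residues)[1:230]
  picks <- sa[match(hit_res, sa$protein_pos), ]
  muts <- tibble::tibble(
    sample_id = "S1", donor_id = "D1", chrom = picks$chrom, pos = picks$pos,
    ref = picks$ref, alt = picks$alt, mut_type = "SNV",
    vaf_duplex = 0.01, vaf_all_molecules = 0.01,
    gene = "P53LIKE", consequence = picks$consequence,
    protein_pos = picks$protein_pos
  )
  tal <- residue_saturation(muts, panel, "P53LIKE")
  cov <- attr(tal, "coverage")
  expect_equal(cov$n_residues, 394)
  expect_equal(cov$n_mutated, 230)
  expect_equal(round(cov$percent_mutated), 58)

  # empty catalog -> 0%
  cov0 <- attr(residue_saturation(muts[0, ], panel, "P53LIKE"), "coverage")
  expect_equal(cov0$percent_mutated, 0)

  # one mutation on every residue -> 100%
  all_picks <- sa[match(residues, sa$protein_pos), ]
  muts_all <- muts[rep(1, length(residues)), ]
  muts_all$pos <- all_picks$pos
  muts_all$protein_pos <- all_picks$protein_pos
  muts_all$consequence <- all_picks$consequence
  cov100 <- attr(residue_saturation(muts_all, panel, "P53LIKE"), "coverage")
  expect_equal(cov100$percent_mutated, 100)
})

test_that("depth, covariates and whitelist round-trip", {
  co <- shared_cohort()
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  write_depth(co$depth, f1)
  write_covariates(co$covariates, f2)
  write_whitelist(co$whitelist, f3)
  expect_equal(as.data.frame(read_depth(f1)), as.data.frame(co$depth))
  expect_equal(as.data.frame(read_covariates(f2)),
               as.data.frame(co$covariates))
  expect_equal(as.data.frame(read_whitelist(f3)), as.data.frame(co$whitelist))
})
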