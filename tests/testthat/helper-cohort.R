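# shared fixtures built in code: scaled-down synthetic cohorts whose
# per-site-per-sample mutation density matches the full-size default
# (774 mutations per sample over a 111,876-bp panel), so that catalog
# properties are realistic while tests stay fast

test_gene_table <- function(omegas = NULL) {
  tbl <- tibble::tibble(
    gene = c("POSGENE", "NEGGENE", "NEUGENE"),
    cds_length = c(1500, 1200, 900),
    complete = TRUE,
    frame_anchor = 0L,
    strand = c("+", "-", "+"),
    omega_missense = c(3, 0.2, 1),
    omega_truncating = c(10, 0.1, 1),
    omega_indel = c(4, 0.3, 1)
  )
  if (!is.null(omegas)) {
    for (col in names(omegas)) tbl[[col]] <- omegas[[col]]
  }
  tbl
}

# per-sample mutation target keeping the default per-base density
density_scaled_target <- function(total_bp) {
  round(774 * total_bp / 111876)
}

scaled_config <- function(seed = 1, genes = test_gene_table(),
                          flank_length = 800, promoter_length = 200,
                          n_donors = 30, depth_median = 1200, ...) {
  total_bp <- sum(genes$cds_length) + 2 * flank_length * nrow(genes) +
    promoter_length
  cohort_config(
    seed = seed, n_donors = n_donors, genes = genes,
    flank_length = flank_length, promoter_length = promoter_length,
    n_whitelist = 6, depth_median = depth_median,
    target_muts_per_sample = density_scaled_target(total_bp),
    ...
  )
}

no_covariate_effects <- function() {
  tibble::tibble(gene = character(), mclass = character(),
                 covariate = character(), beta = numeric())
}

# one moderate cohort shared across test files (built once per test run)
.test_env <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.test_env$cohort)) {
    .test_env$cohort <- generate_cohort(scaled_config(seed = 202))
  }
  .test_env$cohort
}

shared_spectrum <- function() {
  if (is.null(.test_env$spectrum)) {
    co <- shared_cohort()
    .test_env$spectrum <- fit_neutral_spectrum(
      co$mutations, co$panel, co$depth, exclude = co$whitelist
    )
  }
  .test_env$spectrum
}

# a deterministic miniature panel: one 30-bp gene on "+", known sequence
tiny_panel <- function(strand = "+", splice_window = 2) {
  cds <- "ATGGCTTGCGATGAACGTACCTTAATGTAA"  # 10 codons incl stop
  body <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  } else cds
  left <- "ACGTACGTAC"
  right <- "GTACGTACGT"
  seq <- paste0(left, body, right)
  regions <- tibble::tibble(
    chrom = "chr_T",
    start = c(2L, 10L, 40L),
    end = c(10L, 40L, 48L),
    gene = "TINY",
    region_class = c("intronic_flank", "coding", "intronic_flank"),
    strand = strand,
    frame_anchor = c(NA_integer_, 0L, NA_integer_)
  )
  build_panel(regions, c(chr_T = seq), splice_window = splice_window)
}
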