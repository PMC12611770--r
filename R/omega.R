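#' Depth-aware dN/dS (selection) estimation
#'
#' The neutral expectation of each consequence class in a gene is the sum,
#' over all (site, alt) pairs producing that consequence, of the neutral
#' channel rate times the duplex depth at the site (site-genomes). Observed
#' counts are modelled as Poisson with that fixed expectation: dN/dS is
#' observed/expected, confidence intervals are exact (Garwood) Poisson bounds
#' on the count divided by the expectation, and two-sided p-values double the
#' smaller Poisson tail. The driver excess is the observed count minus the
#' expectation (floored at zero).
#'
#' @name omega
NULL

.CLASS_MAP <- c(
  synonymous = "synonymous", missense = "missense",
  nonsense = "truncating", essential_splice = "truncating"
)

#' Neutral expected mutation counts per gene and consequence class
#'
#' @param panel a `duplex_panel`
#' @param depth wide depth tibble
#' @param spectrum fitted `trinuc_spectrum`
#' @param genes genes to report (default: all panel genes with coding sites)
#' @param scope `"cohort"` or a single sample id
#' @return tibble `gene`, `mclass` (`synonymous`, `missense`, `truncating`),
#'   `expected`
#' @export
expected_counts <- function(panel, depth, spectrum, genes = NULL,
                            scope = "cohort") {
  sa <- class_site_alts(panel, genes)
  sa$rate <- spectrum$rate[match(sa$channel, spectrum$channel)]
  sa$d <- site_depth(depth, sa$chrom, sa$pos, scope)
  sa |>
    dplyr::group_by(.data$gene, .data$mclass) |>
    dplyr::summarise(expected = sum(.data$rate * .data$d, na.rm = TRUE),
                     .groups = "drop")
}

class_site_alts <- function(panel, genes = NULL) {
  sa <- panel$site_alts |>
    dplyr::filter(.data$consequence %in% names(.CLASS_MAP)) |>
    dplyr::mutate(mclass = unname(.CLASS_MAP[.data$consequence]))
  if (!is.null(genes)) {
    missing <- setdiff(genes, unique(panel$site_alts$gene))
    if (length(missing) > 0) {
      stop("gene(s) absent from panel: ", paste(missing, collapse = ", "))
    }
    sa <- dplyr::filter(sa, .data$gene %in% genes)
  }
  sa
}

observed_class_counts <- function(mutations, genes = NULL, scope = "cohort") {
  m <- mutations |>
    dplyr::filter(.data$mut_type == "SNV",
                  .data$consequence %in% names(.CLASS_MAP)) |>
    dplyr::mutate(mclass = unname(.CLASS_MAP[.data$consequence]))
  if (!is.null(genes)) m <- dplyr::filter(m, .data$gene %in% genes)
  if (!identical(scope, "cohort")) {
    m <- dplyr::filter(m, .data$sample_id == scope)
  }
  dplyr::count(m, .data$gene, .data$mclass, name = "observed")
}

#' Fit cohort-level dN/dS per gene and class
#'
#' @param mutations annotated mutation tibble
#' @param panel a `duplex_panel`
#' @param depth wide depth tibble
#' @param spectrum optional pre-fitted `trinuc_spectrum`; fitted from
#'   `neutral_classes` when omitted
#' @param genes genes to test (default: all genes with coding sites)
#' @param classes consequence classes to report
#' @param neutral_classes passed to [fit_neutral_spectrum()] when `spectrum`
#'   is omitted
#' @param exclude optional (`chrom`, `pos`, `alt`) exclusion list for the
#'   spectrum fit
#' @return an `omega_fit`: list with `results` (one row per gene x class:
#'   observed, expected, dnds, exact CI, p, driver excess/fraction),
#'   `spectrum` and `scope`
#' @export
fit_omega <- function(mutations, panel, depth, spectrum = NULL, genes = NULL,
                      classes = c("missense", "truncating"),
                      neutral_classes = c("synonymous", "noncoding"),
                      exclude = NULL) {
  if (is.null(spectrum)) {
    spectrum <- fit_neutral_spectrum(mutations, panel, depth,
                                     neutral_classes = neutral_classes,
                                     exclude = exclude)
  }
  if (is.null(genes)) {
    genes <- unique(panel$regions$gene[panel$regions$region_class == "coding"])
  }
  exp_tbl <- expected_counts(panel, depth, spectrum, genes)
  obs_tbl <- observed_class_counts(mutations, genes)
  grid <- tidyr::expand_grid(gene = genes, mclass = classes) |>
    dplyr::left_join(exp_tbl, by = c("gene", "mclass")) |>
    dplyr::left_join(obs_tbl, by = c("gene", "mclass")) |>
    dplyr::mutate(observed = dplyr::coalesce(.data$observed, 0L),
                  expected = dplyr::coalesce(.data$expected, 0))
  results <- purrr::pmap_dfr(
    grid, function(gene, mclass, expected, observed) {
      selection_row(gene, mclass, "cohort", observed, expected)
    }
  )
  structure(
    list(results = results, spectrum = spectrum, scope = "cohort",
         expected_synonymous = dplyr::filter(exp_tbl,
                                             .data$mclass == "synonymous")),
    class = "omega_fit"
  )
}

#' @method print omega_fit
#' @export
print.omega_fit <- function(x, ...) {
  cat("<omega_fit> scope:", x$scope, "-", nrow(x$results), "gene x class tests\n")
  print(x$results, n = 10)
  invisible(x)
}

#' @method tidy omega_fit
#' @export
tidy.omega_fit <- function(x, ...) x$results

#' @method glance omega_fit
#' @export
glance.omega_fit <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$results),
    n_genes = length(unique(x$results$gene)),
    n_significant = sum(x$results$p_value < 0.05, na.rm = TRUE),
    total_driver_excess = sum(x$results$driver_excess, na.rm = TRUE)
  )
}

#' Selection on tumour-recurrent promoter mutations
#'
#' Promoter substitutions are dichotomised into activating (present in a
#' whitelist of positions/alleles recurrently mutated across tumour genomes)
#' and other. The neutral rate inside the promoter is calibrated so that the
#' non-activating (site, alt) pairs reproduce their observed count exactly;
#' the activating expectation then follows from the whitelist's
#' depth-weighted channel rates.
#'
#' @inheritParams fit_omega
#' @param whitelist tibble (`chrom`, `pos`, `alt`) of activating promoter
#'   substitutions
#' @param gene promoter gene label (default `"TERT"`)
#' @param scope `"cohort"` or a sample id
#' @return one-row selection-result tibble (`mclass = "activating_pTERT"`)
#' @export
dnds_ptert <- function(mutations, panel, depth, whitelist, spectrum = NULL,
                       gene = "TERT", scope = "cohort") {
  if (is.null(whitelist) || nrow(whitelist) == 0) {
    stop("empty activating-mutation whitelist")
  }
  prom <- panel$site_alts |>
    dplyr::filter(.data$gene == !!gene, .data$region_class == "promoter")
  if (nrow(prom) == 0) stop("no promoter sites for gene ", gene)
  wl_key <- stringr::str_c(whitelist$chrom, whitelist$pos, whitelist$alt,
                           sep = ":")
  prom_key <- stringr::str_c(prom$chrom, prom$pos, prom$alt, sep = ":")
  if (!all(wl_key %in% prom_key)) {
    stop("whitelist entries outside the promoter region")
  }
  if (is.null(spectrum)) {
    spectrum <- fit_neutral_spectrum(mutations, panel, depth,
                                     exclude = whitelist)
  }
  prom$rate <- spectrum$rate[match(prom$channel, spectrum$channel)]
  prom$d <- site_depth(depth, prom$chrom, prom$pos, scope)
  prom$activating <- prom_key %in% wl_key

  m <- mutations |>
    dplyr::filter(.data$mut_type == "SNV", .data$gene == !!gene,
                  .data$consequence == "noncoding")
  if (!identical(scope, "cohort")) m <- dplyr::filter(m, .data$sample_id == scope)
  m_key <- stringr::str_c(m$chrom, m$pos, m$alt, sep = ":")
  obs_act <- sum(m_key %in% wl_key)
  obs_other <- sum(!(m_key %in% wl_key))

  w_act <- sum(prom$rate * prom$d * prom$activating, na.rm = TRUE)
  w_other <- sum(prom$rate * prom$d * !prom$activating, na.rm = TRUE)
  if (w_other <= 0 || obs_other == 0) {
    stop("cannot calibrate promoter neutral rate (no non-activating signal)")
  }
  e_act <- obs_other / w_other * w_act
  selection_row(gene, "activating_pTERT", scope, obs_act, e_act)
}

#' Frameshift-indel enrichment per gene
#'
#' The background frameshift-indel rate per depth-weighted coding base is
#' estimated panel-wide excluding the gene under test (leave-one-out); the
#' gene's expectation is that rate times its depth-weighted coding length.
#' The p-value is the upper Poisson tail (enrichment is one-sided).
#'
#' @inheritParams fit_omega
#' @param scope `"cohort"` or a sample id
#' @return selection-result tibble, one row per gene
#'   (`mclass = "frameshift_indel"`)
#' @export
indel_enrichment <- function(mutations, panel, depth, genes = NULL,
                             scope = "cohort") {
  coding_sites <- panel$sites |>
    dplyr::filter(.data$region_class == "coding", !.data$excluded)
  coding_sites$d <- site_depth(depth, coding_sites$chrom, coding_sites$pos,
                               scope)
  len_by_gene <- coding_sites |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(weighted_len = sum(.data$d), .groups = "drop")

  fs <- mutations |>
    dplyr::filter(.data$consequence == "frameshift_indel")
  if (!identical(scope, "cohort")) {
    fs <- dplyr::filter(fs, .data$sample_id == scope)
  }
  fs_by_gene <- dplyr::count(fs, .data$gene, name = "observed")

  if (is.null(genes)) genes <- len_by_gene$gene
  total_fs <- sum(fs_by_gene$observed)
  total_len <- sum(len_by_gene$weighted_len)

  purrr::map_dfr(genes, function(g) {
    obs <- fs_by_gene$observed[match(g, fs_by_gene$gene)]
    obs <- if (is.na(obs)) 0L else obs
    len_g <- len_by_gene$weighted_len[match(g, len_by_gene$gene)]
    if (is.na(len_g)) stop("gene has no coding sites in panel: ", g)
    bg_fs <- total_fs - obs
    bg_len <- total_len - len_g
    if (bg_fs == 0 || bg_len <= 0) {
      return(selection_row(g, "frameshift_indel", scope, obs, NA_real_))
    }
    e <- bg_fs / bg_len * len_g
    row <- selection_row(g, "frameshift_indel", scope, obs, e)
    row$p_value <- poisson_p_upper(obs, e)
    row
  })
}

#' Per-sample dN/dS matrix with eligibility flags
#'
#' Expected counts use each sample's own depth, with the cohort channel
#' shape rescaled to the sample's neutral mutation count. Entries whose
#' expectation is zero (or whose sample has no neutral mutations to calibrate
#' on) are missing; a (gene, class) combination is eligible when it is
#' non-missing for at least `eligibility` of samples.
#'
#' @inheritParams fit_omega
#' @param eligibility minimum fraction of samples with a computable value
#'   (default 0.8)
#' @return list with `results` (selection-result tibble keyed gene x class x
#'   sample) and `eligibility` (tibble gene, mclass, n_non_missing,
#'   n_samples, eligible)
#' @export
per_sample_omega <- function(mutations, panel, depth, genes = NULL,
                             classes = c("missense", "truncating"),
                             neutral_classes = c("synonymous", "noncoding"),
                             exclude = NULL, eligibility = 0.8) {
  spectrum <- fit_neutral_spectrum(mutations, panel, depth,
                                   neutral_classes = neutral_classes,
                                   scope = "sample", exclude = exclude)
  scale <- attr(spectrum, "sample_scale")
  if (is.null(genes)) {
    genes <- unique(panel$regions$gene[panel$regions$region_class == "coding"])
  }
  sa <- class_site_alts(panel, genes) |>
    dplyr::filter(.data$mclass %in% classes)
  sa$rate <- spectrum$rate[match(sa$channel, spectrum$channel)]

  cols <- depth_sample_cols(depth)
  didx <- match(stringr::str_c(sa$chrom, sa$pos, sep = ":"),
                stringr::str_c(depth$chrom, depth$pos, sep = ":"))
  grp <- stringr::str_c(sa$gene, sa$mclass, sep = "\r")

  per_sample <- purrr::map_dfr(cols, function(s) {
    d <- depth[[s]][didx]
    d[is.na(d)] <- 0
    k <- scale$scale[match(s, scale$sample_id)]
    e <- rowsum(sa$rate * d, grp, na.rm = TRUE)[, 1] * k
    parts <- stringr::str_split_fixed(names(e), "\r", 2)
    tibble::tibble(gene = parts[, 1], mclass = parts[, 2],
                   sample_id = s, expected = unname(e))
  })

  obs <- mutations |>
    dplyr::filter(.data$mut_type == "SNV",
                  .data$consequence %in% names(.CLASS_MAP),
                  .data$gene %in% genes) |>
    dplyr::mutate(mclass = unname(.CLASS_MAP[.data$consequence])) |>
    dplyr::filter(.data$mclass %in% classes) |>
    dplyr::count(.data$gene, .data$mclass, .data$sample_id, name = "observed")

  grid <- per_sample |>
    dplyr::left_join(obs, by = c("gene", "mclass", "sample_id")) |>
    dplyr::mutate(observed = dplyr::coalesce(.data$observed, 0L))

  results <- purrr::pmap_dfr(
    grid[, c("gene", "mclass", "sample_id", "expected", "observed")],
    function(gene, mclass, sample_id, expected, observed) {
      selection_row(gene, mclass, sample_id, observed, expected)
    }
  )
  elig <- results |>
    dplyr::group_by(.data$gene, .data$mclass) |>
    dplyr::summarise(
      n_non_missing = sum(is.finite(.data$dnds)),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(eligible = .data$n_non_missing / .data$n_samples >= eligibility)
  list(results = results, eligibility = elig, spectrum = spectrum)
}

#' Eligibility of a (gene, class) column under the fraction-of-samples rule
#'
#' @param n_non_missing samples with a computable value
#' @param n_samples total samples
#' @param threshold minimum fraction (default 0.8)
#' @return logical
#' @export
eligible_column <- function(n_non_missing, n_samples, threshold = 0.8) {
  n_non_missing / n_samples >= threshold
}
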