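#' Site, residue, exon and domain selection scores
#'
#' The gene-level neutral expectation is distributed across all possible
#' substitutions of the gene in proportion to channel rate times site depth
#' (within each consequence-class stratum), so that only trinucleotide
#' mutation probability and sequencing depth drive within-gene differences.
#' Observed counts per unit are compared with these expectations with an
#' upper-tail Poisson test and Benjamini-Hochberg correction across units of
#' the gene.
#'
#' @name siteselect
NULL

#' Neutral expectation per possible substitution of a gene
#'
#' @param panel a `duplex_panel`
#' @param depth wide depth tibble
#' @param spectrum fitted `trinuc_spectrum`
#' @param gene gene symbol
#' @param classes consequence classes to include (default: protein-affecting
#'   SNVs, `missense` + `nonsense`)
#' @param scope `"cohort"` or a sample id
#' @return tibble per (site, alt): `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`, `protein_pos`, `expected`
#' @export
site_expected <- function(panel, depth, spectrum, gene,
                          classes = c("missense", "nonsense"),
                          scope = "cohort") {
  sa <- panel$site_alts |>
    dplyr::filter(.data$gene == !!gene, .data$consequence %in% classes)
  if (nrow(sa) == 0) stop("no sites of the requested classes for gene ", gene)
  sa$rate <- spectrum$rate[match(sa$channel, spectrum$channel)]
  sa$d <- site_depth(depth, sa$chrom, sa$pos, scope)
  sa$expected <- sa$rate * sa$d
  sa[, c("chrom", "pos", "ref", "alt", "consequence", "protein_pos",
         "expected")]
}

#' Score selection per site, residue, exon or domain
#'
#' @param mutations annotated mutation tibble
#' @param panel a `duplex_panel`
#' @param depth wide depth tibble
#' @param spectrum fitted `trinuc_spectrum`
#' @param gene gene symbol
#' @param unit one of `"snv"`, `"residue"`, `"exon"`, `"domain"`
#' @param classes consequence classes included (default protein-affecting)
#' @param intervals for `exon`/`domain`: tibble `unit_id`, `chrom`, `start`,
#'   `end` (0-based half-open genomic intervals)
#' @param epsilon stabiliser in the display score
#'   `log2((obs + eps) / (exp + eps))`; p-values use raw counts
#' @param scope `"cohort"` or a sample id
#' @return tibble of unit scores: `gene`, `unit`, `unit_id`, `observed`,
#'   `expected`, `score`, `dnds`, `ci_low`, `ci_high`, `p_value`, `q_value`;
#'   units with zero expectation are dropped (count in attribute
#'   `n_suppressed`)
#' @export
site_selection <- function(mutations, panel, depth, spectrum, gene,
                           unit = c("residue", "snv", "exon", "domain"),
                           classes = c("missense", "nonsense"),
                           intervals = NULL, epsilon = 0.5, scope = "cohort") {
  unit <- match.arg(unit)
  se <- site_expected(panel, depth, spectrum, gene, classes, scope)

  m <- mutations |>
    dplyr::filter(.data$mut_type == "SNV", .data$gene == !!gene,
                  .data$consequence %in% classes)
  if (!identical(scope, "cohort")) m <- dplyr::filter(m, .data$sample_id == scope)

  if (unit == "snv") {
    se$unit_id <- stringr::str_c(se$chrom, ":", se$pos, se$ref, ">", se$alt)
    m$unit_id <- stringr::str_c(m$chrom, ":", m$pos, m$ref, ">", m$alt)
  } else if (unit == "residue") {
    se <- dplyr::filter(se, !is.na(.data$protein_pos))
    se$unit_id <- as.character(se$protein_pos)
    m <- dplyr::filter(m, !is.na(.data$protein_pos))
    m$unit_id <- as.character(m$protein_pos)
  } else {
    if (is.null(intervals)) stop("exon/domain units require `intervals`")
    se$unit_id <- interval_id(se$chrom, se$pos, intervals)
    m$unit_id <- interval_id(m$chrom, m$pos, intervals)
    se <- dplyr::filter(se, !is.na(.data$unit_id))
    m <- dplyr::filter(m, !is.na(.data$unit_id))
  }

  exp_u <- se |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(expected = sum(.data$expected, na.rm = TRUE),
                     .groups = "drop")
  obs_u <- dplyr::count(m, .data$unit_id, name = "observed")
  tbl <- exp_u |>
    dplyr::left_join(obs_u, by = "unit_id") |>
    dplyr::mutate(observed = dplyr::coalesce(.data$observed, 0L))

  suppressed <- tbl$expected <= 0
  n_suppressed <- sum(suppressed)
  tbl <- tbl[!suppressed, ]

  ci <- purrr::map2(tbl$observed, tbl$expected, poisson_ratio_ci)
  out <- tibble::tibble(
    gene = gene, unit = unit, unit_id = tbl$unit_id,
    observed = tbl$observed, expected = tbl$expected,
    score = log2((tbl$observed + epsilon) / (tbl$expected + epsilon)),
    dnds = tbl$observed / tbl$expected,
    ci_low = purrr::map_dbl(ci, "low"),
    ci_high = purrr::map_dbl(ci, "high"),
    p_value = purrr::map2_dbl(tbl$observed, tbl$expected, poisson_p_upper)
  )
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  if (unit %in% c("snv", "residue")) {
    suppressWarnings({
      num <- as.numeric(out$unit_id)
    })
    if (!anyNA(num)) out <- out[order(num), ]
  }
  attr(out, "n_suppressed") <- n_suppressed
  out
}

interval_id <- function(chrom, pos, intervals) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(intervals))) {
    hit <- chrom == intervals$chrom[i] & pos >= intervals$start[i] &
      pos < intervals$end[i]
    out[hit] <- intervals$unit_id[i]
  }
  out
}
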