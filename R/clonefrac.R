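#' Fraction of genomes and cells carrying driver mutations
#'
#' Given the estimated number of driver mutations of a gene in a sample
#' (rounded driver excess per class), the most likely drivers are the
#' mutations with the largest all-molecules VAF. The fraction of sequenced
#' genomes bearing at least one of them, assuming independence across
#' mutations, is the inclusion-exclusion probability
#' P(G) = 1 - prod(1 - p_x), with p_x the all-molecules VAF of driver x.
#' Under the two-hit assumption (both copies must be inactivated) the
#' fraction of cells equals the fraction of genomes; in the one-hit extreme
#' it is double (capped at 1); a hemizygous male X gene carries one copy, so
#' cells = genomes.
#'
#' @name clonefrac
NULL

#' Select the most likely driver mutations of a gene in a sample
#'
#' The expected driver count is the half-up-rounded missense excess plus the
#' half-up-rounded truncating excess from the per-sample selection results;
#' the top mutations by `vaf_all_molecules` (ties broken by ascending genomic
#' position) are selected. The CI endpoints of dN/dS give bound counts using
#' the same ranking.
#'
#' @param mutations annotated mutation tibble
#' @param selection per-sample selection-result tibble (rows for the gene and
#'   sample, classes `missense` and/or `truncating`)
#' @param gene gene symbol
#' @param sample sample id
#' @return tibble of selected driver mutations, ordered; attributes
#'   `n_expected`, `n_low`, `n_high`, `capped`
#' @export
select_drivers <- function(mutations, selection, gene, sample) {
  sel <- selection |>
    dplyr::filter(.data$gene == !!gene, .data$scope == !!sample,
                  .data$mclass %in% c("missense", "truncating"))
  n_from <- function(ratio_col) {
    v <- pmax((sel[[ratio_col]] - 1) * sel$expected, 0)
    sum(round_half_up(v[is.finite(v)]))
  }
  n_mean <- sum(round_half_up(sel$driver_excess[is.finite(sel$driver_excess)]))
  n_low <- n_from("ci_low")
  n_high <- n_from("ci_high")

  cand <- mutations |>
    dplyr::filter(.data$gene == !!gene, .data$sample_id == !!sample,
                  .data$mut_type == "SNV",
                  .data$consequence %in% c("missense", "nonsense",
                                           "essential_splice")) |>
    dplyr::arrange(dplyr::desc(.data$vaf_all_molecules), .data$chrom, .data$pos)

  capped <- n_mean > nrow(cand)
  n_take <- min(n_mean, nrow(cand))
  out <- cand[seq_len(n_take), , drop = FALSE]
  attr(out, "n_expected") <- n_mean
  attr(out, "n_low") <- min(n_low, nrow(cand))
  attr(out, "n_high") <- min(n_high, nrow(cand))
  attr(out, "capped") <- capped
  out
}

#' Inclusion-exclusion fraction of genomes with a driver mutation
#'
#' @param p numeric vector of all-molecules VAFs in (0, 1]
#' @return P(G) = 1 - prod(1 - p); 0 for an empty set
#' @export
fraction_genomes <- function(p) {
  if (length(p) == 0) return(0)
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("driver VAFs must lie in (0, 1]")
  }
  1 - prod(1 - p)
}

#' Convert a genome fraction to a cell fraction under a ploidy assumption
#'
#' @param genomes fraction of genomes with driver mutations
#' @param ploidy_mode `"two_hit"` (cells = genomes), `"one_hit"`
#'   (cells = min(1, 2 x genomes)) or `"hemizygous_male_X"` (one copy:
#'   cells = genomes)
#' @return fraction of cells
#' @export
fraction_cells <- function(genomes,
                           ploidy_mode = c("two_hit", "one_hit",
                                           "hemizygous_male_X")) {
  ploidy_mode <- match.arg(ploidy_mode)
  switch(ploidy_mode,
         two_hit = genomes,
         one_hit = min(1, 2 * genomes),
         hemizygous_male_X = genomes)
}

#' Clone fractions per gene and sample
#'
#' @param mutations annotated mutation tibble
#' @param selection per-sample selection-result tibble (from
#'   [per_sample_omega()])
#' @param genes genes to report (default: genes present in `selection`)
#' @param samples samples to report (default: scopes present in `selection`)
#' @param ploidy_mode passed to [fraction_cells()] (default `"two_hit"`)
#' @return tibble per (gene, sample): `n_drivers_selected`,
#'   `fraction_genomes`, `fraction_cells`, `fraction_low`, `fraction_high`
#' @export
clone_fractions <- function(mutations, selection, genes = NULL, samples = NULL,
                            ploidy_mode = "two_hit") {
  genes <- genes %||% unique(selection$gene)
  samples <- samples %||% unique(selection$scope)
  purrr::map_dfr(genes, function(g) {
    purrr::map_dfr(samples, function(s) {
      drv <- select_drivers(mutations, selection, g, s)
      fg <- fraction_genomes(drv$vaf_all_molecules)
      ranked <- mutations |>
        dplyr::filter(.data$gene == !!g, .data$sample_id == !!s,
                      .data$mut_type == "SNV",
                      .data$consequence %in% c("missense", "nonsense",
                                               "essential_splice")) |>
        dplyr::arrange(dplyr::desc(.data$vaf_all_molecules), .data$chrom,
                       .data$pos)
      f_at <- function(n) {
        fraction_genomes(ranked$vaf_all_molecules[seq_len(min(n, nrow(ranked)))])
      }
      tibble::tibble(
        gene = g, sample_id = s,
        n_drivers_selected = nrow(drv),
        fraction_genomes = fg,
        fraction_cells = fraction_cells(fg, ploidy_mode),
        fraction_low = f_at(attr(drv, "n_low")),
        fraction_high = f_at(attr(drv, "n_high")),
        capped = attr(drv, "capped")
      )
    })
  })
}
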