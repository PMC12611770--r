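#' Neutral trinucleotide mutation-rate model
#'
#' Neutral per-channel mutation rates are estimated from mutation classes
#' assumed free of selection (synonymous and, optionally, non-coding panel
#' mutations). The opportunity of a channel is the depth-weighted number of
#' (site, alt) pairs of that channel among the neutral classes, in
#' site-genomes; the rate is count/opportunity, in mutations per site-genome.
#'
#' @name spectrum
NULL

depth_sample_cols <- function(depth) {
  setdiff(names(depth), c("chrom", "pos"))
}

# per-site depth aligned to an arbitrary (chrom,pos) key; cohort scope sums
# over samples, otherwise a single sample column
site_depth <- function(depth, chrom, pos, scope = "cohort") {
  idx <- match(stringr::str_c(chrom, pos, sep = ":"),
               stringr::str_c(depth$chrom, depth$pos, sep = ":"))
  cols <- depth_sample_cols(depth)
  if (identical(scope, "cohort")) {
    tot <- rowSums(as.matrix(depth[, cols]))
    out <- tot[idx]
  } else {
    stopifnot(scope %in% cols)
    out <- depth[[scope]][idx]
  }
  out[is.na(out)] <- 0
  out
}

#' Fit the neutral trinucleotide spectrum
#'
#' @param mutations annotated mutation tibble
#' @param panel a `duplex_panel`
#' @param depth wide depth tibble (see [read_depth()])
#' @param neutral_classes consequence classes treated as selection-free
#'   (subset of `synonymous`, `noncoding`); default both
#' @param scope `"cohort"` (pooled) or `"sample"` (pooled channel shape,
#'   per-sample magnitude calibrated on that sample's neutral count)
#' @param pseudocount added to empty channel counts (default 0.5); set to 0
#'   for exact Poisson tests
#' @param exclude optional tibble (`chrom`, `pos`, `alt`) of sites excluded
#'   from rate estimation (e.g. the promoter activating-mutation whitelist)
#' @return a `trinuc_spectrum` tibble: `channel`, `count`, `opportunity`,
#'   `rate`, `probability`; with `scope = "sample"` an additional long tibble
#'   of per-sample scale factors is attached as attribute `sample_scale`
#' @export
fit_neutral_spectrum <- function(mutations, panel, depth,
                                 neutral_classes = c("synonymous", "noncoding"),
                                 scope = "cohort", pseudocount = 0.5,
                                 exclude = NULL) {
  stopifnot(all(neutral_classes %in% c("synonymous", "noncoding")))
  sa <- panel$site_alts |>
    dplyr::filter(.data$consequence %in% neutral_classes)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    sa <- dplyr::anti_join(sa, exclude, by = c("chrom", "pos", "alt"))
  }
  neutral <- mutations |>
    dplyr::filter(.data$mut_type == "SNV",
                  .data$consequence %in% neutral_classes)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    neutral <- dplyr::anti_join(neutral, exclude, by = c("chrom", "pos", "alt"))
  }
  if (nrow(neutral) == 0) {
    stop("no neutral mutations in the catalog; widen `neutral_classes`")
  }

  sa$depth_total <- site_depth(depth, sa$chrom, sa$pos, "cohort")
  opp <- sa |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(opportunity = sum(.data$depth_total), .groups = "drop")

  ch <- collapse_channel(
    trinuc_of(neutral, panel), neutral$alt
  )$channel
  cnt <- tibble::tibble(channel = ch) |> dplyr::count(.data$channel)

  spec <- tibble::tibble(channel = all_channels()) |>
    dplyr::left_join(opp, by = "channel") |>
    dplyr::left_join(cnt, by = "channel") |>
    dplyr::mutate(
      opportunity = dplyr::coalesce(.data$opportunity, 0),
      count = dplyr::coalesce(.data$n, 0L), n = NULL
    )
  usable <- spec$opportunity > 0
  # pseudocount stabilises empty channels only, so the total rate mass is
  # essentially untouched (a global pseudocount visibly biases expectations)
  add <- ifelse(usable & spec$count == 0, pseudocount, 0)
  spec$rate <- ifelse(usable, (spec$count + add) / spec$opportunity, NA_real_)
  spec$probability <- ifelse(usable, spec$rate / sum(spec$rate[usable]), NA_real_)
  attr(spec, "neutral_classes") <- neutral_classes
  attr(spec, "pseudocount") <- pseudocount
  attr(spec, "n_excluded_channels") <- sum(!usable)
  class(spec) <- c("trinuc_spectrum", class(spec))

  if (identical(scope, "sample")) {
    cols <- depth_sample_cols(depth)
    didx <- match(stringr::str_c(sa$chrom, sa$pos, sep = ":"),
                  stringr::str_c(depth$chrom, depth$pos, sep = ":"))
    rate_sa <- spec$rate[match(sa$channel, spec$channel)]
    scale <- purrr::map_dfr(cols, function(s) {
      d <- depth[[s]][didx]
      d[is.na(d)] <- 0
      exp_neutral <- sum(rate_sa * d, na.rm = TRUE)
      obs <- sum(neutral$sample_id == s)
      tibble::tibble(sample_id = s, n_neutral = obs,
                     expected_neutral = exp_neutral,
                     scale = ifelse(exp_neutral > 0, obs / exp_neutral, NA_real_))
    })
    attr(spec, "sample_scale") <- scale
  }
  spec
}

# pyrimidine-raw trinucleotide of each mutation from its panel site
trinuc_of <- function(mutations, panel) {
  idx <- match(stringr::str_c(mutations$chrom, mutations$pos, sep = ":"),
               stringr::str_c(panel$sites$chrom, panel$sites$pos, sep = ":"))
  panel$sites$trinuc_raw[idx]
}

#' Project a panel spectrum onto genome trinucleotide composition
#'
#' Rates estimated on the panel are multiplied by the genome-wide abundance
#' of each trinucleotide, renormalised, and rescaled to preserve the total
#' number of observed mutations.
#'
#' @param spectrum a `trinuc_spectrum`
#' @param genome_comp tibble (`trinuc`, `count`): occurrences of each
#'   pyrimidine-central trinucleotide in the genome (or a stand-in)
#' @param total_observed total mutation count to preserve
#' @return tibble `channel`, `corrected_probability`, `corrected_count`
#' @export
correct_to_genome <- function(spectrum, genome_comp, total_observed) {
  stopifnot(all(all_trinucs() %in% genome_comp$trinuc),
            all(genome_comp$count > 0))
  tri <- channel_trinuc(spectrum$channel)
  gcount <- genome_comp$count[match(tri, genome_comp$trinuc)]
  expected_genome <- spectrum$rate * gcount
  expected_genome[is.na(expected_genome)] <- 0
  prob <- expected_genome / sum(expected_genome)
  tibble::tibble(
    channel = spectrum$channel,
    corrected_probability = prob,
    corrected_count = prob * total_observed
  )
}

#' Read a genome trinucleotide composition table
#'
#' @param path TSV with columns `trinuc` (pyrimidine-central 3-mer), `count`
#' @return tibble
#' @export
read_genome_composition <- function(path) {
  readr::read_tsv(path, col_types = "ci", progress = FALSE)
}

#' Export a spectrum to TSV
#' @param spectrum a `trinuc_spectrum`
#' @param path output path
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(as.data.frame(spectrum), path)
  invisible(path)
}
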