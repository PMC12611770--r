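#' Kinetics of natural saturation mutagenesis
#'
#' As cumulative duplex depth grows, independently arisen somatic mutations
#' accumulate across all sites of a gene. Under neutrality, a possible
#' substitution m with per-site-genome rate r is observed at cumulative site
#' depth D with probability 1 - exp(-r D) (Poisson-process form); the
#' theoretical curve is the mean of this probability over all possible
#' substitutions. The observed curve is obtained by downsampling the catalog,
#' reducing the depth at each position by a factor f while respecting each
#' mutation's VAF: a mutation is retained when at least one of its supporting
#' molecules survives the depth subsampling. Two thinning forms are
#' available: `"molecule"` (default) subsamples the mutation's own
#' k = round(VAF x depth) supporting molecules, Binomial(k, f) >= 1, exact at
#' f = 1 and linear in f for single-molecule variants; `"redraw"` redraws
#' support from scratch, Binomial(round(f x depth), VAF) >= 1, approximating
#' an independent resequencing experiment at the thinned depth.
#'
#' @name saturation
NULL

#' Default log-spaced cumulative-depth grid
#'
#' @param d_full full cohort cumulative depth (top of the grid)
#' @param n number of grid points (default 12)
#' @param d_min lowest depth (default 1e3)
#' @return ascending numeric vector ending at `d_full`
#' @export
depth_grid_default <- function(d_full, n = 12, d_min = 1e3) {
  stopifnot(d_full > d_min)
  exp(seq(log(d_min), log(d_full), length.out = n))
}

#' Theoretical saturation curve of a gene
#'
#' @param panel a `duplex_panel`
#' @param depth wide depth tibble
#' @param spectrum fitted `trinuc_spectrum`
#' @param gene gene symbol
#' @param depth_grid cumulative mean depths at which to evaluate; default
#'   12 log-spaced points from 1e3 to the full cohort mean depth of the gene
#' @param classes consequence classes considered "possible SNVs" (default:
#'   all panel substitutions of the gene)
#' @return `saturation_curve` tibble: `depth`, `theoretical`; attributes
#'   `gene`, `n_possible`, `d_full`
#' @export
saturation_theoretical <- function(panel, depth, spectrum, gene,
                                   depth_grid = NULL, classes = NULL) {
  sa <- gene_site_alts(panel, gene, classes)
  sa$rate <- spectrum$rate[match(sa$channel, spectrum$channel)]
  sa$d_full <- site_depth(depth, sa$chrom, sa$pos, "cohort")
  d_full <- mean(sa$d_full)
  if (is.null(depth_grid)) depth_grid <- depth_grid_default(d_full)
  frac <- vapply(depth_grid, function(D) {
    f <- D / d_full
    mean(1 - exp(-sa$rate * f * sa$d_full), na.rm = TRUE)
  }, numeric(1))
  out <- tibble::tibble(depth = depth_grid, theoretical = frac)
  attr(out, "gene") <- gene
  attr(out, "n_possible") <- nrow(sa)
  attr(out, "d_full") <- d_full
  class(out) <- c("saturation_curve", class(out))
  out
}

#' Observed saturation curve of a gene by downsampling
#'
#' @inheritParams saturation_theoretical
#' @param mutations annotated mutation tibble
#' @param n_reps downsampling replicates per grid point (default 10)
#' @param seed RNG seed for reproducible thinning
#' @param method `"molecule"` (subsample supporting molecules; exact at
#'   full depth) or `"redraw"` (independent redraw of support at the thinned
#'   depth)
#' @return `saturation_curve` tibble: `depth`, `observed_mean`,
#'   `observed_sd`; attributes as for [saturation_theoretical()]
#' @export
saturation_observed <- function(mutations, panel, depth, gene,
                                depth_grid = NULL, classes = NULL,
                                n_reps = 10, seed = 1,
                                method = c("molecule", "redraw")) {
  method <- match.arg(method)
  sa <- gene_site_alts(panel, gene, classes)
  sa$d_full <- site_depth(depth, sa$chrom, sa$pos, "cohort")
  d_full <- mean(sa$d_full)
  if (is.null(depth_grid)) depth_grid <- depth_grid_default(d_full)
  if (max(depth_grid) > d_full * (1 + 1e-9)) {
    stop("depth grid exceeds the full cohort depth; no extrapolation")
  }

  keys <- stringr::str_c(sa$chrom, sa$pos, sa$alt, sep = ":")
  m <- mutations |>
    dplyr::filter(.data$mut_type == "SNV", .data$gene == !!gene)
  m <- m[stringr::str_c(m$chrom, m$pos, m$alt, sep = ":") %in% keys, ]
  mut_id <- match(stringr::str_c(m$chrom, m$pos, m$alt, sep = ":"), keys)
  cols <- depth_sample_cols(depth)
  didx <- match(stringr::str_c(m$chrom, m$pos, sep = ":"),
                stringr::str_c(depth$chrom, depth$pos, sep = ":"))
  d_occ <- vapply(seq_len(nrow(m)), function(i) {
    depth[[m$sample_id[i]]][didx[i]]
  }, numeric(1))
  d_occ[is.na(d_occ)] <- 0
  vaf <- m$vaf_duplex

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  res <- withr_seed({
    purrr::map_dfr(depth_grid, function(D) {
      f <- D / d_full
      fr <- vapply(seq_len(n_reps), function(rep) {
        keep <- thin_keep(d_occ, vaf, f, method)
        kept <- unique(mut_id[keep])
        length(kept) / nrow(sa)
      }, numeric(1))
      tibble::tibble(depth = D, observed_mean = mean(fr),
                     observed_sd = stats::sd(fr))
    })
  })
  attr(res, "gene") <- gene
  attr(res, "n_possible") <- nrow(sa)
  attr(res, "d_full") <- d_full
  class(res) <- c("saturation_curve", class(res))
  res
}

# vectorised retention draw for one thinning replicate
thin_keep <- function(d, vaf, f, method) {
  if (method == "molecule") {
    k <- pmax(round(vaf * d), 1)
    stats::rbinom(length(k), size = k, prob = min(f, 1)) >= 1
  } else {
    stats::rbinom(length(vaf), size = round(f * d), prob = vaf) >= 1
  }
}

#' Empirical retention frequency of a mutation under depth downsampling
#'
#' Simulates the per-mutation retention rule of [saturation_observed()] for
#' a single (depth, VAF) combination.
#'
#' @param depth duplex depth at the mutation's site (haploid genomes)
#' @param vaf duplex VAF of the mutation
#' @param f depth thinning factor in (0, 1]
#' @param n_reps number of simulation replicates (default 1000)
#' @param method thinning form, see [saturation_observed()]
#' @param seed RNG seed
#' @return empirical retention frequency
#' @export
downsample_retention <- function(depth, vaf, f, n_reps = 1000,
                                 method = c("molecule", "redraw"), seed = 1) {
  method <- match.arg(method)
  set.seed(seed)
  mean(thin_keep(rep(depth, n_reps), rep(vaf, n_reps), f, method))
}

gene_site_alts <- function(panel, gene, classes = NULL) {
  sa <- dplyr::filter(panel$site_alts, .data$gene == !!gene)
  if (!is.null(classes)) sa <- dplyr::filter(sa, .data$consequence %in% classes)
  if (nrow(sa) == 0) stop("no panel substitutions for gene ", gene)
  sa
}

#' Compare theoretical and observed saturation curves
#'
#' @param theoretical output of [saturation_theoretical()]
#' @param observed output of [saturation_observed()]
#' @return one-row tibble: `gene`, `signed_area` (trapezoid integral of
#'   observed - theoretical over the grid, positive when the observed curve
#'   runs above, the positive-selection direction), `top_depth_diff`
#'   (difference at the deepest grid point) and `direction`
#' @export
saturation_compare <- function(theoretical, observed) {
  if (length(theoretical$depth) != length(observed$depth) ||
      any(abs(theoretical$depth - observed$depth) >
          1e-8 * pmax(1, theoretical$depth))) {
    stop("theoretical and observed curves use different depth grids")
  }
  diff <- observed$observed_mean - theoretical$theoretical
  x <- theoretical$depth
  area <- sum((diff[-1] + diff[-length(diff)]) / 2 * base::diff(x))
  top <- diff[length(diff)]
  tibble::tibble(
    gene = attr(theoretical, "gene") %||% NA_character_,
    signed_area = area,
    top_depth_diff = top,
    direction = dplyr::case_when(
      top > 0 ~ "positive_selection",
      top < 0 ~ "negative_selection",
      TRUE ~ "neutral"
    )
  )
}

#' @method autoplot saturation_curve
#' @export
autoplot.saturation_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as.data.frame(object),
    cols = dplyr::any_of(c("theoretical", "observed_mean")),
    names_to = "curve", values_to = "fraction"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$fraction,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cumulative depth (haploid genomes)",
                  y = "fraction of possible SNVs observed",
                  title = attr(object, "gene")) +
    ggplot2::theme_minimal()
}
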