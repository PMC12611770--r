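#' End-to-end pipeline over a cohort
#'
#' Runs the full analysis — neutral spectrum, cohort and per-sample dN/dS,
#' promoter-activation selection, frameshift-indel enrichment, site/residue
#' selection, saturation kinetics, clone fractions and covariate association
#' — and optionally writes every report as TSV together with a manifest of
#' output hashes and run parameters.
#'
#' @param panel a `duplex_panel`
#' @param mutations annotated mutation tibble
#' @param depth wide depth tibble
#' @param covariates covariates tibble
#' @param whitelist activating-mutation whitelist (or NULL to skip the
#'   promoter stage)
#' @param genes genes analysed (default: all coding genes of the panel)
#' @param saturation_genes genes for which saturation curves are computed
#'   (default: first analysed gene)
#' @param site_genes genes for which residue selection is scored (default:
#'   same as `saturation_genes`)
#' @param fdr association FDR threshold (default 0.2)
#' @param eligibility per-sample eligibility fraction (default 0.8)
#' @param seed seed for the downsampling stage
#' @param n_reps downsampling replicates
#' @param out_dir optional output directory for TSV reports + manifest
#' @return list of result tables: `spectrum`, `omega`, `ptert`, `indels`,
#'   `per_sample`, `eligibility`, `site_selection`, `saturation`,
#'   `clone_fractions`, `association`, `manifest`
#' @export
run_pipeline <- function(panel, mutations, depth, covariates,
                         whitelist = NULL, genes = NULL,
                         saturation_genes = NULL, site_genes = NULL,
                         fdr = 0.2, eligibility = 0.8, seed = 1, n_reps = 10,
                         out_dir = NULL) {
  if (is.null(genes)) {
    genes <- unique(panel$regions$gene[panel$regions$region_class == "coding"])
  }
  if (is.null(saturation_genes)) saturation_genes <- genes[1]
  if (is.null(site_genes)) site_genes <- saturation_genes

  spectrum <- fit_neutral_spectrum(mutations, panel, depth,
                                   exclude = whitelist)
  omega <- fit_omega(mutations, panel, depth, spectrum = spectrum,
                     genes = genes)
  ptert <- if (!is.null(whitelist)) {
    dnds_ptert(mutations, panel, depth, whitelist, spectrum = spectrum)
  } else NULL
  indels <- indel_enrichment(mutations, panel, depth, genes = genes)
  per_sample <- per_sample_omega(mutations, panel, depth, genes = genes,
                                 exclude = whitelist,
                                 eligibility = eligibility)

  sites <- purrr::map_dfr(site_genes, function(g) {
    site_selection(mutations, panel, depth, spectrum, g, unit = "residue")
  })

  saturation <- purrr::map_dfr(saturation_genes, function(g) {
    theo <- saturation_theoretical(panel, depth, spectrum, g)
    obs <- saturation_observed(mutations, panel, depth, g,
                               depth_grid = theo$depth, n_reps = n_reps,
                               seed = seed)
    dplyr::bind_cols(gene = g, theo,
                     obs[, c("observed_mean", "observed_sd")])
  })

  fractions <- clone_fractions(mutations, per_sample$results, genes = genes)

  responses <- build_responses(per_sample, mutations, panel, depth,
                               whitelist = whitelist)
  association <- associate_selection(responses, covariates, fdr = fdr)

  out <- list(
    spectrum = tibble::as_tibble(spectrum),
    omega = omega$results,
    ptert = ptert,
    indels = indels,
    per_sample = per_sample$results,
    eligibility = per_sample$eligibility,
    site_selection = sites,
    saturation = saturation,
    clone_fractions = fractions,
    association = association$results
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (nm in names(out)) {
      if (is.null(out[[nm]])) next
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      readr::write_tsv(as.data.frame(out[[nm]]), f)
      files <- c(files, f)
    }
    manifest <- tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files)),
      n_rows = purrr::map_int(out[!purrr::map_lgl(out, is.null)], nrow),
      seed = seed, fdr = fdr, eligibility = eligibility,
      package_version = as.character(utils::packageVersion("deepdnds"))
    )
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
    out$manifest <- manifest
  }
  out
}
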