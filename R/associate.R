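#' Association of clonal-landscape summaries with donor covariates
#'
#' Per-sample responses (mutation densities, per-sample dN/dS on the log
#' scale, activating promoter-mutation density) are regressed on donor
#' covariates with a donor-level random intercept (two samples per donor are
#' never independent). A two-step screen is used: univariate mixed models
#' identify candidate covariates, a multivariate mixed model (age, sex,
#' smoking, alcohol, BMI, chemotherapy) confirms them, and
#' Benjamini-Hochberg q-values are computed per response family with
#' significance called at FDR < 0.2. For the promoter activating-mutation
#' density the age x smoking interaction replaces the separate age and
#' smoking terms.
#'
#' @name associate
NULL

.COVARIATE_TERMS <- c("age_decades", "sex", "smoking", "alcohol",
                      "bmi_scaled", "chemo")

#' Build a per-sample response table
#'
#' @param per_sample output of [per_sample_omega()]
#' @param mutations annotated mutation tibble
#' @param panel a `duplex_panel`
#' @param depth wide depth tibble
#' @param whitelist optional activating-mutation whitelist; adds an
#'   activating promoter-mutation density response
#' @param log_offset offset added to dN/dS before taking logs (default 0.05)
#' @param eligible_only keep only (gene, class) responses computable for at
#'   least the eligibility fraction of samples (default TRUE)
#' @return long tibble: `sample_id`, `response`, `value`, plus a logical
#'   `interaction` marking responses modelled with the age x smoking
#'   interaction
#' @export
build_responses <- function(per_sample, mutations, panel, depth,
                            whitelist = NULL, log_offset = 0.05,
                            eligible_only = TRUE) {
  cols <- depth_sample_cols(depth)
  site_mb <- purrr::map_dbl(cols, function(s) sum(depth[[s]]) / 1e6)
  names(site_mb) <- cols

  res <- per_sample$results
  if (eligible_only) {
    keep <- per_sample$eligibility |>
      dplyr::filter(.data$eligible)
    res <- dplyr::semi_join(res, keep, by = c("gene", "mclass"))
  }
  dnds_resp <- res |>
    dplyr::filter(is.finite(.data$dnds)) |>
    dplyr::transmute(
      sample_id = .data$scope,
      response = stringr::str_c("dnds_", .data$mclass, ":", .data$gene),
      value = log(.data$dnds + log_offset),
      interaction = FALSE
    )

  prot <- c("missense", "nonsense", "essential_splice", "frameshift_indel",
            "inframe_indel")
  dens <- purrr::map_dfr(cols, function(s) {
    m <- mutations[mutations$sample_id == s, ]
    tibble::tibble(
      sample_id = s,
      response = c("density_protein_affecting", "density_non_protein_affecting"),
      value = c(sum(m$consequence %in% prot),
                sum(!(m$consequence %in% prot))) / site_mb[[s]],
      interaction = FALSE
    )
  })

  out <- dplyr::bind_rows(dnds_resp, dens)

  if (!is.null(whitelist) && nrow(whitelist) > 0) {
    wl_key <- stringr::str_c(whitelist$chrom, whitelist$pos, whitelist$alt,
                             sep = ":")
    prom_genes <- unique(
      panel$regions$gene[panel$regions$region_class == "promoter"]
    )
    prom_sites <- panel$sites |>
      dplyr::filter(.data$region_class == "promoter")
    prom_mb <- purrr::map_dbl(cols, function(s) {
      sum(site_depth(depth[, c("chrom", "pos", s)], prom_sites$chrom,
                     prom_sites$pos, s)) / 1e6
    })
    names(prom_mb) <- cols
    act <- purrr::map_dfr(cols, function(s) {
      m <- mutations[mutations$sample_id == s &
                       mutations$gene %in% prom_genes &
                       mutations$mut_type == "SNV", ]
      n_act <- sum(stringr::str_c(m$chrom, m$pos, m$alt, sep = ":") %in% wl_key)
      tibble::tibble(sample_id = s, response = "ptert_activating_density",
                     value = n_act / prom_mb[[s]], interaction = TRUE)
    })
    out <- dplyr::bind_rows(out, act)
  }
  out
}

#' Two-step mixed-effects association of responses with covariates
#'
#' @param responses long response tibble from [build_responses()] (columns
#'   `sample_id`, `response`, `value`, optional `interaction`)
#' @param covariates covariates tibble (see [read_covariates()])
#' @param design `"two_step"` (univariate screen then multivariate
#'   confirmation) or `"multivariate"` (multivariate only)
#' @param fdr significance threshold on BH q-values (default 0.2)
#' @param screen_p univariate screen threshold (default 0.05)
#' @return an `association_fit`: results tibble with one row per
#'   (response, term): `effect`, `ci_low`, `ci_high`, `p_univariate`,
#'   `p_value` (multivariate), `q_value` (BH within response family over
#'   screened candidates), `significant`, `n_samples`, `converged`
#' @export
associate_selection <- function(responses, covariates,
                                design = c("two_step", "multivariate"),
                                fdr = 0.2, screen_p = 0.05) {
  design <- match.arg(design)
  if (!"interaction" %in% names(responses)) responses$interaction <- FALSE
  cov <- covariates |>
    dplyr::mutate(
      sex = factor(.data$sex, levels = c("F", "M")),
      smoking = factor(.data$smoking, levels = c("never", "ever", "unknown"))
    )

  results <- responses |>
    dplyr::group_by(.data$response) |>
    dplyr::group_map(function(df, key) {
      fit_one_response(key$response, df, cov, design, screen_p,
                       interaction = any(df$interaction))
    }) |>
    dplyr::bind_rows()

  results <- results |>
    dplyr::group_by(.data$response) |>
    dplyr::mutate(
      q_value = bh_over_candidates(.data$p_value, .data$candidate,
                                   .data$converged)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$q_value) & .data$q_value < fdr)

  structure(list(results = results, design = design, fdr = fdr),
            class = "association_fit")
}

bh_over_candidates <- function(p, candidate, converged) {
  q <- rep(NA_real_, length(p))
  sel <- candidate & converged & !is.na(p)
  q[sel] <- stats::p.adjust(p[sel], method = "BH")
  q
}

fit_one_response <- function(resp_name, df, cov, design, screen_p,
                             interaction = FALSE) {
  dat <- dplyr::inner_join(df, cov, by = "sample_id")
  # unknown smoking history: excluded wherever smoking enters the model
  dat_smk <- dat[dat$smoking != "unknown", , drop = FALSE]
  dat_smk$smoking <- droplevels(dat_smk$smoking)

  terms <- if (interaction) {
    c("age_decades:smoking", "sex", "alcohol", "bmi_scaled", "chemo")
  } else {
    .COVARIATE_TERMS
  }

  uni <- purrr::map_dfr(terms, function(tm) {
    d <- if (grepl("smoking", tm)) dat_smk else dat
    f <- stats::as.formula(paste("value ~", tm, "+ (1 | donor_id)"))
    fit <- safe_lmer(f, d)
    extract_terms(fit, tm, step = "univariate", n = nrow(d))
  })

  d_multi <- dat_smk
  f_multi <- stats::as.formula(
    paste("value ~", paste(terms, collapse = " + "), "+ (1 | donor_id)")
  )
  multi_fit <- safe_lmer(f_multi, d_multi)
  multi <- extract_terms(multi_fit, terms, step = "multivariate",
                         n = nrow(d_multi))

  out <- multi |>
    dplyr::left_join(
      uni |> dplyr::select(term_label = "term_label",
                           p_univariate = "p_value"),
      by = "term_label"
    ) |>
    dplyr::mutate(
      response = resp_name,
      candidate = if (design == "two_step") {
        !is.na(.data$p_univariate) & .data$p_univariate < screen_p
      } else TRUE
    ) |>
    dplyr::select("response", term = "term_label", "effect", "ci_low",
                  "ci_high", "p_univariate", "p_value", "candidate",
                  "n_samples", "converged")
  out
}

safe_lmer <- function(formula, data) {
  tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(formula, data = data, REML = TRUE,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore",
                       check.nobs.vs.nlev = "ignore",
                       check.nobs.vs.rankZ = "ignore",
                       check.nobs.vs.nRE = "ignore"
                     ))
    )),
    error = function(e) NULL
  )
}

extract_terms <- function(fit, wanted, step, n) {
  if (is.null(fit)) {
    return(tibble::tibble(term_label = wanted, effect = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, n_samples = n,
                          converged = FALSE, step = step))
  }
  sm <- stats::coef(summary(fit))
  rows <- rownames(sm)
  purrr::map_dfr(wanted, function(tm) {
    # match model-matrix labels (sexM, smokingever, age_decades:smokingever)
    base <- gsub(":", ".*:", gsub("smoking", "smoking(ever)?", tm))
    hit <- rows[grepl(paste0("^", gsub("sex", "sex(M)?", base)), rows)]
    hit <- setdiff(hit, "(Intercept)")
    if (length(hit) == 0) {
      return(tibble::tibble(term_label = tm, effect = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p_value = NA_real_, n_samples = n,
                            converged = FALSE, step = step))
    }
    h <- hit[1]
    est <- sm[h, "Estimate"]
    se <- sm[h, "Std. Error"]
    p <- sm[h, "Pr(>|t|)"]
    tibble::tibble(term_label = tm, effect = est,
                   ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                   p_value = p, n_samples = n, converged = TRUE, step = step)
  })
}

#' @method print association_fit
#' @export
print.association_fit <- function(x, ...) {
  cat("<association_fit> design:", x$design, "- FDR threshold:", x$fdr, "\n")
  print(dplyr::filter(x$results, .data$significant), n = 20)
  invisible(x)
}

#' @method tidy association_fit
#' @export
tidy.association_fit <- function(x, ...) x$results

#' @method glance association_fit
#' @export
glance.association_fit <- function(x, ...) {
  tibble::tibble(
    n_responses = length(unique(x$results$response)),
    n_terms = nrow(x$results),
    n_significant = sum(x$results$significant, na.rm = TRUE),
    n_non_converged = sum(!x$results$converged)
  )
}
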