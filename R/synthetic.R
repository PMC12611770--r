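#' Synthetic duplex-sequencing cohorts with known ground truth
#'
#' Generates a complete cohort — panel regions, reference sequence,
#' site-by-sample duplex depth, mutation catalog, donor covariates,
#' promoter whitelist and a truth table of every injected parameter — from a
#' generative model mirroring the inference model: neutral counts per
#' (site, alt, sample) are Poisson with rate channel-weight x depth,
#' protein-affecting classes are inflated by gene- and class-specific
#' selection multipliers (modulated by donor covariates and a donor frailty),
#' promoter whitelist sites by an activation multiplier with an age x smoking
#' dependence, and VAFs follow a truncated power-law clone-size law.
#'
#' The default configuration emulates the study conditions of an ultradeep
#' bladder-urothelium cohort: 45 donors (34 with two samples, dome and
#' trigone; 79 samples), median depth ~5,164 haploid genomes, a
#' 111,876-bp panel (65,086 bp coding across 15 genes plus a 590-bp
#' promoter block), a 3-component trinucleotide signature mixture
#' (APOBEC-like, ageing-like with age-dependent loading, flat) and ~774
#' detected mutations per sample at median depth.
#'
#' @name synthetic_data
NULL

#' Default synthetic gene table and covariate effects
#'
#' The default panel emulates a 16-target bladder panel: 12 complete coding
#' genes, 3 partial fragments and a promoter block, with gene-level selection
#' multipliers on missense, truncating and frameshift-indel classes.
#'
#' @return tibble of gene definitions / covariate effect definitions
#' @export
default_gene_table <- function() {
  tibble::tribble(
    ~gene,     ~cds_length, ~complete, ~frame_anchor, ~strand,
    ~omega_missense, ~omega_truncating, ~omega_indel,
    "ARID1A",   6858, TRUE,  0L, "+", 1.5,  8,   5,
    "NOTCH2",   7416, TRUE,  0L, "+", 1.5,  3,   2,
    "FOXQ1",    1209, TRUE,  0L, "+", 2.0,  4,   2,
    "CDKN1A",    495, TRUE,  0L, "+", 2.0, 15,   8,
    "KMT2D",   17283, TRUE,  0L, "+", 1.5,  4,   3,
    "RB1",      2787, TRUE,  0L, "+", 1.5,  5,   3,
    "CREBBP",   7329, TRUE,  0L, "+", 1.5,  3,   2,
    "TP53",     1182, TRUE,  0L, "-", 5.0, 10,   6,
    "EP300",    7245, TRUE,  0L, "+", 1.5,  3,   2,
    "KDM6A",    4206, TRUE,  0L, "+", 1.5,  6,   4,
    "RBM10",    2892, TRUE,  0L, "-", 2.0, 20,  10,
    "STAG2",    3786, TRUE,  0L, "+", 1.5, 10,   6,
    "PIK3CA",    699, FALSE, 1L, "+", 3.0,  1,   1,
    "FGFR3",     800, FALSE, 2L, "+", 1.0,  0.3, 0.3,
    "KMT2C",     899, FALSE, 1L, "+", 2.0,  2,   2
  )
}

#' @rdname default_gene_table
#' @export
default_covariate_effects <- function() {
  tibble::tribble(
    ~gene,    ~mclass,      ~covariate, ~beta,
    "RBM10",  "truncating", "sexM",     0.5,
    "CDKN1A", "truncating", "sexM",     0.5,
    "ARID1A", "truncating", "sexM",     0.5
  )
}

#' Configuration of a synthetic cohort
#'
#' @param seed RNG seed (generation is bit-reproducible given the seed)
#' @param n_donors number of donors (default 45)
#' @param paired_fraction fraction of donors with both dome and trigone
#'   samples (default 34/45)
#' @param genes gene table: `gene`, `cds_length`, `complete`,
#'   `frame_anchor`, `strand`, `omega_missense`, `omega_truncating`,
#'   `omega_indel`
#' @param flank_length intronic flank on each side of a coding block (bp)
#' @param promoter_length promoter block length (bp)
#' @param n_whitelist number of whitelisted activating promoter substitutions
#' @param activation_multiplier baseline rate multiplier on whitelist
#'   substitutions
#' @param activation_age_smoking log-scale increment of the activation
#'   multiplier per (age decade above 6) in ever-smokers
#' @param depth_median median per-sample mean depth (haploid genomes)
#' @param depth_sdlog lognormal sd of per-sample mean depth
#' @param site_jitter_sd lognormal sd of per-site capture efficiency
#' @param target_muts_per_sample expected detected mutations in a sample at
#'   median depth under neutrality
#' @param signature_weights mixture weights (APOBEC-like, ageing-like, flat)
#' @param ageing_age_slope relative increase of the ageing-like weight per
#'   age decade above 6
#' @param density_age_beta log-scale increase of overall mutation rate per
#'   age decade above 6
#' @param rate_frailty_sd donor-level lognormal frailty on mutation rate
#' @param selection_frailty_sd donor-level lognormal frailty on the excess
#'   selection strength (omega - 1)
#' @param covariate_effects tibble `gene`, `mclass`, `covariate`
#'   (`sexM` or `age_decades`), `beta`: log-scale multipliers on (omega - 1)
#' @param clone_alpha Pareto tail exponent of the latent clone-fraction law
#' @param clone_w_min lower truncation of latent clone fractions; far below
#'   the single-molecule detection limit, so most detected mutations are
#'   single-molecule, as in real ultradeep duplex data
#' @param clone_w_max upper truncation of latent clone fractions (default
#'   0.25)
#' @param all_molecules_factor total (duplex + non-duplex) molecule count as
#'   a multiple of duplex depth; used for the all-molecules VAF
#' @param indel_rate_frac frameshift+inframe indel rate per coding
#'   site-genome, as a fraction of the mean per-site SNV rate
#' @param splice_window intronic bases treated as essential splice
#' @return a `cohort_config` list
#' @export
cohort_config <- function(seed = 1,
                          n_donors = 45,
                          paired_fraction = 34 / 45,
                          genes = default_gene_table(),
                          flank_length = 1540,
                          promoter_length = 590,
                          n_whitelist = 12,
                          activation_multiplier = 15,
                          activation_age_smoking = 0.22,
                          depth_median = 5164,
                          depth_sdlog = 0.4,
                          site_jitter_sd = 0.1,
                          target_muts_per_sample = 774,
                          signature_weights = c(apobec = 0.35, ageing = 0.45,
                                                flat = 0.20),
                          ageing_age_slope = 0.15,
                          density_age_beta = 0.08,
                          rate_frailty_sd = 0.25,
                          selection_frailty_sd = 0.2,
                          covariate_effects = default_covariate_effects(),
                          clone_alpha = 2,
                          clone_w_min = 2e-5,
                          clone_w_max = 0.25,
                          all_molecules_factor = 2.5,
                          indel_rate_frac = 0.05,
                          splice_window = 2) {
  stopifnot(n_donors >= 1, all(genes$cds_length > 0),
            abs(sum(signature_weights) - 1) < 1e-9,
            all(genes$omega_missense > 0), all(genes$omega_truncating > 0))
  if (n_whitelist * 1 > promoter_length * 3) {
    stop("whitelist larger than the promoter allows")
  }
  structure(as.list(environment()), class = "cohort_config")
}

signature_profiles <- function() {
  ch <- all_channels()
  flat <- rep(1, 96)
  apobec <- rep(0.5, 96)
  apobec[ch %in% c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T")] <- 8
  ageing <- rep(0.5, 96)
  ageing[grepl("\\[C>T\\]G$", ch)] <- 8
  ageing[grepl("\\[C>T\\]", ch) & !grepl("\\[C>T\\]G$", ch)] <- 2.5
  m <- cbind(apobec = apobec / sum(apobec), ageing = ageing / sum(ageing),
             flat = flat / sum(flat))
  rownames(m) <- ch
  m
}

nonstop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_cds <- function(n_codons) {
  cods <- sample(nonstop_codons(), n_codons, replace = TRUE)
  paste0(cods, collapse = "")
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Panel geometry and reference sequence of a synthetic cohort
#'
#' Builds the regions table and reference contigs implied by a
#' [cohort_config()] without simulating any samples: each gene contig holds
#' an intronic flank, the (possibly partial) CDS and a second flank, plus a
#' promoter contig. Called internally by [generate_cohort()].
#'
#' @param config a `cohort_config`
#' @return list with `regions` (tibble) and `reference` (named character)
#' @export
synthetic_regions <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pad <- 10L
  genes <- config$genes
  regs <- list()
  refs <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene[i]
    chrom <- paste0("chr_", g)
    fl <- config$flank_length
    cds_len <- genes$cds_length[i]
    if (genes$complete[i]) {
      n_cod <- cds_len / 3L
      stopifnot(n_cod == round(n_cod))
      body <- paste0("ATG", random_cds(n_cod - 2L), "TAA")
    } else {
      # fragment cut mid-codon: the frame anchor points into a codon whose
      # missing bases lie in the upstream flank, completable genomically
      stream <- random_cds(ceiling((cds_len + 6) / 3))
      body <- substring(stream, 1, cds_len)
    }
    body_genomic <- if (genes$strand[i] == "-") revcomp_str(body) else body
    left <- substring(random_cds(ceiling((pad + fl) / 3)), 1, pad + fl)
    right <- substring(random_cds(ceiling((pad + fl) / 3)), 1, pad + fl)
    seq <- paste0(left, body_genomic, right)
    refs[chrom] <- seq
    cds_start <- pad + fl
    regs[[length(regs) + 1]] <- tibble::tibble(
      chrom = chrom,
      start = c(pad, cds_start, cds_start + cds_len),
      end = c(cds_start, cds_start + cds_len, cds_start + cds_len + fl),
      gene = g,
      region_class = c("intronic_flank", "coding", "intronic_flank"),
      strand = genes$strand[i],
      frame_anchor = c(NA_integer_, genes$frame_anchor[i], NA_integer_)
    )
  }
  prom_chrom <- "chr_TERT"
  prom_len <- config$promoter_length
  prom_seq <- substring(random_cds(ceiling((prom_len + 2 * pad) / 3)), 1,
                        prom_len + 2 * pad)
  refs[prom_chrom] <- prom_seq
  regs[[length(regs) + 1]] <- tibble::tibble(
    chrom = prom_chrom, start = pad, end = pad + prom_len, gene = "TERT",
    region_class = "promoter", strand = "+", frame_anchor = NA_integer_
  )
  list(regions = dplyr::bind_rows(regs), reference = refs)
}

#' Generate a complete synthetic cohort
#'
#' @param config a [cohort_config()]
#' @return a `synthetic_cohort` list: `config`, `regions`, `reference`,
#'   `panel` (annotated via [build_panel()]), `depth` (wide tibble),
#'   `mutations` (catalog with the generator's own consequence labels),
#'   `covariates`, `whitelist`, `truth` (long tibble of injected parameters
#'   and per-sample expectations)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  geom <- synthetic_regions(config)
  regions <- geom$regions
  refs <- geom$reference
  genes <- config$genes

  # generator-side site/alt table with its own consequence labels
  sa <- generator_site_alts(regions, refs, genes, config$splice_window)

  # ---- donors, samples, covariates ----
  nd <- config$n_donors
  donors <- sprintf("D%02d", seq_len(nd))
  age <- round(stats::runif(nd, 3.0, 9.5), 1)
  sex <- sample(c("M", "F"), nd, replace = TRUE)
  smoking <- sample(c("ever", "never"), nd, replace = TRUE, prob = c(.55, .45))
  if (nd >= 10) smoking[sample(nd, 1)] <- "unknown"
  alcohol <- stats::rbinom(nd, 1, 0.5)
  bmi <- round(stats::runif(nd), 2)
  chemo <- stats::rbinom(nd, 1, 0.2)
  n_paired <- round(config$paired_fraction * nd)
  paired <- c(rep(TRUE, n_paired), rep(FALSE, nd - n_paired))
  covariates <- purrr::map_dfr(seq_len(nd), function(i) {
    locs <- if (paired[i]) c("dome", "trigone") else sample(c("dome", "trigone"), 1)
    tibble::tibble(
      sample_id = paste0(donors[i], "_", substr(locs, 1, 1)),
      donor_id = donors[i], location = locs,
      age_decades = age[i], sex = sex[i], smoking = smoking[i],
      alcohol = alcohol[i], bmi_scaled = bmi[i], chemo = chemo[i]
    )
  })
  samples <- covariates$sample_id
  ns <- length(samples)

  # ---- depth model ----
  n_sites <- sum(regions$end - regions$start)
  site_eff <- exp(stats::rnorm(n_sites, 0, config$site_jitter_sd))
  samp_mean <- config$depth_median *
    exp(stats::rnorm(ns, 0, config$depth_sdlog))
  depth_mat <- round(outer(site_eff, samp_mean))
  depth_mat[depth_mat < 8] <- 8
  site_keys <- sa |> dplyr::distinct(.data$chrom, .data$pos)
  stopifnot(nrow(site_keys) == n_sites)
  depth <- dplyr::bind_cols(
    site_keys,
    tibble::as_tibble(as.data.frame(depth_mat, col.names = samples))
  )
  names(depth) <- c("chrom", "pos", samples)

  # ---- promoter whitelist ----
  prom_sa <- which(sa$region_class == "promoter")
  wl_idx <- sample(prom_sa, config$n_whitelist)
  whitelist <- sa[wl_idx, c("chrom", "pos", "alt")]

  # ---- per-site-alt latent clone-rate machinery ----
  # mutations arise as latent clones with fraction w from a truncated Pareto
  # law reaching far below the detection limit; a clone is detected when at
  # least one of the d sampled molecules carries it (k ~ Poisson(w d), k >= 1)
  # and its duplex VAF is the measured k/d
  profiles <- signature_profiles()
  ch_idx <- match(sa$channel, rownames(profiles))
  site_idx <- match(stringr::str_c(sa$chrom, sa$pos, sep = ":"),
                    stringr::str_c(site_keys$chrom, site_keys$pos, sep = ":"))
  w_mc <- rpareto_trunc(20000, config$clone_alpha, config$clone_w_min,
                        config$clone_w_max)
  pbar <- function(d) {
    vapply(d, function(x) mean(1 - exp(-w_mc * x)), numeric(1))
  }
  d_grid <- exp(seq(log(max(1, min(depth_mat))), log(max(depth_mat)),
                    length.out = 40))
  pbar_fun <- stats::approxfun(log(d_grid), pbar(d_grid), rule = 2)
  pbar_at <- function(d) pbar_fun(log(pmax(d, 1)))
  # detected-mutation rate per (site, alt) at median depth calibrates the
  # latent clone rate nu
  theta <- config$target_muts_per_sample /
    (nrow(sa) * pbar_at(config$depth_median))

  # donor-level frailties
  rate_frail <- exp(stats::rnorm(nd, 0, config$rate_frailty_sd))
  sel_frail <- exp(stats::rnorm(nd, 0, config$selection_frailty_sd))
  names(rate_frail) <- names(sel_frail) <- donors

  # selection groups: gene x class
  cls <- dplyr::case_when(
    sa$consequence %in% c("nonsense", "essential_splice") ~ "truncating",
    sa$consequence == "missense" ~ "missense",
    TRUE ~ "neutral"
  )
  grp_key <- stringr::str_c(sa$gene, cls, sep = "|")
  grp_levels <- unique(grp_key)
  grp_idx <- match(grp_key, grp_levels)
  is_wl <- seq_len(nrow(sa)) %in% wl_idx

  cov_eff <- config$covariate_effects

  omega_for <- function(gene, mclass, donor_row) {
    base <- if (mclass == "missense") {
      genes$omega_missense[match(gene, genes$gene)]
    } else {
      genes$omega_truncating[match(gene, genes$gene)]
    }
    if (is.na(base)) return(1)
    # purging selection (omega < 1) is kept fixed: the excess-multiplier
    # modulation below is only meaningful for selection above neutrality and
    # would otherwise drive rates negative
    if (base <= 1) return(base)
    eff <- cov_eff[cov_eff$gene == gene & cov_eff$mclass == mclass, ]
    lin <- 0
    if (nrow(eff) > 0) {
      for (j in seq_len(nrow(eff))) {
        x <- switch(eff$covariate[j],
                    sexM = as.numeric(donor_row$sex == "M"),
                    age_decades = donor_row$age_decades - 6,
                    0)
        lin <- lin + eff$beta[j] * x
      }
    }
    1 + (base - 1) * exp(lin) * sel_frail[[donor_row$donor_id]]
  }

  # ---- draw SNVs per sample ----
  mix_norm <- tabulate(ch_idx, 96)
  all_rows <- vector("list", ns)
  expected_snv <- numeric(ns)
  expected_snv_distinct <- numeric(ns)
  for (si in seq_len(ns)) {
    srow <- covariates[si, ]
    d_id <- srow$donor_id
    # signature mixture with age-dependent ageing-like loading
    w <- config$signature_weights
    w["ageing"] <- w["ageing"] *
      max(0.1, 1 + config$ageing_age_slope * (srow$age_decades - 6))
    w <- w / sum(w)
    mix <- as.numeric(profiles %*% w)
    mean_mix <- sum(mix * mix_norm) / nrow(sa)
    rho <- mix[ch_idx] / mean_mix

    dens_mult <- rate_frail[[d_id]] *
      exp(config$density_age_beta * (srow$age_decades - 6))

    gmult <- vapply(grp_levels, function(k) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      if (parts[2] == "neutral") 1 else omega_for(parts[1], parts[2], srow)
    }, numeric(1))

    act <- 1 + (config$activation_multiplier - 1) *
      exp(config$activation_age_smoking * (srow$age_decades - 6) *
            as.numeric(srow$smoking == "ever"))

    d_s <- depth_mat[site_idx, si]
    # latent clone rate per (site, alt); depth enters through detection only
    lam_lat <- theta * rho * dens_mult * gmult[grp_idx]
    lam_lat[is_wl] <- lam_lat[is_wl] * act
    p_det <- pbar_at(d_s)
    lam_det <- lam_lat * p_det
    expected_snv[si] <- sum(lam_det)
    # recurrent identical detected variants in one sample collapse into one
    # catalog row
    expected_snv_distinct[si] <- sum(1 - exp(-lam_det))

    n_lat <- stats::rpois(length(lam_lat), lam_lat)
    hit <- which(n_lat > 0)
    if (length(hit) == 0) next
    rep_idx <- rep(hit, n_lat[hit])
    w <- rpareto_trunc(length(rep_idx), config$clone_alpha,
                       config$clone_w_min, config$clone_w_max)
    d_evt <- d_s[rep_idx]
    k <- stats::rpois(length(rep_idx), w * d_evt)
    det <- k >= 1
    if (!any(det)) next
    df <- tibble::tibble(idx = rep_idx[det], w = w[det], k = k[det],
                         d = d_evt[det]) |>
      dplyr::group_by(.data$idx) |>
      dplyr::summarise(w = sum(.data$w), k = sum(.data$k), d = .data$d[1],
                       .groups = "drop")
    k_extra <- stats::rpois(nrow(df),
                            (config$all_molecules_factor - 1) * df$w * df$d)
    rows <- sa[df$idx, c("chrom", "pos", "ref", "alt", "gene",
                         "consequence", "protein_pos")]
    rows$sample_id <- srow$sample_id
    rows$donor_id <- d_id
    rows$mut_type <- "SNV"
    rows$vaf_duplex <- pmin(df$k / df$d, 1)
    rows$vaf_all_molecules <- pmin((df$k + k_extra) /
                                     (config$all_molecules_factor * df$d), 1)
    rows$w_truth <- pmin(df$w, 1)
    all_rows[[si]] <- rows
  }
  snvs <- dplyr::bind_rows(all_rows)

  # ---- indels in coding regions ----
  theta_detected <- theta * pbar_at(config$depth_median)
  indels <- draw_indels(sa, depth_mat, site_idx, covariates, genes, config,
                        theta_detected, rate_frail, refs)
  if (!is.null(indels) && nrow(indels) > 0) indels$w_truth <- NA_real_

  mutations <- dplyr::bind_rows(snvs, indels) |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos) |>
    dplyr::select("sample_id", "donor_id", "chrom", "pos", "ref", "alt",
                  "mut_type", "vaf_duplex", "vaf_all_molecules", "gene",
                  "consequence", "protein_pos", "w_truth")

  # ---- truth table ----
  truth <- dplyr::bind_rows(
    genes |>
      tidyr::pivot_longer(dplyr::starts_with("omega_"), names_to = "param",
                          values_to = "value") |>
      dplyr::transmute(record = "selection", gene = .data$gene,
                       param = .data$param, value = .data$value),
    cov_eff |>
      dplyr::transmute(record = "covariate_effect", gene = .data$gene,
                       param = stringr::str_c(.data$mclass, ":", .data$covariate),
                       value = .data$beta),
    tibble::tibble(record = "global", gene = NA_character_,
                   param = c("theta", "seed", "activation_multiplier",
                             "activation_age_smoking", "density_age_beta"),
                   value = c(theta, config$seed, config$activation_multiplier,
                             config$activation_age_smoking,
                             config$density_age_beta)),
    tibble::tibble(record = "expected_snv_per_sample", gene = samples,
                   param = "expected_snv", value = expected_snv),
    tibble::tibble(record = "expected_snv_per_sample", gene = samples,
                   param = "expected_snv_distinct",
                   value = expected_snv_distinct)
  )

  panel <- build_panel(regions, refs, splice_window = config$splice_window)

  structure(
    list(config = config, regions = regions, reference = refs, panel = panel,
         depth = depth, mutations = mutations, covariates = covariates,
         whitelist = whitelist, truth = truth),
    class = "synthetic_cohort"
  )
}

#' @method print synthetic_cohort
#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$covariates), " samples / ",
      length(unique(x$covariates$donor_id)), " donors, ",
      nrow(x$mutations), " mutations, panel ",
      sum(x$regions$end - x$regions$start), " bp\n", sep = "")
  invisible(x)
}

# truncated Pareto sampler via inverse CDF (vectorised over vmin)
rpareto_trunc <- function(n, alpha, vmin, vmax) {
  vmin <- pmin(vmin, vmax * 0.999)
  u <- stats::runif(n)
  a <- vmin^(-alpha)
  b <- vmax^(-alpha)
  (a - u * (a - b))^(-1 / alpha)
}

# generator-side annotation: assembles each gene's CDS string and classifies
# every substitution by translating the affected codon slice of that string
# (a deliberately separate code path from the panel annotator's genomic
# codon arithmetic)
generator_site_alts <- function(regions, refs, genes, splice_window) {
  out <- list()
  gc_tab <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    pos <- seq(r$start, r$end - 1)
    seq <- refs[[r$chrom]]
    ref_b <- strsplit(substring(seq, r$start + 1, r$end), "")[[1]]
    base_tbl <- tibble::tibble(
      chrom = r$chrom, pos = pos, ref = ref_b, gene = r$gene,
      region_class = r$region_class, strand = r$strand
    )
    alts <- lapply(ref_b, function(b) setdiff(c("A", "C", "G", "T"), b))
    rep3 <- rep(seq_along(pos), lengths(alts))
    sa <- base_tbl[rep3, ]
    sa$alt <- unlist(alts)
    sa$protein_pos <- NA_integer_

    if (r$region_class == "coding") {
      f <- r$frame_anchor
      cds_g_start <- r$start - ifelse(r$strand == "+", f, 0)
      cds_g_end <- r$end + ifelse(r$strand == "+", 0, f)
      len <- cds_g_end - cds_g_start
      padn <- (3 - len %% 3) %% 3
      if (r$strand == "+") {
        cds_g_end <- cds_g_end + padn
        cds <- substring(seq, cds_g_start + 1, cds_g_end)
        idx_in_cds <- sa$pos - cds_g_start
        alt_in_cds <- sa$alt
      } else {
        cds_g_start <- cds_g_start - padn
        cds <- revcomp_str(substring(seq, cds_g_start + 1, cds_g_end))
        idx_in_cds <- cds_g_end - 1 - sa$pos
        alt_in_cds <- complement_base(sa$alt)
      }
      codon_i <- idx_in_cds %/% 3
      off <- idx_in_cds %% 3
      codon <- substring(cds, codon_i * 3 + 1, codon_i * 3 + 3)
      mut_codon <- codon
      substr(mut_codon, off + 1, off + 1) <- alt_in_cds
      ref_aa <- unname(gc_tab[codon])
      alt_aa <- unname(gc_tab[mut_codon])
      cons <- ifelse(is.na(ref_aa) | is.na(alt_aa), "missense",
                     ifelse(ref_aa == alt_aa, "synonymous",
                            ifelse(alt_aa == "*", "nonsense", "missense")))
      sa$consequence <- cons
      sa$protein_pos <- codon_i + 1L
    } else if (r$region_class == "promoter") {
      sa$consequence <- "noncoding"
    } else {
      sa$consequence <- "noncoding"
    }
    out[[i]] <- sa
  }
  sa <- dplyr::bind_rows(out)

  # essential splice: intronic bases within splice_window of a coding edge
  cod <- regions[regions$region_class == "coding", ]
  for (j in seq_len(nrow(cod))) {
    w <- splice_window
    spl <- c(seq(cod$start[j] - w, cod$start[j] - 1),
             seq(cod$end[j], cod$end[j] + w - 1))
    hit <- sa$chrom == cod$chrom[j] & sa$pos %in% spl &
      sa$region_class == "intronic_flank"
    sa$consequence[hit] <- "essential_splice"
  }

  # channel labels from raw context
  up <- fetch_bases(refs, sa$chrom, sa$pos - 1)
  down <- fetch_bases(refs, sa$chrom, sa$pos + 1)
  coll <- collapse_channel(stringr::str_c(up, sa$ref, down), sa$alt)
  sa$channel <- coll$channel
  sa
}

draw_indels <- function(sa, depth_mat, site_idx, covariates, genes, config,
                        theta_detected, rate_frail, refs) {
  coding_sites <- sa[sa$region_class == "coding", ] |>
    dplyr::distinct(.data$chrom, .data$pos, .data$gene, .data$ref)
  if (nrow(coding_sites) == 0) return(NULL)
  cs_idx <- match(stringr::str_c(coding_sites$chrom, coding_sites$pos,
                                 sep = ":"),
                  stringr::str_c(sa$chrom, sa$pos, sep = ":"))
  site_of <- site_idx[cs_idx]
  # detected indel rate per coding site-genome
  rate0 <- theta_detected * 3 * config$indel_rate_frac
  omega_ind <- genes$omega_indel[match(coding_sites$gene, genes$gene)]
  omega_ind[is.na(omega_ind)] <- 1

  # detected-VAF sampler: latent w conditioned on >= 1 supporting molecule
  draw_detected_vaf <- function(d) {
    n <- length(d)
    k <- integer(n)
    w <- numeric(n)
    todo <- seq_len(n)
    while (length(todo) > 0) {
      w[todo] <- rpareto_trunc(length(todo), config$clone_alpha,
                               config$clone_w_min, config$clone_w_max)
      k[todo] <- stats::rpois(length(todo), w[todo] * d[todo])
      todo <- todo[k[todo] < 1]
    }
    pmin(k / d, 1)
  }

  rows <- list()
  for (si in seq_len(nrow(covariates))) {
    srow <- covariates[si, ]
    # depth enters relative to the calibration depth (rate0 is the detected
    # rate per coding site in a median-depth sample)
    d_rel <- depth_mat[site_of, si] / config$depth_median
    # frameshift portion carries the selection multiplier, inframe is neutral
    lam_fs <- rate0 * 0.8 * d_rel * rate_frail[[srow$donor_id]] * omega_ind
    lam_if <- rate0 * 0.2 * d_rel * rate_frail[[srow$donor_id]]
    k_fs <- stats::rpois(length(lam_fs), lam_fs)
    k_if <- stats::rpois(length(lam_if), lam_if)
    mk <- function(hit, lens, cons) {
      if (length(hit) == 0) return(NULL)
      cs <- coding_sites[hit, ]
      d_hit <- depth_mat[site_of[hit], si]
      vaf <- draw_detected_vaf(pmax(d_hit, 8))
      del <- stats::runif(length(hit)) < 0.5
      ref_str <- alt_str <- character(length(hit))
      for (q in seq_along(hit)) {
        L <- lens[q]
        anchor <- cs$ref[q]
        if (del[q]) {
          ext <- fetch_bases(refs, rep(cs$chrom[q], L), cs$pos[q] + seq_len(L))
          ref_str[q] <- paste0(anchor, paste0(ext, collapse = ""))
          alt_str[q] <- anchor
        } else {
          ins <- paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = "")
          ref_str[q] <- anchor
          alt_str[q] <- paste0(anchor, ins)
        }
      }
      tibble::tibble(
        chrom = cs$chrom, pos = cs$pos, ref = ref_str, alt = alt_str,
        gene = cs$gene, consequence = cons, protein_pos = NA_integer_,
        sample_id = srow$sample_id, donor_id = srow$donor_id,
        mut_type = ifelse(del, "deletion", "insertion"),
        vaf_duplex = pmin(vaf, 1),
        vaf_all_molecules = pmin(vaf * exp(stats::rnorm(length(hit), 0, 0.05)), 1)
      )
    }
    fs_hit <- which(k_fs > 0)
    if_hit <- which(k_if > 0)
    rows[[length(rows) + 1]] <- mk(fs_hit,
                                   sample(c(1L, 2L), length(fs_hit),
                                          replace = TRUE),
                                   "frameshift_indel")
    rows[[length(rows) + 1]] <- mk(if_hit, rep(3L, length(if_hit)),
                                   "inframe_indel")
  }
  dplyr::bind_rows(rows)
}

#' Write a synthetic cohort to standard files
#'
#' Emits `panel.bed`, `reference.fa`, `depth.tsv`, `mutations.tsv`,
#' `covariates.tsv`, `whitelist.tsv` and `truth.tsv` under `dir`.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(cohort$panel, file.path(dir, "panel.bed"),
              file.path(dir, "reference.fa"))
  write_depth(cohort$depth, file.path(dir, "depth.tsv"))
  write_mutations(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_covariates(cohort$covariates, file.path(dir, "covariates.tsv"))
  write_whitelist(cohort$whitelist, file.path(dir, "whitelist.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a cohort back from files written by [write_cohort()]
#'
#' @param dir directory holding the cohort files
#' @param splice_window passed to [read_panel()]
#' @return list with `panel`, `depth`, `mutations` (re-annotated against the
#'   panel), `covariates`, `whitelist`, `truth`
#' @export
read_cohort <- function(dir, splice_window = 2) {
  panel <- read_panel(file.path(dir, "panel.bed"),
                      file.path(dir, "reference.fa"),
                      splice_window = splice_window)
  depth <- read_depth(file.path(dir, "depth.tsv"))
  covariates <- read_covariates(file.path(dir, "covariates.tsv"))
  mutations <- read_mutations(file.path(dir, "mutations.tsv"), panel,
                              samples = covariates$sample_id)
  whitelist <- read_whitelist(file.path(dir, "whitelist.tsv"))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           col_types = "cccd", progress = FALSE)
  list(panel = panel, depth = depth, mutations = mutations,
       covariates = covariates, whitelist = whitelist, truth = truth)
}
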