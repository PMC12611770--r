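#' Mutation catalogs, depth tracks, covariates and whitelists
#'
#' A mutation catalog is a tibble with one row per called somatic variant per
#' sample: `sample_id`, `donor_id`, `chrom`, `pos` (0-based), `ref`, `alt`,
#' `mut_type` (`SNV`, `MNV`, `insertion`, `deletion`), `vaf_duplex`,
#' `vaf_all_molecules`. Annotation against a panel adds `gene`,
#' `consequence` and `protein_pos`. Depth is a wide tibble (`chrom`, `pos`,
#' one column per sample, in haploid genomes). Covariates hold one row per
#' sample with donor-level clinical features.
#'
#' @name catalog
NULL

.CONSEQUENCE_SEVERITY <- c(
  nonsense = 5, essential_splice = 4, missense = 3,
  synonymous = 2, noncoding = 1
)

#' Read a mutation catalog and annotate it against a panel
#'
#' Records with a VAF outside (0, 1] and SNV/MNV records at positions not
#' covered by the panel are rejected (a message reports how many); an unknown
#' sample identifier is an error when `samples` is supplied.
#'
#' @param path TSV with the catalog columns (see [catalog])
#' @param panel a `duplex_panel`
#' @param samples optional character vector of valid sample ids
#' @return annotated tibble of accepted records; the number of rejected rows
#'   is attached as attribute `n_rejected`
#' @export
read_mutations <- function(path, panel, samples = NULL) {
  muts <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", donor_id = "c", chrom = "c", pos = "i",
    ref = "c", alt = "c", mut_type = "c", gene = "c", consequence = "c",
    protein_pos = "i", .default = "d"
  ), progress = FALSE)
  annotate_mutations(muts, panel, samples = samples)
}

#' Write a mutation catalog to TSV
#' @param mutations mutation tibble
#' @param path output path
#' @export
write_mutations <- function(mutations, path) {
  core <- c("sample_id", "donor_id", "chrom", "pos", "ref", "alt",
            "mut_type", "vaf_duplex", "vaf_all_molecules")
  readr::write_tsv(mutations[, intersect(c(core, "gene", "consequence",
                                           "protein_pos"), names(mutations))],
                   path)
  invisible(path)
}

#' Annotate mutation records against a panel
#'
#' SNVs take the consequence of their (site, alt) in the panel; MNVs are
#' counted as single events with the worst consequence of their constituent
#' substitutions; indels within coding regions are `frameshift_indel` when
#' their length is not a multiple of 3, `inframe_indel` otherwise, and
#' `noncoding` outside coding regions.
#'
#' @param mutations tibble of raw records
#' @param panel a `duplex_panel`
#' @param samples optional character vector of valid sample ids
#' @return annotated tibble (rejected rows dropped; count in attribute
#'   `n_rejected`)
#' @export
annotate_mutations <- function(mutations, panel, samples = NULL) {
  if (!is.null(samples)) {
    unknown <- setdiff(unique(mutations$sample_id), samples)
    if (length(unknown) > 0) {
      stop("unknown sample id(s) in catalog: ", paste(unknown, collapse = ", "))
    }
  }
  m <- mutations
  if (!"mut_type" %in% names(m)) m$mut_type <- NA_character_
  m$mut_type <- dplyr::coalesce(m$mut_type, classify_mut_type(m$ref, m$alt))

  bad_vaf <- !is.finite(m$vaf_duplex) | m$vaf_duplex <= 0 | m$vaf_duplex > 1 |
    !is.finite(m$vaf_all_molecules) | m$vaf_all_molecules <= 0 |
    m$vaf_all_molecules > 1
  indel_len <- abs(nchar(m$ref) - nchar(m$alt))
  bad_len <- indel_len > 100

  sa <- panel$site_alts
  key_sa <- stringr::str_c(sa$chrom, sa$pos, sa$alt, sep = ":")
  snv <- m$mut_type == "SNV"
  hit <- match(stringr::str_c(m$chrom, m$pos, m$alt, sep = ":"), key_sa)

  # site lookup irrespective of alt (for indels / MNV anchors)
  sites <- panel$sites
  site_hit <- match(stringr::str_c(m$chrom, m$pos, sep = ":"),
                    stringr::str_c(sites$chrom, sites$pos, sep = ":"))

  out_of_panel <- (snv & is.na(hit)) | (!snv & is.na(site_hit))
  reject <- bad_vaf | bad_len | out_of_panel
  n_rejected <- sum(reject)
  if (n_rejected > 0) {
    message(n_rejected, " record(s) rejected (",
            sum(bad_vaf), " invalid VAF, ", sum(bad_len & !bad_vaf),
            " over-long indel, ",
            sum(out_of_panel & !bad_vaf & !bad_len), " outside panel)")
  }
  m <- m[!reject, ]
  hit <- hit[!reject]
  site_hit <- site_hit[!reject]
  snv <- m$mut_type == "SNV"

  m$gene <- ifelse(snv, sa$gene[hit], sites$gene[site_hit])
  m$consequence <- NA_character_
  m$protein_pos <- NA_integer_
  m$consequence[snv] <- sa$consequence[hit[snv]]
  m$protein_pos[snv] <- sa$protein_pos[hit[snv]]

  is_mnv <- m$mut_type == "MNV"
  if (any(is_mnv)) {
    mn <- which(is_mnv)
    m$consequence[mn] <- vapply(mn, function(i) {
      mnv_consequence(m$chrom[i], m$pos[i], m$ref[i], m$alt[i], sa, key_sa)
    }, character(1))
  }

  is_indel <- m$mut_type %in% c("insertion", "deletion")
  if (any(is_indel)) {
    ii <- which(is_indel)
    len <- abs(nchar(m$ref[ii]) - nchar(m$alt[ii]))
    in_coding <- sites$region_class[site_hit[ii]] == "coding"
    m$consequence[ii] <- dplyr::case_when(
      in_coding & len %% 3 != 0 ~ "frameshift_indel",
      in_coding ~ "inframe_indel",
      TRUE ~ "noncoding"
    )
  }
  out <- tibble::as_tibble(m)
  attr(out, "n_rejected") <- n_rejected
  out
}

classify_mut_type <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1 & nchar(alt) == 1 ~ "SNV",
    nchar(ref) == nchar(alt) ~ "MNV",
    nchar(ref) > nchar(alt) ~ "deletion",
    TRUE ~ "insertion"
  )
}

# worst consequence among the constituent substitutions of an MNV
mnv_consequence <- function(chrom, pos, ref, alt, sa, key_sa) {
  bases <- seq_len(nchar(ref))
  cons <- character(0)
  for (k in bases) {
    r <- substring(ref, k, k)
    a <- substring(alt, k, k)
    if (r == a) next
    j <- match(stringr::str_c(chrom, pos + k - 1, a, sep = ":"), key_sa)
    if (!is.na(j)) cons <- c(cons, sa$consequence[j])
  }
  if (length(cons) == 0) return("noncoding")
  cons[which.max(.CONSEQUENCE_SEVERITY[cons])]
}

#' Per-residue tally of protein-affecting mutations
#'
#' Counts missense and nonsense mutations per protein position of a gene,
#' aggregated over samples, against the residues covered by the panel.
#'
#' @param mutations annotated mutation tibble
#' @param panel a `duplex_panel`
#' @param gene gene symbol
#' @return tibble with one row per covered protein position (`protein_pos`,
#'   `n_mutations`); attribute `coverage` holds a one-row summary
#'   (`n_residues`, `n_mutated`, `percent_mutated`)
#' @export
residue_saturation <- function(mutations, panel, gene) {
  covered <- sort(unique(
    panel$site_alts$protein_pos[panel$site_alts$gene == gene &
                                  panel$site_alts$region_class == "coding"]
  ))
  if (length(covered) == 0) stop("gene has no coding residues in panel: ", gene)
  hits <- mutations |>
    dplyr::filter(.data$gene == !!gene,
                  .data$consequence %in% c("missense", "nonsense"),
                  !is.na(.data$protein_pos)) |>
    dplyr::count(.data$protein_pos, name = "n_mutations")
  out <- tibble::tibble(protein_pos = covered) |>
    dplyr::left_join(hits, by = "protein_pos") |>
    dplyr::mutate(n_mutations = dplyr::coalesce(.data$n_mutations, 0L))
  attr(out, "coverage") <- tibble::tibble(
    gene = gene,
    n_residues = length(covered),
    n_mutated = sum(out$n_mutations > 0),
    percent_mutated = 100 * sum(out$n_mutations > 0) / length(covered)
  )
  out
}

#' Summarise residue coverage for one or more genes
#'
#' @inheritParams residue_saturation
#' @param genes character vector of gene symbols (default: all coding genes)
#' @return tibble with `gene`, `n_residues`, `n_mutated`, `percent_mutated`
#' @export
residue_coverage <- function(mutations, panel, genes = NULL) {
  if (is.null(genes)) {
    genes <- unique(panel$regions$gene[panel$regions$region_class == "coding"])
  }
  purrr::map_dfr(genes, function(g) {
    attr(residue_saturation(mutations, panel, g), "coverage")
  })
}

#' Read / write a site-by-sample duplex depth matrix
#'
#' Wide TSV: `chrom`, `pos` (0-based) and one numeric column per sample
#' (haploid genomes).
#'
#' @param path TSV path
#' @return depth tibble
#' @export
read_depth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", .default = "d"
  ), progress = FALSE)
}

#' @rdname read_depth
#' @param depth depth tibble
#' @export
write_depth <- function(depth, path) {
  readr::write_tsv(depth, path)
  invisible(path)
}

#' Read / write donor covariates
#'
#' One row per sample: `sample_id`, `donor_id`, `location`, `age_decades`,
#' `sex` (M/F), `smoking` (ever/never/unknown), `alcohol` (0/1),
#' `bmi_scaled` (in 0-1), `chemo` (0/1).
#'
#' @param path TSV path
#' @return covariates tibble
#' @export
read_covariates <- function(path) {
  cov <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", donor_id = "c", location = "c", sex = "c",
    smoking = "c", .default = "d"
  ), progress = FALSE)
  stopifnot(all(cov$bmi_scaled >= 0 & cov$bmi_scaled <= 1, na.rm = TRUE))
  n_per_donor <- table(cov$donor_id)
  stopifnot(all(n_per_donor <= 2))
  cov
}

#' @rdname read_covariates
#' @param covariates covariates tibble
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path)
  invisible(path)
}

#' Read / write a promoter activating-mutation whitelist
#'
#' TSV with `chrom`, `pos` (0-based), `alt`; positions of promoter
#' substitutions recurrently observed across tumour genomes.
#'
#' @param path TSV path
#' @return whitelist tibble
#' @export
read_whitelist <- function(path) {
  readr::read_tsv(path, col_types = "cic", progress = FALSE)
}

#' @rdname read_whitelist
#' @param whitelist whitelist tibble
#' @export
write_whitelist <- function(whitelist, path) {
  readr::write_tsv(whitelist, path)
  invisible(path)
}
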