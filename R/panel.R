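#' Sequencing-panel model
#'
#' A panel is the set of targeted genomic intervals together with the
#' reference sequence they lie on. Intervals carry a gene label, a region
#' class (`coding`, `intronic_flank`, `promoter`) and, for coding regions, a
#' strand and the frame anchor (offset of the region's first base within its
#' codon). From these the package derives one record per targeted base
#' (trinucleotide context, strand-collapsed channel) and, for every possible
#' single-base substitution, its coding consequence by codon translation.
#'
#' Coordinates are 0-based half-open throughout (BED native); 1-based
#' coordinates appear only in VCF-style input/output.
#'
#' @name panel
NULL

.REGION_CLASSES <- c("coding", "intronic_flank", "promoter")
.SNV_CONSEQUENCES <- c("synonymous", "missense", "nonsense",
                       "essential_splice", "noncoding")

#' Read a panel definition from BED + FASTA
#'
#' The BED name field encodes `gene|region_class|strand|frame_anchor`.
#'
#' @param bed_path path to panel BED file
#' @param fasta_path path to reference FASTA covering the panel contigs
#' @param splice_window number of intronic bases flanking each coding-region
#'   boundary treated as essential splice sites (default 2)
#' @return a `duplex_panel` object; see [build_panel()]
#' @export
read_panel <- function(bed_path, fasta_path, splice_window = 2) {
  bed <- readr::read_tsv(
    bed_path,
    col_names = c("chrom", "start", "end", "name"),
    col_types = "ciic", progress = FALSE
  )
  parts <- stringr::str_split_fixed(bed$name, stringr::fixed("|"), 4)
  regions <- tibble::tibble(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    gene = parts[, 1], region_class = parts[, 2], strand = parts[, 3],
    frame_anchor = suppressWarnings(as.integer(parts[, 4]))
  )
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  reference <- as.character(seqs)
  names(reference) <- stringr::str_extract(names(seqs), "^\\S+")
  build_panel(regions, reference, splice_window = splice_window)
}

#' Write a panel's regions to BED
#'
#' @param panel a `duplex_panel`
#' @param bed_path output BED path
#' @param fasta_path optional output FASTA path for the reference
#' @return `bed_path`, invisibly
#' @export
write_panel <- function(panel, bed_path, fasta_path = NULL) {
  r <- panel$regions
  bed <- tibble::tibble(
    chrom = r$chrom, start = r$start, end = r$end,
    name = stringr::str_c(r$gene, r$region_class, r$strand,
                          dplyr::coalesce(as.character(r$frame_anchor), "."),
                          sep = "|")
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(panel$reference)
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  invisible(bed_path)
}

#' Build a panel object from in-memory regions and reference
#'
#' @param regions tibble with columns chrom, start, end, gene, region_class
#'   (`coding`, `intronic_flank`, `promoter`), strand (`+`/`-`) and
#'   frame_anchor (integer, coding regions only)
#' @param reference named character vector of contig sequences
#' @param splice_window intronic bases flanking coding boundaries scored as
#'   essential splice
#' @return a `duplex_panel` list with elements `regions`, `sites` (one row
#'   per targeted base), `site_alts` (one row per possible substitution with
#'   channel and consequence), `reference` and `splice_window`
#' @export
build_panel <- function(regions, reference, splice_window = 2) {
  validate_regions(regions, reference)
  sites <- expand_sites(regions, reference)
  site_alts <- annotate_site_alts(sites, regions, reference, splice_window)
  structure(
    list(
      regions = regions,
      sites = sites,
      site_alts = site_alts,
      reference = reference,
      splice_window = splice_window
    ),
    class = "duplex_panel"
  )
}

#' @method print duplex_panel
#' @export
print.duplex_panel <- function(x, ...) {
  n_coding <- sum(x$regions$end[x$regions$region_class == "coding"] -
                    x$regions$start[x$regions$region_class == "coding"])
  total <- sum(x$regions$end - x$regions$start)
  cat("<duplex_panel> ", length(unique(x$regions$gene)), " genes, ",
      total, " bp (", n_coding, " coding, ", total - n_coding,
      " non-coding), ", nrow(x$site_alts), " possible substitutions\n",
      sep = "")
  invisible(x)
}

#' Per-class base-pair accounting of a panel
#'
#' @param panel a `duplex_panel`
#' @return tibble with coding bp, non-coding bp and their total
#' @export
panel_accounting <- function(panel) {
  r <- panel$regions
  coding <- sum((r$end - r$start)[r$region_class == "coding"])
  noncoding <- sum((r$end - r$start)[r$region_class != "coding"])
  tibble::tibble(coding_bp = coding, noncoding_bp = noncoding,
                 total_bp = coding + noncoding)
}

validate_regions <- function(regions, reference) {
  stopifnot(all(regions$start < regions$end))
  stopifnot(all(regions$region_class %in% .REGION_CLASSES))
  missing_contig <- setdiff(unique(regions$chrom), names(reference))
  if (length(missing_contig) > 0) {
    stop("panel interval on contig absent from reference: ",
         paste(missing_contig, collapse = ", "))
  }
  clen <- nchar(reference)[match(regions$chrom, names(reference))]
  if (any(regions$end > clen) || any(regions$start < 0)) {
    stop("panel interval outside its reference contig")
  }
  # regions of one gene must not overlap
  by_gene <- split(regions, regions$gene)
  for (g in by_gene) {
    g <- g[order(g$chrom, g$start), ]
    same <- g$chrom[-1] == g$chrom[-nrow(g)]
    if (nrow(g) > 1 && any(same & g$start[-1] < g$end[-nrow(g)])) {
      stop("overlapping regions for gene ", g$gene[1])
    }
  }
  invisible(TRUE)
}

# vectorised base fetch: 0-based positions
fetch_bases <- function(reference, chrom, pos) {
  out <- character(length(pos))
  for (ct in unique(chrom)) {
    i <- chrom == ct
    seq <- reference[[ct]]
    p <- pos[i]
    ok <- p >= 0 & p < nchar(seq)
    b <- rep("N", sum(i))
    b[ok] <- substring(seq, p[ok] + 1, p[ok] + 1)
    out[i] <- b
  }
  out
}

expand_sites <- function(regions, reference) {
  n <- regions$end - regions$start
  sites <- tibble::tibble(
    chrom = rep(regions$chrom, n),
    pos = unlist(purrr::map2(regions$start, regions$end - 1, seq)),
    gene = rep(regions$gene, n),
    region_class = rep(regions$region_class, n),
    strand = rep(regions$strand, n),
    region_id = rep(seq_len(nrow(regions)), n)
  )
  up <- fetch_bases(reference, sites$chrom, sites$pos - 1)
  ref <- fetch_bases(reference, sites$chrom, sites$pos)
  down <- fetch_bases(reference, sites$chrom, sites$pos + 1)
  sites$ref <- ref
  sites$trinuc_raw <- stringr::str_c(up, ref, down)
  sites$excluded <- stringr::str_detect(sites$trinuc_raw, "[^ACGT]")
  coll <- collapse_channel(
    ifelse(sites$excluded, "ACA", sites$trinuc_raw),
    rep("T", nrow(sites))
  )
  sites$trinuc <- ifelse(sites$excluded, NA_character_, coll$trinuc)
  sites
}

# absolute CDS offset per coding region, following transcription order and
# honouring the declared frame anchors (partial fragments may start mid-codon)
cds_offsets <- function(regions) {
  regions$cds_offset <- NA_integer_
  for (g in unique(regions$gene[regions$region_class == "coding"])) {
    idx <- which(regions$gene == g & regions$region_class == "coding")
    strand <- regions$strand[idx[1]]
    ord <- idx[order(regions$start[idx], decreasing = (strand == "-"))]
    cum <- 0L
    for (i in ord) {
      anchor <- regions$frame_anchor[i] %||% 0L
      if (is.na(anchor)) anchor <- 0L
      shift <- (anchor - cum) %% 3L
      regions$cds_offset[i] <- cum + shift
      cum <- cum + shift + (regions$end[i] - regions$start[i])
    }
  }
  regions
}

annotate_site_alts <- function(sites, regions, reference, splice_window) {
  regions <- cds_offsets(regions)
  keep <- !sites$excluded
  s <- sites[keep, ]

  # essential splice: intronic bases within splice_window of a coding boundary
  splice_pos <- splice_positions(regions, splice_window)
  key <- stringr::str_c(s$chrom, s$pos, s$gene, sep = ":")
  is_splice <- s$region_class == "intronic_flank" &
    key %in% stringr::str_c(splice_pos$chrom, splice_pos$pos, splice_pos$gene,
                            sep = ":")

  is_coding <- s$region_class == "coding"
  cds_pos <- rep(NA_integer_, nrow(s))
  if (any(is_coding)) {
    off <- regions$cds_offset[s$region_id[is_coding]]
    within <- ifelse(
      s$strand[is_coding] == "-",
      regions$end[s$region_id[is_coding]] - 1L - s$pos[is_coding],
      s$pos[is_coding] - regions$start[s$region_id[is_coding]]
    )
    cds_pos[is_coding] <- off + within
  }

  # expand 3 alts per site
  alts_for <- function(ref) lapply(ref, function(r) setdiff(.BASES, r))
  alt_list <- alts_for(s$ref)
  rep3 <- rep(seq_len(nrow(s)), lengths(alt_list))
  sa <- s[rep3, c("chrom", "pos", "ref", "gene", "region_class", "strand",
                  "trinuc_raw")]
  sa$alt <- unlist(alt_list)
  sa$cds_pos <- cds_pos[rep3]
  sa$is_splice <- is_splice[rep3]

  coll <- collapse_channel(sa$trinuc_raw, sa$alt)
  sa$channel <- coll$channel
  sa$trinuc <- coll$trinuc

  # consequence
  cons <- rep("noncoding", nrow(sa))
  cons[sa$is_splice] <- "essential_splice"
  ic <- sa$region_class == "coding"
  if (any(ic)) {
    cons[ic] <- coding_consequence(sa[ic, ], reference)
  }
  sa$consequence <- cons
  sa$protein_pos <- ifelse(ic, sa$cds_pos %/% 3L + 1L, NA_integer_)

  tibble::as_tibble(sa[, c("chrom", "pos", "ref", "alt", "gene",
                           "region_class", "strand", "trinuc", "channel",
                           "consequence", "protein_pos", "cds_pos")])
}

splice_positions <- function(regions, w) {
  cod <- regions[regions$region_class == "coding", ]
  if (nrow(cod) == 0 || w == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          gene = character()))
  }
  pos <- purrr::pmap_dfr(
    list(cod$chrom, cod$start, cod$end, cod$gene),
    function(chrom, start, end, gene) {
      tibble::tibble(
        chrom = chrom,
        pos = c(seq(start - w, start - 1), seq(end, end + w - 1)),
        gene = gene
      )
    }
  )
  pos
}

# codon-arithmetic consequence for coding (site, alt) rows, assuming codons
# are genomically contiguous (single-CDS-block gene model)
coding_consequence <- function(sa, reference) {
  pic <- sa$cds_pos %% 3L
  # genomic positions of the codon's three bases
  offs <- lapply(0:2, function(k) {
    ifelse(sa$strand == "-", sa$pos - (k - pic), sa$pos + (k - pic))
  })
  b1 <- fetch_bases(reference, sa$chrom, offs[[1]])
  b2 <- fetch_bases(reference, sa$chrom, offs[[2]])
  b3 <- fetch_bases(reference, sa$chrom, offs[[3]])
  neg <- sa$strand == "-"
  if (any(neg)) {
    b1[neg] <- complement_base(b1[neg])
    b2[neg] <- complement_base(b2[neg])
    b3[neg] <- complement_base(b3[neg])
  }
  codon <- stringr::str_c(b1, b2, b3)
  alt_cod <- sa$alt
  alt_cod[neg] <- complement_base(sa$alt[neg])
  mut <- codon
  for (k in 0:2) {
    i <- pic == k
    stringr::str_sub(mut[i], k + 1, k + 1) <- alt_cod[i]
  }
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[codon])
  alt_aa <- unname(gc[mut])
  bad <- is.na(ref_aa) | is.na(alt_aa)
  out <- dplyr::case_when(
    ref_aa == alt_aa ~ "synonymous",
    alt_aa == "*" ~ "nonsense",
    TRUE ~ "missense"
  )
  out[bad] <- "missense"  # ambiguous flank at contig edge; conservative label
  out
}
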