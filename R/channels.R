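#' Trinucleotide substitution channels
#'
#' Single-base substitutions are binned into 96 channels defined by the
#' mutated base and its two flanking bases, collapsed onto the pyrimidine
#' strand (the COSMIC convention). A purine reference is reverse-complemented
#' together with its context and alternative allele, so each of the 192
#' stranded (trinucleotide, alt) labels maps to exactly one of the 96
#' pyrimidine-central channels.
#'
#' @name channels
NULL

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Complement a vector of bases
#' @noRd
complement_base <- function(x) {
  unname(.COMP[x])
}

#' Reverse-complement 3-mers, vectorised
#' @noRd
revcomp_trinuc <- function(x) {
  stringr::str_c(
    complement_base(stringr::str_sub(x, 3, 3)),
    complement_base(stringr::str_sub(x, 2, 2)),
    complement_base(stringr::str_sub(x, 1, 1))
  )
}

#' Collapse stranded (context, alt) pairs onto pyrimidine-central channels
#'
#' @param trinuc character vector of reference 3-mers (middle base = ref)
#' @param alt character vector of alternative alleles on the same strand
#' @return tibble with columns `trinuc` (pyrimidine-central 3-mer), `alt`
#'   (collapsed alt) and `channel` (label `"A[C>T]G"` style)
#' @export
collapse_channel <- function(trinuc, alt) {
  stopifnot(length(trinuc) == length(alt))
  ref <- stringr::str_sub(trinuc, 2, 2)
  is_pur <- ref %in% c("A", "G")
  tri <- trinuc
  al <- alt
  tri[is_pur] <- revcomp_trinuc(trinuc[is_pur])
  al[is_pur] <- complement_base(alt[is_pur])
  tibble::tibble(
    trinuc = tri,
    alt = al,
    channel = stringr::str_c(
      stringr::str_sub(tri, 1, 1), "[", stringr::str_sub(tri, 2, 2),
      ">", al, "]", stringr::str_sub(tri, 3, 3)
    )
  )
}

#' All 96 pyrimidine-central substitution channels
#'
#' @return character vector of length 96, lexicographically sorted
#' @export
all_channels <- function() {
  refs <- c("C", "T")
  out <- character(0)
  for (ref in refs) {
    for (alt in setdiff(.BASES, ref)) {
      for (up in .BASES) {
        for (down in .BASES) {
          out <- c(out, stringr::str_c(up, "[", ref, ">", alt, "]", down))
        }
      }
    }
  }
  sort(out)
}

#' All 32 pyrimidine-central trinucleotides
#' @export
all_trinucs <- function() {
  refs <- c("C", "T")
  out <- character(0)
  for (ref in refs) {
    for (up in .BASES) for (down in .BASES) {
      out <- c(out, stringr::str_c(up, ref, down))
    }
  }
  sort(out)
}

#' Trinucleotide part of a channel label
#' @noRd
channel_trinuc <- function(channel) {
  stringr::str_c(
    stringr::str_sub(channel, 1, 1),
    stringr::str_sub(channel, 3, 3),
    stringr::str_sub(channel, 7, 7)
  )
}
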