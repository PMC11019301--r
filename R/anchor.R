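# Canonical anchor sequence, tuning-site list and residue polarity table.

# one-letter codes; X/B/Z/J are ambiguity codes normalised at extraction
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("X", "B", "Z", "J")

#' Bovine rhodopsin anchor sequence
#'
#' The 348-residue bovine rhodopsin protein (UniProt P02699; chain A of PDB
#' 1U19), packaged as the anchor against which opsin residue positions are
#' numbered. Spectral tuning sites are conventionally reported in this
#' coordinate space.
#'
#' @return A single character string of 348 amino acids.
#' @examples
#' nchar(bovine_rhodopsin())
#' @export
bovine_rhodopsin <- function() {
  path <- system.file("extdata", "bovine_rhodopsin_1u19.fasta",
                      package = "uvopsin", mustWork = TRUE)
  as.character(Biostrings::readAAStringSet(path)[[1]])
}

#' Canonical SWS1 spectral tuning sites
#'
#' Positions (bovine rhodopsin numbering) of the known SWS1 tuning sites in
#' the retinal binding pocket and transmembrane regions I (46, 49, 52),
#' II (86, 90, 91, 93, 97), III (109, 113, 114, 116, 118) and VI (265).
#' Site 125, a putative tuning site in the retinal binding pocket flagged by
#' polarity change, is appended when `include_125 = TRUE`; it is extracted
#' and polarity-flagged but excluded from lambda-max arithmetic.
#'
#' @param include_125 Append putative site 125? Default `FALSE`.
#' @return Integer vector of anchor positions.
#' @export
canonical_tuning_sites <- function(include_125 = FALSE) {
  sites <- c(46L, 49L, 52L, 86L, 90L, 91L, 93L, 97L,
             109L, 113L, 114L, 116L, 118L, 265L)
  if (include_125) sites <- sort(c(sites, 125L))
  sites
}

#' Amino-acid polarity table
#'
#' Binary polar/nonpolar classification of the 20 canonical residues, used to
#' flag polarity-changing substitutions at tuning sites.
#'
#' @return A tibble with columns `residue` and `polarity`
#'   (`"polar"`/`"nonpolar"`).
#' @export
aa_polarity <- function() {
  polar <- c("S", "T", "C", "Y", "N", "Q", "D", "E", "K", "R", "H")
  tibble(
    residue = AA_CANONICAL,
    polarity = if_else(AA_CANONICAL %in% polar, "polar", "nonpolar")
  )
}

#' Is a substitution a polarity change?
#'
#' `TRUE` when the two residues fall in different polarity classes
#' (e.g. S125A), `FALSE` when they share a class, and `NA` (with a warning)
#' when either residue is ambiguous or missing, for which polarity is
#' undefined. Vectorised over `residue_a`/`residue_b`.
#'
#' @param site Anchor position(s); recorded in the result only.
#' @param residue_a,residue_b One-letter residues.
#' @param table Polarity table, default [aa_polarity()].
#' @return Logical vector.
#' @examples
#' polarity_change(125, "S", "A")  # TRUE
#' polarity_change(114, "S", "T")  # FALSE, both polar
#' @export
polarity_change <- function(site, residue_a, residue_b, table = aa_polarity()) {
  lk <- setNames(table$polarity, table$residue)
  pa <- unname(lk[toupper(residue_a)])
  pb <- unname(lk[toupper(residue_b)])
  out <- pa != pb
  if (anyNA(out)) {
    warn("polarity undefined for ambiguous or missing residues; returning NA")
  }
  out
}
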