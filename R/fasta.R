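# FASTA IO for opsin protein sequences.
#
# Header convention: "id|species|gene"; headers without pipes fall back to
# the whole header as id with species/gene NA.

#' Read opsin protein sequences from FASTA
#'
#' Multi-record protein FASTA (wrapped or unwrapped). Headers of the form
#' `id|species|gene` are split into the corresponding columns; any other
#' header is kept whole as `id`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `species`, `gene`, `residues`.
#' @export
read_opsin_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort("no sequences found in FASTA")
  headers <- names(set)
  parts <- stringr::str_split(headers, stringr::fixed("|"))
  tibble(
    id = map_chr(parts, 1),
    species = map_chr(parts, ~ if (length(.x) >= 2) .x[[2]] else NA_character_),
    gene = map_chr(parts, ~ if (length(.x) >= 3) stringr::str_split_1(.x[[3]], " ")[1] else NA_character_),
    residues = toupper(unname(as.character(set)))
  )
}

#' Write opsin protein sequences to FASTA
#'
#' Inverse of [read_opsin_fasta()]: emits `id|species|gene` headers (fields
#' that are `NA` are dropped from the right).
#'
#' @param seqs Tibble with columns `id`, `residues` and optionally
#'   `species`, `gene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_opsin_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  hdr <- pmap(
    list(seqs$id,
         seqs$species %||% rep(NA_character_, nrow(seqs)),
         seqs$gene %||% rep(NA_character_, nrow(seqs))),
    function(i, s, g) paste(Filter(Negate(is.na), c(i, s, g)), collapse = "|")
  )
  set <- Biostrings::AAStringSet(seqs$residues)
  names(set) <- unlist(hdr)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
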