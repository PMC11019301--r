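# Anchored numbering: place query opsins in bovine rhodopsin coordinates by
# global pairwise alignment and read off tuning-site residues.

validate_protein <- function(residues, what = "query") {
  residues <- toupper(residues)
  if (!nzchar(residues)) abort(paste(what, "sequence is empty"))
  chars <- unique(stringr::str_split_1(residues, ""))
  bad <- setdiff(chars, c(AA_CANONICAL, AA_AMBIGUOUS))
  if (length(bad) > 0) {
    abort(paste0(what, " contains non-amino-acid characters: ",
                 paste(bad, collapse = ", ")))
  }
  residues
}

#' Align a query opsin to the anchor and build a position map
#'
#' Global (Needleman-Wunsch) alignment of a query opsin protein against the
#' bovine rhodopsin anchor, BLOSUM62 scoring with affine gaps (open 10,
#' extend 1). The returned map sends each anchor position to the query
#' position aligned with it; anchor positions aligned to gaps are absent.
#' The traceback is deterministic, so numbering is reproducible.
#'
#' @param query Query protein as a character string, or a one-row tibble
#'   with a `residues` column (as from [read_opsin_fasta()]). Must be at
#'   least 50 residues; shorter fragments cannot establish homologous
#'   numbering. Ambiguity codes X/B/Z/J are permitted.
#' @param anchor Anchor protein string; default the packaged bovine
#'   rhodopsin ([bovine_rhodopsin()]).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return A tibble of class `position_map` with columns `anchor_pos`,
#'   `query_pos` (both 1-based, strictly increasing), and attributes
#'   `score`, `anchor_coverage` (fraction of anchor positions mapped) and
#'   `anchor_length`.
#' @examples
#' m <- align_to_anchor(bovine_rhodopsin())
#' all(m$anchor_pos == m$query_pos)
#' @export
align_to_anchor <- function(query, anchor = bovine_rhodopsin(),
                            gap_opening = 10, gap_extension = 1) {
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1, "residues" %in% names(query))
    query <- query$residues[[1]]
  }
  query <- validate_protein(query, "query")
  anchor <- validate_protein(anchor, "anchor")
  if (nchar(query) < 50) {
    abort("query shorter than 50 residues; cannot establish homologous numbering")
  }

  # BLOSUM62 lacks a J (I/L) row; score ambiguity codes as X
  score_seq <- function(s) chartr("J", "X", s)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(score_seq(query)),
    subject = Biostrings::AAString(score_seq(anchor)),
    type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening,
    gapExtension = gap_extension
  )
  qa <- stringr::str_split_1(as.character(Biostrings::alignedPattern(aln)), "")
  aa <- stringr::str_split_1(as.character(Biostrings::alignedSubject(aln)), "")
  stopifnot(length(qa) == length(aa))
  qpos <- cumsum(qa != "-")
  apos <- cumsum(aa != "-")
  both <- qa != "-" & aa != "-"
  out <- tibble(anchor_pos = apos[both], query_pos = qpos[both])
  attr(out, "score") <- Biostrings::score(aln)
  attr(out, "anchor_coverage") <- nrow(out) / nchar(anchor)
  attr(out, "anchor_length") <- nchar(anchor)
  attr(out, "query_length") <- nchar(query)
  class(out) <- c("position_map", class(out))
  out
}

#' Extract tuning-site residues through a position map
#'
#' Reads the query residue aligned with each requested anchor site. Sites
#' aligned to a gap come back `NA` (missing); ambiguity codes (X, and B/Z/J,
#' which are normalised) come back `"X"`.
#'
#' @param query The same query passed to [align_to_anchor()].
#' @param map A `position_map` produced from that query.
#' @param sites Anchor positions to extract; default the canonical tuning
#'   sites plus putative site 125.
#' @return A one-row tibble with one `site_<n>` column per requested site.
#' @export
extract_site_profile <- function(query, map,
                                 sites = canonical_tuning_sites(include_125 = TRUE)) {
  if (is.data.frame(query) && "residues" %in% names(query)) {
    query <- query$residues[[1]]
  }
  query <- toupper(query)
  stopifnot(inherits(map, "position_map"))
  if (nchar(query) != attr(map, "query_length")) {
    abort("position map was not produced from this query")
  }
  anchor_len <- attr(map, "anchor_length")
  if (any(sites < 1 | sites > anchor_len)) {
    abort("requested site outside anchor length")
  }
  res <- map_chr(sites, function(s) {
    hit <- map$query_pos[map$anchor_pos == s]
    if (length(hit) == 0) return(NA_character_)
    r <- substr(query, hit, hit)
    if (r %in% AA_AMBIGUOUS) "X" else r
  })
  as_tibble(as.list(setNames(res, paste0("site_", sites))))
}

#' Site profiles for a table of sequences
#'
#' Aligns every sequence to the anchor and extracts its tuning-site
#' residues; the workhorse for turning a FASTA into the per-sequence site
#' matrix. Emit with `readr::write_tsv()` for the one-row-per-sequence TSV.
#'
#' @param seqs Tibble with columns `id`, `residues` (and optionally
#'   `species`, `gene`), as from [read_opsin_fasta()].
#' @inheritParams extract_site_profile
#' @inheritParams align_to_anchor
#' @return A tibble: the identifier columns of `seqs` followed by one
#'   `site_<n>` column per site.
#' @export
extract_site_profiles <- function(seqs,
                                  sites = canonical_tuning_sites(include_125 = TRUE),
                                  anchor = bovine_rhodopsin()) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  idcols <- intersect(c("id", "species", "gene"), names(seqs))
  profs <- map(seq_len(nrow(seqs)), function(i) {
    q <- seqs$residues[[i]]
    extract_site_profile(q, align_to_anchor(q, anchor = anchor), sites = sites)
  })
  bind_cols(seqs[idcols], bind_rows(profs))
}
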