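# Lambda-max estimation: match a tuning-site profile to the closest
# reference pigment and apply known per-substitution spectral effects.

#' Packaged site-effect table
#'
#' Known spectral shifts of single tuning-site substitutions, applied in
#' either direction with the sign flipped. Ships with A118S = +5 nm and a
#' default A114S = +5 nm; both carry provenance strings and can be replaced
#' with a user table via [read_site_effects()].
#'
#' @return A tibble with columns `site`, `from`, `to`, `delta_nm`,
#'   `provenance`.
#' @export
default_site_effects <- function() {
  read_site_effects(system.file("extdata", "site_effects.tsv",
                                package = "uvopsin", mustWork = TRUE))
}

#' Read a site-effect TSV
#'
#' Columns: `site`, `from`, `to`, `delta_nm`, `provenance`.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_site_effects <- function(path) {
  # residue columns must stay character ("T"/"F" would otherwise be
  # guessed as logicals)
  eff <- readr::read_tsv(
    path, show_col_types = FALSE, comment = "#",
    col_types = readr::cols(site = readr::col_integer(),
                            delta_nm = readr::col_double(),
                            .default = readr::col_character()))
  need <- c("site", "from", "to", "delta_nm")
  if (!all(need %in% names(eff))) {
    abort(paste("site-effect table must have columns:", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(eff$delta_nm))) abort("delta_nm must be finite")
  eff
}

#' Packaged reference panel (synthetic)
#'
#' A small panel of SWS1 pigments with known lambda-max (in-vitro expression
#' or microspectrophotometry) and their tuning-site profiles, used as the
#' default for [estimate_lambda_max()]. The in-vitro entries carry published
#' lambda-max values (Nile tilapia 360 nm, zebra mbuna 368 nm, medaka
#' 356 nm); the damselfish MSP entries and all site profiles are synthetic
#' placeholders consistent with the short (356-362 nm) and long (368-370 nm)
#' damselfish SWS1 classes. Replace with a curated panel via
#' [read_reference_panel()] for real analyses.
#'
#' @return A tibble with columns `species`, `gene`, `lambda_max_nm`,
#'   `method`, `is_damselfish` and one `site_<n>` column per canonical site.
#' @export
default_reference_panel <- function() {
  read_reference_panel(system.file("extdata", "reference_panel_synthetic.tsv",
                                   package = "uvopsin", mustWork = TRUE))
}

#' Read a reference-panel TSV
#'
#' Columns: `species`, `gene`, `lambda_max_nm`, `method` (`in-vitro` or
#' `MSP`), `is_damselfish`, then one `site_<n>` column per tuning site.
#' SWS1-class references are expected in 330-420 nm; values outside that
#' window trigger a warning.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_reference_panel <- function(path) {
  # residue columns must stay character ("T"/"F" would otherwise be
  # guessed as logicals)
  panel <- readr::read_tsv(
    path, show_col_types = FALSE, comment = "#",
    col_types = readr::cols(lambda_max_nm = readr::col_double(),
                            is_damselfish = readr::col_logical(),
                            .default = readr::col_character()))
  need <- c("species", "gene", "lambda_max_nm", "method", "is_damselfish")
  if (!all(need %in% names(panel))) {
    abort(paste("reference panel must have columns:", paste(need, collapse = ", ")))
  }
  if (!any(stringr::str_detect(names(panel), "^site_"))) {
    abort("reference panel has no site_<n> columns")
  }
  if (any(panel$lambda_max_nm < 330 | panel$lambda_max_nm > 420)) {
    warn("reference lambda_max_nm outside the expected SWS1 window (330-420 nm)")
  }
  panel
}

# named residue vector ("46" -> "A", ...) from a one-row profile
profile_vec <- function(profile, sites = NULL) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1)
    cols <- names(profile)[stringr::str_detect(names(profile), "^site_")]
    v <- setNames(as.character(unlist(profile[cols], use.names = FALSE)),
                  stringr::str_remove(cols, "^site_"))
  } else {
    v <- profile
  }
  if (!is.null(sites)) v <- v[as.character(sites)]
  v
}

#' Rank reference pigments by tuning-site mismatch
#'
#' Compares a profile to every panel entry over the sites observed in both
#' (ambiguous and missing residues are not comparable and are skipped) and
#' ranks by ascending mismatch count. Ties are broken deterministically:
#' damselfish references first, then in-vitro before MSP, then lexicographic
#' species id — so estimation is reproducible under panel permutation.
#'
#' @param profile A one-row tibble with `site_<n>` columns (as from
#'   [extract_site_profiles()]) or a named residue vector keyed by site.
#' @param panel Reference panel tibble; default [default_reference_panel()].
#' @param sites Sites used for matching; default the canonical 14.
#' @return The panel, ranked, with `n_mismatch` and list-column
#'   `mismatched_sites`.
#' @export
match_reference <- function(profile, panel = default_reference_panel(),
                            sites = canonical_tuning_sites()) {
  if (nrow(panel) == 0) abort("reference panel is empty")
  q <- profile_vec(profile, sites)
  if (all(is.na(q))) abort("profile has no residues at the requested sites; no match possible")
  cmp <- map(seq_len(nrow(panel)), function(i) {
    r <- profile_vec(panel[i, ], sites)
    comparable <- !is.na(q) & !is.na(r) & q != "X" & r != "X"
    sites[comparable & q != r]
  })
  panel |>
    mutate(
      mismatched_sites = cmp,
      n_mismatch = map_int(cmp, length),
      .method_rank = if_else(.data$method == "in-vitro", 1L, 2L)
    ) |>
    arrange(.data$n_mismatch, desc(.data$is_damselfish), .data$.method_rank,
            .data$species) |>
    select(-".method_rank")
}

#' Estimate SWS1 lambda-max from tuning-site profiles
#'
#' For each sequence, finds the closest-matching reference pigment
#' ([match_reference()]) and adds or subtracts the known spectral effect of
#' every mismatched tuning site from the reference lambda-max. Because
#' single-site effects are usually not additive, estimation is refused
#' (UNDETERMINED) rather than chained when more than `homology_threshold`
#' mismatched sites lack a known effect; profiles with any ambiguous tuning
#' site are likewise UNDETERMINED. Site 125 is never part of the arithmetic.
#'
#' @param profiles Tibble of site profiles, one row per sequence (as from
#'   [extract_site_profiles()]).
#' @param panel Reference panel; default [default_reference_panel()].
#' @param effects Site-effect table; default [default_site_effects()].
#' @param homology_threshold Maximum number of mismatched sites without a
#'   known effect before the estimate is refused. Default 0.
#' @param sites Sites entering the estimate; default the canonical 14.
#' @return A tibble with one row per input sequence: `id`, `reference`,
#'   `reference_lambda_nm`, `lambda_max_nm` (`NA` when undetermined),
#'   `applied_effects`, `n_applied`, `n_unmatched_sites`, `variant_class`,
#'   `reason`.
#' @examples
#' prof <- tibble::tibble(id = "q", site_114 = "A", site_118 = "A")
#' estimate_lambda_max(prof)
#' @export
estimate_lambda_max <- function(profiles, panel = default_reference_panel(),
                                effects = default_site_effects(),
                                homology_threshold = 0,
                                sites = canonical_tuning_sites()) {
  stopifnot(is.data.frame(profiles))
  ids <- if ("id" %in% names(profiles)) profiles$id else as.character(seq_len(nrow(profiles)))

  one <- function(i) {
    und <- function(reason, reference = NA_character_, ref_lambda = NA_real_) {
      tibble(id = ids[[i]], reference = reference,
             reference_lambda_nm = ref_lambda, lambda_max_nm = NA_real_,
             applied_effects = NA_character_, n_applied = 0L,
             n_unmatched_sites = NA_integer_,
             variant_class = "unclassified", reason = reason)
    }
    q <- profile_vec(profiles[i, ], sites)
    if (any(!is.na(q) & q == "X")) {
      amb <- sites[!is.na(q) & q == "X"]
      return(und(paste0("ambiguous residue at site(s) ",
                        paste(amb, collapse = ", "))))
    }
    if (all(is.na(q))) return(und("no tuning sites extracted"))
    ranked <- match_reference(profiles[i, ], panel, sites)
    best <- ranked[1, ]
    r <- profile_vec(best, sites)
    mism <- best$mismatched_sites[[1]]
    deltas <- map_dbl(mism, function(s) {
      fwd <- effects[effects$site == s & effects$from == r[[as.character(s)]] &
                       effects$to == q[[as.character(s)]], ]
      if (nrow(fwd) > 0) return(fwd$delta_nm[[1]])
      rev <- effects[effects$site == s & effects$from == q[[as.character(s)]] &
                       effects$to == r[[as.character(s)]], ]
      if (nrow(rev) > 0) return(-rev$delta_nm[[1]])
      NA_real_
    })
    unmatched <- mism[is.na(deltas)]
    if (length(unmatched) > homology_threshold) {
      return(und(paste0("low tuning-site homology: no known effect at site(s) ",
                        paste(unmatched, collapse = ", ")),
                 reference = best$species, ref_lambda = best$lambda_max_nm))
    }
    applied <- mism[!is.na(deltas)]
    dd <- deltas[!is.na(deltas)]
    lam <- best$lambda_max_nm + sum(dd)
    eff_str <- if (length(applied) == 0) NA_character_ else {
      paste(sprintf("%s%d%s(%+g)",
                    map_chr(applied, ~ r[[as.character(.x)]]), applied,
                    map_chr(applied, ~ q[[as.character(.x)]]), dd),
            collapse = "; ")
    }
    tibble(id = ids[[i]], reference = best$species,
           reference_lambda_nm = best$lambda_max_nm, lambda_max_nm = lam,
           applied_effects = eff_str, n_applied = length(applied),
           n_unmatched_sites = length(unmatched),
           variant_class = classify_variant(lam), reason = NA_character_)
  }
  bind_rows(map(seq_len(nrow(profiles)), one))
}

#' Classify an SWS1 lambda-max estimate as short or long
#'
#' Damselfish SWS1 pigments fall into a short class (356-362 nm, inclusive)
#' and a long class (368-370 nm, inclusive), about 10 nm apart. Estimates
#' strictly between the classes are `"intermediate"`; anything else
#' (including `NA` from undetermined estimates) is `"unclassified"`, never
#' silently coerced.
#'
#' @param lambda_max_nm Numeric vector of estimates (nm).
#' @return Character vector of class labels.
#' @examples
#' classify_variant(c(360, 370, 365, 350, NA))
#' @export
classify_variant <- function(lambda_max_nm) {
  dplyr::case_when(
    is.na(lambda_max_nm) ~ "unclassified",
    lambda_max_nm >= 356 & lambda_max_nm <= 362 ~ "short",
    lambda_max_nm >= 368 & lambda_max_nm <= 370 ~ "long",
    lambda_max_nm > 362 & lambda_max_nm < 368 ~ "intermediate",
    TRUE ~ "unclassified"
  )
}
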