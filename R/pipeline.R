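# End-to-end orchestration: sequences -> site profiles -> lambda-max ->
# ancestral states / duplications -> expression -> spectra -> joined summary.

write_stage_tsv <- function(tbl, path, meta) {
  hdr <- c(sprintf("# uvopsin %s", as.character(utils::packageVersion("uvopsin"))),
           sprintf("# %s: %s", names(meta), unname(unlist(meta))))
  writeLines(hdr, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full SWS1 analysis pipeline
#'
#' Ties the analysis stages together on whatever inputs are supplied (at
#' least one is required): tuning-site extraction and lambda-max estimation
#' from sequences; ancestral reconstruction of sites 114/118 and the root's
#' joint label when a species/gene tree accompanies the sequences;
#' duplication (gain) parsimony when a presence table accompanies a tree;
#' proportional expression and SWS1-copy usage from counts; and T50 /
#' UV-reflectance classification of spectra. Results are returned as a
#' named list of tibbles plus a per-taxon summary; when `out_dir` is given,
#' each table is written as TSV with header metadata (package version,
#' configuration hash with all thresholds, input checksums). Any stage
#' failure aborts with a stage-named error and leaves a `FAILED` marker in
#' `out_dir`.
#'
#' @param sequences Tibble `id`, `species`, `gene`, `residues` (as from
#'   [read_opsin_fasta()]), or `NULL`.
#' @param tree Rooted `ape::phylo` whose tip labels match `sequences$id`
#'   (for ancestral states) and/or `presence$label`, or `NULL`.
#' @param presence Tibble `label`, `present` for duplicate copy number, or
#'   `NULL`.
#' @param counts Expression count tibble (see
#'   [proportional_expression()]), or `NULL`.
#' @param spectra Named list with optional elements `transmission` and
#'   `reflectance`, each a named list of spectrum tibbles, or `NULL`.
#' @param panel,effects Reference panel and site-effect table.
#' @param homology_threshold,detection_threshold,criterion_fraction
#'   Stage thresholds (see [estimate_lambda_max()],
#'   [classify_sws1_usage()], [classify_uv_reflectance()]).
#' @param gene_groups Gene-group mapping for expression.
#' @param ancestral_method `"ml"` (default) or `"fitch"` for the reported
#'   114/118 reconstruction; both are computed.
#' @param out_dir Optional output directory for TSV exports.
#' @return A list with elements `site_profiles`, `lambda_estimates`,
#'   `ancestral`, `duplications`, `expression`, `sws1_usage`,
#'   `spectra_summary`, `summary` and `config` (unsupplied stages are
#'   `NULL`).
#' @export
run_sws1_pipeline <- function(sequences = NULL, tree = NULL, presence = NULL,
                              counts = NULL, spectra = NULL,
                              panel = default_reference_panel(),
                              effects = default_site_effects(),
                              homology_threshold = 0,
                              detection_threshold = 0.01,
                              criterion_fraction = 0.2,
                              gene_groups = default_gene_groups(),
                              ancestral_method = c("ml", "fitch"),
                              out_dir = NULL) {
  ancestral_method <- match.arg(ancestral_method)
  if (is.null(sequences) && is.null(tree) && is.null(counts) &&
      is.null(spectra) && is.null(presence)) {
    abort("at least one input must be supplied")
  }
  config <- list(homology_threshold = homology_threshold,
                 detection_threshold = detection_threshold,
                 criterion_fraction = criterion_fraction,
                 ancestral_method = ancestral_method)
  meta <- c(config,
            config_hash = rlang::hash(config),
            input_checksums = rlang::hash(list(sequences, tree, presence,
                                               counts, spectra)))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(paste("stage", name, "failed:", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  out <- list(config = meta)

  if (!is.null(sequences)) {
    out$site_profiles <- stage("sites", extract_site_profiles(sequences))
    out$lambda_estimates <- stage("lambda", estimate_lambda_max(
      out$site_profiles, panel = panel, effects = effects,
      homology_threshold = homology_threshold))
  }

  if (!is.null(tree) && !is.null(out$site_profiles)) {
    out$ancestral <- stage("ancestral", {
      prof <- out$site_profiles
      common <- intersect(tree$tip.label, prof$id)
      if (length(common) < 2) {
        abort("fewer than two tree tips match sequence ids")
      }
      sub <- if (length(common) < ape::Ntip(tree)) {
        ape::keep.tip(tree, common)
      } else tree
      fit_site <- function(col) {
        st <- tibble(label = prof$id, state = prof[[col]])
        if (ancestral_method == "ml") {
          ml_marginal_states(sub, st)
        } else {
          fitch_states(sub, st)
        }
      }
      f114 <- fit_site("site_114")
      f118 <- fit_site("site_118")
      list(site_114 = f114, site_118 = f118,
           root_label = joint_site_label(f114, f118))
    })
  }

  if (!is.null(tree) && !is.null(presence)) {
    out$duplications <- stage("duplications",
                              count_gain_events(tree, presence))
  }

  if (!is.null(counts)) {
    out$expression <- stage("express",
                            proportional_expression(counts, gene_groups))
    out$sws1_usage <- stage("express", classify_sws1_usage(
      out$expression, detection_threshold = detection_threshold))
  }

  if (!is.null(spectra)) {
    out$spectra_summary <- stage("spectra", {
      tr <- imap(spectra$transmission %||% list(), function(s, nm) {
        mutate(compute_t50(s), id = nm, kind = "transmission")
      })
      rf <- imap(spectra$reflectance %||% list(), function(s, nm) {
        mutate(classify_uv_reflectance(
          s, criterion_fraction = criterion_fraction),
          id = nm, kind = "reflectance")
      })
      bind_rows(bind_rows(tr), bind_rows(rf)) |>
        select("id", "kind", dplyr::everything())
    })
  }

  out$summary <- stage("summary", {
    pieces <- list()
    if (!is.null(out$lambda_estimates)) {
      lam <- out$lambda_estimates
      if (!is.null(out$site_profiles) &&
          "species" %in% names(out$site_profiles)) {
        lam <- left_join(lam,
                         select(out$site_profiles, "id", "species"),
                         by = "id")
      } else {
        lam$species <- lam$id
      }
      pieces$lambda <- lam |>
        group_by(.data$species) |>
        summarise(
          lambda_max_nm = paste(stats::na.omit(.data$lambda_max_nm),
                                collapse = ";"),
          variant_class = paste(.data$variant_class, collapse = ";"),
          .groups = "drop")
    }
    if (!is.null(out$sws1_usage)) {
      pieces$usage <- out$sws1_usage |>
        select(species = "sample", sws1_usage = "usage")
    }
    if (!is.null(out$duplications)) {
      pieces$dup <- out$duplications$assignment |>
        filter(.data$is_tip) |>
        select(species = "label", sws1_copy = "state")
    }
    ss <- out$spectra_summary
    if (!is.null(ss) && nrow(ss) > 0) {
      if ("t50_nm" %in% names(ss)) {
        t50 <- ss |>
          filter(.data$kind == "transmission") |>
          select(species = "id", t50_nm = "t50_nm",
                 lens_class = "classification")
        if (nrow(t50) > 0) pieces$t50 <- t50
      }
      if ("uv_reflective" %in% names(ss)) {
        uv <- ss |>
          filter(.data$kind == "reflectance") |>
          select(species = "id", uv_reflective = "uv_reflective")
        if (nrow(uv) > 0) pieces$uv <- uv
      }
    }
    if (length(pieces) == 0) tibble(species = character(0))
    else Reduce(function(a, b) dplyr::full_join(a, b, by = "species"),
                pieces)
  })

  if (!is.null(out_dir)) {
    tbls <- list(
      site_profiles = out$site_profiles,
      lambda_estimates = out$lambda_estimates,
      expression = out$expression,
      sws1_usage = out$sws1_usage,
      spectra_summary = out$spectra_summary,
      summary = out$summary
    )
    for (nm in names(tbls)) {
      if (!is.null(tbls[[nm]])) {
        write_stage_tsv(tbls[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                        meta)
      }
    }
    if (!is.null(out$duplications)) {
      write_stage_tsv(tidy(out$duplications),
                      file.path(out_dir, "duplication_events.tsv"), meta)
    }
    if (!is.null(out$ancestral)) {
      write_annotated_newick(out$ancestral$site_114,
                             file.path(out_dir, "ancestral_site114.nwk"))
      write_annotated_newick(out$ancestral$site_118,
                             file.path(out_dir, "ancestral_site118.nwk"))
    }
  }
  out
}
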