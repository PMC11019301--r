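# Proportional opsin gene expression from mapped-read counts, normalised by
# CDS length, within single-cone and double-cone gene groups.

#' Default damselfish cone gene groups
#'
#' Damselfish single cones express the SWS genes (SWS1 and its paralogues,
#' SWS2B) while fused double cones express RH2A, RH2B and LWS; proportions
#' are therefore computed within these two groups separately.
#'
#' @return A tibble with columns `gene`, `group`.
#' @export
default_gene_groups <- function() {
  tibble(
    gene = c("SWS1", "SWS1A", "SWS1B", "SWS2B", "RH2A", "RH2B", "LWS"),
    group = c(rep("single_cone", 4), rep("double_cone", 3))
  )
}

#' Proportional opsin gene expression
#'
#' For each gene, the number of mapped reads divided by its CDS length
#' (N_i), expressed as a fraction of the summed N_i over all genes of the
#' same cone-class group in the same sample (T_i / T_all = N_i / sum N_i).
#' Groups whose genes all have zero reads in a sample get `NA` proportions
#' (undefined), never 0.
#'
#' @param counts Tibble with columns `sample`, `gene`, `mapped_reads`
#'   (>= 0) and `cds_length` (> 0); rows with missing or non-positive CDS
#'   length are rejected loudly rather than imputed.
#' @param gene_groups Tibble mapping `gene` to `group`; default
#'   [default_gene_groups()]. Every gene in `counts` must be assigned to
#'   exactly one group.
#' @return A tibble `sample`, `gene`, `group`, `density` (N_i) and
#'   `proportion`, summing to 1 per sample and group wherever defined.
#' @examples
#' counts <- tibble::tibble(
#'   sample = "s1", gene = c("SWS1", "SWS2B"),
#'   mapped_reads = c(100, 200), cds_length = c(1000, 1000))
#' proportional_expression(counts)
#' @export
proportional_expression <- function(counts, gene_groups = default_gene_groups()) {
  need <- c("sample", "gene", "mapped_reads", "cds_length")
  if (!all(need %in% names(counts))) {
    abort(paste("counts must have columns:", paste(need, collapse = ", ")))
  }
  if (any(is.na(counts$cds_length) | counts$cds_length <= 0)) {
    abort("cds_length must be present and > 0 for every row")
  }
  if (any(is.na(counts$mapped_reads) | counts$mapped_reads < 0)) {
    abort("mapped_reads must be present and >= 0")
  }
  dup <- gene_groups |> dplyr::count(.data$gene) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste("genes assigned to more than one group:",
                paste(dup$gene, collapse = ", ")))
  }
  unassigned <- setdiff(unique(counts$gene), gene_groups$gene)
  if (length(unassigned) > 0) {
    abort(paste("genes without a group assignment:",
                paste(unassigned, collapse = ", ")))
  }
  counts |>
    left_join(gene_groups, by = "gene") |>
    mutate(density = .data$mapped_reads / .data$cds_length) |>
    group_by(.data$sample, .data$group) |>
    mutate(proportion = if (sum(.data$density) > 0) {
      .data$density / sum(.data$density)
    } else NA_real_) |>
    ungroup() |>
    select("sample", "gene", "group", "density", "proportion")
}

#' Classify per-sample SWS1 copy usage
#'
#' Labels each sample by how many designated SWS1 paralogues it expresses
#' above a detection threshold: `"both copies"`, `"one copy"` or `"none"`.
#' "Expressed" means the paralogue's proportion of its group's expression is
#' strictly greater than `detection_threshold`.
#'
#' @param proportions Output of [proportional_expression()].
#' @param sws1_genes Gene ids of the SWS1 paralogues. Default
#'   `c("SWS1A", "SWS1B")`.
#' @param detection_threshold Minimum proportion to call a gene expressed;
#'   default 0.01 of group expression. Echoed in the output.
#' @return A tibble `sample`, `n_expressed`, `usage`,
#'   `detection_threshold`.
#' @export
classify_sws1_usage <- function(proportions, sws1_genes = c("SWS1A", "SWS1B"),
                                detection_threshold = 0.01) {
  if (!any(proportions$gene %in% sws1_genes)) {
    warn("no designated SWS1 gene found in the expression table")
  }
  proportions |>
    group_by(.data$sample) |>
    summarise(
      n_expressed = sum(.data$gene %in% sws1_genes &
                          !is.na(.data$proportion) &
                          .data$proportion > detection_threshold),
      .groups = "drop"
    ) |>
    mutate(
      usage = dplyr::case_when(
        .data$n_expressed >= 2 ~ "both copies",
        .data$n_expressed == 1 ~ "one copy",
        TRUE ~ "none"
      ),
      detection_threshold = detection_threshold
    )
}
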