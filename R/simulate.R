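# Seeded synthetic-data generators: every analysis stage can be exercised
# against known ground truth without any external data. A single user seed
# fans out to fixed per-generator offsets so adding a generator never
# perturbs the streams of the others.

SEED_OFFSET <- c(tips = 101L, counts = 211L, presence = 307L, spectrum = 401L)

#' SWS1-consensus root tuning profile used by the sequence simulator
#'
#' Residues planted at the canonical tuning sites of the simulated root
#' sequence: a generic UV-opsin-like profile with the intermediate A114/S118
#' configuration, matching the packaged synthetic reference panel.
#'
#' @return Named character vector keyed by site.
#' @export
sws1_root_profile <- function() {
  c("46" = "F", "49" = "F", "52" = "T", "86" = "F", "90" = "S", "91" = "V",
    "93" = "P", "97" = "S", "109" = "A", "113" = "E", "114" = "A",
    "116" = "L", "118" = "S", "125" = "S", "265" = "W")
}

sim_tree <- function(n_tips, shape, branch_length = 0.1) {
  tree <- switch(shape,
    balanced = ape::stree(n_tips, "balanced"),
    pectinate = ape::stree(n_tips, "left"),
    random = ape::rtree(n_tips),
    abort("tree shape must be balanced, pectinate or random")
  )
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(branch_length, nrow(tree$edge))
  }
  if (!ape::is.rooted(tree)) tree <- ape::multi2di(tree)
  tree
}

#' Simulate opsin tip sequences on a tree with planted tuning-site states
#'
#' Evolves protein sequences down a tree from a root built on the packaged
#' bovine rhodopsin anchor with SWS1-consensus tuning residues. Background
#' positions mutate as a Poisson process (`rate` expected substitutions per
#' residue per unit branch length); the canonical tuning sites are excluded
#' from background mutation (unless `mutate_sites = TRUE`) so planted states
#' stay exact. After evolution, `planted_states` overrides tuning-site
#' residues at named tips, giving every tip a known ground-truth profile.
#'
#' @param n_tips Number of tips when `tree` is not supplied.
#' @param tree Optional `ape::phylo`; default a tree of `tree_shape` with
#'   0.1-substitution branches.
#' @param tree_shape `"balanced"`, `"pectinate"` or `"random"`.
#' @param rate Background substitution rate (per residue per unit branch
#'   length); must be >= 0.
#' @param planted_states Tibble `label`, `site`, `residue` of tuning-site
#'   states to plant at specific tips.
#' @param root_profile Named residue vector for the root's tuning sites;
#'   default [sws1_root_profile()].
#' @param mutate_sites Allow background mutation at tuning sites.
#' @param seed Integer seed; fixes all output bit-for-bit.
#' @return A list: `sequences` (tibble `id`, `species`, `gene`,
#'   `residues`), `tree`, `truth` (tibble `label`, `site`, `residue` — the
#'   ground-truth sidecar for every tip and canonical site) and `config`.
#' @export
simulate_opsin_tips <- function(n_tips = 8, tree = NULL,
                                tree_shape = "balanced", rate = 0.2,
                                planted_states = NULL,
                                root_profile = sws1_root_profile(),
                                mutate_sites = FALSE, seed = 1) {
  if (rate < 0) abort("rate must be >= 0")
  withr::with_seed(seed + SEED_OFFSET[["tips"]], {
    if (is.null(tree)) tree <- sim_tree(n_tips, tree_shape)
    ntip <- ape::Ntip(tree)
    anchor <- stringr::str_split_1(bovine_rhodopsin(), "")
    sites <- as.integer(names(root_profile))
    root <- anchor
    root[sites] <- unname(root_profile)
    bg <- setdiff(seq_along(root),
                  if (mutate_sites) integer(0) else sites)

    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[ntip + 1L]] <- root
    po <- ape::reorder.phylo(tree, "postorder")
    for (e in rev(seq_len(nrow(po$edge)))) {   # preorder
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      s <- seqs[[p]]
      nmut <- rpois(1, rate * po$edge.length[e] * length(bg))
      if (nmut > 0) {
        pos <- sample(bg, min(nmut, length(bg)))
        s[pos] <- map_chr(s[pos], ~ sample(setdiff(AA_CANONICAL, .x), 1))
      }
      seqs[[ch]] <- s
    }

    tipseq <- setNames(seqs[seq_len(ntip)], tree$tip.label)
    if (!is.null(planted_states)) {
      stopifnot(all(c("label", "site", "residue") %in% names(planted_states)))
      bad <- setdiff(planted_states$label, tree$tip.label)
      if (length(bad) > 0) abort(paste("planted labels not in tree:",
                                       paste(bad, collapse = ", ")))
      for (i in seq_len(nrow(planted_states))) {
        lab <- planted_states$label[[i]]
        tipseq[[lab]][planted_states$site[[i]]] <- planted_states$residue[[i]]
      }
    }

    truth_sites <- canonical_tuning_sites(include_125 = TRUE)
    truth <- tidyr::expand_grid(label = tree$tip.label, site = truth_sites) |>
      mutate(residue = purrr::map2_chr(.data$label, .data$site,
                                       function(l, s) tipseq[[l]][s]))
    list(
      sequences = tibble(
        id = tree$tip.label, species = tree$tip.label, gene = "SWS1",
        residues = map_chr(tipseq, paste, collapse = "")
      ),
      tree = tree,
      truth = truth,
      config = list(rate = rate, tree_shape = tree_shape, seed = seed,
                    mutate_sites = mutate_sites)
    )
  })
}

#' Simulate mapped-read counts from known expression proportions
#'
#' Draws reads multinomially within each sample and cone-class group with
#' probabilities proportional to `proportion * cds_length`, so the
#' length-normalised proportional-expression estimator is unbiased for the
#' planted proportions.
#'
#' @param true_proportions Tibble `gene`, `group`, `proportion`,
#'   `cds_length` (optionally `sample`); proportions must sum to 1 within
#'   each sample and group.
#' @param total_reads Reads drawn per sample and group; must be > 0.
#' @param seed Integer seed.
#' @return A list: `counts` (tibble `sample`, `gene`, `mapped_reads`,
#'   `cds_length`), `truth` (the input proportions — the ground-truth
#'   sidecar) and `config`.
#' @export
simulate_counts <- function(true_proportions, total_reads = 1e6, seed = 1) {
  if (total_reads <= 0) abort("total_reads must be > 0")
  tp <- true_proportions
  need <- c("gene", "group", "proportion", "cds_length")
  stopifnot(all(need %in% names(tp)))
  if (!"sample" %in% names(tp)) tp$sample <- "s1"
  sums <- tp |> group_by(.data$sample, .data$group) |>
    summarise(s = sum(.data$proportion), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-6)) {
    abort("true proportions must sum to 1 per sample and group")
  }
  withr::with_seed(seed + SEED_OFFSET[["counts"]], {
    counts <- tp |>
      group_by(.data$sample, .data$group) |>
      mutate(mapped_reads = as.vector(rmultinom(
        1, size = total_reads,
        prob = .data$proportion * .data$cds_length))) |>
      ungroup() |>
      select("sample", "gene", "mapped_reads", "cds_length")
    list(counts = counts, truth = tp,
         config = list(total_reads = total_reads, seed = seed))
  })
}

#' Simulate a gene-presence matrix with planted gain events
#'
#' Marks the duplicate copy present in every tip descending from each
#' planted gain branch (the stem of a clade), then removes it again below
#' any planted loss branches. Loss clades must be nested inside a gain
#' clade; gain clades must be non-nested unless losses are also planted.
#'
#' @param tree Optional `ape::phylo`; default a balanced tree of `n_tips`.
#' @param n_tips Number of tips when `tree` is not supplied.
#' @param gain_clades List of tip-label vectors; each defines the clade
#'   (MRCA of the tips, or the single tip) whose stem carries a gain.
#' @param loss_clades List of tip-label vectors for planted losses.
#' @param seed Integer seed (used only when the tree is generated).
#' @return A list: `tree`, `presence` (tibble `label`, `present`), `truth`
#'   (tibble `event`, `branch`, `n_tips` — the sidecar of planted events)
#'   and `config`.
#' @export
simulate_presence <- function(tree = NULL, n_tips = 16,
                              gain_clades = list(), loss_clades = list(),
                              seed = 1) {
  withr::with_seed(seed + SEED_OFFSET[["presence"]], {
    if (is.null(tree)) tree <- sim_tree(n_tips, "balanced")
  })
  clade_tips <- function(tips) {
    bad <- setdiff(tips, tree$tip.label)
    if (length(bad) > 0) abort(paste("unknown tips:", paste(bad, collapse = ", ")))
    if (length(tips) == 1) return(tips)
    node <- ape::getMRCA(tree, tips)
    ape::extract.clade(tree, node)$tip.label
  }
  gains <- map(gain_clades, clade_tips)
  losses <- map(loss_clades, clade_tips)
  if (length(losses) == 0 && length(gains) > 1) {
    for (i in seq_along(gains)) for (j in seq_along(gains)) {
      if (i != j && all(gains[[i]] %in% gains[[j]])) {
        abort("planted gain clades are nested; plant losses to make this consistent")
      }
    }
  }
  for (l in losses) {
    if (!any(purrr::map_lgl(gains, function(g) all(l %in% g)))) {
      abort("a planted loss clade is not nested inside any gain clade")
    }
  }
  present <- setNames(rep(FALSE, ape::Ntip(tree)), tree$tip.label)
  for (g in gains) present[g] <- TRUE
  for (l in losses) present[l] <- FALSE
  truth <- bind_rows(
    bind_rows(map(gains, ~ tibble(event = "gain",
                                  branch = paste(.x, collapse = ","),
                                  n_tips = length(.x)))),
    bind_rows(map(losses, ~ tibble(event = "loss",
                                   branch = paste(.x, collapse = ","),
                                   n_tips = length(.x))))
  )
  list(
    tree = tree,
    presence = tibble(label = tree$tip.label, present = unname(present)),
    truth = truth,
    config = list(n_gains = length(gains), n_losses = length(losses),
                  seed = seed)
  )
}

#' Simulate a long-pass transmission spectrum
#'
#' Logistic (sigmoidal) transmission curve on a 300-800 nm grid at 1 nm,
#' with optional additive Gaussian noise; the analytic half-maximum
#' midpoint is the planted T50.
#'
#' @param midpoint_nm Logistic midpoint (the true T50); must lie within the
#'   grid.
#' @param width_nm Logistic width parameter (nm); default 8.
#' @param max_value Asymptotic maximal transmission; default 100 (percent).
#' @param noise_sd Additive Gaussian noise SD in value units; must be >= 0.
#' @param wavelength_nm Wavelength grid; default 300:800.
#' @param seed Integer seed.
#' @return A spectrum tibble `wavelength_nm`, `value`, with the planted
#'   parameters in attribute `"truth"`.
#' @export
simulate_spectrum <- function(midpoint_nm = 380, width_nm = 8,
                              max_value = 100, noise_sd = 0,
                              wavelength_nm = 300:800, seed = 1) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (midpoint_nm < min(wavelength_nm) || midpoint_nm > max(wavelength_nm)) {
    abort("midpoint must lie within the wavelength grid")
  }
  withr::with_seed(seed + SEED_OFFSET[["spectrum"]], {
    v <- max_value / (1 + exp(-(wavelength_nm - midpoint_nm) / width_nm))
    if (noise_sd > 0) v <- pmax(v + rnorm(length(v), 0, noise_sd), 0)
    out <- tibble(wavelength_nm = as.numeric(wavelength_nm), value = v)
    attr(out, "truth") <- list(midpoint_nm = midpoint_nm,
                               width_nm = width_nm, max_value = max_value,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}
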