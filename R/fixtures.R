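# Packaged study fixtures: the published damselfish SWS1 copy-number
# matrix, and a schematic tuning-site matrix for ancestral reconstruction.
# Both are built in code; trees are schematic clade topologies, not
# branch-length-calibrated phylogenies.

#' Damselfish SWS1 copy-number matrix on the subfamily clade topology
#'
#' The published genome/transcriptome survey of SWS1 copy number in
#' damselfishes: single-copy *Stegastes partitus* (Stegastinae),
#' *Dascyllus trimaculatus* (Chrominae) and *Acanthochromis polyacanthus*
#' (Pomacentrinae); two copies in *Chromis chromis* (Chrominae), the 11
#' anemonefish species (Amphiprionini), *Pomacentrus amboinensis* and
#' *P. australis*. Tips are arranged on the described clade topology, with
#' the *Pomacentrus* + Amphiprionini clade sister to *A. polyacanthus*
#' within Pomacentrinae — so minimum-gain parsimony recovers one gain at
#' the base of that species-rich Pomacentrinae clade and one on the
#' *Chromis chromis* branch. Branch lengths are uniform placeholders.
#'
#' @return A list with `tree` (`ape::phylo`, 18 tips) and `presence`
#'   (tibble `label`, `present` — `TRUE` when a second SWS1 copy is
#'   present).
#' @examples
#' fx <- damselfish_copy_number()
#' count_gain_events(fx$tree, fx$presence)$n_gains
#' @export
damselfish_copy_number <- function() {
  anemone <- c("akallopisos", "biaculeatus", "bicinctus", "frenatus",
               "melanopus", "nigripes", "ocellaris", "percula",
               "perideraion", "polymnus", "sebae")
  amph <- paste0("Amphiprion_", anemone)
  amph_nwk <- paste0("(", paste(amph, collapse = ","), ")")
  nwk <- paste0(
    "(Stegastes_partitus,((Chromis_chromis,Dascyllus_trimaculatus),",
    "(Acanthochromis_polyacanthus,((Pomacentrus_amboinensis,",
    "Pomacentrus_australis),", amph_nwk, "))));"
  )
  tree <- ape::read.tree(text = nwk)
  tree$edge.length <- rep(0.1, nrow(tree$edge))
  two_copy <- c("Chromis_chromis", "Pomacentrus_amboinensis",
                "Pomacentrus_australis", amph)
  list(
    tree = tree,
    presence = tibble(label = tree$tip.label,
                      present = tree$tip.label %in% two_copy)
  )
}

#' Schematic damselfish tuning-site matrix for sites 114 and 118
#'
#' A synthetic, schematic encoding of the described evolutionary history of
#' the two key SWS1 tuning sites: basal Stegastinae and Abudefdufinae carry
#' the short-variant A114/A118, Chrominae the long-variant S114/S118, and
#' Pomacentrinae carries both post-duplication paralogues (alpha short,
#' beta long). Two outgroup tips carry the intermediate A114/S118
#' configuration, standing in for the non-damselfish reference species
#' included in the published reconstruction. Branch lengths are uniform
#' placeholders; this is a reconstruction fixture, not the authors' tree.
#'
#' @return A list with `tree` (`ape::phylo`, 10 tips) and `tip_states`
#'   (tibble `label`, `site`, `state` for sites 114 and 118).
#' @examples
#' fx <- damselfish_site_matrix()
#' s114 <- dplyr::filter(fx$tip_states, site == 114)
#' fitch_states(fx$tree, s114)
#' @export
damselfish_site_matrix <- function() {
  nwk <- paste0(
    "(Outgroup_1,(Outgroup_2,((Stegastes_partitus,Abudefduf_sexfasciatus),",
    "((Chromis_viridis,Dascyllus_trimaculatus),",
    "((Pomacentrus_amboinensis_alpha,Pomacentrus_australis_alpha),",
    "(Amphiprion_percula_beta,Amphiprion_melanopus_beta))))));"
  )
  tree <- ape::read.tree(text = nwk)
  tree$edge.length <- rep(0.1, nrow(tree$edge))
  prof <- tibble(
    label = tree$tip.label,
    s114 = c("A", "A", "A", "A", "S", "S", "A", "A", "S", "S"),
    s118 = c("S", "S", "A", "A", "S", "S", "A", "A", "S", "S")
  )
  list(
    tree = tree,
    tip_states = prof |>
      tidyr::pivot_longer(-"label", names_to = "site", values_to = "state") |>
      mutate(site = if_else(.data$site == "s114", 114L, 118L)) |>
      arrange(.data$site, .data$label)
  )
}
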