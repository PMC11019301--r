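# Ancestral reconstruction of discrete characters on rooted trees:
# weighted small parsimony (Sankoff; unit costs give Fitch state sets) and
# Mk-model marginal maximum likelihood via Felsenstein pruning.

check_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) abort("tree has duplicated tip labels")
  if (!ape::is.rooted(tree)) {
    abort("tree must be rooted; see root_on() to root on an outgroup or midpoint")
  }
  tree
}

#' Root a tree on an outgroup or at its midpoint
#'
#' Rooted trees are required by the reconstruction functions. Already-rooted
#' input is returned unchanged; otherwise the tree is rooted on the named
#' outgroup, or (when no outgroup is given and branch lengths exist) at its
#' midpoint. The rooting applied is recorded in attribute `"rooting"`.
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup Tip label(s) to root on, or `NULL` for midpoint rooting.
#' @return A rooted `phylo`.
#' @export
root_on <- function(tree, outgroup = NULL) {
  if (ape::is.rooted(tree) && is.null(outgroup)) {
    attr(tree, "rooting") <- "input"
    return(tree)
  }
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    attr(tree, "rooting") <- paste0("outgroup:", paste(outgroup, collapse = ","))
  } else {
    if (!requireNamespace("phangorn", quietly = TRUE)) {
      abort("midpoint rooting needs the phangorn package; supply an outgroup instead")
    }
    tree <- phangorn::midpoint(tree)
    attr(tree, "rooting") <- "midpoint"
  }
  tree
}

# tip states as a character vector named by and aligned to tree$tip.label;
# NA marks a missing (marginalised) tip
tip_state_vec <- function(tree, tip_states, strict = FALSE) {
  if (is.data.frame(tip_states)) {
    stopifnot(all(c("label", "state") %in% names(tip_states)))
    v <- setNames(as.character(tip_states$state), tip_states$label)
  } else {
    v <- as.character(tip_states)
    if (is.null(names(v))) {
      if (length(v) != length(tree$tip.label)) {
        abort("unnamed tip states must match the number of tips")
      }
      names(v) <- tree$tip.label
    }
  }
  extra <- setdiff(names(v), tree$tip.label)
  if (length(extra) > 0) {
    abort(paste("tip states given for labels absent from the tree:",
                paste(extra, collapse = ", ")))
  }
  out <- setNames(v[tree$tip.label], tree$tip.label)
  if (anyNA(out)) {
    miss <- tree$tip.label[is.na(out)]
    if (strict) abort(paste("tips without a state:", paste(miss, collapse = ", ")))
    warn(paste("tips without a state are marginalised over:",
               paste(miss, collapse = ", ")))
  }
  if (all(is.na(out))) abort("no tip has an observed state")
  out
}

# descriptive branch label for a node: tip label, or mrca(first,last tips)
node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  tips <- ape::extract.clade(tree, node)$tip.label
  paste0("mrca(", tips[1], ",", tips[length(tips)], ")")
}

# Sankoff small parsimony. Returns per-node minimal subtree costs, the
# minimum total cost, min-cost state sets and a deterministic assignment
# (ties resolved toward the parent state, then alphabet order).
sankoff <- function(tree, states, alphabet, cost) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  k <- length(alphabet)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  C <- matrix(0, ntip + nnode, k, dimnames = list(NULL, alphabet))
  for (i in seq_len(ntip)) {
    s <- states[[i]]
    if (!is.na(s)) C[i, ] <- if_else(alphabet == s, 0, Inf)
  }
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; ch <- po[e, 2]
    # min over child states of child cost + transition cost, per parent state
    C[p, ] <- C[p, ] + apply(cost + rep(C[ch, ], each = k), 1, min)
  }
  root <- ntip + 1L
  min_cost <- min(C[root, ])

  assign <- character(ntip + nnode)
  pick <- function(costs, prefer = NULL) {
    cand <- alphabet[costs == min(costs)]
    if (!is.null(prefer) && prefer %in% cand) prefer else cand[1]
  }
  assign[root] <- pick(C[root, ])
  for (e in rev(seq_len(nrow(po)))) {       # preorder
    p <- po[e, 1]; ch <- po[e, 2]
    ps <- assign[p]
    assign[ch] <- pick(C[ch, ] + cost[ps, ], prefer = ps)
  }
  sets <- map(seq_len(ntip + nnode),
              function(i) alphabet[C[i, ] == min(C[i, ])])
  list(cost = C, min_cost = min_cost, assignment = assign, state_sets = sets)
}

#' Fitch parsimony ancestral states
#'
#' Minimum-change reconstruction of a discrete character on a rooted tree.
#' Computed as unit-cost weighted parsimony, whose per-node minimum-cost
#' state sets coincide with the Fitch bottom-up sets on binary trees and
#' generalise them to multifurcations. A concrete assignment is chosen by a
#' deterministic top-down pass (ties resolved toward the parent state, then
#' alphabetically), so results are reproducible.
#'
#' Tips without a state (`NA`) are marginalised over with a warning, or
#' rejected when `strict = TRUE`.
#'
#' @param tree A rooted `ape::phylo`.
#' @param tip_states Tibble with columns `label`, `state`, or a character
#'   vector named by tip label.
#' @param states Optional extra states to include in the alphabet beyond
#'   those observed at the tips.
#' @param strict Reject missing tip states instead of marginalising.
#' @return An object of class `ancestral_fit` with elements `tree`,
#'   `method`, `states`, `min_changes` and `assignment` (a tibble with
#'   `node`, `label`, `state` and list-column `state_set`). Use [tidy()] /
#'   [glance()] to extract tables.
#' @examples
#' tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
#' fit <- fitch_states(tr, c(t1 = "A", t2 = "A", t3 = "S", t4 = "S"))
#' fit$min_changes
#' @export
fitch_states <- function(tree, tip_states, states = NULL, strict = FALSE) {
  tree <- check_tree(tree)
  v <- tip_state_vec(tree, tip_states, strict = strict)
  alphabet <- sort(unique(c(v[!is.na(v)], states)))
  k <- length(alphabet)
  cost <- matrix(1, k, k, dimnames = list(alphabet, alphabet)) - diag(k)
  res <- sankoff(tree, v, alphabet, cost)
  ntip <- ape::Ntip(tree)
  assignment <- tibble(
    node = seq_len(ntip + tree$Nnode),
    label = map_chr(seq_len(ntip + tree$Nnode), ~ node_label(tree, .x)),
    is_tip = .data$node <= ntip,
    state = res$assignment,
    state_set = res$state_sets
  )
  structure(
    list(tree = tree, method = "fitch", states = alphabet,
         min_changes = res$min_cost, assignment = assignment,
         tip_states = v),
    class = "ancestral_fit"
  )
}

# Mk transition probability: symmetric k-state model with pairwise rate
# `rate`; P_ii = 1/k + (k-1)/k e^{-k r t}, P_ij = 1/k - 1/k e^{-k r t}
mk_pmat <- function(k, rate, t) {
  e <- exp(-k * rate * t)
  matrix(1 / k - e / k, k, k) + diag(k) * e
}

#' Mk-model marginal maximum-likelihood ancestral states
#'
#' Marginal posterior state probabilities at every internal node under the
#' symmetric k-state Markov (Mk) model, computed by Felsenstein pruning
#' with the node of interest constrained to each state in turn (exact
#' marginalisation; flat root prior). The reported state is the posterior
#' argmax with a deterministic alphabetical tie-break. Missing branch
#' lengths default to 1.
#'
#' @inheritParams fitch_states
#' @param rate Pairwise substitution rate of the Mk model (per unit branch
#'   length). Default 1.
#' @return An `ancestral_fit` with `loglik`, `rate`, and an `assignment`
#'   tibble carrying one posterior column `p_<state>` per state (rows sum
#'   to 1).
#' @export
ml_marginal_states <- function(tree, tip_states, rate = 1, states = NULL,
                               strict = FALSE) {
  tree <- check_tree(tree)
  if (ape::Ntip(tree) < 2) abort("tree must have at least two tips")
  if (rate <= 0) abort("rate must be positive")
  v <- tip_state_vec(tree, tip_states, strict = strict)
  alphabet <- sort(unique(c(v[!is.na(v)], states)))
  k <- length(alphabet)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  bl <- po$edge.length
  if (is.null(bl)) bl <- rep(1, nrow(po$edge))
  bl[is.na(bl)] <- 1
  if (any(bl < 0)) abort("negative branch lengths")
  pmats <- map(bl, ~ mk_pmat(k, rate, .x))

  # likelihood of the data with one node optionally constrained to a state
  lik <- function(constrain_node = NULL, constrain_state = NULL) {
    L <- matrix(1, ntip + nnode, k)
    for (i in seq_len(ntip)) {
      if (!is.na(v[[i]])) L[i, ] <- as.numeric(alphabet == v[[i]])
    }
    if (!is.null(constrain_node) && constrain_node <= ntip) {
      L[constrain_node, ] <- L[constrain_node, ] *
        as.numeric(alphabet == constrain_state)
    }
    done <- rep(FALSE, ntip + nnode)
    for (e in seq_len(nrow(po$edge))) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      if (ch > ntip && !done[ch]) {
        # child's partials complete (postorder); apply any constraint once
        if (!is.null(constrain_node) && ch == constrain_node) {
          L[ch, ] <- L[ch, ] * as.numeric(alphabet == constrain_state)
        }
        done[ch] <- TRUE
      }
      L[p, ] <- L[p, ] * as.vector(pmats[[e]] %*% L[ch, ])
    }
    root <- ntip + 1L
    if (!is.null(constrain_node) && constrain_node == root) {
      L[root, ] <- L[root, ] * as.numeric(alphabet == constrain_state)
    }
    sum(L[root, ] / k)
  }

  total <- lik()
  if (total <= 0) abort("data have zero likelihood under the Mk model")
  internal <- ntip + seq_len(nnode)
  post <- matrix(NA_real_, nnode, k, dimnames = list(NULL, alphabet))
  for (j in seq_len(nnode)) {
    post[j, ] <- map_dbl(alphabet, ~ lik(internal[j], .x)) / total
  }
  tip_post <- matrix(0, ntip, k, dimnames = list(NULL, alphabet))
  for (i in seq_len(ntip)) {
    tip_post[i, ] <- if (is.na(v[[i]])) {
      map_dbl(alphabet, ~ lik(i, .x)) / total
    } else {
      as.numeric(alphabet == v[[i]])
    }
  }
  allpost <- rbind(tip_post, post)
  # argmax with an alphabetical tie-break robust to float noise in exact ties
  state <- alphabet[apply(allpost, 1, function(p) {
    which(p >= max(p) - 1e-9)[1]
  })]
  assignment <- bind_cols(
    tibble(
      node = seq_len(ntip + nnode),
      label = map_chr(seq_len(ntip + nnode), ~ node_label(tree, .x)),
      is_tip = .data$node <= ntip,
      state = state
    ),
    as_tibble(as.data.frame(allpost)) |>
      rlang::set_names(paste0("p_", alphabet))
  )
  structure(
    list(tree = tree, method = "ml", states = alphabet, rate = rate,
         loglik = log(total), assignment = assignment, tip_states = v),
    class = "ancestral_fit"
  )
}

#' Joint label of two tuning sites at a node
#'
#' Concatenates the reported states of two single-site reconstructions at
#' one node, in the order the fits are supplied (here conventionally sites
#' 114 then 118, so e.g. `"AS"` denotes the intermediate pigment between the
#' short `"AA"` and long `"SS"` forms). Both fits must be on the same tree.
#'
#' @param fit_a,fit_b `ancestral_fit` objects on the same tree.
#' @param node Node number, tip label, or internal-node label as given in
#'   the fits' `assignment`; default the root.
#' @return A two-letter character label.
#' @export
joint_site_label <- function(fit_a, fit_b, node = NULL) {
  stopifnot(inherits(fit_a, "ancestral_fit"), inherits(fit_b, "ancestral_fit"))
  same <- identical(fit_a$tree$tip.label, fit_b$tree$tip.label) &&
    identical(fit_a$tree$edge, fit_b$tree$edge)
  if (!same) abort("the two reconstructions are not on the same tree")
  if (is.null(node)) node <- ape::Ntip(fit_a$tree) + 1L
  find <- function(fit) {
    a <- fit$assignment
    row <- if (is.numeric(node)) which(a$node == node) else which(a$label == node)
    if (length(row) != 1) abort(paste("node not found in assignment:", node))
    a$state[[row]]
  }
  paste0(find(fit_a), find(fit_b))
}

#' Minimum gain (duplication) events for a presence/absence character
#'
#' Weighted small parsimony (Sankoff) over states absent/present, with
#' configurable gain (absent to present) and loss costs. A gain here proxies
#' a gene duplication becoming detectable on a branch. Tips with `NA`
#' presence (e.g. absence from a transcriptome that may reflect expression
#' failure rather than gene loss) are marginalised over. Among co-optimal
#' labellings the deterministic traceback keeps ancestral nodes in their
#' parent's state where possible, which places ties tipward (later gains).
#'
#' @param tree A rooted `ape::phylo`.
#' @param presence Tibble with columns `label` and `present`
#'   (logical/0/1, `NA` for missing), or a named logical vector.
#' @param gain_cost,loss_cost Transition costs; defaults 1/1. A sensitivity
#'   setting of `gain_cost = 2, loss_cost = 1` is useful when absence calls
#'   are soft.
#' @return An object of class `gain_report`: `n_gains`, `n_losses`,
#'   `total_cost`, tibbles `gain_branches`/`loss_branches` (branch named by
#'   its child node), and the full node `assignment`.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' count_gain_events(tr, c(a = TRUE, b = TRUE, c = FALSE, d = FALSE))
#' @export
count_gain_events <- function(tree, presence, gain_cost = 1, loss_cost = 1) {
  tree <- check_tree(tree)
  if (is.data.frame(presence)) {
    stopifnot(all(c("label", "present") %in% names(presence)))
    pv <- setNames(as.logical(presence$present), presence$label)
  } else {
    pv <- as.logical(presence)
    if (is.null(names(pv))) names(pv) <- tree$tip.label
  }
  v <- setNames(rep(NA_character_, ape::Ntip(tree)), tree$tip.label)
  known <- names(pv)[!is.na(pv)]
  v[known] <- if_else(pv[known], "present", "absent")
  if (all(is.na(v))) abort("presence is missing for every tip")
  if (anyNA(v)) {
    warn(paste("tips with missing presence are marginalised over:",
               paste(names(v)[is.na(v)], collapse = ", ")))
  }
  alphabet <- c("absent", "present")
  cost <- matrix(c(0, loss_cost, gain_cost, 0), 2, 2,
                 dimnames = list(alphabet, alphabet))
  res <- sankoff(tree, v, alphabet, cost)

  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  ps <- res$assignment[edge[, 1]]
  cs <- res$assignment[edge[, 2]]
  gain_e <- which(ps == "absent" & cs == "present")
  loss_e <- which(ps == "present" & cs == "absent")
  branch_tbl <- function(es) tibble(
    parent = edge[es, 1], child = edge[es, 2],
    branch = map_chr(edge[es, 2], ~ node_label(tree, .x))
  )
  n_gains <- length(gain_e); n_losses <- length(loss_e)
  stopifnot(isTRUE(all.equal(
    n_gains * gain_cost + n_losses * loss_cost, res$min_cost)))
  assignment <- tibble(
    node = seq_len(ntip + tree$Nnode),
    label = map_chr(seq_len(ntip + tree$Nnode), ~ node_label(tree, .x)),
    is_tip = .data$node <= ntip,
    state = res$assignment
  )
  structure(
    list(n_gains = n_gains, n_losses = n_losses, total_cost = res$min_cost,
         gain_cost = gain_cost, loss_cost = loss_cost,
         gain_branches = branch_tbl(gain_e), loss_branches = branch_tbl(loss_e),
         assignment = assignment, tree = tree),
    class = "gain_report"
  )
}

#' Write a tree annotated with reconstructed node states
#'
#' Emits newick with internal-node labels carrying the reconstructed state
#' (and, for ML fits, the posterior of that state to two decimals).
#'
#' @param fit An `ancestral_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_newick <- function(fit, path) {
  stopifnot(inherits(fit, "ancestral_fit"))
  tree <- fit$tree
  ntip <- ape::Ntip(tree)
  a <- fit$assignment[!fit$assignment$is_tip, ]
  lab <- a$state
  if (fit$method == "ml") {
    pmax <- apply(as.matrix(a[paste0("p_", fit$states)]), 1, max)
    lab <- sprintf("%s_%.2f", lab, pmax)
  }
  tree$node.label <- lab
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @export
print.ancestral_fit <- function(x, ...) {
  cat("Ancestral state reconstruction (", x$method, ")\n", sep = "")
  cat("  tips:", ape::Ntip(x$tree), " states:", paste(x$states, collapse = "/"), "\n")
  if (x$method == "fitch") cat("  minimum changes:", x$min_changes, "\n")
  if (x$method == "ml") cat("  log-likelihood:", format(x$loglik), " rate:", x$rate, "\n")
  root <- x$assignment$state[[ape::Ntip(x$tree) + 1L]]
  cat("  root state:", root, "\n")
  invisible(x)
}

#' @export
print.gain_report <- function(x, ...) {
  cat("Gain/loss parsimony (gain cost ", x$gain_cost, ", loss cost ",
      x$loss_cost, ")\n", sep = "")
  cat("  gains:", x$n_gains, " losses:", x$n_losses,
      " total cost:", x$total_cost, "\n")
  if (x$n_gains > 0) {
    cat("  gain branches:\n")
    for (b in x$gain_branches$branch) cat("    -", b, "\n")
  }
  invisible(x)
}
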