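# Independent brute-force oracles for the reconstruction functions, and
# small fixture builders. The oracles enumerate all internal-node state
# assignments directly; they share no code with the package's dynamic
# programming.

# minimum weighted change cost over all internal assignments
oracle_parsimony <- function(tree, tip_states, alphabet, cost) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  edge <- tree$edge
  tip_idx <- match(tip_states[tree$tip.label], alphabet)
  grids <- rep(list(seq_along(alphabet)), nnode)
  combos <- expand.grid(grids)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    assign <- c(tip_idx, as.integer(combos[r, ]))
    tot <- sum(cost[cbind(assign[edge[, 1]], assign[edge[, 2]])])
    best <- min(best, tot)
  }
  best
}

# Mk transition probability, written out independently of the package
oracle_pij <- function(k, rate, t, same) {
  e <- exp(-k * rate * t)
  if (same) 1 / k + (k - 1) / k * e else 1 / k - 1 / k * e
}

# marginal posterior at every internal node by explicit summation
oracle_ml_posteriors <- function(tree, tip_states, alphabet, rate = 1) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  k <- length(alphabet)
  edge <- tree$edge
  bl <- tree$edge.length
  tip_idx <- match(tip_states[tree$tip.label], alphabet)
  combos <- expand.grid(rep(list(seq_len(k)), nnode))
  post <- matrix(0, nnode, k, dimnames = list(NULL, alphabet))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    assign <- c(tip_idx, as.integer(combos[r, ]))
    p <- 1 / k
    for (e in seq_len(nrow(edge))) {
      p <- p * oracle_pij(k, rate, bl[e],
                          assign[edge[e, 1]] == assign[edge[e, 2]])
    }
    total <- total + p
    for (j in seq_len(nnode)) {
      s <- as.integer(combos[r, j])
      post[j, s] <- post[j, s] + p
    }
  }
  post / total
}

random_binary_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- pmax(tr$edge.length, 0.05)
  tr
}

random_states <- function(tree, alphabet = c("A", "S")) {
  setNames(sample(alphabet, ape::Ntip(tree), replace = TRUE),
           tree$tip.label)
}
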