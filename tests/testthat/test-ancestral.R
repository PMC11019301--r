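quartet <- ape::read.tree(text = "((t1,t2),(t3,t4));")
quartet$edge.length <- rep(1, nrow(quartet$edge))

test_that("constant characters reconstruct with zero changes", {
  fit <- fitch_states(quartet, c(t1 = "A", t2 = "A", t3 = "A", t4 = "A"))
  expect_equal(fit$min_changes, 0)
  internal <- dplyr::filter(tidy(fit), !is_tip)
  expect_true(all(purrr::map_lgl(internal$state_set, identical, "A")))
  expect_true(all(internal$state == "A"))
})

test_that("a single clade-level substitution costs one change with an ambiguous root", {
  fit <- fitch_states(quartet, c(t1 = "A", t2 = "A", t3 = "S", t4 = "S"))
  expect_equal(fit$min_changes, 1)
  root_set <- tidy(fit)$state_set[[5]]
  expect_setequal(root_set, c("A", "S"))
})

test_that("parsimony counts match brute-force enumeration and phangorn on random trees", {
  alphabet <- c("A", "S")
  cost <- matrix(1, 2, 2, dimnames = list(alphabet, alphabet)) - diag(2)
  for (seed in 1:100) {
    set.seed(seed)
    tr <- random_binary_tree(6)
    st <- random_states(tr, alphabet)
    fit <- fitch_states(tr, st)
    expect_equal(fit$min_changes, oracle_parsimony(tr, st, alphabet, cost),
                 info = paste("seed", seed))
  }
  # independent library cross-check of the unit-cost count
  set.seed(202)
  tr <- random_binary_tree(12)
  st <- random_states(tr, c("A", "S", "T"))
  pd <- phangorn::phyDat(matrix(st[tr$tip.label], ncol = 1,
                                dimnames = list(tr$tip.label, NULL)),
                         type = "USER", levels = c("A", "S", "T"))
  expect_equal(fitch_states(tr, st)$min_changes,
               as.numeric(phangorn::parsimony(tr, pd)))
})

test_that("missing tip states are marginalised with a warning, or rejected in strict mode", {
  st <- c(t1 = "A", t2 = "A", t3 = NA, t4 = "S")
  expect_warning(fit <- fitch_states(quartet, st), "marginalised")
  expect_equal(fit$min_changes, 1)
  expect_error(fitch_states(quartet, st, strict = TRUE), "without a state")
  expect_error(suppressWarnings(
    fitch_states(quartet, c(t1 = NA, t2 = NA, t3 = NA, t4 = NA))),
    "no tip")
})

test_that("ML posteriors behave at the degenerate and symmetric limits", {
  fit <- ml_marginal_states(quartet, c(t1 = "A", t2 = "A", t3 = "A", t4 = "A"),
                            rate = 0.05, states = "S")
  root <- dplyr::filter(tidy(fit), node == 5)
  expect_gte(root$p_A, 0.99)

  # mirrored states on a symmetric tree: exactly 0.5/0.5 at the root
  fit2 <- ml_marginal_states(quartet, c(t1 = "A", t2 = "S", t3 = "A", t4 = "S"))
  root2 <- dplyr::filter(tidy(fit2), node == 5)
  expect_equal(root2$p_A, 0.5, tolerance = 1e-12)
  expect_equal(root2$p_S, 0.5, tolerance = 1e-12)
  # deterministic alphabetical tie-break
  expect_equal(root2$state, "A")

  expect_error(ml_marginal_states(quartet, "A"), "unnamed tip states")
})

test_that("ML marginal posteriors match brute-force summation on small trees", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:5, 1)
    tr <- random_binary_tree(n)
    st <- random_states(tr)
    if (length(unique(st)) < 2) st[1] <- setdiff(c("A", "S"), st[1])[1]
    fit <- ml_marginal_states(tr, st, rate = 0.7)
    oracle <- oracle_ml_posteriors(tr, st, sort(unique(st)), rate = 0.7)
    got <- as.matrix(dplyr::filter(tidy(fit), !is_tip)[c("p_A", "p_S")])
    expect_equal(unname(got), unname(oracle), tolerance = 1e-8,
                 info = paste("seed", seed))
    # posteriors sum to one at every node
    expect_equal(unname(rowSums(got)), rep(1, nrow(got)), tolerance = 1e-9)
  }
})

test_that("ML posteriors are invariant to tip-state row order", {
  set.seed(5)
  tr <- random_binary_tree(6)
  st <- tibble::tibble(label = tr$tip.label,
                       state = sample(c("A", "S"), 6, replace = TRUE))
  a <- ml_marginal_states(tr, st)
  b <- ml_marginal_states(tr, st[sample(6), ])
  expect_equal(tidy(a), tidy(b))
})

test_that("joint site labels concatenate per-site root states", {
  fx <- damselfish_site_matrix()
  f114 <- fitch_states(fx$tree, dplyr::filter(fx$tip_states, site == 114))
  f118 <- fitch_states(fx$tree, dplyr::filter(fx$tip_states, site == 118))
  expect_equal(joint_site_label(f114, f118), "AS")
  # tip of a short-variant lineage
  expect_equal(joint_site_label(f114, f118, node = "Stegastes_partitus"), "AA")
  other <- fitch_states(quartet, c(t1 = "A", t2 = "A", t3 = "S", t4 = "S"))
  expect_error(joint_site_label(f114, other), "same tree")
  expect_error(joint_site_label(f114, f118, node = "no_such_node"), "not found")
})

test_that("gain parsimony recovers a single origin and handles missing tips", {
  tr <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  rep1 <- count_gain_events(tr, c(a = FALSE, b = FALSE, c = TRUE, d = TRUE,
                                  e = TRUE))
  expect_equal(rep1$n_gains, 1)
  expect_equal(rep1$n_losses, 0)
  expect_equal(rep1$gain_branches$branch, "mrca(c,e)")

  expect_warning(
    rep2 <- count_gain_events(tr, c(a = FALSE, b = FALSE, c = NA, d = TRUE,
                                    e = TRUE)),
    "marginalised")
  expect_equal(rep2$n_gains, 1)
  expect_error(count_gain_events(tr, setNames(rep(NA, 5), tr$tip.label)),
               "missing")
})

test_that("weighted gain/loss cost matches brute force on random presence patterns", {
  alphabet <- c("absent", "present")
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:7, 1)
    tr <- random_binary_tree(n)
    pres <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), tr$tip.label)
    if (!any(pres)) pres[1] <- TRUE
    for (gc in c(1, 2)) {
      cost <- matrix(c(0, 1, gc, 0), 2, 2,
                     dimnames = list(alphabet, alphabet))
      rep <- count_gain_events(tr, pres, gain_cost = gc, loss_cost = 1)
      st <- ifelse(pres, "present", "absent")
      expect_equal(rep$total_cost, oracle_parsimony(tr, st, alphabet, cost),
                   info = paste("seed", seed, "gain cost", gc))
      expect_equal(rep$n_gains * gc + rep$n_losses, rep$total_cost)
    }
  }
})

test_that("rooting helper roots on an outgroup and flags the choice", {
  tr <- ape::unroot(ape::read.tree(text = "((a,b),(c,d),e);"))
  rooted <- root_on(tr, outgroup = "e")
  expect_true(ape::is.rooted(rooted))
  expect_match(attr(rooted, "rooting"), "outgroup:e")
  expect_error(fitch_states(tr, c(a = "A", b = "A", c = "S", d = "S", e = "A")),
               "rooted")
})

test_that("tidiers and the annotated newick writer expose the reconstruction", {
  fx <- damselfish_site_matrix()
  fit <- ml_marginal_states(fx$tree, dplyr::filter(fx$tip_states, site == 118))
  g <- glance(fit)
  expect_equal(g$method, "ml")
  expect_equal(g$root_state, "S")
  expect_true(all(c("p_A", "p_S") %in% names(tidy(fit))))

  f <- withr::local_tempfile(fileext = ".nwk")
  write_annotated_newick(fit, f)
  back <- ape::read.tree(f)
  expect_equal(sort(back$tip.label), sort(fx$tree$tip.label))
  expect_match(back$node.label[1], "^[AS]_0\\.\\d+")

  rep <- count_gain_events(damselfish_copy_number()$tree,
                           damselfish_copy_number()$presence)
  expect_equal(glance(rep)$n_gains, 2)
  expect_equal(nrow(tidy(rep)), 2)
})
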