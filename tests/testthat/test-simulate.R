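test_that("zero-rate simulation leaves all tips identical to the root", {
  sim <- simulate_opsin_tips(n_tips = 4, rate = 0, seed = 3)
  expect_equal(length(unique(sim$sequences$residues)), 1)
  # root carries the consensus tuning residues on the anchor backbone
  prof <- extract_site_profiles(sim$sequences[1, ])
  expect_equal(prof$site_114, "A")
  expect_equal(prof$site_118, "S")
  expect_error(simulate_opsin_tips(rate = -1), "rate")
})

test_that("sequence simulation is byte-deterministic under a fixed seed", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_opsin_fasta(simulate_opsin_tips(n_tips = 8, rate = 0.3, seed = 9)$sequences, f1)
  write_opsin_fasta(simulate_opsin_tips(n_tips = 8, rate = 0.3, seed = 9)$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  alt <- simulate_opsin_tips(n_tips = 8, rate = 0.3, seed = 10)$sequences
  expect_false(identical(
    simulate_opsin_tips(n_tips = 8, rate = 0.3, seed = 9)$sequences$residues,
    alt$residues))
})

test_that("planted clade states are recovered through the full tuning pipeline", {
  tree <- ape::stree(8, "balanced")
  tree$edge.length <- rep(0.1, nrow(tree$edge))
  short_tips <- tree$tip.label[1:4]
  long_tips <- tree$tip.label[5:8]
  planted <- dplyr::bind_rows(
    tidyr::expand_grid(label = short_tips, site = c(114L, 118L),
                       residue = "A"),
    tidyr::expand_grid(label = long_tips, site = c(114L, 118L),
                       residue = "S")
  )
  sim <- simulate_opsin_tips(tree = tree, rate = 0.15,
                             planted_states = planted, seed = 21)
  est <- extract_site_profiles(sim$sequences) |>
    estimate_lambda_max()
  expect_equal(est$variant_class[match(short_tips, est$id)],
               rep("short", 4))
  expect_equal(est$variant_class[match(long_tips, est$id)],
               rep("long", 4))
})

test_that("count simulation is degenerate, deterministic and validated", {
  tp <- tibble::tibble(gene = c("g1", "g2"), group = "single_cone",
                       proportion = c(1, 0), cds_length = c(1000, 1000))
  sim <- simulate_counts(tp, total_reads = 1e4, seed = 2)
  expect_equal(sim$counts$mapped_reads, c(1e4, 0))

  tp2 <- tibble::tibble(gene = c("g1", "g2"), group = "single_cone",
                        proportion = c(0.4, 0.6), cds_length = c(800, 1600))
  a <- simulate_counts(tp2, total_reads = 1e5, seed = 4)$counts
  b <- simulate_counts(tp2, total_reads = 1e5, seed = 4)$counts
  expect_identical(a, b)
  expect_error(simulate_counts(tp2, total_reads = 0), "total_reads")
  bad <- dplyr::mutate(tp2, proportion = c(0.5, 0.6))
  expect_error(simulate_counts(bad), "sum to 1")
})

test_that("presence simulation plants recoverable gain and loss events", {
  tree <- ape::stree(16, "balanced")
  tree$edge.length <- rep(1, nrow(tree$edge))
  t <- tree$tip.label

  two <- simulate_presence(tree = tree, gain_clades = list(t[1:4], t[9:12]))
  expect_equal(count_gain_events(two$tree, two$presence)$n_gains, 2)
  expect_equal(nrow(two$truth), 2)

  none <- simulate_presence(tree = tree, gain_clades = list())
  expect_equal(count_gain_events(none$tree, none$presence)$n_gains, 0)

  # one gain with a nested loss: reported reconstruction cost 2,
  # confirmed against exhaustive enumeration
  gl <- simulate_presence(tree = tree, gain_clades = list(t[1:8]),
                          loss_clades = list(t[1:2]))
  rep <- count_gain_events(gl$tree, gl$presence)
  expect_equal(rep$total_cost, 2)
  st <- setNames(ifelse(gl$presence$present, "present", "absent"),
                 gl$presence$label)
  cost <- matrix(c(0, 1, 1, 0), 2, 2,
                 dimnames = list(c("absent", "present"),
                                 c("absent", "present")))
  # brute force on a pruned 8-tip copy of the informative clade
  sub8 <- ape::keep.tip(tree, t[1:8])
  expect_equal(oracle_parsimony(sub8, st[t[1:8]], c("absent", "present"),
                                cost) + 1,  # +1 for the gain on the stem
               rep$total_cost)

  expect_error(simulate_presence(tree = tree,
                                 gain_clades = list(t[1:8], t[1:2])),
               "nested")
  expect_error(simulate_presence(tree = tree, gain_clades = list(t[1:4]),
                                 loss_clades = list(t[9:10])),
               "not nested inside")
})

test_that("spectrum simulation hits its planted midpoint and validates inputs", {
  s <- simulate_spectrum(midpoint_nm = 380, noise_sd = 0)
  expect_equal(compute_t50(s)$t50_nm, 380)
  expect_equal(compute_t50(simulate_spectrum(410, noise_sd = 0))$classification,
               "UV-blocking")
  a <- simulate_spectrum(370, noise_sd = 2, seed = 8)
  b <- simulate_spectrum(370, noise_sd = 2, seed = 8)
  expect_identical(a$value, b$value)
  expect_error(simulate_spectrum(noise_sd = -1), "noise_sd")
  expect_error(simulate_spectrum(midpoint_nm = 250), "within the wavelength grid")
})
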