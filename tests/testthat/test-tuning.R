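# fixture profiles: only sites 114/118 vary, other sites at panel consensus
consensus_profile <- function(id, s114, s118) {
  p <- default_reference_panel()[1, ]
  p <- p[grepl("^site_", names(p))]
  p$site_114 <- s114
  p$site_118 <- s118
  dplyr::bind_cols(tibble::tibble(id = id), p)
}

test_that("polarity change flags differing polarity classes", {
  expect_true(polarity_change(125, "S", "A"))
  expect_false(polarity_change(114, "S", "T"))
  expect_false(polarity_change(118, "A", "G"))
  expect_warning(res <- polarity_change(114, "X", "A"), "undefined")
  expect_true(is.na(res))
  expect_equal(nrow(aa_polarity()), 20)
})

test_that("reference matching ranks by mismatch with deterministic tie-breaks", {
  panel <- tibble::tibble(
    species = c("ref_damsel", "ref_vitro", "ref_msp"),
    gene = "SWS1",
    lambda_max_nm = c(360, 360, 368),
    method = c("MSP", "in-vitro", "MSP"),
    is_damselfish = c(TRUE, FALSE, FALSE),
    site_114 = c("A", "A", "S"),
    site_118 = c("A", "A", "S")
  )
  # identical profile -> first with 0 mismatches
  q <- tibble::tibble(id = "q", site_114 = "S", site_118 = "S")
  r <- match_reference(q, panel, sites = c(114, 118))
  expect_equal(r$species[1], "ref_msp")
  expect_equal(r$n_mismatch[1], 0L)

  # one substitution away: mismatch list has length 1
  q2 <- tibble::tibble(id = "q", site_114 = "A", site_118 = "S")
  r2 <- match_reference(q2, panel, sites = c(114, 118))
  expect_equal(r2$n_mismatch[1], 1L)
  expect_length(r2$mismatched_sites[[1]], 1)

  # q2 is 1 mismatch from all three entries: damselfish entry must win
  expect_equal(r2$species[1], "ref_damsel")
  # among the two non-damselfish ties, in-vitro precedes MSP
  expect_equal(r2$species[2:3], c("ref_vitro", "ref_msp"))

  expect_error(match_reference(
    tibble::tibble(id = "q", site_114 = NA_character_), panel, sites = 114
  ), "no residues")
})

test_that("lambda-max estimation applies site effects from the closest reference", {
  # identity: no effects applied
  aa <- consensus_profile("aa", "A", "A")
  e <- estimate_lambda_max(aa)
  expect_equal(e$lambda_max_nm, e$reference_lambda_nm)
  expect_equal(e$n_applied, 0L)

  # A118S applied forward: +5 nm
  ref <- tibble::tibble(species = "ref", gene = "SWS1", lambda_max_nm = 358,
                        method = "in-vitro", is_damselfish = FALSE,
                        site_114 = "A", site_118 = "A")
  q <- tibble::tibble(id = "q", site_114 = "A", site_118 = "S")
  e2 <- estimate_lambda_max(q, panel = ref, sites = c(114, 118))
  expect_equal(e2$lambda_max_nm, 363)
  expect_match(e2$applied_effects, "A118S\\(\\+5\\)")

  # reverse direction with sign flip: SS reference at 370 predicts AA at 360
  ref_ss <- tibble::tibble(species = "ref_ss", gene = "SWS1",
                           lambda_max_nm = 370, method = "in-vitro",
                           is_damselfish = FALSE,
                           site_114 = "S", site_118 = "S")
  qaa <- tibble::tibble(id = "q", site_114 = "A", site_118 = "A")
  e3 <- estimate_lambda_max(qaa, panel = ref_ss, sites = c(114, 118))
  expect_equal(e3$lambda_max_nm, 360)
  expect_equal(e3$variant_class, "short")
})

test_that("ambiguity and low homology give undetermined estimates", {
  qx <- consensus_profile("qx", "X", "A")
  ex <- estimate_lambda_max(qx)
  expect_true(is.na(ex$lambda_max_nm))
  expect_match(ex$reason, "ambiguous")
  expect_equal(ex$variant_class, "unclassified")

  # mismatch at a site with no packaged effect -> refused at threshold 0
  q265 <- consensus_profile("q265", "A", "A")
  q265$site_265 <- "Y"
  e <- estimate_lambda_max(q265)
  expect_true(is.na(e$lambda_max_nm))
  expect_match(e$reason, "homology")
  # but allowed when the homology threshold admits one unmatched site
  e2 <- estimate_lambda_max(q265, homology_threshold = 1)
  expect_false(is.na(e2$lambda_max_nm))
  expect_equal(e2$n_unmatched_sites, 1L)
})

test_that("estimation is invariant to panel row order", {
  q <- consensus_profile("q", "A", "S")
  panel <- default_reference_panel()
  base <- estimate_lambda_max(q, panel = panel)
  set.seed(11)
  for (i in 1:10) {
    perm <- panel[sample(nrow(panel)), ]
    e <- estimate_lambda_max(q, panel = perm)
    expect_equal(e$lambda_max_nm, base$lambda_max_nm)
    expect_equal(e$reference, base$reference)
  }
})

test_that("opposite substitutions cancel exactly", {
  eff <- default_site_effects()
  ref_a <- tibble::tibble(species = "ra", gene = "SWS1", lambda_max_nm = 360,
                          method = "in-vitro", is_damselfish = FALSE,
                          site_118 = "A")
  ref_s <- dplyr::mutate(ref_a, species = "rs", site_118 = "S")
  up <- estimate_lambda_max(tibble::tibble(id = "q", site_118 = "S"),
                            panel = ref_a, effects = eff, sites = 118)
  down <- estimate_lambda_max(tibble::tibble(id = "q", site_118 = "A"),
                              panel = ref_s, effects = eff, sites = 118)
  shift_up <- up$lambda_max_nm - up$reference_lambda_nm
  shift_down <- down$lambda_max_nm - down$reference_lambda_nm
  expect_equal(shift_up + shift_down, 0)
})

test_that("AA profiles land in the short class and SS in the long class from any damselfish reference", {
  panel <- default_reference_panel()
  damsels <- dplyr::filter(panel, is_damselfish)
  expect_gt(nrow(damsels), 1)
  for (i in seq_len(nrow(damsels))) {
    one <- damsels[i, ]
    aa <- estimate_lambda_max(consensus_profile("aa", "A", "A"), panel = one)
    ss <- estimate_lambda_max(consensus_profile("ss", "S", "S"), panel = one)
    expect_true(aa$lambda_max_nm >= 356 && aa$lambda_max_nm <= 362,
                info = one$species)
    expect_true(ss$lambda_max_nm >= 368 && ss$lambda_max_nm <= 370,
                info = one$species)
    expect_equal(ss$lambda_max_nm - aa$lambda_max_nm, 10)
  }
})

test_that("variant classes respect the printed range boundaries", {
  expect_equal(
    classify_variant(c(355, 356, 360, 362, 362.5, 365, 367.9, 368, 370, 371, NA)),
    c("unclassified", "short", "short", "short", "intermediate",
      "intermediate", "intermediate", "long", "long", "unclassified",
      "unclassified")
  )
})
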