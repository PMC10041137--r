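test_that("molecule generation is a pure function of the seed", {
  d1 <- generate_molecules(100, seed = 1)
  d2 <- generate_molecules(100, seed = 1)
  expect_identical(d1, d2)
  d3 <- generate_molecules(100, seed = 2)
  expect_false(identical(d1$smiles, d3$smiles))
  expect_true(all(!is.na(d1$canonical_smiles)))
})

test_that("motif_fraction = 1 plants a detectable motif in every molecule", {
  d <- generate_molecules(40, seed = 5, motif_fraction = 1)
  has <- vapply(seq_len(nrow(d)), function(i)
    detect_motif(d[i, , drop = FALSE], "tertiary_amine") ||
      detect_motif(d[i, , drop = FALSE], "carboxyl"), logical(1))
  expect_true(all(has))
  d0 <- generate_molecules(40, seed = 5, motif_fraction = 0)
  has0 <- vapply(seq_len(nrow(d0)), function(i)
    detect_motif(d0[i, , drop = FALSE], "tertiary_amine") ||
      detect_motif(d0[i, , drop = FALSE], "carboxyl"), logical(1))
  expect_false(any(has0))
})

test_that("planted motif counts stay inside the binomial 99% interval", {
  d <- generate_molecules(500, seed = 7, motif_fraction = 0.3)
  n_mot <- sum(d$motif != "none")
  bounds <- qbinom(c(0.005, 0.995), 500, 0.3)
  expect_gte(n_mot, bounds[1])
  expect_lte(n_mot, bounds[2])
})

test_that("motif detection is structural, not metadata", {
  expect_true(detect_motif("CCN(C)C", "tertiary_amine"))
  expect_true(detect_motif("CN(CC)CC", "tertiary_amine"))
  expect_false(detect_motif("CCNC", "tertiary_amine"))    # secondary amine
  expect_false(detect_motif("CC#N", "tertiary_amine"))    # nitrile
  expect_true(detect_motif("CCC(=O)O", "carboxyl"))
  expect_true(detect_motif("OC(=O)c1ccccc1", "carboxyl"))
  expect_false(detect_motif("CCC(=O)C", "carboxyl"))      # ketone
  expect_false(detect_motif("CCO", "carboxyl"))           # alcohol
  expect_false(detect_motif("CCOC(C)C", "carboxyl"))      # ether
})

test_that("noise-free labels equal independent rule evaluation", {
  drugs <- generate_molecules(30, seed = 9, motif_fraction = 0.6)
  rules <- list(planted_rule(89, "tertiary_amine"),
                planted_rule(53, "tertiary_amine", "carboxyl"))
  pairs <- plant_labels(drugs, rules, 150, seed = 10)
  expect_identical(pairs$type_ids, pairs$truth_type_ids)
  cat <- load_catalog()
  # independent oracle: re-evaluate each rule from detect_motif
  for (i in sample(nrow(pairs), 40)) {
    a <- drugs[drugs$drug_id == pairs$drug_a_id[i], , drop = FALSE]
    b <- drugs[drugs$drug_id == pairs$drug_b_id[i], , drop = FALSE]
    a_amn <- detect_motif(a, "tertiary_amine"); a_cbx <- detect_motif(a, "carboxyl")
    b_amn <- detect_motif(b, "tertiary_amine"); b_cbx <- detect_motif(b, "carboxyl")
    want <- integer(0)
    if (a_amn) want <- c(want, 89)                         # directional
    if ((a_amn && b_cbx) || (b_amn && a_cbx)) want <- c(want, 53)  # symmetric
    expect_equal(pairs$type_ids[i], paste(sort(want), collapse = ";"))
  }
  # a pair with the motif in neither drug is an explicit negative
  none <- drugs$motif == "none"
  neg <- pairs$drug_a_id %in% drugs$drug_id[none] &
    pairs$drug_b_id %in% drugs$drug_id[none]
  if (any(neg)) expect_true(all(pairs$type_ids[neg] == ""))
})

test_that("label noise flips stay inside the binomial 99% interval", {
  drugs <- generate_molecules(80, seed = 3, motif_fraction = 0.5)
  rules <- list(planted_rule(89, "tertiary_amine", NULL, 0.05),
                planted_rule(3, "carboxyl", NULL, 0.05))
  pairs <- plant_labels(drugs, rules, 1000, seed = 3)
  flips <- 0
  for (i in seq_len(nrow(pairs))) {
    noisy <- ddiscreen:::parse_type_ids(pairs$type_ids[i])
    clean <- ddiscreen:::parse_type_ids(pairs$truth_type_ids[i])
    flips <- flips + length(setdiff(noisy, clean)) + length(setdiff(clean, noisy))
  }
  bounds <- qbinom(c(0.005, 0.995), 1000 * 2, 0.05)
  expect_gte(flips, bounds[1])
  expect_lte(flips, bounds[2])
})

test_that("oversampling pairs and unmatched triggers are rejected", {
  drugs <- generate_molecules(6, seed = 2, motif_fraction = 0.5)
  rules <- list(planted_rule(89, "tertiary_amine"))
  expect_error(plant_labels(drugs, rules, 100, seed = 1),
               class = "ddi_config_error")
  no_motif <- generate_molecules(6, seed = 2, motif_fraction = 0)
  expect_error(plant_labels(no_motif, rules, 5, seed = 1),
               class = "ddi_config_error")
  expect_error(plant_labels(drugs, list(), 5, seed = 1),
               class = "ddi_config_error")
  expect_error(planted_rule(89, "tertiary_amine", NULL, 0.7),
               class = "ddi_config_error")
})

test_that("screen fixtures are deterministic with self-consistent counts", {
  f1 <- make_screen_fixture(seed = 6)
  f2 <- make_screen_fixture(seed = 6)
  expect_identical(f1, f2)
  expect_equal(f1$expected$total_ddis, nrow(f1$expected$triples))
  expect_setequal(f1$expected$interacting_union,
                  unique(f1$expected$triples$partner_id))
  expect_equal(sum(f1$expected$per_drug_type_counts$n_types),
               f1$expected$total_ddis)
  # empty rule set: nothing interacts
  f0 <- make_screen_fixture(seed = 6, rules = list())
  expect_equal(f0$expected$total_ddis, 0)
  expect_length(f0$expected$interacting_union, 0)
})

test_that("fixture files round-trip through the CSV writers", {
  p <- synth_preset("tiny", seed = 4)
  dir <- tempfile()
  write_synth_fixtures(p, dir)
  r <- read_drug_table(file.path(dir, "drugs.csv"))
  expect_equal(nrow(r$drugs), nrow(p$drugs))
  expect_equal(nrow(r$rejected), 0)
  gold <- read_gold_standard(file.path(dir, "gold_standard.csv"))
  expect_equal(gold$type_ids, p$pairs$type_ids)
})
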