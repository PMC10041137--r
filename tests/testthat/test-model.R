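test_that("pair features are swap-symmetric halves of the reduced SSPs", {
  drugs <- drug_table(c("CCO", "CCCN(C)C", "c1ccccc1O", "CCCC(=O)O", "CCCCC"))
  ref <- reference_set(drugs)
  red <- fit_reducer(build_ssp_matrix(drugs, ref), 3)
  a <- drugs[1, , drop = FALSE]; b <- drugs[4, , drop = FALSE]
  f_ab <- assemble_features(list(a, b), ref, red)
  f_ba <- assemble_features(list(b, a), ref, red)
  expect_length(f_ab, 6)
  expect_equal(f_ab, c(f_ba[4:6], f_ba[1:3]))
  # composition oracle: reduce o build_ssp applied by hand
  expect_equal(f_ab, c(reduce_ssp(build_ssp(a, ref), red),
                       reduce_ssp(build_ssp(b, ref), red)))
  # same molecule re-written gives identical halves
  a2 <- drug_table("OCC", ids = "T900")
  f <- assemble_features(list(a, a2), ref, red)
  expect_equal(f[1:3], f[4:6])
})

test_that("training is reproducible: same seed, byte-identical weight files", {
  p <- tiny_preset()
  cfg <- ddi_train_config(hidden = c(16L, 16L), epochs = 8L, k = 10L)
  m1 <- train_ddi_model(p$pairs[1:80, ], p$drugs, config = cfg, seed = 5)
  m2 <- train_ddi_model(p$pairs[1:80, ], p$drugs, config = cfg, seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  save_ddi_model(m1, d1); save_ddi_model(m2, d2)
  w1 <- readBin(file.path(d1, "weights.json"), "raw", 1e7)
  w2 <- readBin(file.path(d2, "weights.json"), "raw", 1e7)
  expect_identical(w1, w2)
  m3 <- train_ddi_model(p$pairs[1:80, ], p$drugs, config = cfg, seed = 6)
  expect_false(identical(m1$params$W[[1]], m3$params$W[[1]]))
})

test_that("a single-type gold standard trains (with warning) and recalls it", {
  p <- tiny_preset()
  pairs <- p$pairs[1:60, ]
  pairs$type_ids <- "1"
  cfg <- ddi_train_config(hidden = c(16L, 16L), epochs = 15L, k = 10L)
  expect_warning(m <- train_ddi_model(pairs, p$drugs, config = cfg, seed = 2),
                 "single")
  held <- p$pairs[61:70, ]
  for (i in seq_len(nrow(held))) {
    a <- p$drugs[p$drugs$drug_id == held$drug_a_id[i], , drop = FALSE]
    b <- p$drugs[p$drugs$drug_id == held$drug_b_id[i], , drop = FALSE]
    expect_gt(predict_pair(m, a, b)[[1]], m$threshold)
  }
})

test_that("prediction is a pure function with catalogue-length output", {
  m <- tiny_model()
  p <- tiny_preset()
  a <- p$drugs[1, , drop = FALSE]; b <- p$drugs[2, , drop = FALSE]
  s1 <- predict_pair(m, a, b)
  s2 <- predict_pair(m, a, b)
  expect_identical(s1, s2)
  expect_length(s1, m$catalog_size)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("prediction refuses a model whose reference provenance is broken", {
  m <- tiny_model()
  p <- tiny_preset()
  m$reference$smiles[1] <- "CCCCCCCCCC"
  expect_error(predict_pair(m, p$drugs[1, , drop = FALSE], p$drugs[2, , drop = FALSE]),
               class = "ddi_comparability_error")
})

test_that("unresolvable drug ids and unknown types abort training", {
  p <- tiny_preset()
  pairs <- p$pairs[1:10, ]
  pairs$drug_a_id[3] <- "NOPE"
  expect_error(train_ddi_model(pairs, p$drugs), class = "ddi_data_error")
  pairs2 <- p$pairs[1:10, ]
  pairs2$type_ids[1] <- "999"
  expect_error(train_ddi_model(pairs2, p$drugs), class = "ddi_data_error")
})

test_that("thresholding and direction handling follow the call conventions", {
  stub <- model_stub(threshold = 0.5)
  nc <- nrow(stub$catalog$entries)
  lo <- rep(0.1, nc)
  # all below threshold: no records
  expect_equal(nrow(process_predictions(lo, lo, stub, "q", "d")), 0)

  # non-directional type 53: max over orders, emitted once
  s_ab <- lo; s_ba <- lo
  s_ab[53] <- 0.9; s_ba[53] <- 0.4
  r <- process_predictions(s_ab, s_ba, stub, "q", "d", "Quer", "Drug")
  expect_equal(nrow(r), 1)
  expect_equal(r$score, 0.9)
  expect_equal(r$type_id, 53)
  # swap-consistency for non-directional types
  r_swapped <- process_predictions(s_ba, s_ab, stub, "q", "d", "Quer", "Drug")
  expect_equal(r_swapped$score, r$score)
  expect_equal(r_swapped$type_id, r$type_id)

  # directional type 89 above threshold in both orders: two records,
  # distinct sentences
  s_ab <- lo; s_ba <- lo
  s_ab[89] <- 0.8; s_ba[89] <- 0.7
  r2 <- process_predictions(s_ab, s_ba, stub, "q", "d", "Quer", "Drug")
  expect_equal(nrow(r2), 2)
  expect_false(r2$sentence[1] == r2$sentence[2])
  expect_setequal(r2$direction, c("query_first", "partner_first"))
  # records sorted by descending score; none below threshold
  expect_true(all(diff(r2$score) <= 0))
  expect_true(all(r2$score >= 0.5))
})

test_that("model bundles round-trip through save and load", {
  m <- tiny_model()
  p <- tiny_preset()
  d <- tempfile()
  save_ddi_model(m, d)
  m2 <- load_ddi_model(d)
  a <- p$drugs[3, , drop = FALSE]; b <- p$drugs[7, , drop = FALSE]
  expect_equal(predict_pair(m2, a, b), predict_pair(m, a, b), tolerance = 1e-12)
  expect_identical(m2$reference_digest, m$reference_digest)
  # tampering with the stored reference breaks the digest check
  rf <- jsonlite::fromJSON(file.path(d, "reference.json"))
  rf$smiles[1] <- "CCCCCCCC"
  jsonlite::write_json(rf, file.path(d, "reference.json"), auto_unbox = TRUE, digits = NA)
  expect_error(load_ddi_model(d), class = "ddi_comparability_error")
})
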