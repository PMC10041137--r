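toy_screen_summary <- function(interacting, queries = "q1", panel_ids = NULL) {
  recs <- if (length(interacting) == 0) {
    data.frame(query_id = character(), partner_id = character(),
               type_id = integer())
  } else {
    data.frame(query_id = queries[1], partner_id = interacting, type_id = 89L,
               stringsAsFactors = FALSE)
  }
  summarize_screen(as_screen_result(recs, queries = queries,
                                    panel_ids = panel_ids))
}

test_that("both substitution criteria are enforced", {
  panel <- data.frame(drug_id = c("dX", "dY", "dZ", "dW"),
                      name = c("Xdipine", "Ydipine", "Zdipine", "Wprofen"),
                      stringsAsFactors = FALSE)
  moa <- data.frame(name = c("Xdipine", "Ydipine", "Zdipine", "Wprofen"),
                    moa = c("calcium channel blocker", "calcium channel blocker",
                            "calcium channel blocker", "cyclooxygenase inhibitor"),
                    stringsAsFactors = FALSE)
  # X and Z interact; Y is clean and shares X's mechanism -> suggested.
  # Z shares the mechanism but interacts (criterion 1) -> excluded.
  # W is clean but has a different mechanism (criterion 2) -> not suggested.
  sm <- toy_screen_summary(c("dX", "dZ"), panel_ids = panel$drug_id)
  alt <- find_alternatives(sm, panel, moa)
  expect_equal(nrow(alt$suggestions), 2)  # one row each for flagged X and Z
  expect_setequal(alt$suggestions$flagged_drug, c("Xdipine", "Zdipine"))
  expect_true(all(alt$suggestions$alternatives == "Ydipine"))
  expect_length(alt$unannotated, 0)
})

test_that("flagged drugs without MoA annotation are reported, not suggested", {
  panel <- data.frame(drug_id = c("d1", "d2"), name = c("Mystery", "Known"),
                      stringsAsFactors = FALSE)
  moa <- data.frame(name = "Known", moa = "beta blocker", stringsAsFactors = FALSE)
  sm <- toy_screen_summary("d1", panel_ids = panel$drug_id)
  alt <- find_alternatives(sm, panel, moa)
  expect_equal(alt$unannotated, "Mystery")
  expect_equal(nrow(alt$suggestions), 0)
  # empty MoA table: everything flagged is unannotated
  alt2 <- find_alternatives(sm, panel, moa[0, ])
  expect_equal(alt2$unannotated, "Mystery")
})

test_that("multi-valued MoA cells split on | and ;", {
  panel <- data.frame(drug_id = c("d1", "d2", "d3"),
                      name = c("Aa", "Bb", "Cc"), stringsAsFactors = FALSE)
  moa <- data.frame(name = c("Aa", "Bb", "Cc"),
                    moa = c("m1|m2", "m2; m3", "m9"), stringsAsFactors = FALSE)
  sm <- toy_screen_summary("d1", panel_ids = panel$drug_id)
  alt <- find_alternatives(sm, panel, moa)
  expect_true("Bb" %in% unlist(strsplit(alt$suggestions$alternatives, ";")))
  expect_false("Cc" %in% unlist(strsplit(alt$suggestions$alternatives, ";")))
})

test_that("suggestions are sound and complete against a brute-force filter", {
  p <- synth_preset("screen", seed = 11)
  fx <- make_screen_fixture(seed = 11)
  sm <- summarize_screen(as_screen_result(
    fx$expected$triples[, c("query_id", "partner_id", "type_id")],
    queries = fx$queries$drug_id, panel_ids = fx$panel$drug_id))
  alt <- find_alternatives(sm, fx$panel, fx$moa_table)

  # soundness: no suggested alternative is in the interacting union
  flagged_names <- fx$panel$name[fx$panel$drug_id %in% sm$interacting_union]
  sugg_names <- unique(unlist(strsplit(alt$suggestions$alternatives, ";")))
  expect_length(intersect(sugg_names, flagged_names), 0)

  # completeness at toy scale: independent brute-force filter over the panel
  brute <- list()
  for (fn in sort(flagged_names)) {
    fmoa <- fx$moa_table$moa[fx$moa_table$name == fn]
    for (m in fmoa) {
      cands <- fx$moa_table$name[fx$moa_table$moa == m]
      cands <- sort(setdiff(intersect(cands, fx$panel$name), c(flagged_names, fn)))
      if (length(cands) > 0) {
        brute[[paste(fn, m)]] <- paste(cands, collapse = ";")
      }
    }
  }
  got <- setNames(alt$suggestions$alternatives,
                  paste(alt$suggestions$flagged_drug, alt$suggestions$moa))
  expect_equal(length(got), length(brute))
  for (key in names(brute)) expect_equal(unname(got[key]), brute[[key]])
})

test_that("the within-class filter narrows candidates by drug class", {
  panel <- data.frame(drug_id = c("d1", "d2", "d3"),
                      name = c("Aa", "Bb", "Cc"),
                      drug_class = c("class1", "class1", "class2"),
                      stringsAsFactors = FALSE)
  moa <- data.frame(name = c("Aa", "Bb", "Cc"), moa = "m1",
                    stringsAsFactors = FALSE)
  sm <- toy_screen_summary("d1", panel_ids = panel$drug_id)
  alt_all <- find_alternatives(sm, panel, moa)
  expect_setequal(unlist(strsplit(alt_all$suggestions$alternatives, ";")),
                  c("Bb", "Cc"))
  alt_cls <- find_alternatives(sm, panel, moa, within_class = TRUE)
  expect_equal(alt_cls$suggestions$alternatives, "Bb")
})
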