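# Seeded synthetic inputs: small valid molecules with controllable planted
# motifs, gold-standard pair labels generated by fingerprint-detectable
# rules, and full screening fixtures with brute-force expected counts.

MOTIF_VOCAB <- c("tertiary_amine", "carboxyl")

#' Planted labelling rule
#'
#' A pair (A, B) satisfies the rule when A carries `trigger` and, if
#' `partner_trigger` is given, B carries it. The motif vocabulary is
#' `tertiary_amine` (an N with three carbon neighbours, all single bonds) and
#' `carboxyl` (a C bearing a double-bonded O and a terminal single-bonded O);
#' both are radius-2-fingerprint-detectable by construction, which makes
#' planted datasets learnable by the structural classifier.
#'
#' @param type_id catalogue type id the rule plants.
#' @param trigger motif required in drug A.
#' @param partner_trigger optional motif required in drug B.
#' @param noise_rate independent label-flip probability in \[0, 0.5).
#' @return a list of class `planted_rule`.
#' @export
planted_rule <- function(type_id, trigger, partner_trigger = NULL, noise_rate = 0) {
  if (noise_rate < 0 || noise_rate >= 0.5) stop_config("noise_rate must be in [0, 0.5)")
  if (!trigger %in% MOTIF_VOCAB) stop_config("unknown motif: ", trigger)
  if (!is.null(partner_trigger) && !partner_trigger %in% MOTIF_VOCAB) {
    stop_config("unknown motif: ", partner_trigger)
  }
  structure(list(type_id = as.integer(type_id), trigger = trigger,
                 partner_trigger = partner_trigger, noise_rate = noise_rate),
            class = "planted_rule")
}

#' Detect a planted motif in a molecule
#'
#' Structural detection over the parsed connection table (not generation
#' metadata), so it holds for any SMILES writing of the molecule.
#'
#' @param smiles SMILES string (or single-row drug data.frame).
#' @param motif `"tertiary_amine"` or `"carboxyl"`.
#' @return logical.
#' @export
detect_motif <- function(smiles, motif) {
  if (is.data.frame(smiles)) smiles <- (smiles$canonical_smiles %||% smiles$smiles)[1]
  canon <- canonicalize_smiles(smiles)
  if (is.na(canon)) stop_structure("unparseable SMILES")
  detect_motif_mol(parse_molecule(canon), motif)
}

detect_motif_mol <- function(mol, motif) {
  el <- mol$elements; bb <- mol$bonds
  deg_of <- function(i) sum(bb[, 1] == i | bb[, 2] == i)
  nbrs_of <- function(i) {
    sel <- bb[, 1] == i | bb[, 2] == i
    cbind(ifelse(bb[sel, 1] == i, bb[sel, 2], bb[sel, 1]), bb[sel, 3])
  }
  if (motif == "tertiary_amine") {
    for (i in which(el == "N")) {
      nb <- nbrs_of(i)
      if (nrow(nb) == 3 && all(nb[, 2] == 1) && all(el[nb[, 1]] == "C")) return(TRUE)
    }
    return(FALSE)
  }
  if (motif == "carboxyl") {
    for (i in which(el == "C")) {
      nb <- nbrs_of(i)
      has_dbl_o <- any(el[nb[, 1]] == "O" & nb[, 2] == 2)
      term_o <- nb[el[nb[, 1]] == "O" & nb[, 2] == 1, 1]
      if (has_dbl_o && length(term_o) > 0 && any(vapply(term_o, deg_of, 0) == 1)) {
        return(TRUE)
      }
    }
    return(FALSE)
  }
  stop_config("unknown motif: ", motif)
}

#' Generate synthetic drug molecules
#'
#' Builds valid SMILES from a small grammar: an alkyl chain, optionally
#' terminated by a phenyl or cyclohexyl ring or a hydroxyl, with a planted
#' motif fragment (tertiary amine `N(C)C` or carboxyl `C(=O)O`) appended on
#' approximately `motif_fraction` of molecules (split evenly across
#' `motifs`). Pure function of the seed.
#'
#' @param n number of molecules (>= 2).
#' @param seed integer seed.
#' @param motif_fraction fraction of molecules carrying a motif, in \[0, 1\].
#' @param motifs motif names drawn from when planting.
#' @param id_prefix prefix for generated drug ids.
#' @return drug data.frame with columns `drug_id`, `name`, `smiles`,
#'   `canonical_smiles`, `motif` (motif name or `"none"`).
#' @export
generate_molecules <- function(n, seed = 1L, motif_fraction = 0.5,
                               motifs = MOTIF_VOCAB, id_prefix = "D") {
  if (n < 2) stop_config("n must be >= 2")
  if (motif_fraction < 0 || motif_fraction > 1) stop_config("motif_fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  smiles <- character(n); motif <- character(n)
  for (i in seq_len(n)) {
    chain <- strrep("C", sample(2:6, 1))
    tail <- sample(c("", "c1ccccc1", "C1CCCCC1", "O"), 1,
                   prob = c(0.4, 0.25, 0.25, 0.1))
    base <- paste0(chain, tail)
    m <- "none"
    if (stats::runif(1) < motif_fraction) {
      m <- sample(motifs, 1)
      frag <- if (m == "tertiary_amine") "N(C)C" else "C(=O)O"
      # attach the motif to the chain end; rings/hydroxyl stay on the far end
      base <- if (tail %in% c("", "O")) paste0(chain, frag, if (tail == "O") "" else "")
              else paste0(tail, chain, frag)
      if (tail == "O") base <- paste0("OC", substring(base, 2))
    }
    smiles[i] <- base
    motif[i] <- m
  }
  df <- data.frame(
    drug_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    name = sprintf("synthadrug-%s%04d", tolower(id_prefix), seq_len(n)),
    smiles = smiles, stringsAsFactors = FALSE)
  df$canonical_smiles <- canonicalize_smiles(df$smiles)
  stopifnot(!anyNA(df$canonical_smiles))
  df$motif <- motif
  df
}

# Motif indicator matrix (drugs x motifs), computed structurally with one
# parse per drug.
motif_flags <- function(drugs) {
  m <- t(vapply(drugs$canonical_smiles, function(s) {
    mol <- parse_molecule(s)
    vapply(MOTIF_VOCAB, function(mo) detect_motif_mol(mol, mo), logical(1))
  }, logical(length(MOTIF_VOCAB)), USE.NAMES = FALSE))
  dimnames(m) <- list(drugs$drug_id, MOTIF_VOCAB)
  m
}

rule_fires <- function(rule, flags_a, flags_b) {
  flags_a[rule$trigger] &&
    (is.null(rule$partner_trigger) || flags_b[rule$partner_trigger])
}

#' Plant gold-standard labels on sampled drug pairs
#'
#' Samples `n_pairs` distinct unordered pairs (orientation then randomized),
#' evaluates every rule on the recorded orientation, and flips each
#' (pair, rule) label independently with the rule's `noise_rate`. Pairs with
#' no label are kept as explicit negatives. The clean (pre-noise) rule
#' evaluation is retained in `truth_type_ids` for recovery assessment.
#'
#' Rule evaluation respects the catalogue's direction semantics: a rule
#' planting a directional type fires only in the recorded orientation, while
#' one planting a non-directional (symmetric) type fires if either
#' orientation satisfies it.
#'
#' @param drugs drug data.frame from [generate_molecules()].
#' @param rules list of [planted_rule()]s.
#' @param n_pairs number of pairs to sample (at most `choose(n, 2)`).
#' @param seed integer seed.
#' @param catalog catalogue supplying type directionality.
#' @return data.frame with `drug_a_id`, `drug_b_id`, `type_ids` (noisy,
#'   ';'-joined, empty = negative), `truth_type_ids` (clean).
#' @export
plant_labels <- function(drugs, rules, n_pairs, seed = 1L,
                         catalog = load_catalog()) {
  if (length(rules) == 0) stop_config("rules must be non-empty")
  n <- nrow(drugs)
  npairs_all <- choose(n, 2)
  if (n_pairs > npairs_all) {
    stop_config("n_pairs (", n_pairs, ") exceeds available distinct pairs (",
                npairs_all, ")")
  }
  flags <- motif_flags(drugs)
  for (rule in rules) {
    if (!any(flags[, rule$trigger])) {
      stop_config("trigger motif '", rule$trigger, "' matches no generated molecule")
    }
  }
  set.seed(as.integer(seed))
  all_pairs <- utils::combn(n, 2)
  sel <- sample.int(npairs_all, n_pairs)
  ai <- all_pairs[1, sel]; bi <- all_pairs[2, sel]
  swap <- stats::runif(n_pairs) < 0.5
  tmp <- ai[swap]; ai[swap] <- bi[swap]; bi[swap] <- tmp

  directional <- stats::setNames(catalog$entries$directional,
                                 catalog$entries$type_id)
  type_ids <- character(n_pairs); truth_ids <- character(n_pairs)
  for (p in seq_len(n_pairs)) {
    clean <- integer(0); noisy <- integer(0)
    for (rule in rules) {
      fires <- rule_fires(rule, flags[ai[p], ], flags[bi[p], ])
      if (!directional[[as.character(rule$type_id)]]) {
        fires <- fires || rule_fires(rule, flags[bi[p], ], flags[ai[p], ])
      }
      if (fires) clean <- c(clean, rule$type_id)
      labelled <- if (stats::runif(1) < rule$noise_rate) !fires else fires
      if (labelled) noisy <- c(noisy, rule$type_id)
    }
    truth_ids[p] <- paste(sort(unique(clean)), collapse = ";")
    type_ids[p] <- paste(sort(unique(noisy)), collapse = ";")
  }
  data.frame(drug_a_id = drugs$drug_id[ai], drug_b_id = drugs$drug_id[bi],
             type_ids = type_ids, truth_type_ids = truth_ids,
             stringsAsFactors = FALSE)
}

default_rules <- function(noise_rate = 0.05) {
  list(planted_rule(89, "tertiary_amine", NULL, noise_rate),
       planted_rule(3, "carboxyl", NULL, noise_rate),
       planted_rule(53, "tertiary_amine", "carboxyl", noise_rate))
}

screen_rules <- function() {
  list(planted_rule(89, "tertiary_amine", "carboxyl", 0),
       planted_rule(53, "carboxyl", "tertiary_amine", 0),
       planted_rule(3, "tertiary_amine", "tertiary_amine", 0))
}

#' Generate a complete screening fixture with known expected counts
#'
#' Builds two query drugs (one amine-bearing, one carboxyl-bearing), a panel,
#' an MoA table, two regulator-style reference name lists, and the screening
#' counts expected under the planted rules, computed by brute-force rule
#' evaluation over every (query, panel drug) pair in both orders with the
#' same direction/triple-counting conventions the screening layer uses. This
#' gives end-to-end pipeline tests a known answer.
#'
#' @param seed integer seed.
#' @param n_panel panel size.
#' @param rules planted rules (default: the noise-free screening rules).
#' @return list with `queries`, `panel`, `moa_table`, `ref_lists` (named list
#'   of name vectors), `rules`, and `expected` (list of expected counts, sets
#'   and alternative suggestions).
#' @export
make_screen_fixture <- function(seed = 1L, n_panel = 40L, rules = screen_rules()) {
  panel <- generate_molecules(n_panel, seed = seed, motif_fraction = 0.5,
                              id_prefix = "P")
  # queries follow the panel grammar (chain + motif) so that a model trained
  # on generated molecules sees them as in-distribution chemistry
  queries <- data.frame(
    drug_id = c("Q-AMN", "Q-CBX"),
    name = c("querinavir", "queriprofen"),
    smiles = c("CCCCN(C)C", "CCCCC(=O)O"),
    stringsAsFactors = FALSE)
  queries$canonical_smiles <- canonicalize_smiles(queries$smiles)

  qflags <- motif_flags(queries)
  pflags <- motif_flags(panel)

  # brute-force expected triples under the screening conventions
  triples <- list()
  if (length(rules) > 0) {
    for (qi in seq_len(nrow(queries))) {
      for (pi in seq_len(n_panel)) {
        for (rule in rules) {
          if (rule_fires(rule, qflags[qi, ], pflags[pi, ]) ||
              rule_fires(rule, pflags[pi, ], qflags[qi, ])) {
            triples[[length(triples) + 1]] <- data.frame(
              partner_id = panel$drug_id[pi], query_id = queries$drug_id[qi],
              type_id = rule$type_id, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  triples <- if (length(triples) == 0) {
    data.frame(partner_id = character(), query_id = character(),
               type_id = integer(), stringsAsFactors = FALSE)
  } else unique(do.call(rbind, triples))

  interacting_union <- sort(unique(triples$partner_id))
  interacting_by_query <- lapply(stats::setNames(nm = queries$drug_id), function(q)
    sort(unique(triples$partner_id[triples$query_id == q])))

  # MoA annotations: motif carriers get a motif-linked mechanism; motif-free
  # drugs are split across the same two mechanisms so alternatives exist.
  set.seed(as.integer(seed) + 7919L)
  moa_of <- character(n_panel)
  moa_of[panel$motif == "tertiary_amine"] <- "calcium channel blocker"
  moa_of[panel$motif == "carboxyl"] <- "cyclooxygenase inhibitor"
  free <- which(panel$motif == "none")
  moa_of[free] <- sample(c("calcium channel blocker", "cyclooxygenase inhibitor"),
                         length(free), replace = TRUE)
  moa_table <- data.frame(name = panel$name, moa = moa_of,
                          stringsAsFactors = FALSE)
  panel$drug_class <- moa_of

  # regulator-style reference lists: a mix of interacting and clean drugs
  flagged_names <- panel$name[panel$drug_id %in% interacting_union]
  clean_names <- setdiff(panel$name, flagged_names)
  take <- function(x, k) if (length(x) == 0) character() else
    x[sort(sample.int(length(x), min(k, length(x))))]
  ref_lists <- list(
    fda_like = sort(c(take(flagged_names, 8), take(clean_names, 4))),
    ema_like = sort(c(take(flagged_names, 10), take(clean_names, 2))))
  expected_overlap <- lapply(ref_lists, function(rl) {
    n_int <- sum(rl %in% flagged_names)
    list(n_ref = length(rl), n_predicted_interacting = n_int,
         fraction_pct = round(100 * n_int / length(rl), 1))
  })

  # brute-force alternatives: clean panel drugs sharing a mechanism
  alt <- list()
  for (fn in sort(flagged_names)) {
    m <- moa_table$moa[moa_table$name == fn]
    cands <- sort(setdiff(intersect(clean_names, moa_table$name[moa_table$moa == m]), fn))
    if (length(cands) > 0) {
      alt[[length(alt) + 1]] <- data.frame(
        flagged_drug = fn, moa = norm_name(m),
        alternatives = paste(cands, collapse = ";"),
        n_alternatives = length(cands), stringsAsFactors = FALSE)
    }
  }
  expected_alternatives <- if (length(alt) == 0) empty_suggestion_table() else
    do.call(rbind, alt)

  per_drug <- if (nrow(triples) == 0) {
    data.frame(partner_id = character(), query_id = character(), n_types = integer())
  } else {
    a <- stats::aggregate(type_id ~ partner_id + query_id, data = triples,
                          FUN = function(x) length(unique(x)))
    names(a)[3] <- "n_types"
    a
  }

  list(queries = queries, panel = panel, moa_table = moa_table,
       ref_lists = ref_lists, rules = rules,
       expected = list(
         triples = triples[order(triples$partner_id, triples$query_id, triples$type_id), ],
         total_ddis = nrow(triples),
         interacting_union = interacting_union,
         interacting_by_query = interacting_by_query,
         per_drug_type_counts = per_drug,
         max_types_per_pair = if (nrow(per_drug) == 0) 0L else max(per_drug$n_types),
         overlap = expected_overlap,
         alternatives = expected_alternatives))
}

#' Generate a named synthetic preset
#'
#' `tiny` (50 drugs, 300 pairs, 2 noise-free rules) for fast smoke tests;
#' `default` (200 drugs, 2,000 pairs, 3 rules, 5% label noise), the
#' planted-rule recovery condition; `screen` adds a training set (160 drugs,
#' 1,600 noise-free pairs) plus a full screening fixture with brute-force
#' expected counts.
#'
#' @param preset `"tiny"`, `"default"` or `"screen"`.
#' @param seed integer seed.
#' @return list with `drugs`, `pairs`, `rules` and (for `screen`) the
#'   [make_screen_fixture()] components.
#' @export
synth_preset <- function(preset = c("default", "tiny", "screen"), seed = 1L) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  if (preset == "tiny") {
    rules <- list(planted_rule(89, "tertiary_amine"), planted_rule(3, "carboxyl"))
    drugs <- generate_molecules(50, seed = seed, motif_fraction = 0.5)
    pairs <- plant_labels(drugs, rules, 300, seed = seed + 1L)
    return(list(preset = preset, drugs = drugs, pairs = pairs, rules = rules))
  }
  if (preset == "default") {
    rules <- default_rules(noise_rate = 0.05)
    drugs <- generate_molecules(200, seed = seed, motif_fraction = 0.5)
    pairs <- plant_labels(drugs, rules, 2000, seed = seed + 1L)
    return(list(preset = preset, drugs = drugs, pairs = pairs, rules = rules))
  }
  rules <- screen_rules()
  drugs <- generate_molecules(160, seed = seed, motif_fraction = 0.5)
  pairs <- plant_labels(drugs, rules, 1600, seed = seed + 1L)
  fixture <- make_screen_fixture(seed = seed + 2L)
  c(list(preset = preset, drugs = drugs, pairs = pairs, rules = rules), fixture)
}

#' Write a synthetic preset to CSV fixtures
#'
#' @param preset_data result of [synth_preset()].
#' @param dir output directory.
#' @export
write_synth_fixtures <- function(preset_data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(preset_data$drugs, file.path(dir, "drugs.csv"), row.names = FALSE)
  utils::write.csv(preset_data$pairs, file.path(dir, "gold_standard.csv"), row.names = FALSE)
  if (!is.null(preset_data$panel)) {
    utils::write.csv(preset_data$queries, file.path(dir, "queries.csv"), row.names = FALSE)
    utils::write.csv(preset_data$panel, file.path(dir, "panel.csv"), row.names = FALSE)
    utils::write.csv(preset_data$moa_table, file.path(dir, "moa.csv"), row.names = FALSE)
    for (nm in names(preset_data$ref_lists)) {
      writeLines(preset_data$ref_lists[[nm]], file.path(dir, paste0(nm, ".txt")))
    }
    jsonlite::write_json(preset_data$expected[
      c("total_ddis", "interacting_union", "max_types_per_pair")],
      file.path(dir, "expected_counts.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
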