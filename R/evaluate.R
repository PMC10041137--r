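#' Macro-averaged F1 recovery of planted DDI types
#'
#' Scores held-out ordered pairs with the model and compares thresholded
#' calls against the clean planted-rule truth (`truth_type_ids`). A
#' directional type is called for a pair when its score in the recorded
#' orientation clears the threshold; a non-directional type when the maximum
#' over both orientations does. F1 is computed per type over the types
#' present in the truth and macro-averaged; a type with no true or called
#' positives contributes F1 = 1 only if both are absent.
#'
#' @param model a `ddi_model`.
#' @param pairs held-out pair data.frame with `drug_a_id`, `drug_b_id` and a
#'   truth column.
#' @param drugs drug table resolving every id in `pairs`.
#' @param truth_col column holding the ';'-joined true type ids.
#' @return list with `macro_f1` and `per_type` (data.frame: type_id, tp, fp,
#'   fn, f1).
#' @export
evaluate_recovery <- function(model, pairs, drugs, truth_col = "truth_type_ids") {
  check_model_provenance(model)
  used <- unique(c(pairs$drug_a_id, pairs$drug_b_id))
  drugs <- drugs[drugs$drug_id %in% used, , drop = FALSE]
  red <- reduce_ssp(build_ssp_matrix(drugs, model$reference), model$reducer)
  rownames(red) <- drugs$drug_id

  n <- nrow(pairs)
  Xab <- cbind(red[pairs$drug_a_id, , drop = FALSE], red[pairs$drug_b_id, , drop = FALSE])
  Xba <- cbind(red[pairs$drug_b_id, , drop = FALSE], red[pairs$drug_a_id, , drop = FALSE])
  Sab <- mlp_forward(model$params, Xab)
  Sba <- mlp_forward(model$params, Xba)

  truth <- lapply(pairs[[truth_col]], parse_type_ids)
  types <- sort(unique(unlist(truth)))
  if (length(types) == 0) stop_data("no true types in held-out pairs")
  directional <- stats::setNames(model$catalog$entries$directional,
                                 model$catalog$entries$type_id)
  thr <- model$threshold

  per_type <- do.call(rbind, lapply(types, function(t) {
    called <- if (directional[[as.character(t)]]) Sab[, t] >= thr
              else pmax(Sab[, t], Sba[, t]) >= thr
    is_true <- vapply(truth, function(tt) t %in% tt, logical(1))
    tp <- sum(called & is_true); fp <- sum(called & !is_true)
    fn <- sum(!called & is_true)
    f1 <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    data.frame(type_id = t, tp = tp, fp = fp, fn = fn, f1 = f1)
  }))
  list(macro_f1 = mean(per_type$f1), per_type = per_type)
}
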