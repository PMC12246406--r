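#' Double (nested) cross-validation
#'
#' Constructs stratified 5 x 5 nested folds over patients -- outer folds
#' for out-of-fold validation over the entire development set, inner folds
#' for early stopping -- yielding 25 (outer, inner) model slots, and
#' orchestrates training with machine-checkable leakage provenance: every
#' development patient is predicted only by models whose outer fold
#' excluded them, and held-out test patients receive the full 25-model
#' ensemble.
#'
#' @name double_cv
NULL

# deal shuffled ids round-robin into k folds (stratified per class outside)
deal_folds <- function(ids, k) {
  ids <- sample(ids)
  split(ids, rep_len(seq_len(k), length(ids)))
}

#' Build a double cross-validation plan
#'
#' Outer folds partition the development patients, stratified on LNM
#' status (per-fold class counts within one patient of proportionality);
#' for each outer training set, inner folds partition it the same way.
#'
#' @param patient_ids Character vector of development patient ids.
#' @param lnm_labels 0/1 labels aligned with `patient_ids`.
#' @param k_outer,k_inner Fold counts (5 x 5 yields the 25 model slots).
#' @param seed Integer seed.
#' @return List of class `double_cv_plan` with `outer_folds` (list of id
#'   vectors), `inner_folds` (per outer fold, list of id vectors
#'   partitioning its training set), `slots` (`data.frame` of the
#'   `k_outer * k_inner` slot ids), and the inputs.
#' @export
make_plan <- function(patient_ids, lnm_labels, k_outer = 5, k_inner = 5,
                      seed = 1) {
  stopifnot(length(patient_ids) == length(lnm_labels),
            !anyDuplicated(patient_ids))
  if (length(patient_ids) < k_outer * k_inner)
    stop("need at least k_outer * k_inner patients")
  pos <- patient_ids[lnm_labels == 1]; neg <- patient_ids[lnm_labels == 0]
  if (length(pos) < k_outer || length(neg) < k_outer)
    stop("insufficient class counts for stratified outer folds")
  local_rng(seed)
  outer <- Map(c, deal_folds(pos, k_outer), deal_folds(neg, k_outer))
  names(outer) <- paste0("o", seq_len(k_outer))
  inner <- lapply(seq_len(k_outer), function(o) {
    train <- setdiff(patient_ids, outer[[o]])
    tp <- intersect(train, pos); tn <- intersect(train, neg)
    if (length(tp) < k_inner || length(tn) < k_inner)
      stop("insufficient class counts for stratified inner folds")
    f <- Map(c, deal_folds(tp, k_inner), deal_folds(tn, k_inner))
    names(f) <- paste0("i", seq_len(k_inner))
    f
  })
  names(inner) <- names(outer)
  slots <- expand.grid(outer = seq_len(k_outer), inner = seq_len(k_inner))
  slots <- slots[order(slots$outer, slots$inner), ]
  slots$slot_id <- sprintf("o%di%d", slots$outer, slots$inner)
  rownames(slots) <- NULL
  structure(list(outer_folds = outer, inner_folds = inner, slots = slots,
                 patient_ids = patient_ids, lnm_labels = lnm_labels,
                 k_outer = k_outer, k_inner = k_inner, seed = seed),
            class = "double_cv_plan")
}

#' Run double cross-validation
#'
#' Executes the trainer once per (outer, inner) slot. The trainer receives
#' the slot's training ids (outer training set minus the inner fold), the
#' inner-fold ids for early stopping, and the slot id; it must return a
#' prediction function `function(ids) -> data.frame` (rows aligned with
#' `ids`). Out-of-fold predictions for each development patient average
#' the `k_inner` models of the patient's own outer fold (whose training
#' excluded them); `test_ids` receive the average over all slots.
#'
#' @param plan A [make_plan()] object.
#' @param trainer `function(train_ids, earlystop_ids, slot_id)` returning
#'   a prediction function.
#' @param test_ids Optional held-out ids to predict with the full
#'   ensemble.
#' @return List of class `double_cv_result` with `oof` (development
#'   out-of-fold predictions, `data.frame` keyed by `patient_id`), `test`
#'   (ensemble predictions for `test_ids`, or `NULL`), `provenance`
#'   (per-patient contributing slots), and `slot_train_ids` (per-slot ids
#'   used in fitting, for the leakage audit).
#' @export
run_double_cv <- function(plan, trainer, test_ids = NULL) {
  stopifnot(inherits(plan, "double_cv_plan"))
  predictors <- list()
  slot_train <- list()
  for (r in seq_len(nrow(plan$slots))) {
    o <- plan$slots$outer[r]; i <- plan$slots$inner[r]
    sid <- plan$slots$slot_id[r]
    es <- plan$inner_folds[[o]][[i]]
    tr <- setdiff(setdiff(plan$patient_ids, plan$outer_folds[[o]]), es)
    pred <- tryCatch(trainer(tr, es, sid),
                     error = function(e) stop("trainer failed in slot ", sid,
                                              ": ", conditionMessage(e)))
    predictors[[sid]] <- pred
    slot_train[[sid]] <- c(tr, es)
  }
  avg_slots <- function(ids, sids) {
    mats <- lapply(sids, function(s) as.matrix(predictors[[s]](ids)))
    out <- Reduce(`+`, mats) / length(mats)
    df <- data.frame(patient_id = ids, out, stringsAsFactors = FALSE,
                     row.names = NULL)
    df
  }
  oof <- NULL; prov <- list()
  for (o in seq_len(plan$k_outer)) {
    ids <- plan$outer_folds[[o]]
    sids <- sprintf("o%di%d", o, seq_len(plan$k_inner))
    oof <- rbind(oof, avg_slots(ids, sids))
    for (id in ids) prov[[id]] <- sids
  }
  oof <- oof[match(intersect(plan$patient_ids, oof$patient_id),
                   oof$patient_id), ]
  rownames(oof) <- NULL
  test <- NULL
  if (!is.null(test_ids) && length(test_ids))
    test <- avg_slots(test_ids, plan$slots$slot_id)
  structure(list(oof = oof, test = test, provenance = prov,
                 slot_train_ids = slot_train, plan = plan),
            class = "double_cv_result")
}

#' Audit out-of-fold predictions for leakage
#'
#' Machine-checks the provenance of every development prediction: none of
#' the slots contributing to a patient's out-of-fold prediction may have
#' seen that patient during fitting (training or early stopping).
#'
#' @param result A [run_double_cv()] result.
#' @return List with `ok` (logical) and `violations` (character vector of
#'   offending patient ids).
#' @export
audit_provenance <- function(result) {
  stopifnot(inherits(result, "double_cv_result"))
  bad <- character(0)
  for (id in names(result$provenance)) {
    for (sid in result$provenance[[id]]) {
      if (id %in% result$slot_train_ids[[sid]]) bad <- c(bad, id)
    }
  }
  list(ok = length(bad) == 0, violations = unique(bad))
}
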