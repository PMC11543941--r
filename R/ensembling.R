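# Leave-one-out test-time ensembling and top-k validation-ranked selection.

#' Build a leave-one-out ensemble training plan
#'
#' For each test image, the remaining test images are added to the training
#' roster and `models_per_test` models (differing only by seed) are planned,
#' so a test image never contributes to any model that predicts it. With 36
#' test ids and 5 models per test image the plan holds 180 models.
#'
#' @param train_ids,val_ids,test_ids Disjoint character/integer id sets.
#' @param models_per_test Models trained per test image (default 5).
#' @return An object of class `ensemble_plan`: `plan` (data.frame with
#'   `test_id`, `model`, `seed_offset`), `rosters` (named list: per test id,
#'   the training roster), `n_models`.
#' @export
make_loo_plan <- function(train_ids, val_ids, test_ids, models_per_test = 5) {
  ids <- list(train = train_ids, val = val_ids, test = test_ids)
  for (a in 1:2) for (b in (a + 1):3) {
    ov <- intersect(ids[[a]], ids[[b]])
    .check(length(ov) == 0, "id sets overlap (%s/%s): %s",
           names(ids)[a], names(ids)[b], paste(utils::head(ov, 3), collapse = ", "))
  }
  .check(models_per_test >= 1, "models_per_test must be >= 1")
  rosters <- lapply(test_ids, function(id) c(train_ids, setdiff(test_ids, id)))
  names(rosters) <- as.character(test_ids)
  plan <- data.frame(
    test_id = rep(as.character(test_ids), each = models_per_test),
    model = rep(seq_len(models_per_test), times = length(test_ids)),
    stringsAsFactors = FALSE)
  plan$seed_offset <- seq_len(nrow(plan))
  structure(list(plan = plan, rosters = rosters,
                 models_per_test = as.integer(models_per_test),
                 n_models = nrow(plan)),
            class = "ensemble_plan")
}

#' @export
print.ensemble_plan <- function(x, ...) {
  cat(sprintf("leave-one-out ensemble plan: %d test images x %d models = %d models\n",
              length(x$rosters), x$models_per_test, x$n_models))
  invisible(x)
}

#' Ensemble prediction by softmax averaging
#'
#' Averages the per-pixel softmax stacks of the member models arithmetically
#' and takes the class with the highest mean score (ties broken toward the
#' lowest class code). The averaged stack still sums to one per pixel.
#'
#' @param models List of `trained_unet` models sharing one spec geometry.
#' @param img A `bscan_image` or intensity matrix.
#' @param scheme An `oct_scheme` for the output mask.
#' @return `list(probs = <softmax_prediction>, mask = <label_mask>)`.
#' @export
ensemble_predict <- function(models, img, scheme = oct_class_scheme()) {
  .check(length(models) >= 1, "need at least one member model")
  sizes <- vapply(models, function(m) m$spec$input_size, integer(1))
  ks <- vapply(models, function(m) m$spec$n_classes, integer(1))
  .check(length(unique(sizes)) == 1 && length(unique(ks)) == 1,
         "member models have mixed input sizes or class counts")
  acc <- NULL
  for (m in models) {
    p <- unclass(predict_softmax(m, img))
    acc <- if (is.null(acc)) p else acc + p
  }
  probs <- structure(acc / length(models), class = "softmax_prediction")
  list(probs = probs, mask = probs_to_mask(probs, scheme))
}

#' Select the k models with the best validation scores
#'
#' Ties are broken by stable pool order.
#'
#' @param pool List of `trained_unet` models.
#' @param k Number of models to keep (k <= pool size).
#' @return A list of `k` models, sorted by decreasing validation score.
#' @export
select_top_models <- function(pool, k) {
  .check(k >= 1 && k <= length(pool),
         "k (%d) must be between 1 and the pool size (%d)", k, length(pool))
  scores <- vapply(pool, function(m) m$validation_score, numeric(1))
  pool[order(-scores)[seq_len(k)]]
}
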