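# Pixel-concatenated per-class F1 and inter-annotator concordance.

.mask_codes_list <- function(masks) {
  lapply(masks, function(m) if (inherits(m, "label_mask")) m$codes else m)
}

#' Pixel-concatenated per-class F1 report
#'
#' Accumulates TP/FP/FN over all pixels of all images before computing
#' precision, recall and F1 per class (no per-image averaging, hence no
#' between-image SDs). The background class is excluded. Classes absent
#' from both truth and prediction (TP+FP+FN = 0) are reported as `NA`
#' (undefined), not 0, and are excluded from macro averages.
#'
#' @param pred_masks,true_masks Equal-length lists of `label_mask` (or code
#'   matrices), pairwise shape-matched.
#' @param scheme An `oct_scheme`.
#' @return A `data.frame` (class `f1_report`) with one row per foreground
#'   class: `class`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`; the
#'   image count is in attribute `n_images`.
#' @export
f1_per_class <- function(pred_masks, true_masks, scheme = oct_class_scheme()) {
  .check(length(pred_masks) == length(true_masks),
         "prediction and truth lists must have equal length")
  pred <- .mask_codes_list(pred_masks)
  truth <- .mask_codes_list(true_masks)
  K <- length(scheme$labels)
  conf <- matrix(0, K, K)  # rows = predicted, cols = true
  for (i in seq_along(pred)) {
    .check(all(dim(pred[[i]]) == dim(truth[[i]])),
           "shape mismatch between prediction and truth at image %d", i)
    v <- c(pred[[i]], truth[[i]])
    .check(all(v >= 0 & v < K), "unknown class code at image %d", i)
    joint <- as.integer(pred[[i]]) * K + as.integer(truth[[i]]) + 1L
    conf <- conf + matrix(tabulate(joint, nbins = K * K), K, K, byrow = TRUE)
  }
  tp <- diag(conf)
  fp <- rowSums(conf) - tp
  fn <- colSums(conf) - tp
  fg <- seq_len(K)[-1]
  denom <- 2 * tp[fg] + fp[fg] + fn[fg]
  f1 <- ifelse(denom > 0, 2 * tp[fg] / denom, NA_real_)
  out <- data.frame(
    class = scheme$classes,
    tp = tp[fg], fp = fp[fg], fn = fn[fg],
    precision = ifelse(tp[fg] + fp[fg] > 0, tp[fg] / (tp[fg] + fp[fg]), NA_real_),
    recall = ifelse(tp[fg] + fn[fg] > 0, tp[fg] / (tp[fg] + fn[fg]), NA_real_),
    f1 = f1, stringsAsFactors = FALSE)
  attr(out, "n_images") <- length(pred)
  class(out) <- c("f1_report", "data.frame")
  out
}

#' Macro-averaged foreground F1 of an `f1_report`
#'
#' Undefined classes (absent from both truth and prediction) are excluded
#' from the average rather than scored 0 or 1.
#'
#' @param report An `f1_report`.
#' @return Scalar macro F1 (or `NA` if every class is undefined).
#' @export
macro_f1 <- function(report) {
  stopifnot(inherits(report, "f1_report"))
  if (all(is.na(report$f1))) NA_real_ else mean(report$f1, na.rm = TRUE)
}

#' Per-pixel majority-vote consensus of several annotations
#'
#' Stand-in for a human consensus panel when testing on synthetic data:
#' each pixel takes the most frequent code across annotators, ties broken
#' toward the lowest class code. An `override` mask (values `NA` = keep the
#' vote) provides the expert-override hook.
#'
#' @param masks List of `label_mask` objects over the same scan.
#' @param override Optional integer matrix; non-`NA` entries replace the
#'   voted code.
#' @return A `label_mask`.
#' @export
consensus_vote <- function(masks, override = NULL) {
  .check(length(masks) >= 1, "need at least one annotation")
  codes <- .mask_codes_list(masks)
  scheme <- masks[[1]]$scheme
  K <- length(scheme$labels)
  counts <- lapply(seq_len(K) - 1L, function(k)
    Reduce(`+`, lapply(codes, function(m) m == k)))
  best <- counts[[1]]
  vote <- matrix(0L, nrow(best), ncol(best))
  for (k in 2:K) {
    better <- counts[[k]] > best
    vote[better] <- k - 1L
    best <- pmax(best, counts[[k]])
  }
  if (!is.null(override)) {
    keep <- !is.na(override)
    vote[keep] <- as.integer(override[keep])
  }
  label_mask(vote, scheme)
}

#' Bar chart of per-class F1 scores
#'
#' Quick visual summary of an [f1_per_class()] report (and optionally a
#' [concordance_report()], grouped by rater).
#'
#' @param x An `f1_report` or `concordance_report`.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_f1 <- function(x, ...) {
  if (inherits(x, "concordance_report")) {
    m <- tapply(x$f1, list(x$rater, x$class), mean)
    graphics::barplot(m, beside = TRUE, ylim = c(0, 1), ylab = "F1",
                      legend.text = rownames(m), ...)
  } else {
    graphics::barplot(stats::setNames(x$f1, x$class), ylim = c(0, 1),
                      ylab = "F1", las = 2, ...)
  }
}

#' Annotator-vs-consensus concordance report
#'
#' One pixel-concatenated F1 row set per annotator, plus one for the model
#' ensemble, each scored against the consensus annotation and restricted to
#' the evaluated (ambiguous) classes. The ensemble row is computed exactly
#' like an annotator row and does not depend on the annotator rows.
#'
#' @param annotator_masks Named list; each element is a list of masks (one
#'   per scan) for one annotator.
#' @param consensus_masks List of consensus masks, aligned to the same scans.
#' @param ensemble_masks List of model-ensemble masks, same alignment.
#' @param scheme An `oct_scheme`.
#' @param eval_classes Classes to report (default: the ambiguous lesions
#'   SHRM, fPED, dPED, Fibrosis).
#' @return A `data.frame` (class `concordance_report`): `rater`, `class`,
#'   `f1`.
#' @export
concordance_report <- function(annotator_masks, consensus_masks, ensemble_masks,
                               scheme = oct_class_scheme(),
                               eval_classes = c("SHRM", "fPED", "dPED", "Fibrosis")) {
  n <- length(consensus_masks)
  for (a in annotator_masks)
    .check(length(a) == n, "annotator mask list not aligned to consensus (%d scans)", n)
  .check(length(ensemble_masks) == n, "ensemble mask list not aligned to consensus")
  raters <- c(annotator_masks, list(ensemble = ensemble_masks))
  if (is.null(names(raters)) || any(names(raters)[-length(raters)] == ""))
    names(raters)[seq_along(annotator_masks)] <-
      paste0("annotator", seq_along(annotator_masks))
  out <- do.call(rbind, lapply(names(raters), function(nm) {
    rep_ <- f1_per_class(raters[[nm]], consensus_masks, scheme)
    rep_ <- rep_[rep_$class %in% eval_classes, c("class", "f1")]
    data.frame(rater = nm, rep_, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("concordance_report", "data.frame")
  out
}
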