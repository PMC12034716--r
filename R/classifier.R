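#' Class scores by mean label-word probability
#'
#' Wraps the text into the soft prompt, takes the backbone's mask-fill
#' distribution, and scores each class as the mean probability of its
#' label words — every word in the verbalizer contributes equally. The
#' prediction is the argmax; exact ties go to the first class in the
#' verbalizer's fixed (sorted) class order and set the tie flag.
#'
#' @param text Input string.
#' @param state An `msp_soft_prompt`.
#' @param verbalizer An `msp_verbalizer`.
#' @param model The frozen backbone.
#' @param h Optional precomputed encoded soft-token matrix.
#' @param class_ids Optional pre-resolved label-word id sets.
#' @return An `msp_scores`: named numeric `scores`, `label`, `tie`.
#' @export
class_scores <- function(text, state, verbalizer, model, h = NULL,
                         class_ids = NULL) {
  if (is.null(class_ids))
    class_ids <- resolve_verbalizer_ids(verbalizer, model$vocab)
  a <- wrap_text(text, state, model, h = h)
  p <- mask_fill_distribution(model, a, attr(a, "mask_pos"))
  s <- scores_from_distribution(p, class_ids)
  names(s) <- verbalizer$classes
  best <- which.max(s)
  tie <- sum(s == s[best]) > 1L
  structure(list(scores = s, label = verbalizer$classes[best], tie = tie),
            class = "msp_scores")
}

#' @export
print.msp_scores <- function(x, ...) {
  cat("<msp_scores> -> ", x$label, if (x$tie) " (tie)" else "", "\n",
      sep = "")
  print(round(x$scores, 4))
  invisible(x)
}

#' Classify a batch of texts
#'
#' Elementwise application of [class_scores()]; the soft encoding and the
#' verbalizer resolution are shared across the batch, so batching changes
#' no prediction relative to one-at-a-time calls.
#'
#' @param texts Character vector.
#' @inheritParams class_scores
#' @return Character vector of predicted labels, same order as `texts`.
#' @export
classify_batch <- function(texts, state, verbalizer, model) {
  class_ids <- resolve_verbalizer_ids(verbalizer, model$vocab)
  h <- encode_soft_tokens(state)
  vapply(seq_along(texts), function(i) {
    out <- tryCatch(
      class_scores(texts[i], state, verbalizer, model, h = h,
                   class_ids = class_ids),
      error = function(e) stop("classification failed at input ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    out$label
  }, character(1))
}

#' Evaluate predictions against gold labels
#'
#' @param predictions,gold Character vectors of equal length.
#' @param classes Optional fixed class order for the confusion matrix.
#' @param meta Optional list of episode metadata (seed, K, ...) carried on
#'   the report.
#' @return An `msp_eval`: `accuracy` (fraction), `accuracy_pct`
#'   (percentage, 2 decimals), `confusion`, per-class `precision` and
#'   `recall`, `n`, `meta`.
#' @export
evaluate <- function(predictions, gold, classes = NULL, meta = list()) {
  if (length(predictions) != length(gold))
    stop("misaligned data: predictions and gold differ in length")
  classes <- classes %||% sort(unique(c(predictions, gold)))
  conf <- table(factor(gold, levels = classes),
                factor(predictions, levels = classes),
                dnn = c("gold", "predicted"))
  acc <- sum(diag(conf)) / length(gold)
  precision <- diag(conf) / pmax(colSums(conf), 1L)
  recall <- diag(conf) / pmax(rowSums(conf), 1L)
  structure(list(accuracy = acc, accuracy_pct = round(100 * acc, 2),
                 confusion = conf, precision = precision, recall = recall,
                 n = length(gold), meta = meta),
            class = "msp_eval")
}

#' @export
print.msp_eval <- function(x, ...) {
  cat("<msp_eval> accuracy ", sprintf("%.2f%%", x$accuracy_pct),
      " on n=", x$n, "\n", sep = "")
  print(x$confusion)
  invisible(x)
}
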