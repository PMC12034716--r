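# Soft-prompt training: cross-entropy over classes with class logits equal
# to the log of the mean label-word mask-fill probability (the same score
# the classifier uses at prediction time), optimized with AdamW while the
# backbone stays frozen. All gradients here are analytic and are checked
# against numerical differentiation in the test suite.

# Per-class vocabulary ids of a verbalizer's label words. Words that are
# not single in-vocabulary tokens are skipped (with a warning); a class
# losing all words is an error.
resolve_verbalizer_ids <- function(verbalizer, vocab, warn = TRUE) {
  out <- lapply(verbalizer$classes, function(cl) {
    words <- verbalizer$sets[[cl]]$word
    ids <- unname(vocab$index[words])
    bad <- is.na(ids) | ids %in% special_ids(vocab)
    if (any(bad) && warn)
      warning("verbalizer words outside vocabulary skipped for class '",
              cl, "': ", paste(words[bad], collapse = ", "), call. = FALSE)
    ids <- ids[!bad]
    if (!length(ids))
      stop("unusable verbalizer: no in-vocabulary label words for class '",
           cl, "'")
    as.integer(ids)
  })
  names(out) <- verbalizer$classes
  out
}

# Mean label-word probability per class from a mask-fill distribution.
scores_from_distribution <- function(p, class_ids) {
  vapply(class_ids, function(ids) mean(p[ids]), numeric(1))
}

# Forward + backward of the classification loss for one context mean.
# Returns loss and the gradient with respect to the context mean.
class_loss_grad <- function(params, ctx, class_ids, true_idx) {
  u <- tanh(as.vector(params$W %*% ctx) + params$b_h)
  p <- softmax(as.vector(params$U %*% u) + params$b_o)
  s <- unname(scores_from_distribution(p, class_ids))
  q <- s / sum(s)
  loss <- -log(q[true_idx])

  ds <- rep(1 / sum(s), length(s))
  ds[true_idx] <- ds[true_idx] - 1 / s[true_idx]
  dp <- numeric(length(p))
  for (k in seq_along(class_ids)) {
    ids <- class_ids[[k]]
    dp[ids] <- dp[ids] + ds[k] / length(ids)
  }
  dz <- p * (dp - sum(dp * p))
  du <- as.vector(crossprod(params$U, dz))
  da <- du * (1 - u * u)
  dctx <- as.vector(crossprod(params$W, da))
  list(loss = loss, dctx = dctx)
}

# Precompute the fixed (frozen-backbone) parts of each training example.
precompute_examples <- function(texts, labels, model, classes) {
  lapply(seq_along(texts), function(i) {
    toks <- tokenize(texts[i], model$vocab)
    E <- model$params$E[toks$ids, , drop = FALSE]
    list(sum_x = colSums(E), nx = length(toks$ids),
         y = match(labels[i], classes))
  })
}

# Loss and soft-prompt gradients for a batch of precomputed examples.
# drop_masks: list (one n_soft x dim 0/1 matrix per example) or NULL for
# evaluation-mode (no dropout).
sp_batch_grad <- function(state, model, examples, class_ids,
                          drop_masks = NULL, dropout = 0) {
  cache <- encode_soft_cache(state)
  H <- cache$H
  n_soft <- nrow(H)
  nb <- length(examples)
  keep <- 1 - dropout
  dH <- matrix(0, n_soft, ncol(H))
  total <- 0
  for (b in seq_len(nb)) {
    ex <- examples[[b]]
    Hb <- if (is.null(drop_masks)) H else H * drop_masks[[b]] / keep
    denom <- n_soft + ex$nx
    ctx <- (colSums(Hb) + ex$sum_x) / denom
    fb <- class_loss_grad(model$params, ctx, class_ids, ex$y)
    if (!is.finite(fb$loss))
      stop("divergence: non-finite loss at batch element ", b)
    total <- total + fb$loss
    g <- fb$dctx / denom / nb
    if (is.null(drop_masks)) {
      dH <- dH + matrix(g, n_soft, length(g), byrow = TRUE)
    } else {
      dH <- dH + (drop_masks[[b]] / keep) *
        matrix(g, n_soft, length(g), byrow = TRUE)
    }
  }
  grads <- encode_soft_backward(state, cache, dH)
  list(loss = total / nb, grads = grads)
}

#' Train the soft prompt against a frozen backbone
#'
#' Optimizes the raw soft tokens, the BiLSTM and the projection with AdamW;
#' the backbone receives no updates (its parameter digest is unchanged).
#' The per-example loss is the cross-entropy of the true class under
#' softmax-normalized class scores, each class score being the mean
#' mask-fill probability of its label words — the same quantity the
#' classifier maximizes.
#'
#' @param train A data.frame with columns `text` and `label`.
#' @param verbalizer An `msp_verbalizer` covering every label in `train`.
#' @param model A frozen `msp_backbone`.
#' @param sp_config A [soft_prompt_config()].
#' @param t_config A [train_config()].
#' @param state Optional initial `msp_soft_prompt`; defaults to a fresh
#'   seed-controlled init.
#' @return A list with `state` (the trained `msp_soft_prompt`) and `log`
#'   (data.frame of per-epoch mean loss; epoch 0 is the pre-training loss).
#' @export
train_soft_prompt <- function(train, verbalizer, model,
                              sp_config = soft_prompt_config(),
                              t_config = train_config(),
                              state = NULL) {
  if (!isTRUE(model$frozen))
    stop("backbone must be frozen before soft-prompt training")
  missing_lab <- setdiff(unique(train$label), verbalizer$classes)
  if (length(missing_lab))
    stop("labels absent from verbalizer: ",
         paste(missing_lab, collapse = ", "))
  class_ids <- resolve_verbalizer_ids(verbalizer, model$vocab)
  if (is.null(state))
    state <- soft_prompt_init(model, sp_config,
                              seed = derive_seed(t_config$seed, 7L))
  examples <- precompute_examples(train$text, train$label, model,
                                  verbalizer$classes)
  n <- length(examples)
  dropout <- state$config$dropout
  set.seed(derive_seed(t_config$seed, 29L))
  opt <- adam_init(state$params)
  log <- data.frame(epoch = 0L,
                    loss = sp_batch_grad(state, model, examples,
                                         class_ids)$loss)
  for (epoch in seq_len(t_config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = t_config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + t_config$batch_size - 1L, n)]
      masks <- if (dropout > 0) {
        lapply(idx, function(i)
          matrix(stats::rbinom(length(state$params$S), 1L, 1 - dropout),
                 nrow(state$params$S), ncol(state$params$S)))
      } else NULL
      step <- sp_batch_grad(state, model, examples[idx], class_ids,
                            drop_masks = masks, dropout = dropout)
      ep_loss <- ep_loss + step$loss * length(idx)
      upd <- adam_step(opt, state$params, step$grads, lr = t_config$lr,
                       weight_decay = t_config$weight_decay)
      state$params <- upd$params
      opt <- upd$opt
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = ep_loss / n))
  }
  rownames(log) <- NULL
  list(state = state, log = log)
}
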