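#' Masked-language-model backbone
#'
#' The backbone contract consumed by every other module: it supplies token
#' embeddings, a vocabulary distribution at a masked position, and a
#' masked-token cross-entropy loss. The packaged reference implementation is
#' a deliberately small trainable MLM so the whole pipeline runs on one CPU
#' without downloads; any model honoring the same generics can be plugged in.
#'
#' Reference architecture: an embedding table `E` (|V| x d) and a one-layer
#' mean-context encoder. To predict the token at a masked position, the mean
#' `c` of the embeddings at all *other* positions is encoded as
#' `u = tanh(W c + b_h)` and scored as `logits = U u + b_o`, softmaxed over
#' the vocabulary. The masked position itself always carries the `[MASK]`
#' embedding and contributes nothing, so the encoder conditions exactly on
#' the context, which is what both pretraining and cloze classification
#' need.
#'
#' @name backbone
NULL

#' Initialize an untrained reference backbone
#'
#' @param vocab An `msp_vocabulary`.
#' @param dim Embedding dimension (default 32).
#' @param hidden Encoder hidden width (default 64).
#' @param init_sd Standard deviation of the normal parameter init.
#' @param seed Integer seed for the init.
#' @return An `msp_backbone` (not frozen).
#' @export
backbone_init <- function(vocab, dim = 32L, hidden = 64L, init_sd = 0.05,
                          seed = 1L) {
  nv <- length(vocab)
  set.seed(seed)
  params <- list(
    E   = matrix(stats::rnorm(nv * dim, sd = init_sd), nv, dim),
    W   = matrix(stats::rnorm(hidden * dim, sd = init_sd), hidden, dim),
    b_h = numeric(hidden),
    U   = matrix(stats::rnorm(nv * hidden, sd = init_sd), nv, hidden),
    b_o = numeric(nv)
  )
  # special-token embeddings: PAD stays zero; MASK/UNK random like the rest
  params$E[vocab$pad_id, ] <- 0
  structure(
    list(vocab = vocab, params = params,
         dim = as.integer(dim), hidden = as.integer(hidden),
         frozen = FALSE),
    class = "msp_backbone"
  )
}

#' @export
print.msp_backbone <- function(x, ...) {
  cat("<msp_backbone> |V|=", length(x$vocab), " dim=", x$dim,
      " hidden=", x$hidden, if (isTRUE(x$frozen)) " [frozen]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Digest of a backbone's parameters
#'
#' Used to verify the frozen-backbone contract: the digest must be
#' identical before and after any soft-prompt training run.
#'
#' @param model An `msp_backbone`.
#' @return Character hash.
#' @export
backbone_digest <- function(model) param_digest(model$params)

#' Embedding sequence from a token sequence
#'
#' Row i is the embedding-table row of the i-th token id; all positions are
#' tagged `"input"`.
#'
#' @param tokens An `msp_tokens` (or bare integer id vector).
#' @param model An `msp_backbone`.
#' @return An `msp_embeddings` object: matrix `E` (positions x dim), `tags`,
#'   and the originating `ids` (`NA` at non-token positions).
#' @export
embed_sequence <- function(tokens, model) {
  ids <- if (inherits(tokens, "msp_tokens")) tokens$ids else as.integer(tokens)
  if (length(ids) < 1L) stop("empty token sequence")
  if (any(ids < 1L | ids > length(model$vocab)))
    stop("token id out of range: corrupt sequence")
  embeddings(model$params$E[ids, , drop = FALSE],
             tags = rep("input", length(ids)), ids = ids)
}

embeddings <- function(E, tags, ids) {
  structure(list(E = E, tags = tags, ids = ids), class = "msp_embeddings")
}

#' @export
print.msp_embeddings <- function(x, ...) {
  cat("<msp_embeddings> ", nrow(x$E), " x ", ncol(x$E), " [",
      paste(x$tags, collapse = ","), "]\n", sep = "")
  invisible(x)
}

# ids with the given position replaced by [MASK], as an embedding sequence
masked_embeddings <- function(model, ids, mask_at) {
  seq <- embed_sequence(ids, model)
  seq$E[mask_at, ] <- model$params$E[model$vocab$mask_id, ]
  seq$tags[mask_at] <- "mask"
  seq$ids[mask_at] <- NA_integer_
  seq
}

#' Vocabulary distribution at a masked position
#'
#' Runs the backbone at the (single) masked position of an embedding
#' sequence and returns the probability of every vocabulary item filling
#' the mask. Dispatches on the model so alternative backbones (including
#' the test stub) can implement the same contract.
#'
#' @param model A backbone object.
#' @param seq An `msp_embeddings` with a `"mask"` tag at `mask_pos`.
#' @param mask_pos Integer position of the mask.
#' @return Numeric probability vector over the vocabulary (sums to 1).
#' @export
mask_fill_distribution <- function(model, seq, mask_pos) {
  UseMethod("mask_fill_distribution")
}

#' @export
mask_fill_distribution.msp_backbone <- function(model, seq, mask_pos) {
  check_mask_at(seq, mask_pos)
  ctx <- context_mean(seq$E, mask_pos)
  p <- model$params
  u <- tanh(as.vector(p$W %*% ctx) + p$b_h)
  softmax(as.vector(p$U %*% u) + p$b_o)
}

check_mask_at <- function(seq, mask_pos) {
  if (mask_pos < 1L || mask_pos > nrow(seq$E) ||
      !identical(seq$tags[mask_pos], "mask"))
    stop("malformed prompt: no mask at position ", mask_pos)
  invisible(TRUE)
}

context_mean <- function(E, mask_pos) {
  if (nrow(E) <= 1L) return(numeric(ncol(E)))
  colMeans(E[-mask_pos, , drop = FALSE])
}

#' A stub backbone with a prescribed mask-fill distribution
#'
#' For tests and oracles: implements the backbone contract but returns a
#' caller-supplied distribution (optionally a function of the sequence and
#' mask position) instead of running an encoder.
#'
#' @param vocab An `msp_vocabulary`.
#' @param probs Numeric probability vector over the vocabulary, or a
#'   function `(seq, mask_pos) -> probs`.
#' @param dim Embedding dimension for `embed_sequence` compatibility.
#' @param embedding Optional |V| x dim embedding table.
#' @param seed Seed for the random embedding table when none is given.
#' @return An `msp_stub_backbone`.
#' @export
backbone_stub <- function(vocab, probs, dim = 8L, embedding = NULL,
                          seed = 1L) {
  if (is.null(embedding)) {
    set.seed(seed)
    embedding <- matrix(stats::rnorm(length(vocab) * dim, sd = 0.5),
                        length(vocab), dim)
  }
  structure(
    list(vocab = vocab, params = list(E = embedding), dim = ncol(embedding),
         probs = probs, frozen = TRUE),
    class = c("msp_stub_backbone", "msp_backbone")
  )
}

#' @export
mask_fill_distribution.msp_stub_backbone <- function(model, seq, mask_pos) {
  check_mask_at(seq, mask_pos)
  p <- if (is.function(model$probs)) model$probs(seq, mask_pos) else model$probs
  p <- as.numeric(p)
  if (length(p) != length(model$vocab)) stop("stub distribution wrong length")
  p / sum(p)
}

#' Cross-entropy of the true token at a masked position
#'
#' Masks `position` inside a context window and returns
#' `-log p(v = w_position | window with position masked)` under the model's
#' mask-fill distribution — the per-word loss of the windowed
#' pseudo-log-likelihood.
#'
#' @param model A backbone object.
#' @param window An `msp_window` (see [context_window()]), or a bare integer
#'   id vector treated as an unpadded window.
#' @param position Index of the token to mask, in window coordinates.
#' @return Non-negative loss value.
#' @export
masked_token_loss <- function(model, window, position) {
  if (!inherits(window, "msp_window")) window <- context_window(window)
  if (position < 1L || position > length(window$ids) ||
      isTRUE(window$pad[position]))
    stop("invalid window position ", position)
  keep <- !window$pad
  ids <- window$ids[keep]
  pos <- sum(keep[seq_len(position)])
  true_id <- window$ids[position]
  seq <- masked_embeddings(model, ids, pos)
  p <- mask_fill_distribution(model, seq, pos)
  -log(p[true_id])
}

#' Tiny-MLM training configuration
#'
#' @param dim,hidden Embedding dimension and encoder width.
#' @param epochs,batch_size,lr Optimization schedule (Adam).
#' @param mask_rate Fraction of positions masked per sentence per epoch
#'   (at least one), uniformly at random.
#' @param init_sd Parameter init scale.
#' @return A list of class `msp_mlm_config`.
#' @export
mlm_config <- function(dim = 32L, hidden = 64L, epochs = 30L,
                       batch_size = 64L, lr = 0.005, mask_rate = 0.15,
                       init_sd = 0.05) {
  structure(list(dim = as.integer(dim), hidden = as.integer(hidden),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 mask_rate = mask_rate, init_sd = init_sd),
            class = "msp_mlm_config")
}

#' Pretrain the reference MLM on a corpus
#'
#' Random-masking cross-entropy training of the mean-context encoder and
#' embedding table. Deterministic given `seed`. The returned model is
#' marked frozen; soft-prompt training never updates it.
#'
#' @param corpus List of `msp_tokens` (or integer id vectors).
#' @param vocab The `msp_vocabulary` covering the corpus.
#' @param config An [mlm_config()].
#' @param seed Integer seed.
#' @return An `msp_backbone` with `frozen = TRUE` and attribute
#'   `training_log` (per-epoch mean loss, epoch 0 = pre-training loss).
#' @export
train_tiny_mlm <- function(corpus, vocab, config = mlm_config(), seed = 1L) {
  if (length(corpus) == 0L) stop("nothing to train: empty corpus")
  id_list <- lapply(corpus, function(x)
    if (inherits(x, "msp_tokens")) x$ids else as.integer(x))
  nv <- length(vocab)
  if (any(unlist(id_list) > nv)) stop("corpus id outside vocabulary")

  model <- backbone_init(vocab, dim = config$dim, hidden = config$hidden,
                         init_sd = config$init_sd, seed = seed)
  set.seed(derive_seed(seed, 17L))
  opt <- adam_init(model$params)
  log <- numeric(config$epochs + 1L)

  for (epoch in seq_len(config$epochs)) {
    items <- sample_mask_items(id_list, config$mask_rate)
    items <- items[sample.int(nrow(items)), , drop = FALSE]
    if (epoch == 1L)
      log[1L] <- mlm_epoch_loss(model, id_list, items)
    n <- nrow(items)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      batch <- items[s:min(s + config$batch_size - 1L, n), , drop = FALSE]
      step <- mlm_batch_grad(model$params, id_list, batch, vocab)
      ep_loss <- ep_loss + step$loss * nrow(batch)
      upd <- adam_step(opt, model$params, step$grads, lr = config$lr)
      model$params <- upd$params
      opt <- upd$opt
      model$params$E[vocab$pad_id, ] <- 0
    }
    log[epoch + 1L] <- ep_loss / n
  }
  model$frozen <- TRUE
  attr(model, "training_log") <- log
  model
}

# (sentence, position) pairs to mask this epoch: ceil(rate * len) per
# sentence, uniform positions
sample_mask_items <- function(id_list, rate) {
  out <- lapply(seq_along(id_list), function(i) {
    len <- length(id_list[[i]])
    k <- max(1L, ceiling(rate * len))
    pos <- if (len == 1L) 1L else sample.int(len, k)
    cbind(sent = rep(i, k), pos = pos)
  })
  do.call(rbind, out)
}

# Batched forward/backward for (sentence, position) mask items.
mlm_batch_grad <- function(params, id_list, items, vocab) {
  n <- nrow(items)
  d <- ncol(params$E)
  C <- matrix(0, n, d)
  targets <- integer(n)
  ctx_ids <- vector("list", n)
  for (i in seq_len(n)) {
    ids <- id_list[[items[i, "sent"]]]
    pos <- items[i, "pos"]
    targets[i] <- ids[pos]
    ctx <- ids[-pos]
    ctx_ids[[i]] <- ctx
    if (length(ctx)) C[i, ] <- colMeans(params$E[ctx, , drop = FALSE])
  }
  A <- C %*% t(params$W)
  A <- sweep(A, 2L, params$b_h, "+")
  H <- tanh(A)
  Z <- H %*% t(params$U)
  Z <- sweep(Z, 2L, params$b_o, "+")
  P <- softmax_rows(Z)
  loss <- -mean(log(P[cbind(seq_len(n), targets)]))

  dZ <- P
  dZ[cbind(seq_len(n), targets)] <- dZ[cbind(seq_len(n), targets)] - 1
  dZ <- dZ / n
  dU <- t(dZ) %*% H
  db_o <- colSums(dZ)
  dH <- dZ %*% params$U
  dA <- dH * (1 - H * H)
  dW <- t(dA) %*% C
  db_h <- colSums(dA)
  dC <- dA %*% params$W
  dE <- matrix(0, nrow(params$E), d)
  for (i in seq_len(n)) {
    ctx <- ctx_ids[[i]]
    if (length(ctx)) {
      g <- dC[i, ] / length(ctx)
      for (j in ctx) dE[j, ] <- dE[j, ] + g
    }
  }
  list(loss = loss,
       grads = list(E = dE, W = dW, b_h = db_h, U = dU, b_o = db_o))
}

mlm_epoch_loss <- function(model, id_list, items) {
  n <- nrow(items)
  tot <- 0
  for (s in seq(1L, n, by = 256L)) {
    batch <- items[s:min(s + 255L, n), , drop = FALSE]
    tot <- tot + mlm_batch_grad(model$params, id_list, batch,
                                model$vocab)$loss * nrow(batch)
  }
  tot / n
}

#' Save / load a backbone checkpoint
#'
#' Single-file checkpoint holding parameters, dimensions, vocabulary and a
#' vocabulary hash; loading verifies the hash.
#'
#' @param model An `msp_backbone`.
#' @param path File path.
#' @export
save_backbone <- function(model, path) {
  saveRDS(list(params = model$params, dim = model$dim,
               hidden = model$hidden, frozen = model$frozen,
               vocab = model$vocab, vocab_hash = param_digest(model$vocab),
               training_log = attr(model, "training_log")),
          path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  x <- readRDS(path)
  if (!identical(param_digest(x$vocab), x$vocab_hash))
    stop("backbone checkpoint vocabulary hash mismatch")
  model <- structure(
    list(vocab = x$vocab, params = x$params, dim = x$dim,
         hidden = x$hidden, frozen = x$frozen),
    class = "msp_backbone")
  attr(model, "training_log") <- x$training_log
  model
}
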