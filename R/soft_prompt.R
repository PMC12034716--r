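#' Soft-prompt configuration
#'
#' Geometry and regularization of the continuous prompt. `n_soft` raw soft
#' tokens are re-encoded by a BiLSTM; `insert_index` of the encoded vectors
#' precede the input embeddings and the rest follow them, with the mask
#' embedding last.
#'
#' @param n_soft Number of soft tokens (default 4).
#' @param insert_index How many soft tokens precede the input
#'   (0..`n_soft`; default `n_soft / 2` so soft tokens flank the input).
#' @param hidden_size BiLSTM hidden width per direction (default 200).
#' @param dropout Dropout rate on the encoded soft tokens during training
#'   only (default 0.5).
#' @return An `msp_sp_config`.
#' @export
soft_prompt_config <- function(n_soft = 4L, insert_index = NULL,
                               hidden_size = 200L, dropout = 0.5) {
  n_soft <- as.integer(n_soft)
  if (n_soft < 1L) stop("empty prompt: n_soft must be >= 1")
  insert_index <- as.integer(insert_index %||% (n_soft %/% 2L))
  if (insert_index < 0L || insert_index > n_soft)
    stop("insert_index must lie in 0..n_soft")
  if (hidden_size < 1L) stop("hidden_size must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(n_soft = n_soft, insert_index = insert_index,
                 hidden_size = as.integer(hidden_size), dropout = dropout),
            class = "msp_sp_config")
}

#' Optimization configuration for soft-prompt training
#'
#' Defaults follow the few-shot training regime of the method: AdamW,
#' learning rate 3e-4, weight decay 0.01, batch size 64, 10 epochs, with a
#' named learning-rate preset `"sensitivity_optimum"` (3e-5) exposed because
#' the two reported values disagree.
#'
#' @param lr Learning rate, or one of the preset names
#'   `"reported"` (3e-4) / `"sensitivity_optimum"` (3e-5).
#' @param weight_decay Decoupled weight decay (default 0.01).
#' @param batch_size Minibatch size (default 64).
#' @param epochs Training epochs (default 10).
#' @param seed Integer seed controlling init, shuffling and dropout.
#' @return An `msp_train_config`.
#' @export
train_config <- function(lr = 3e-4, weight_decay = 0.01, batch_size = 64L,
                         epochs = 10L, seed = 1L) {
  if (is.character(lr))
    lr <- switch(lr, reported = 3e-4, sensitivity_optimum = 3e-5,
                 stop("unknown learning-rate preset: ", lr))
  if (lr <= 0) stop("learning rate must be positive")
  if (batch_size < 1L) stop("batch size must be >= 1")
  structure(list(optimizer = "adamw", lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "msp_train_config")
}

#' Initialize a soft-prompt state
#'
#' Raw soft-token embeddings plus BiLSTM and projection parameters. Raw
#' tokens are drawn N(0, 0.02^2) by default, or initialized from the
#' embeddings of randomly sampled vocabulary words.
#'
#' @param model The (frozen) backbone whose embedding dimension the prompt
#'   must match.
#' @param config An [soft_prompt_config()].
#' @param init `"normal"` or `"vocab"`.
#' @param seed Integer seed.
#' @return An `msp_soft_prompt`.
#' @export
soft_prompt_init <- function(model, config = soft_prompt_config(),
                             init = c("normal", "vocab"), seed = 1L) {
  init <- match.arg(init)
  d <- model$dim
  hd <- config$hidden_size
  set.seed(seed)
  S <- if (init == "normal") {
    matrix(stats::rnorm(config$n_soft * d, sd = 0.02), config$n_soft, d)
  } else {
    nonspecial <- setdiff(seq_len(length(model$vocab)), special_ids(model$vocab))
    model$params$E[sample(nonspecial, config$n_soft), , drop = FALSE]
  }
  params <- list(S = S)
  lf <- lstm_init(d, hd)
  lb <- lstm_init(d, hd)
  params$Wx_f <- lf$Wx; params$Wh_f <- lf$Wh; params$b_f <- lf$b
  params$Wx_b <- lb$Wx; params$Wh_b <- lb$Wh; params$b_b <- lb$b
  params$W_p <- matrix(stats::rnorm(d * 2 * hd, sd = 0.02), d, 2 * hd)
  params$b_p <- numeric(d)
  structure(list(params = params, config = config, dim = d),
            class = "msp_soft_prompt")
}

#' @export
print.msp_soft_prompt <- function(x, ...) {
  cat("<msp_soft_prompt> n_soft=", x$config$n_soft,
      " insert=", x$config$insert_index,
      " hidden=", x$config$hidden_size, " dim=", x$dim, "\n", sep = "")
  invisible(x)
}

#' Digest of a soft-prompt state
#' @param state An `msp_soft_prompt`.
#' @return Character hash of all trainable parameters.
#' @export
soft_prompt_digest <- function(state) param_digest(state$params)

# Forward pass with caches for BPTT. Returns H (n_soft x dim).
encode_soft_cache <- function(state) {
  p <- state$params
  n <- nrow(p$S)
  fw <- lstm_forward(list(Wx = p$Wx_f, Wh = p$Wh_f, b = p$b_f), p$S)
  Srev <- p$S[rev(seq_len(n)), , drop = FALSE]
  bw <- lstm_forward(list(Wx = p$Wx_b, Wh = p$Wh_b, b = p$b_b), Srev)
  HB <- bw$H[rev(seq_len(n)), , drop = FALSE]
  Cat <- cbind(fw$H, HB)
  H <- Cat %*% t(p$W_p)
  H <- sweep(H, 2L, p$b_p, "+")
  list(H = H, fw = fw, bw = bw, Cat = Cat)
}

# Gradients of all soft-prompt parameters given dH on encoded outputs.
encode_soft_backward <- function(state, cache, dH) {
  p <- state$params
  n <- nrow(p$S)
  hd <- state$config$hidden_size
  dW_p <- t(dH) %*% cache$Cat
  db_p <- colSums(dH)
  dCat <- dH %*% p$W_p
  dHF <- dCat[, seq_len(hd), drop = FALSE]
  dHB <- dCat[, hd + seq_len(hd), drop = FALSE]
  bf <- lstm_backward(list(Wx = p$Wx_f, Wh = p$Wh_f, b = p$b_f),
                      p$S, cache$fw, dHF)
  Srev <- p$S[rev(seq_len(n)), , drop = FALSE]
  bb <- lstm_backward(list(Wx = p$Wx_b, Wh = p$Wh_b, b = p$b_b),
                      Srev, cache$bw, dHB[rev(seq_len(n)), , drop = FALSE])
  dS <- bf$dX + bb$dX[rev(seq_len(n)), , drop = FALSE]
  list(S = dS,
       Wx_f = bf$Wx, Wh_f = bf$Wh, b_f = bf$b,
       Wx_b = bb$Wx, Wh_b = bb$Wh, b_b = bb$b,
       W_p = dW_p, b_p = db_p)
}

#' Encode the raw soft tokens with the BiLSTM
#'
#' Runs the forward and backward recurrences over the raw soft-token
#' sequence, concatenates the two hidden states at each position, and
#' projects to the backbone embedding dimension. Evaluation mode: dropout
#' is off, so repeated calls are identical.
#'
#' @param state An `msp_soft_prompt`.
#' @return Matrix `n_soft` x `dim` whose i-th row is the encoded soft
#'   vector h_i.
#' @export
encode_soft_tokens <- function(state) {
  encode_soft_cache(state)$H
}

#' Assemble the full prompt embedding sequence
#'
#' Lays out the continuous prompt as: the first `insert_index` encoded soft
#' vectors, the input embeddings, the remaining soft vectors, and the mask
#' embedding last. Exactly one mask position results.
#'
#' @param h Matrix of encoded soft vectors (`n_soft` x dim).
#' @param x_emb An `msp_embeddings` for the input tokens.
#' @param mask_emb The mask embedding vector.
#' @param config An [soft_prompt_config()].
#' @return An `msp_embeddings` with `tags` in `{"soft","input","mask"}` and
#'   attributes `mask_pos` and `positions` (a list giving the soft / input /
#'   mask index sets).
#' @export
assemble_prompt <- function(h, x_emb, mask_emb, config) {
  if (nrow(h) != config$n_soft)
    stop("encoded soft vectors do not match n_soft")
  d <- ncol(x_emb$E)
  if (ncol(h) != d || length(mask_emb) != d)
    stop("incompatible backbone: embedding dimensions disagree")
  i <- config$insert_index
  n <- config$n_soft
  pre <- h[seq_len(i), , drop = FALSE]
  post <- h[setdiff(seq_len(n), seq_len(i)), , drop = FALSE]
  E <- rbind(pre, x_emb$E, post, matrix(mask_emb, 1L, d))
  nx <- nrow(x_emb$E)
  tags <- c(rep("soft", i), rep("input", nx), rep("soft", n - i), "mask")
  ids <- c(rep(NA_integer_, i), x_emb$ids, rep(NA_integer_, n - i),
           NA_integer_)
  out <- embeddings(E, tags, ids)
  attr(out, "mask_pos") <- n + nx + 1L
  attr(out, "positions") <- list(
    soft = c(seq_len(i), i + nx + seq_len(n - i)),
    input = i + seq_len(nx),
    mask = n + nx + 1L)
  out
}

#' Wrap a text into its prompt assembly
#'
#' Tokenizes, embeds, encodes the soft tokens (or uses a precomputed
#' matrix), and assembles the prompt.
#'
#' @param text Input string.
#' @param state An `msp_soft_prompt`.
#' @param model The backbone.
#' @param h Optional precomputed encoded soft matrix.
#' @return The prompt assembly (see [assemble_prompt()]).
#' @export
wrap_text <- function(text, state, model, h = NULL) {
  toks <- tokenize(text, model$vocab)
  x_emb <- embed_sequence(toks, model)
  if (is.null(h)) h <- encode_soft_tokens(state)
  assemble_prompt(h, x_emb, model$params$E[model$vocab$mask_id, ],
                  state$config)
}

#' Save / load a soft-prompt checkpoint
#'
#' The checkpoint records the backbone vocabulary hash and refuses to load
#' against a backbone with a different vocabulary.
#'
#' @param state An `msp_soft_prompt`.
#' @param model The backbone it was trained against.
#' @param path File path.
#' @export
save_soft_prompt <- function(state, model, path) {
  saveRDS(list(params = state$params, config = state$config,
               dim = state$dim, vocab_hash = param_digest(model$vocab)),
          path)
  invisible(path)
}

#' @rdname save_soft_prompt
#' @export
load_soft_prompt <- function(path, model) {
  x <- readRDS(path)
  if (!identical(x$vocab_hash, param_digest(model$vocab)))
    stop("soft-prompt checkpoint was trained against a different vocabulary")
  structure(list(params = x$params, config = x$config, dim = x$dim),
            class = "msp_soft_prompt")
}
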