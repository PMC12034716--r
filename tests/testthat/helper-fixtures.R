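# Shared fixtures: tiny vocabularies, stub backbones with prescribed
# distributions, a unigram Naive-Bayes oracle, and a memoized "study world"
# (default synthetic conditions + pretrained tiny MLM) for the slower
# end-to-end tests.

tiny_vocab <- function(tokens = letters[1:5]) vocabulary(tokens)

# Stub whose mask-fill distribution is fixed (named by token) regardless of
# input; unnamed mass is spread over the remaining non-special tokens.
stub_with_probs <- function(vocab, named_probs) {
  p <- rep(0, length(vocab))
  ids <- vocab_ids(vocab, names(named_probs))
  p[ids] <- unlist(named_probs)
  rest <- setdiff(seq_len(length(vocab)), c(ids, vocab$pad_id))
  p[rest] <- (1 - sum(p)) / length(rest)
  backbone_stub(vocab, p)
}

uniform_stub <- function(vocab) {
  backbone_stub(vocab, rep(1 / length(vocab), length(vocab)))
}

# Stub whose mask-fill distribution gives the true token at window
# position i the probability exp(-loss[i]) (so masked_token_loss returns
# exactly loss[i]).
loss_stub <- function(vocab, window_ids, losses) {
  backbone_stub(vocab, function(seq, mask_pos) {
    slot <- which(is.na(seq$ids))[1L]
    orig <- window_ids[slot]
    li <- losses[slot]
    nv <- length(vocab)
    p <- rep((1 - exp(-li)) / (nv - 1), nv)
    p[orig] <- exp(-li)
    p
  })
}

# Unigram Naive-Bayes classifier with Laplace smoothing — independent
# oracle for the separability of generated datasets.
nb_oracle <- function(train, test, vocab) {
  classes <- sort(unique(train$label))
  counts <- lapply(classes, function(cl) {
    toks <- unlist(lapply(train$text[train$label == cl], normalize_tokens))
    tab <- table(factor(toks, levels = vocab$tokens))
    (tab + 1) / sum(tab + 1)
  })
  names(counts) <- classes
  vapply(test$text, function(tx) {
    toks <- normalize_tokens(tx)
    ll <- vapply(classes, function(cl)
      sum(log(counts[[cl]][toks])), numeric(1))
    classes[which.max(ll)]
  }, character(1), USE.NAMES = FALSE)
}

# Default synthetic study conditions with a pretrained frozen tiny MLM,
# built once per test file.
.world_cache <- new.env(parent = emptyenv())
study_world <- function() {
  if (!is.null(.world_cache$w)) return(.world_cache$w)
  specs <- default_topic_specs(4)
  vocab <- gen_vocabulary(specs, 500)
  corpus_df <- gen_dataset(specs, 200, vocab, mixing = 0.9, seed = 11)
  corpus <- lapply(corpus_df$text, tokenize, vocab = vocab)
  model <- train_tiny_mlm(corpus, vocab, mlm_config(epochs = 20), seed = 42)
  pool <- gen_dataset(specs, 100, vocab, mixing = 0.9, seed = 12)
  kb <- gen_toy_kb(specs, seed = 13)
  .world_cache$w <- list(specs = specs, vocab = vocab, model = model,
                         pool = pool, kb = kb)
  .world_cache$w
}

# A fast, lower-capacity world for harness-level tests.
.small_cache <- new.env(parent = emptyenv())
small_world <- function() {
  if (!is.null(.small_cache$w)) return(.small_cache$w)
  specs <- default_topic_specs(3, words_per_class = 12)
  vocab <- gen_vocabulary(specs, 120)
  corpus_df <- gen_dataset(specs, 80, vocab, mixing = 0.9, seed = 21)
  corpus <- lapply(corpus_df$text, tokenize, vocab = vocab)
  model <- train_tiny_mlm(corpus, vocab,
                          mlm_config(dim = 16L, hidden = 32L, epochs = 10L),
                          seed = 22)
  pool <- gen_dataset(specs, 40, vocab, mixing = 0.9, seed = 23)
  kb <- gen_toy_kb(specs, seed = 24)
  .small_cache$w <- list(specs = specs, vocab = vocab, model = model,
                         pool = pool, kb = kb)
  .small_cache$w
}
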