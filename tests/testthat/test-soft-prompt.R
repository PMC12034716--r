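sp_small <- function(n_soft = 3L, insert = 1L, hidden = 4L, dropout = 0)
  soft_prompt_config(n_soft = n_soft, insert_index = insert,
                     hidden_size = hidden, dropout = dropout)

test_that("encode_soft_tokens projects to the backbone dimension and is order-sensitive", {
  v <- tiny_vocab(letters[1:6])
  m <- backbone_init(v, dim = 8, seed = 2)
  st <- soft_prompt_init(m, sp_small(n_soft = 1L, insert = 0L), seed = 4)
  h1 <- encode_soft_tokens(st)
  expect_equal(dim(h1), c(1L, 8L))
  st3 <- soft_prompt_init(m, sp_small(), seed = 4)
  h <- encode_soft_tokens(st3)
  expect_equal(dim(h), c(3L, 8L))
  expect_identical(h, encode_soft_tokens(st3))  # eval mode: no dropout
  # a BiLSTM is order-sensitive: reversing the raw tokens changes outputs
  strev <- st3
  strev$params$S <- st3$params$S[3:1, ]
  expect_false(isTRUE(all.equal(encode_soft_tokens(strev), h)))
  expect_error(soft_prompt_config(n_soft = 0L), "empty prompt")
})

test_that("assemble_prompt follows the soft/input/mask layout exactly", {
  v <- tiny_vocab(letters[1:6])
  m <- backbone_init(v, dim = 8, seed = 2)
  cfg <- soft_prompt_config(n_soft = 2L, insert_index = 1L, hidden_size = 4L)
  st <- soft_prompt_init(m, cfg, seed = 1)
  h <- encode_soft_tokens(st)
  x <- embed_sequence(vocab_ids(v, c("a", "b", "c")), m)
  mask_e <- m$params$E[v$mask_id, ]
  a <- assemble_prompt(h, x, mask_e, cfg)
  expect_equal(nrow(a$E), 6L)
  expect_equal(attr(a, "mask_pos"), 6L)
  expect_equal(a$tags, c("soft", "input", "input", "input", "soft", "mask"))
  expect_equal(a$E[1, ], h[1, ])
  expect_equal(a$E[5, ], h[2, ])
  expect_equal(a$E[2:4, ], x$E, ignore_attr = TRUE)
  expect_equal(a$E[6, ], mask_e)
  # boundary: all soft tokens precede the input
  cfg2 <- soft_prompt_config(n_soft = 2L, insert_index = 2L, hidden_size = 4L)
  a2 <- assemble_prompt(h, x, mask_e, cfg2)
  expect_equal(a2$tags, c("soft", "soft", "input", "input", "input", "mask"))
  expect_equal(sum(a2$tags == "mask"), 1L)
  # reading tags back recovers the partition
  pos <- attr(a, "positions")
  expect_equal(which(a$tags == "soft"), pos$soft)
  expect_equal(which(a$tags == "input"), pos$input)
  expect_equal(which(a$tags == "mask"), pos$mask)
  expect_error(assemble_prompt(h[, 1:4], x, mask_e, cfg),
               "incompatible backbone")
})

test_that("layout and mask position hold across the full geometry sweep", {
  v <- tiny_vocab(letters[1:8])
  m <- backbone_init(v, dim = 5, seed = 3)
  mask_e <- m$params$E[v$mask_id, ]
  for (n_soft in 1:6) for (ins in 0:n_soft) for (nx in c(1L, 7L, 20L)) {
    cfg <- soft_prompt_config(n_soft, ins, hidden_size = 3L)
    st <- soft_prompt_init(m, cfg, seed = 1)
    h <- encode_soft_tokens(st)
    ids <- rep(vocab_ids(v, "a"), nx)
    a <- assemble_prompt(h, embed_sequence(ids, m), mask_e, cfg)
    expect_equal(nrow(a$E), n_soft + nx + 1L)
    expect_equal(attr(a, "mask_pos"), n_soft + nx + 1L)
    expect_equal(a$tags,
                 c(rep("soft", ins), rep("input", nx),
                   rep("soft", n_soft - ins), "mask"))
  }
})

test_that("analytic soft-prompt gradients match numerical differentiation", {
  v <- tiny_vocab(letters[1:9])  # |V| = 12
  m <- backbone_init(v, dim = 5, hidden = 4, seed = 6)
  m$frozen <- TRUE
  cfg <- sp_small(n_soft = 3L, insert = 1L, hidden = 4L)
  st <- soft_prompt_init(m, cfg, seed = 7)
  classes <- c("a", "b")
  verb <- singleton_verbalizer(classes)
  cids <- msprompt:::resolve_verbalizer_ids(verb, v)
  ex <- msprompt:::precompute_examples(c("c d e", "f g", "h i c"),
                                       c("a", "b", "a"), m, classes)
  loss_at <- function(state) {
    msprompt:::sp_batch_grad(state, m, ex, cids)$loss
  }
  g <- msprompt:::sp_batch_grad(st, m, ex, cids)$grads
  eps <- 1e-6
  set.seed(99)
  for (nm in names(st$params)) {
    entries <- sample(length(st$params[[nm]]), min(5, length(st$params[[nm]])))
    for (j in entries) {
      up <- st; up$params[[nm]][j] <- up$params[[nm]][j] + eps
      dn <- st; dn$params[[nm]][j] <- dn$params[[nm]][j] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(g[[nm]][j], num, tolerance = 1e-4,
                   label = paste("grad", nm, "entry", j))
    }
  }
})

test_that("soft-prompt training moves only the prompt and is seed-deterministic", {
  w <- small_world()
  ep <- kshot_episodes(w$pool, 10, repetitions = 1, seed = 31)[[1]]
  classes <- sort(unique(w$pool$label))
  verb <- singleton_verbalizer(classes)
  cfg <- soft_prompt_config(hidden_size = 32L)
  tc <- train_config(epochs = 2L, seed = 5)
  before <- backbone_digest(w$model)
  st0 <- soft_prompt_init(w$model, cfg, seed = 5)
  fit <- train_soft_prompt(ep$train, verb, w$model, cfg, tc, state = st0)
  # frozen-backbone conservation
  expect_identical(backbone_digest(w$model), before)
  # gradient flow: the prompt changed
  expect_false(identical(soft_prompt_digest(fit$state),
                         soft_prompt_digest(st0)))
  # determinism: identical seed, identical final state
  fit2 <- train_soft_prompt(ep$train, verb, w$model, cfg, tc, state = st0)
  expect_identical(soft_prompt_digest(fit$state), soft_prompt_digest(fit2$state))
  # zero epochs is a no-op
  tc0 <- train_config(epochs = 0L, seed = 5)
  fit0 <- train_soft_prompt(ep$train, verb, w$model, cfg, tc0, state = st0)
  expect_identical(soft_prompt_digest(fit0$state), soft_prompt_digest(st0))
  # unfrozen backbone and uncovered labels are refused
  m_unfrozen <- w$model; m_unfrozen$frozen <- FALSE
  expect_error(train_soft_prompt(ep$train, verb, m_unfrozen, cfg, tc),
               "frozen")
  bad <- ep$train; bad$label[1] <- "unmapped_class"
  expect_error(train_soft_prompt(bad, verb, w$model, cfg, tc),
               "absent from verbalizer")
})

test_that("training loss decreases on a separable two-class task", {
  specs <- default_topic_specs(2, words_per_class = 10)
  vocab <- gen_vocabulary(specs, 80)
  corpus <- lapply(gen_dataset(specs, 60, vocab, mixing = 1, seed = 41)$text,
                   tokenize, vocab = vocab)
  model <- train_tiny_mlm(corpus, vocab,
                          mlm_config(dim = 16, hidden = 16, epochs = 10),
                          seed = 42)
  pool <- gen_dataset(specs, 30, vocab, mixing = 1, seed = 43)
  ep <- kshot_episodes(pool, 10, repetitions = 1, seed = 44)[[1]]
  verb <- singleton_verbalizer(sort(unique(pool$label)))
  cfg <- soft_prompt_config(hidden_size = 16L)
  fit <- train_soft_prompt(ep$train, verb, model, cfg,
                           train_config(epochs = 8L, seed = 2))
  expect_lt(fit$log$loss[nrow(fit$log)], fit$log$loss[1])
})

test_that("soft-prompt checkpoints refuse a different vocabulary", {
  w <- small_world()
  cfg <- soft_prompt_config(hidden_size = 8L)
  st <- soft_prompt_init(w$model, cfg, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_soft_prompt(st, w$model, path)
  st2 <- load_soft_prompt(path, w$model)
  expect_identical(soft_prompt_digest(st2), soft_prompt_digest(st))
  other <- backbone_init(tiny_vocab(letters[1:4]), dim = w$model$dim)
  expect_error(load_soft_prompt(path, other), "different vocabulary")
})
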