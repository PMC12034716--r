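test_that("knowledge-base TSV round-trips and validates its invariants", {
  kb <- knowledge_base(data.frame(
    entity = c("epilepsy", "epilepsy", "cervical diseases"),
    concept = c("neurology", "seizure", "gynecology"),
    probability = c(0.9, 0.4, 0.8)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kb(kb, path)
  kb2 <- read_kb(path)
  expect_equal(kb2$entries, kb$entries)
  # headerless file also parses
  writeLines("epilepsy\tneurology\t0.9", path)
  expect_equal(nrow(read_kb(path)$entries), 1L)
  expect_error(knowledge_base(data.frame(entity = "a", concept = "b",
                                         probability = 1.2)),
               "probabilities")
  expect_error(knowledge_base(data.frame(entity = c("a", "a"),
                                         concept = c("b", "b"),
                                         probability = c(0.1, 0.2))),
               "duplicate")
})

test_that("entity matching is greedy longest-match without overlap", {
  kb <- knowledge_base(data.frame(
    entity = c("epilepsy", "cervical", "cervical diseases"),
    concept = c("neurology", "gynecology", "gynecology"),
    probability = c(0.9, 0.5, 0.8)))
  expect_equal(match_entities("i have epilepsy today", kb), "epilepsy")
  expect_equal(match_entities("nothing relevant here", kb), character(0))
  expect_equal(match_entities("severe cervical diseases found", kb),
               "cervical diseases")
})

test_that("concept retrieval ranks by probability with truncation", {
  kb <- knowledge_base(data.frame(
    entity = c("e1", "e1"), concept = c("ca", "cb"),
    probability = c(0.9, 0.4)))
  expect_equal(retrieve_concepts("e1", kb)$word, c("ca", "cb"))
  expect_equal(retrieve_concepts("e1", kb, N_v = 1)$word, "ca")
  expect_warning(out <- retrieve_concepts(c("e1", "ghost"), kb), "ghost")
  expect_equal(out$word, c("ca", "cb"))
})

test_that("anchor distance is a cosine distance with an UNK sentinel", {
  v <- tiny_vocab(c("x", "y"))
  E <- matrix(0, length(v), 2)
  E[vocab_ids(v, "x"), ] <- c(1, 0)
  E[vocab_ids(v, "y"), ] <- c(0, 1)
  m <- backbone_stub(v, rep(1 / 5, 5), embedding = E)
  expect_equal(anchor_distance("x", "x", m), 0)
  expect_equal(anchor_distance("x", "y", m), anchor_distance("y", "x", m))
  expect_equal(anchor_distance("x", "y", m), 1)
  expect_equal(anchor_distance("zzz", "x", m), Inf)
})

test_that("anchor selection excludes derivations and matches brute force", {
  v <- tiny_vocab(sprintf("w%02d", 1:20))
  m <- backbone_stub(v, rep(1 / 23, 23), dim = 6, seed = 8)
  cands <- sprintf("w%02d", 1:20)
  sel <- select_by_anchor(c(cands, "w05"), "w05", N_a = 15, model = m)
  expect_false("w05" %in% sel$word)
  expect_equal(nrow(sel), 15L)
  # brute force: full sort by (distance, word) after the same exclusion
  d <- vapply(cands, anchor_distance, numeric(1), anchor = "w05", model = m)
  keep <- !vapply(cands, msprompt:::is_derivation_of, logical(1), y = "w05")
  expected <- cands[keep][order(d[keep], cands[keep])][1:15]
  expect_equal(sel$word, expected)
  expect_error(select_by_anchor("w05", "w05", model = m), "excluded")
})

test_that("mask candidates respect tie-breaks and never include specials", {
  v <- tiny_vocab(c("neurology", "aaa", "zzz"))
  st <- soft_prompt_init(backbone_init(v, dim = 4, seed = 1),
                         soft_prompt_config(n_soft = 1, insert_index = 0,
                                            hidden_size = 2))
  m_unif <- uniform_stub(v)
  h <- encode_soft_tokens(st)
  wrap <- wrap_text("aaa zzz", st, backbone_init(v, dim = 4, seed = 1), h = h)
  # uniform probabilities: lexicographic among equals
  out <- predict_mask_candidates(list(wrap), m_unif, K_cand = 2)
  expect_equal(sort(out$word), c("aaa", "neurology"))
  # peaked stub: argmax only
  peak <- stub_with_probs(v, list(neurology = 0.97))
  expect_equal(predict_mask_candidates(list(wrap), peak, K_cand = 1)$word,
               "neurology")
  all_out <- predict_mask_candidates(list(wrap), m_unif, K_cand = 99)
  expect_false(any(c("[PAD]", "[UNK]", "[MASK]") %in% all_out$word))
})

test_that("context windows have length 2c+1 with padding flagged", {
  ids <- 4:10
  w <- context_window(ids, center = 2L, half_size = 3L)
  expect_length(w$ids, 7L)
  expect_equal(w$center, 4L)
  expect_equal(w$pad, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(w$ids[!w$pad], 4:8)
  expect_error(context_window(ids, center = 99L), "center")
})

test_that("sequence loss averages per-position losses over included positions", {
  v <- tiny_vocab(letters[1:5])
  ids <- vocab_ids(v, c("a", "b", "c"))
  w <- context_window(ids, center = 2L, half_size = 1L)
  # prescribed per-position losses {0.2, 0.4, 0.6} -> mean 0.4
  stub <- loss_stub(v, w$ids, c(0.2, 0.4, 0.6))
  expect_equal(sequence_loss(stub, w), 0.4, tolerance = 1e-9)
  # all-certain stub: zero
  certain <- backbone_stub(v, function(seq, mask_pos) {
    orig <- w$ids[which(is.na(seq$ids))[1L]]
    p <- rep(1e-12, length(v)); p[orig] <- 1; p / sum(p)
  })
  expect_lt(sequence_loss(certain, w), 1e-9)
  # constant loss ell -> ell, and min <= L(W) <= max on random stubs
  stub2 <- loss_stub(v, w$ids, c(0.7, 0.7, 0.7))
  expect_equal(sequence_loss(stub2, w), 0.7, tolerance = 1e-9)
  for (i in 1:10) {
    set.seed(i)
    ls <- stats::runif(3, 0.1, 2)
    got <- sequence_loss(loss_stub(v, w$ids, ls), w)
    expect_gte(got, min(ls) - 1e-9)
    expect_lte(got, max(ls) + 1e-9)
  }
  all_pad <- context_window(ids, center = 2L, half_size = 1L)
  all_pad$pad[] <- TRUE
  expect_error(sequence_loss(stub, all_pad), "degenerate")
})

test_that("batched context scoring equals the per-candidate loop on the real backbone", {
  w <- small_world()
  txt_ids <- tokenize(w$pool$text[1], w$vocab)$ids
  win <- msprompt:::class_context(txt_ids, half_size = 5L)
  cand_ids <- vocab_ids(w$vocab, c("t01001", "t02003", "t03002", "bg001"))
  fast <- msprompt:::sequence_loss_batch(w$model, win, cand_ids)
  slow <- vapply(cand_ids, function(id)
    sequence_loss(w$model, msprompt:::substitute_center(win, id)),
    numeric(1))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("context ranking matches exhaustive brute force and truncates", {
  v <- tiny_vocab(sprintf("w%02d", 1:8))
  ids <- vocab_ids(v, c("w01", "w02", "w03"))
  contexts <- list(msprompt:::class_context(ids, half_size = 2L))
  m <- backbone_init(v, dim = 6, seed = 12)
  cands <- sprintf("w%02d", 1:8)
  got <- rank_by_context(cands, contexts, m, N_a = 5)
  brute <- vapply(cands, function(wd) {
    mean(vapply(contexts, function(cw)
      sequence_loss(m, msprompt:::substitute_center(cw, vocab_ids(v, wd))),
      numeric(1)))
  }, numeric(1))
  expected <- cands[order(brute, cands)][1:5]
  expect_equal(got$word, expected)
  # N_a beyond the candidate count returns all, sorted
  all_got <- rank_by_context(cands, contexts, m, N_a = 99)
  expect_equal(all_got$word, cands[order(brute, cands)])
  expect_error(rank_by_context(cands, list(), m), "insufficient data")
})

test_that("strategy merge unions with provenance and drops cross-class words", {
  mk <- function(words, src) data.frame(word = words, score = seq_along(words),
                                        source = src, stringsAsFactors = FALSE)
  cr <- list(c1 = mk(c("a", "b"), "concepts_retrieval"),
             c2 = mk(c("d"), "concepts_retrieval"))
  ci <- list(c1 = mk(c("b", "c"), "context_information"),
             c2 = mk(c("e"), "context_information"))
  v <- merge_strategies(cr, ci)
  expect_setequal(v$sets$c1$word, c("a", "b", "c"))
  expect_equal(v$sets$c1$source[v$sets$c1$word == "b"],
               "concepts_retrieval+context_information")
  # a word claimed by two classes vanishes from both
  ci2 <- ci; ci2$c2 <- mk(c("e", "a"), "context_information")
  v2 <- merge_strategies(cr, ci2)
  expect_false("a" %in% v2$sets$c1$word)
  expect_false("a" %in% v2$sets$c2$word)
  # ablations: one-sided merges
  expect_setequal(merge_strategies(cr, NULL)$sets$c1$word, c("a", "b"))
  expect_setequal(merge_strategies(NULL, ci)$sets$c1$word, c("b", "c"))
  # class emptied by dedup is an error naming the class
  cr3 <- list(c1 = mk("x", "concepts_retrieval"),
              c2 = mk("x", "concepts_retrieval"))
  expect_error(merge_strategies(cr3, NULL), "c1|c2")
})

test_that("built verbalizers are disjoint across classes and within budget", {
  w <- small_world()
  ep <- kshot_episodes(w$pool, 8, repetitions = 1, seed = 3)[[1]]
  st <- soft_prompt_init(w$model, soft_prompt_config(hidden_size = 16L),
                         seed = 2)
  verb <- build_verbalizer(ep$train, w$kb, w$model, st, strategy = "both",
                           N_a = 10)
  words <- unlist(lapply(verb$sets, `[[`, "word"))
  expect_equal(anyDuplicated(words), 0L)
  for (cl in verb$classes) {
    expect_gt(nrow(verb$sets[[cl]]), 0L)
    expect_lte(nrow(verb$sets[[cl]]), 2L * 10L)
  }
  # JSON round trip preserves the verbalizer
  path <- withr::local_tempfile(fileext = ".json")
  write_verbalizer(verb, path)
  verb2 <- read_verbalizer(path)
  expect_equal(verb2$sets, verb$sets)
  expect_equal(verb2$classes, verb$classes)
})
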