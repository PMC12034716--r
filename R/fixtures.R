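#' Synthetic short-text study conditions
#'
#' The real datasets the method targets (crawled medical inquiries) are
#' not deposited, so the package ships generators that emulate their
#' statistical structure: class-conditional unigram mixtures over short
#' token sequences, a toy entity-concept knowledge base whose retrieval
#' ranking is nontrivial, and the K-shot episode sampler used for
#' evaluation.
#'
#' @name fixtures
NULL

#' Topic specification for one class
#'
#' @param class_name Class label (also the anchor word; it occurs in the
#'   class's texts at a mid-rank weight).
#' @param topic_words Character vector of class topic tokens.
#' @param weights Positive sampling weights, one per topic word
#'   (default Zipf: 1/rank).
#' @param length_range Text length range in tokens (default 5-20, the
#'   short-text regime).
#' @return An `msp_topic_spec`.
#' @export
topic_spec <- function(class_name, topic_words, weights = NULL,
                       length_range = c(5L, 20L)) {
  topic_words <- tolower(as.character(topic_words))
  weights <- weights %||% (1 / seq_along(topic_words))
  if (length(weights) != length(topic_words) || any(weights <= 0))
    stop("weights must be positive, one per topic word")
  if (length_range[1L] < 1L || length_range[2L] < length_range[1L])
    stop("bad length range")
  structure(list(class_name = tolower(class_name),
                 topic_words = topic_words,
                 weights = weights / sum(weights),
                 length_range = as.integer(length_range)),
            class = "msp_topic_spec")
}

#' Default class specifications
#'
#' Four (by default) medical-department-style classes, each with its class
#' name plus synthetic topic tokens unique to the class. The class name is
#' inserted at rank 10 so it co-occurs with its topic words without
#' dominating them.
#'
#' @param n_classes Number of classes (default 4, up to 8).
#' @param words_per_class Topic tokens per class besides the class name
#'   (default 30).
#' @param length_range Text length range (default 5-20 tokens).
#' @return List of `msp_topic_spec`.
#' @export
default_topic_specs <- function(n_classes = 4L, words_per_class = 30L,
                                length_range = c(5L, 20L)) {
  pool <- c("neurology", "cardiology", "gynecology", "dermatology",
            "orthopedics", "respiratory", "oncology", "urology")
  if (n_classes < 2L || n_classes > length(pool))
    stop("n_classes must be in 2..", length(pool))
  lapply(seq_len(n_classes), function(k) {
    words <- sprintf("t%02d%03d", k, seq_len(words_per_class))
    words <- append(words, pool[k], after = min(9L, length(words)))
    topic_spec(pool[k], words, length_range = length_range)
  })
}

#' Vocabulary covering a set of topic specs plus background tokens
#'
#' @param specs List of `msp_topic_spec`.
#' @param vocab_size Total vocabulary size including the three special
#'   tokens (default 500).
#' @return An `msp_vocabulary`.
#' @export
gen_vocabulary <- function(specs, vocab_size = 500L) {
  topic <- unique(unlist(lapply(specs, `[[`, "topic_words")))
  n_bg <- vocab_size - 3L - length(topic)
  if (n_bg < 0L)
    stop("vocab_size too small for the topic words of the specs")
  vocabulary(c(topic, sprintf("bg%03d", seq_len(n_bg))))
}

background_tokens <- function(vocab, specs) {
  topic <- unique(unlist(lapply(specs, `[[`, "topic_words")))
  setdiff(vocab$tokens[-(1:3)], topic)
}

#' Generate a labeled class-conditional dataset
#'
#' Each text draws its length uniformly from the spec's range and each
#' token from the class's topic distribution with probability `mixing`,
#' otherwise uniformly from the shared background vocabulary. `mixing`
#' therefore controls class separability: 1 is purely topical, 0 carries
#' no class signal.
#'
#' @param specs List of `msp_topic_spec` (at least 2 classes).
#' @param n_per_class Texts per class.
#' @param vocab The vocabulary (supplies the background tokens).
#' @param mixing Topic-vs-background mixture weight in `[0, 1]`
#'   (default 0.9).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Data.frame with columns `text`, `label`.
#' @export
gen_dataset <- function(specs, n_per_class, vocab, mixing = 0.9,
                        seed = 1L) {
  if (length(specs) < 2L) stop("need at least 2 classes")
  bg <- background_tokens(vocab, specs)
  if (!length(bg) && mixing < 1)
    stop("config error: vocabulary has no background tokens but mixing < 1")
  set.seed(seed)
  rows <- list()
  for (sp in specs) {
    lens <- sample(seq(sp$length_range[1L], sp$length_range[2L]),
                   n_per_class, replace = TRUE)
    texts <- vapply(lens, function(len) {
      topical <- stats::runif(len) < mixing
      toks <- character(len)
      if (any(topical))
        toks[topical] <- sample(sp$topic_words, sum(topical),
                                replace = TRUE, prob = sp$weights)
      if (any(!topical))
        toks[!topical] <- sample(bg, sum(!topical), replace = TRUE)
      paste(toks, collapse = " ")
    }, character(1))
    rows[[sp$class_name]] <- data.frame(text = texts,
                                        label = sp$class_name,
                                        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a toy knowledge base over the topic specs
#'
#' Entities are the topic words; each entity's concepts are the other
#' words of its class, with membership probabilities decreasing in the
#' class's weight rank, plus a few low-probability distractor edges into
#' other classes so that retrieval ranking is nontrivial. Every class has
#' comfortably more reachable concepts than the default selection budget.
#'
#' @param specs List of `msp_topic_spec`.
#' @param seed Integer seed (controls the distractor edges).
#' @param concepts_per_entity Same-class concepts per entity (default 18).
#' @param distractors Cross-class distractor edges per entity (default 3).
#' @return An `msp_kb`.
#' @export
gen_toy_kb <- function(specs, seed = 1L, concepts_per_entity = 18L,
                       distractors = 3L) {
  if (!length(specs)) stop("no specs")
  set.seed(seed)
  all_words <- lapply(specs, `[[`, "topic_words")
  rows <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    ranked <- sp$topic_words[order(-sp$weights, sp$topic_words)]
    other <- unlist(all_words[-k])
    for (ent in sp$topic_words) {
      concepts <- utils::head(setdiff(ranked, ent), concepts_per_entity)
      probs <- 0.95 * 0.85^(seq_along(concepts) - 1L)
      d <- if (distractors > 0L && length(other))
        sample(other, min(distractors, length(other)))
      else character(0)
      rows[[length(rows) + 1L]] <- data.frame(
        entity = ent,
        concept = c(concepts, d),
        probability = c(probs,
                        stats::runif(length(d), 0.01, 0.08)),
        stringsAsFactors = FALSE)
    }
  }
  knowledge_base(do.call(rbind, rows))
}

#' K-shot episodes with repeated random resampling
#'
#' For each repetition, K texts per class are drawn for training and
#' another disjoint K per class for testing; reported metrics are averaged
#' (mean and standard deviation) across the repetitions.
#'
#' @param dataset Data.frame with `text`, `label` (at least 2K per class).
#' @param K Shots per class.
#' @param repetitions Number of independently sampled episodes (default 3).
#' @param seed Master seed; each repetition derives its own.
#' @return List of `msp_episode` objects with fields `K`, `r`, `seed`,
#'   `train`, `test`, `train_idx`, `test_idx`.
#' @export
kshot_episodes <- function(dataset, K, repetitions = 3L, seed = 1L) {
  idx_by_class <- split(seq_len(nrow(dataset)), dataset$label)
  short <- names(idx_by_class)[vapply(idx_by_class, length, 0L) < 2L * K]
  if (length(short))
    stop("K too large: classes with fewer than 2K texts: ",
         paste(short, collapse = ", "))
  lapply(seq_len(repetitions), function(r) {
    ep_seed <- derive_seed(seed, 100L + r)
    set.seed(ep_seed)
    train_idx <- test_idx <- integer(0)
    for (cl in names(idx_by_class)) {
      pick <- sample(idx_by_class[[cl]], 2L * K)
      train_idx <- c(train_idx, pick[seq_len(K)])
      test_idx <- c(test_idx, pick[K + seq_len(K)])
    }
    structure(list(K = K, r = r, seed = ep_seed,
                   train = dataset[train_idx, , drop = FALSE],
                   test = dataset[test_idx, , drop = FALSE],
                   train_idx = train_idx, test_idx = test_idx),
              class = "msp_episode")
  })
}

#' @export
print.msp_episode <- function(x, ...) {
  cat("<msp_episode> K=", x$K, " rep=", x$r, " seed=", x$seed,
      " (", nrow(x$train), " train / ", nrow(x$test), " test)\n", sep = "")
  invisible(x)
}

#' Read / write datasets as TSV
#'
#' Format: `text<TAB>label` with a header line, UTF-8.
#'
#' @param dataset Data.frame with `text`, `label`.
#' @param path File path.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.table(dataset[, c("text", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}
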