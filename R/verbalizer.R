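#' Automatic verbalizer construction
#'
#' Two complementary strategies expand each class name into a set of label
#' words: Concepts Retrieval ranks knowledge-base concepts of in-text
#' entities by membership probability and then by embedding distance to the
#' class-name anchor; Context Information scores mask-fill candidates by
#' the average masked-token loss of a symmetric context window (a windowed
#' pseudo-log-likelihood) and keeps the low-loss ones. Their union, with
#' cross-class duplicates removed, is the final verbalizer.
#'
#' @name verbalizer
NULL

new_verbalizer <- function(sets, N_a) {
  classes <- sort(names(sets))
  sets <- lapply(sets[classes], function(s) { rownames(s) <- NULL; s })
  for (cl in classes) {
    if (!nrow(sets[[cl]]))
      stop("empty class verbalizer for '", cl, "'")
    if (anyDuplicated(sets[[cl]]$word))
      stop("duplicate label word within class '", cl, "'")
  }
  structure(list(classes = classes, sets = sets, N_a = N_a),
            class = "msp_verbalizer")
}

#' @export
print.msp_verbalizer <- function(x, ...) {
  cat("<msp_verbalizer> ", length(x$classes), " classes, N_a=", x$N_a, "\n",
      sep = "")
  for (cl in x$classes) {
    w <- x$sets[[cl]]$word
    shown <- paste(utils::head(w, 6L), collapse = ", ")
    if (length(w) > 6L) shown <- paste0(shown, ", ...")
    cat("  ", cl, " (", length(w), "): ", shown, "\n", sep = "")
  }
  invisible(x)
}

#' Embedding-space distance to a class-name anchor
#'
#' Cosine distance (1 - cosine similarity) between the embeddings of a
#' candidate word and the class name, in the backbone's input embedding
#' space. Multi-token strings use the mean of their token embeddings;
#' strings that are entirely out of vocabulary get `+Inf` (ranked last).
#'
#' @param word Candidate word (may be multi-token).
#' @param anchor Class name.
#' @param model The backbone.
#' @return Distance in `[0, 2]`, or `Inf`.
#' @export
anchor_distance <- function(word, anchor, model) {
  a <- pooled_embedding(word, model)
  b <- pooled_embedding(anchor, model)
  if (is.null(a) || is.null(b)) return(Inf)
  1 - cosine_similarity(a, b)
}

pooled_embedding <- function(text, model) {
  ids <- vocab_ids(model$vocab, normalize_tokens(text))
  ids <- ids[!ids %in% special_ids(model$vocab)]
  if (!length(ids)) return(NULL)
  colMeans(model$params$E[ids, , drop = FALSE])
}

# Morphological-derivation filter for the anchor: reject a candidate that
# equals the class name, contains it (or is contained in it) after
# normalization, or shares at least half of its character bigrams with it.
is_derivation_of <- function(word, y) {
  nw <- gsub("[^a-z0-9]", "", tolower(word))
  ny <- gsub("[^a-z0-9]", "", tolower(y))
  if (!nzchar(nw) || !nzchar(ny)) return(FALSE)
  if (nw == ny || grepl(ny, nw, fixed = TRUE) || grepl(nw, ny, fixed = TRUE))
    return(TRUE)
  bigrams <- function(s) {
    if (nchar(s) < 2L) return(s)
    unique(substring(s, 1:(nchar(s) - 1L), 2:nchar(s)))
  }
  bw <- bigrams(nw); by <- bigrams(ny)
  length(intersect(bw, by)) / length(union(bw, by)) >= 0.5
}

#' Select label words closest to the class-name anchor
#'
#' Sorts candidates ascending by [anchor_distance()] to the class name,
#' drops morphological derivations of the class name, and keeps the top
#' `N_a`. Ties break by distance then lexicographically.
#'
#' @param candidates Data.frame with a `word` column (e.g. from
#'   [retrieve_concepts()]), or a character vector.
#' @param y Class name (anchor).
#' @param N_a Selection size (default 15).
#' @param model The backbone.
#' @return Data.frame `word`, `score` (the anchor distance), `source`.
#' @export
select_by_anchor <- function(candidates, y, N_a = 15L, model) {
  words <- if (is.data.frame(candidates)) candidates$word else
    as.character(candidates)
  if (!length(words)) stop("no candidates to select for class '", y, "'")
  words <- unique(words)
  keep <- !vapply(words, is_derivation_of, logical(1), y = y)
  words <- words[keep]
  if (!length(words))
    stop("empty class verbalizer: all candidates for '", y,
         "' were excluded as derivations of the class name")
  d <- vapply(words, anchor_distance, numeric(1), anchor = y, model = model)
  ord <- order(d, words)
  sel <- utils::head(ord, N_a)
  data.frame(word = words[sel], score = unname(d[sel]),
             source = "concepts_retrieval", stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Candidate label words from mask-fill predictions
#'
#' For each wrapped training input of a class, takes the `K_cand` most
#' probable vocabulary words at the mask (special tokens excluded; ties
#' break lexicographically) and returns the union across inputs.
#'
#' @param wrapped_inputs List of prompt assemblies (see [wrap_text()]).
#' @param model The backbone.
#' @param K_cand Per-input candidate budget (default 50).
#' @return Data.frame `word`, `score` (best mask-fill probability across
#'   inputs), `source` (`"context_information"`).
#' @export
predict_mask_candidates <- function(wrapped_inputs, model, K_cand = 50L) {
  vocab <- model$vocab
  ok_ids <- setdiff(seq_len(length(vocab)), special_ids(vocab))
  best <- numeric(0)
  for (a in wrapped_inputs) {
    p <- mask_fill_distribution(model, a, attr(a, "mask_pos"))
    p <- p[ok_ids]
    toks <- vocab$tokens[ok_ids]
    ord <- order(-p, toks)
    top <- utils::head(ord, K_cand)
    for (j in top) {
      w <- toks[j]
      if (is.na(best[w]) || p[j] > best[w]) best[w] <- p[j]
    }
  }
  if (!length(best))
    return(data.frame(word = character(0), score = numeric(0),
                      source = character(0), stringsAsFactors = FALSE))
  ord <- order(-best, names(best))
  data.frame(word = names(best)[ord], score = unname(best)[ord],
             source = "context_information", stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Symmetric context window around a center word
#'
#' Extracts `half_size` tokens on each side of `center` (window length
#' `2 * half_size + 1`); positions beyond the text boundaries are padding,
#' flagged and excluded from any loss average. With `center = NULL` the
#' ids are wrapped as-is with no padding.
#'
#' @param ids Integer token ids (`NA` allowed at a candidate slot).
#' @param center Index of the center word within `ids`.
#' @param half_size Window half-size c (default 5).
#' @return An `msp_window` with fields `ids`, `pad`, `center`, `half_size`.
#' @export
context_window <- function(ids, center = NULL, half_size = 5L) {
  ids <- as.integer(ids)
  if (is.null(center)) {
    return(structure(list(ids = ids, pad = rep(FALSE, length(ids)),
                          center = NA_integer_, half_size = NA_integer_),
                     class = "msp_window"))
  }
  if (center < 1L || center > length(ids)) stop("center outside sequence")
  pos <- (center - half_size):(center + half_size)
  pad <- pos < 1L | pos > length(ids)
  out_ids <- rep(NA_integer_, length(pos))
  out_ids[!pad] <- ids[pos[!pad]]
  structure(list(ids = out_ids, pad = pad, center = half_size + 1L,
                 half_size = as.integer(half_size)),
            class = "msp_window")
}

#' @export
print.msp_window <- function(x, ...) {
  cat("<msp_window> length ", length(x$ids), ", center ", x$center,
      ", ", sum(x$pad), " padded\n", sep = "")
  invisible(x)
}

# Context for a class training text: the candidate slot (NA) sits at the
# mask position of the wrapped text, i.e. after the text, so the left
# context is the text tail and the right side is padding.
class_context <- function(text_ids, half_size = 5L) {
  context_window(c(text_ids, NA_integer_), center = length(text_ids) + 1L,
                 half_size = half_size)
}

substitute_center <- function(window, id) {
  window$ids[window$center] <- as.integer(id)
  window
}

#' Windowed pseudo-log-likelihood of a context window
#'
#' Masks each non-padding position of the window in turn, computes the
#' cross-entropy of the true token under the backbone's mask-fill
#' distribution ([masked_token_loss()]), and returns the mean over the
#' included positions. Padding positions are excluded from both the sum
#' and the count.
#'
#' @param model A backbone object.
#' @param window An `msp_window` with no `NA` ids at non-padding positions.
#' @return The mean per-position loss L(W).
#' @export
sequence_loss <- function(model, window) {
  keep <- which(!window$pad)
  if (!length(keep)) stop("degenerate window: all positions padded")
  losses <- vapply(keep, function(i) masked_token_loss(model, window, i),
                   numeric(1))
  mean(losses)
}

# Sequence loss of a window for many alternative center words at once.
# Generic so the reference backbone can batch the vocabulary projections;
# the default method is the plain per-candidate loop.
sequence_loss_batch <- function(model, window, cand_ids) {
  UseMethod("sequence_loss_batch")
}

#' @export
sequence_loss_batch.default <- function(model, window, cand_ids) {
  vapply(cand_ids, function(id)
    sequence_loss(model, substitute_center(window, id)), numeric(1))
}

#' @export
sequence_loss_batch.msp_stub_backbone <- function(model, window, cand_ids) {
  sequence_loss_batch.default(model, window, cand_ids)
}

#' @export
sequence_loss_batch.msp_backbone <- function(model, window, cand_ids) {
  keep <- which(!window$pad)
  if (!length(keep)) stop("degenerate window: all positions padded")
  p <- model$params
  center <- window$center
  others <- setdiff(keep, center)
  E_cand <- p$E[cand_ids, , drop = FALSE]
  m <- length(cand_ids)
  total <- numeric(m)
  # mask the center: the context excludes it, so one distribution serves
  # every candidate and only the scored token differs
  ctx0 <- if (length(others))
    colMeans(p$E[window$ids[others], , drop = FALSE]) else numeric(ncol(p$E))
  u0 <- tanh(as.vector(p$W %*% ctx0) + p$b_h)
  p0 <- softmax(as.vector(p$U %*% u0) + p$b_o)
  total <- -log(p0[cand_ids])
  # mask each other position: the candidate enters the context mean
  for (j in others) {
    rest <- setdiff(keep, c(j, center))
    base <- if (length(rest))
      colSums(p$E[window$ids[rest], , drop = FALSE]) else numeric(ncol(p$E))
    C <- sweep(E_cand, 2L, base, "+") / (length(rest) + 1L)
    A <- tanh(sweep(C %*% t(p$W), 2L, p$b_h, "+"))
    Z <- sweep(A %*% t(p$U), 2L, p$b_o, "+")
    P <- softmax_rows(Z)
    total <- total - log(P[, window$ids[j]])
  }
  as.numeric(total) / length(keep)
}

#' Rank candidate label words by contextual pseudo-log-likelihood
#'
#' Each candidate is substituted at the center slot of every context
#' window of the class; its score is the mean [sequence_loss()] across
#' those windows. Candidates are sorted ascending (low loss = fits the
#' class contexts) and truncated to `N_a`; ties break by score then
#' lexicographically. Candidates without a single-token vocabulary id are
#' dropped.
#'
#' @param candidates Data.frame with a `word` column, or character vector.
#' @param contexts List of `msp_window`s from the class's training texts.
#' @param model A backbone object.
#' @param N_a Selection size (default 15).
#' @return Data.frame `word`, `score` (mean window loss), `source`.
#' @export
rank_by_context <- function(candidates, contexts, model, N_a = 15L) {
  if (!length(contexts))
    stop("insufficient data: no context windows for this class")
  words <- if (is.data.frame(candidates)) candidates$word else
    as.character(candidates)
  words <- unique(words)
  ids <- unname(model$vocab$index[words])
  ok <- !is.na(ids) & !(ids %in% special_ids(model$vocab))
  words <- words[ok]; ids <- ids[ok]
  if (!length(words)) stop("no in-vocabulary candidates to rank")
  S <- vapply(contexts, function(w) sequence_loss_batch(model, w, ids),
              numeric(length(ids)))
  if (is.null(dim(S))) S <- matrix(S, nrow = length(ids))
  score <- rowMeans(S)
  ord <- order(score, words)
  sel <- utils::head(ord, N_a)
  data.frame(word = words[sel], score = unname(score[sel]),
             source = "context_information", stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Merge the two strategies into the final verbalizer
#'
#' Per class, the union of the Concepts Retrieval and Context Information
#' lists (provenance retained; a word picked by both is tagged with both
#' sources). A word claimed by more than one class is removed from all of
#' them — under the equal-weight scoring rule a shared word carries no
#' discriminative signal. Passing `NULL` for either side gives the
#' single-strategy (ablation) verbalizer.
#'
#' @param cr,ci Named lists (class name -> data.frame `word`, `score`,
#'   `source`), or `NULL`.
#' @param N_a The per-strategy budget, recorded on the verbalizer.
#' @return An `msp_verbalizer`.
#' @export
merge_strategies <- function(cr, ci, N_a = 15L) {
  if (is.null(cr) && is.null(ci)) stop("both strategies empty")
  if (!is.null(cr) && !is.null(ci) &&
      !setequal(names(cr), names(ci)))
    stop("strategies keyed by different class sets")
  classes <- names(cr) %||% names(ci)
  sets <- lapply(classes, function(cl) {
    d <- rbind(if (!is.null(cr)) cr[[cl]], if (!is.null(ci)) ci[[cl]])
    agg <- lapply(split(d, d$word), function(g) {
      data.frame(word = g$word[1L], score = min(g$score),
                 source = paste(sort(unique(g$source)), collapse = "+"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    out[order(out$word), , drop = FALSE]
  })
  names(sets) <- classes
  counts <- table(unlist(lapply(sets, function(s) unique(s$word))))
  shared <- names(counts)[counts > 1L]
  sets <- lapply(sets, function(s) s[!s$word %in% shared, , drop = FALSE])
  for (cl in classes)
    if (!nrow(sets[[cl]]))
      stop("cross-class deduplication emptied the verbalizer of class '",
           cl, "'")
  new_verbalizer(sets, N_a)
}

#' Verbalizer with the class name as the sole label word
#'
#' The no-expansion baseline the automatic strategies are compared
#' against.
#'
#' @param classes Character vector of class names.
#' @return An `msp_verbalizer`.
#' @export
singleton_verbalizer <- function(classes) {
  sets <- lapply(classes, function(cl)
    data.frame(word = tolower(cl), score = 0, source = "class_name",
               stringsAsFactors = FALSE))
  names(sets) <- classes
  new_verbalizer(sets, N_a = 1L)
}

#' Build a verbalizer from a K-shot training set
#'
#' Runs the configured strategies per class over the class's training
#' texts and merges them. Concepts Retrieval pools the matched entities of
#' all the class's texts, retrieves concepts from the knowledge base, and
#' keeps the `N_a` closest to the class-name anchor. Context Information
#' takes the top mask-fill candidates of the class's wrapped texts and
#' keeps the `N_a` with the lowest windowed pseudo-log-likelihood.
#'
#' @param train Data.frame with columns `text`, `label`.
#' @param kb An `msp_kb` (required for strategies `"cr"`/`"both"`).
#' @param model The frozen backbone.
#' @param state A soft-prompt state used to wrap texts for the Context
#'   Information strategy (an untrained init is fine).
#' @param strategy `"both"`, `"cr"`, or `"ci"`.
#' @param N_a Per-strategy selection size (default 15).
#' @param N_v Concept-retrieval breadth per entity (default 50).
#' @param K_cand Mask-fill candidate budget per text (default 50).
#' @param half_size Context-window half-size c (default 5).
#' @return An `msp_verbalizer`.
#' @export
build_verbalizer <- function(train, kb = NULL, model, state,
                             strategy = c("both", "cr", "ci"),
                             N_a = 15L, N_v = 50L, K_cand = 50L,
                             half_size = 5L) {
  strategy <- match.arg(strategy)
  classes <- sort(unique(as.character(train$label)))
  by_class <- split(as.character(train$text), as.character(train$label))
  cr <- ci <- NULL
  if (strategy %in% c("both", "cr")) {
    if (is.null(kb)) stop("Concepts Retrieval needs a knowledge base")
    cr <- lapply(classes, function(cl) {
      ents <- unique(unlist(lapply(by_class[[cl]], match_entities, kb = kb)))
      cands <- retrieve_concepts(ents, kb, N_v = N_v)
      if (!nrow(cands))
        stop("no knowledge-base concepts reachable for class '", cl, "'")
      select_by_anchor(cands, cl, N_a = N_a, model = model)
    })
    names(cr) <- classes
  }
  if (strategy %in% c("both", "ci")) {
    h <- encode_soft_tokens(state)
    ci <- lapply(classes, function(cl) {
      texts <- by_class[[cl]]
      wrapped <- lapply(texts, wrap_text, state = state, model = model,
                        h = h)
      cands <- predict_mask_candidates(wrapped, model, K_cand = K_cand)
      contexts <- lapply(texts, function(tx)
        class_context(tokenize(tx, model$vocab)$ids, half_size = half_size))
      rank_by_context(cands, contexts, model, N_a = N_a)
    })
    names(ci) <- classes
  }
  merge_strategies(cr, ci, N_a = N_a)
}

#' Export / import a verbalizer as JSON
#'
#' JSON object mapping each class to its list of
#' `{word, source, score}` records.
#'
#' @param verbalizer An `msp_verbalizer`.
#' @param path File path.
#' @export
write_verbalizer <- function(verbalizer, path) {
  jsonlite::write_json(
    list(N_a = verbalizer$N_a, classes = verbalizer$sets),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_verbalizer
#' @export
read_verbalizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- lapply(x$classes, function(d)
    data.frame(word = d$word, score = as.numeric(d$score),
               source = d$source, stringsAsFactors = FALSE))
  new_verbalizer(sets, N_a = x$N_a)
}
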