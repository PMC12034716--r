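#' Knowledge base of entity-concept membership probabilities
#'
#' A Probase-style table: each row says that `entity` belongs to `concept`
#' with the given membership probability. Surface forms are lowercased;
#' multi-word entities are space-separated token sequences.
#'
#' @param entries A data.frame with columns `entity`, `concept`,
#'   `probability`.
#' @return An `msp_kb`.
#' @export
knowledge_base <- function(entries) {
  entries <- data.frame(
    entity = tolower(trimws(as.character(entries$entity))),
    concept = tolower(trimws(as.character(entries$concept))),
    probability = as.numeric(entries$probability),
    stringsAsFactors = FALSE
  )
  if (any(entries$probability <= 0 | entries$probability > 1))
    stop("knowledge-base probabilities must lie in (0, 1]")
  if (anyDuplicated(entries[, c("entity", "concept")]))
    stop("duplicate (entity, concept) pair in knowledge base")
  structure(list(entries = entries), class = "msp_kb")
}

#' @export
print.msp_kb <- function(x, ...) {
  cat("<msp_kb> ", nrow(x$entries), " edges, ",
      length(unique(x$entries$entity)), " entities, ",
      length(unique(x$entries$concept)), " concepts\n", sep = "")
  invisible(x)
}

#' Read / write a knowledge base as 3-column TSV
#'
#' Format: `entity<TAB>concept<TAB>probability`, UTF-8; a header line is
#' detected and skipped if its third field is not numeric.
#'
#' @param path File path.
#' @return An `msp_kb`.
#' @export
read_kb <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          quote = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  names(df)[1:3] <- c("entity", "concept", "probability")
  knowledge_base(df)
}

#' @rdname read_kb
#' @param kb An `msp_kb`.
#' @export
write_kb <- function(kb, path) {
  utils::write.table(kb$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Match knowledge-base entities in a text
#'
#' Greedy longest-match scan of the text's token n-grams against the
#' knowledge base's entity surface forms, left to right, without
#' overlapping matches.
#'
#' @param text Input string.
#' @param kb An `msp_kb`.
#' @return Character vector of matched entity surface forms (possibly
#'   empty, in text order, duplicates kept).
#' @export
match_entities <- function(text, kb) {
  toks <- normalize_tokens(text)
  forms <- unique(kb$entries$entity)
  max_len <- max(lengths(strsplit(forms, " ", fixed = TRUE)))
  found <- character(0)
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    hit <- NULL
    for (L in seq(min(max_len, n - i + 1L), 1L)) {
      cand <- paste(toks[i:(i + L - 1L)], collapse = " ")
      if (cand %in% forms) { hit <- cand; break }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      found <- c(found, hit)
      i <- i + length(strsplit(hit, " ", fixed = TRUE)[[1L]])
    }
  }
  found
}

#' Retrieve ranked concepts for matched entities
#'
#' Per entity, concepts are sorted by membership probability (descending,
#' ties broken lexicographically) and truncated at `N_v`; the per-entity
#' lists are merged keeping each concept's maximum probability.
#'
#' @param entities Character vector of entity surface forms.
#' @param kb An `msp_kb`.
#' @param N_v Retrieval breadth per entity (default 50).
#' @return A data.frame `word`, `score` (probability), `source`
#'   (`"concepts_retrieval"`), sorted by score descending.
#' @export
retrieve_concepts <- function(entities, kb, N_v = 50L) {
  entities <- unique(tolower(entities))
  absent <- setdiff(entities, kb$entries$entity)
  if (length(absent))
    warning("entities absent from knowledge base skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  rows <- kb$entries[kb$entries$entity %in% entities, , drop = FALSE]
  if (!nrow(rows))
    return(data.frame(word = character(0), score = numeric(0),
                      source = character(0), stringsAsFactors = FALSE))
  per <- lapply(split(rows, rows$entity), function(d) {
    d <- d[order(-d$probability, d$concept), , drop = FALSE]
    utils::head(d, N_v)
  })
  merged <- do.call(rbind, per)
  best <- stats::aggregate(probability ~ concept, data = merged, FUN = max)
  best <- best[order(-best$probability, best$concept), , drop = FALSE]
  data.frame(word = best$concept, score = best$probability,
             source = "concepts_retrieval", stringsAsFactors = FALSE,
             row.names = NULL)
}
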