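#' Configuration for a K-shot experiment run
#'
#' Bundles the data, the frozen backbone, the strategy grid and every
#' module configuration, plus the master seed every stage derives its
#' randomness from. The resolved configuration and content hashes of the
#' inputs are embedded in the results for provenance.
#'
#' @param dataset Data.frame `text`, `label` (the pool episodes sample
#'   from).
#' @param kb An `msp_kb` (needed for strategies `"cr"`/`"both"`).
#' @param model A frozen `msp_backbone`.
#' @param K Integer vector of shots per class (default `c(10, 15, 20)`).
#' @param strategies Subset of `c("cr", "ci", "both", "singleton")`;
#'   `"singleton"` is the class-name-only baseline verbalizer.
#' @param repetitions Episodes per K (default 3).
#' @param sp_config,t_config Soft-prompt and optimizer configurations.
#' @param N_a,N_v,K_cand,half_size Verbalizer construction knobs.
#' @param seed Master seed.
#' @return An `msp_run_config`.
#' @export
run_config <- function(dataset, kb = NULL, model,
                       K = c(10L, 15L, 20L),
                       strategies = c("cr", "ci", "both"),
                       repetitions = 3L,
                       sp_config = soft_prompt_config(),
                       t_config = train_config(),
                       N_a = 15L, N_v = 50L, K_cand = 50L,
                       half_size = 5L, seed = 1L) {
  bad <- setdiff(strategies, c("cr", "ci", "both", "singleton"))
  if (length(bad)) stop("unknown strategies: ", paste(bad, collapse = ", "))
  if (any(c("cr", "both") %in% strategies) && is.null(kb))
    stop("strategies cr/both need a knowledge base")
  if (!isTRUE(model$frozen)) stop("backbone must be frozen")
  structure(list(dataset = dataset, kb = kb, model = model,
                 K = as.integer(K), strategies = strategies,
                 repetitions = as.integer(repetitions),
                 sp_config = sp_config, t_config = t_config,
                 N_a = N_a, N_v = N_v, K_cand = K_cand,
                 half_size = half_size, seed = as.integer(seed)),
            class = "msp_run_config")
}

#' Run the K-shot evaluation grid
#'
#' For every K in the grid: sample the episodes, and on each episode build
#' the verbalizer for every strategy, train the soft prompt (same
#' episode, same prompt init across strategies, so the strategy rows are
#' comparable), classify the episode test set and record the accuracy.
#' Fully deterministic given the master seed.
#'
#' @param config An [run_config()].
#' @return An `msp_results`: `rows` (per K/strategy/repetition accuracy),
#'   `summary` (mean, sd and `mean±sd` formatting per K and strategy),
#'   `provenance` (resolved configuration and input hashes).
#' @export
run_kshot <- function(config) {
  stopifnot(inherits(config, "msp_run_config"))
  rows <- list()
  for (K in config$K) {
    episodes <- kshot_episodes(config$dataset, K,
                               repetitions = config$repetitions,
                               seed = derive_seed(config$seed, K))
    for (ep in episodes) {
      run_seed <- derive_seed(config$seed, 1000L + 13L * K + ep$r)
      state0 <- soft_prompt_init(config$model, config$sp_config,
                                 seed = run_seed)
      tc <- config$t_config
      tc$seed <- run_seed
      for (strat in config$strategies) {
        res <- tryCatch(
          run_one(ep, strat, state0, tc, config),
          error = function(e)
            stop("stage failure [strategy=", strat, ", K=", K,
                 ", episode=", ep$r, "]: ", conditionMessage(e),
                 call. = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          K = K, strategy = strat, rep = ep$r, accuracy = res,
          stringsAsFactors = FALSE)
      }
    }
  }
  rows <- do.call(rbind, rows)
  structure(list(rows = rows, summary = summarize_rows(rows),
                 provenance = provenance_of(config)),
            class = "msp_results")
}

run_one <- function(ep, strat, state0, t_config, config) {
  classes <- sort(unique(config$dataset$label))
  verb <- if (strat == "singleton") singleton_verbalizer(classes)
  else build_verbalizer(ep$train, kb = config$kb, model = config$model,
                        state = state0, strategy = strat,
                        N_a = config$N_a, N_v = config$N_v,
                        K_cand = config$K_cand,
                        half_size = config$half_size)
  fit <- train_soft_prompt(ep$train, verb, config$model,
                           sp_config = config$sp_config,
                           t_config = t_config, state = state0)
  preds <- classify_batch(ep$test$text, fit$state, verb, config$model)
  evaluate(preds, ep$test$label, classes = classes,
           meta = list(K = ep$K, rep = ep$r, seed = ep$seed,
                       strategy = strat))$accuracy
}

summarize_rows <- function(rows) {
  if (!nrow(rows))
    return(data.frame(K = integer(0), strategy = character(0),
                      mean = numeric(0), sd = numeric(0),
                      formatted = character(0)))
  agg <- stats::aggregate(accuracy ~ K + strategy, data = rows,
                          FUN = function(a)
                            c(mean = mean(a),
                              sd = if (length(a) > 1L) stats::sd(a) else 0))
  out <- data.frame(K = agg$K, strategy = agg$strategy,
                    mean = agg$accuracy[, "mean"],
                    sd = agg$accuracy[, "sd"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$K, out$strategy), , drop = FALSE]
  out$formatted <- format_mean_sd(out$mean, out$sd)
  rownames(out) <- NULL
  out
}

provenance_of <- function(config) {
  list(seed = config$seed, K = config$K, strategies = config$strategies,
       repetitions = config$repetitions,
       N_a = config$N_a, N_v = config$N_v, K_cand = config$K_cand,
       half_size = config$half_size,
       sp_config = unclass(config$sp_config),
       t_config = unclass(config$t_config),
       dataset_hash = rlang::hash(config$dataset),
       kb_hash = if (!is.null(config$kb)) rlang::hash(config$kb$entries),
       model_digest = backbone_digest(config$model))
}

#' Accuracy formatting as `mean±std` percentages
#'
#' @param mean,sd Accuracies as fractions.
#' @return Character, e.g. `0.8693, 0.0063` becomes `"86.93±0.63"`.
#' @export
format_mean_sd <- function(mean, sd) {
  sprintf("%.2f±%.2f", 100 * mean, 100 * sd)
}

#' @export
print.msp_results <- function(x, ...) {
  cat(report(x), sep = "\n")
  invisible(x)
}

#' Human-readable results table
#'
#' @param results An `msp_results` (or a list with a compatible `summary`
#'   data.frame, e.g. read back from JSON).
#' @return Character vector of table lines (also printed).
#' @export
report <- function(results) {
  s <- results$summary
  if (!nrow(s)) {
    lines <- "accuracy (%) mean±std: (no results)"
  } else {
    lines <- c("accuracy (%) mean±std",
               sprintf("  K=%-3d %-10s %s", s$K, s$strategy, s$formatted))
  }
  lines
}

#' Write / read results as JSON
#'
#' The JSON embeds the per-episode rows, the summary table and the full
#' provenance block; reading it back reproduces the identical report.
#'
#' @param results An `msp_results`.
#' @param path File path.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(
    list(rows = results$rows, summary = results$summary,
         provenance = results$provenance),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns",
    null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(rows = as.data.frame(x$rows),
                 summary = as.data.frame(x$summary),
                 provenance = x$provenance),
            class = "msp_results")
}
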