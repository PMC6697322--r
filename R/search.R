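#' Options controlling a model-space search
#'
#' @param ic_type information criterion used for all model comparisons.
#' @param n_data number of data points entering the likelihood; required for
#'   AICc/BIC when the cost function returns -2 log-likelihood values.
#' @param start starting model: `"global"` (all selectable parameters
#'   included), `"random"` (a uniformly sampled admissible model), or an
#'   explicit model in any form accepted by [model_id()].
#' @param initial_method first neighbourhood move, `"forward"` or
#'   `"backward"` (or `"swap"` if swap/critical sets exist).
#' @param use_swap whether the swap move may be used at all (it also requires
#'   swap or critical sets in the space).
#' @param reuse_history if `TRUE` (default), models fitted in earlier
#'   iterations are not refitted; their stored records still compete whenever
#'   they are re-proposed.
#' @param refit force refitting of re-proposed models (with inheritance); the
#'   better of the old and new fit is kept.
#' @param auto_repair if the user-supplied starting model violates critical
#'   sets, add the lowest-index member of each violated set instead of
#'   erroring.
#' @param max_iterations safety cap on search iterations.
#' @param fit_options a [fit_options()] object (default `NULL`: package
#'   defaults; its seed falls back to `seed`).
#' @param cost_returns `"minus2LL"` or `"ic"`, see [fit_submodel()].
#' @param seed master seed for the run (starting-model sampling and all fits).
#' @param verbose print a per-iteration progress line (method, proposed,
#'   fitted, best criterion value).
#' @return list of class `search_options`.
#' @export
search_options <- function(ic_type = c("AICc", "AIC", "BIC"), n_data = NULL,
                           start = "global",
                           initial_method = c("forward", "backward", "swap"),
                           use_swap = TRUE, reuse_history = TRUE,
                           refit = FALSE, auto_repair = FALSE,
                           max_iterations = 100L,
                           fit_options = NULL,
                           cost_returns = c("minus2LL", "ic"),
                           seed = NULL, verbose = FALSE) {
  if (is.null(fit_options)) fit_options <- .default_fit_options()
  structure(list(ic_type = match.arg(ic_type), n_data = n_data,
                 start = start,
                 initial_method = match.arg(initial_method),
                 use_swap = isTRUE(use_swap),
                 reuse_history = isTRUE(reuse_history),
                 refit = isTRUE(refit), auto_repair = isTRUE(auto_repair),
                 max_iterations = as.integer(max_iterations),
                 fit_options = fit_options,
                 cost_returns = match.arg(cost_returns),
                 seed = seed, verbose = isTRUE(verbose)),
            class = "search_options")
}

#' Method schedule of the adaptive search
#'
#' Decides which move generates the next neighbourhood. A successful forward
#' or backward move keeps its method; a successful swap switches to forward.
#' A failed forward switches to backward and vice versa, unless both
#' directions have now failed consecutively, in which case the swap move is
#' tried if available, else the search terminates. A failed swap always
#' terminates.
#'
#' @param current the method that generated the last neighbourhood
#'   (`"forward"`, `"backward"` or `"swap"`).
#' @param improved did the last iteration accept a better model?
#' @param last_two_failed have forward and backward both failed consecutively
#'   (no acceptance in between)?
#' @param swap_available are swap or critical sets defined (and swap use
#'   enabled)?
#' @return `"forward"`, `"backward"`, `"swap"`, or `"terminate"`.
#' @export
next_method <- function(current, improved, last_two_failed, swap_available) {
  stopifnot(current %in% c("forward", "backward", "swap"))
  if (improved) {
    return(if (current == "swap") "forward" else current)
  }
  if (current == "swap") return("terminate")
  if (last_two_failed) {
    return(if (swap_available) "swap" else "terminate")
  }
  if (current == "forward") "backward" else "forward"
}

sample_valid_model <- function(space) {
  free <- which(!fixed_mask(space))
  for (i in 1:1000) {
    alpha <- stats::setNames(integer(length(space$parameters)),
                             space$parameters)
    alpha[free] <- as.integer(stats::runif(length(free)) < 0.5)
    for (s in space$critical_sets) {
      if (!any(alpha[s] == 1L)) {
        alpha[s[sample.int(length(s), 1L)]] <- 1L
      }
    }
    if (sum(alpha) == 0L) alpha[free[sample.int(length(free), 1L)]] <- 1L
    if (is_valid_model(alpha, space)) return(alpha)
  }
  stop("could not sample an admissible model (contradictory critical sets?)")
}

resolve_start <- function(space, options) {
  start <- options$start
  if (is.character(start) && length(start) == 1L &&
      start %in% c("global", "random")) {
    if (start == "global") {
      alpha <- stats::setNames(as.integer(!fixed_mask(space)),
                               space$parameters)
      return(alpha)
    }
    return(with_stream(options$seed %||% 0L, "start-model",
                       function() sample_valid_model(space)))
  }
  alpha <- model_id(start, space)
  if (!is_valid_model(alpha, space)) {
    if (!options$auto_repair) {
      stop("starting model ", model_string(alpha), " is not admissible ",
           "(use auto_repair = TRUE to add one parameter per violated ",
           "critical set)")
    }
    for (s in space$critical_sets) {
      if (!any(alpha[s] == 1L)) alpha[s[1]] <- 1L
    }
    if (sum(alpha) == 0L) {
      alpha[which(!fixed_mask(space))[1]] <- 1L
    }
  }
  alpha
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.default_fit_options <- function() fit_options()

# prefer lower ic, then fewer parameters, then canonical string order
better_record <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$ic_value != b$ic_value) return(a$ic_value < b$ic_value)
  if (a$k != b$k) return(a$k < b$k)
  a$model < b$model
}

#' Adaptive forward/backward/swap search of a model space
#'
#' Runs the full selection loop: starting from an admissible model, the
#' current best model's neighbourhood (under the current move) is generated,
#' every previously unseen candidate is fitted to the data, and the best
#' candidate replaces the current best model if its information criterion is
#' strictly lower. The move schedule follows [next_method()]; the search
#' terminates when no move can improve the current best model. All fitted
#' models are memoized in a history, and per-parameter Akaike weights over
#' that history are reported alongside the selected model.
#'
#' Candidate fits draw from per-model random-number streams derived from the
#' master seed, so the result does not depend on the order in which
#' candidates are evaluated.
#'
#' @param space a [parameter_space()].
#' @param cost_fn cost function over a full named parameter vector, see
#'   [fit_submodel()].
#' @param options a [search_options()] object.
#' @param history optional pre-existing history (named list of fit records)
#'   whose fits are reused; used by [run_campaign()].
#' @param ... passed on to `cost_fn`.
#' @return object of class `search_result`: list with `best` (fit record),
#'   `history` (named list of every fit record, keyed by model string),
#'   `iterations` (data frame trace: method, proposed, fitted, accepted,
#'   best ic), `weights` (from [akaike_weights()]), `start` (starting model
#'   string) and `options`.
#' @examples
#' sp <- parameter_space(c("a", "b", "c"), bounds = c(-5, 5))
#' truth <- c(a = 2, b = -1, c = 0)
#' cost <- function(p) sum((p - truth)^2) * 50
#' res <- model_search(sp, cost, search_options(ic_type = "AIC", seed = 1))
#' res$best$model
#' @export
model_search <- function(space, cost_fn, options = search_options(),
                         history = NULL, ...) {
  stopifnot(inherits(space, "parameter_space"))
  fo <- options$fit_options
  if (is.null(fo$seed)) fo$seed <- options$seed
  if (options$cost_returns == "minus2LL" && options$ic_type != "AIC" &&
      is.null(options$n_data)) {
    stop("'n_data' is required in search_options() for ", options$ic_type)
  }
  swap_available <- options$use_swap &&
    (length(space$swap_sets) + length(space$critical_sets)) > 0
  method <- options$initial_method
  if (method == "swap" && !swap_available) {
    stop("initial_method 'swap' requires swap or critical sets")
  }

  hist_env <- new.env(parent = emptyenv())
  for (key in names(history)) hist_env[[key]] <- history[[key]]

  fit_one <- function(alpha, inherited) {
    fit_submodel(alpha, cost_fn, space, fo, inherited_start = inherited,
                 ic_type = options$ic_type, n_data = options$n_data,
                 cost_returns = options$cost_returns, ...)
  }

  start_alpha <- resolve_start(space, options)
  start_key <- model_string(start_alpha)
  n_new_fits <- 0L
  if (is.null(hist_env[[start_key]])) {
    hist_env[[start_key]] <- fit_one(start_alpha, NULL)
    n_new_fits <- n_new_fits + 1L
  }
  best <- hist_env[[start_key]]
  if (best$failed) {
    stop("cost function returned no finite value for the starting model ",
         start_key)
  }

  log_rows <- list()
  failed_dirs <- character(0)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > options$max_iterations) break
    cands <- neighbor_models(best$alpha, space, method)
    fitted_now <- 0L
    challenger <- NULL
    for (cand in cands) {
      key <- model_string(cand)
      rec <- hist_env[[key]]
      if (is.null(rec)) {
        rec <- fit_one(cand, best$estimates)
        hist_env[[key]] <- rec
        fitted_now <- fitted_now + 1L
        n_new_fits <- n_new_fits + 1L
      } else if (options$refit) {
        rec2 <- fit_one(cand, best$estimates)
        fitted_now <- fitted_now + 1L
        if (better_record(rec2, rec)) {
          hist_env[[key]] <- rec2
          rec <- rec2
        }
      }
      if (!rec$failed && is.finite(rec$ic_value) &&
          better_record(rec, challenger)) {
        challenger <- rec
      }
    }
    improved <- !is.null(challenger) && challenger$ic_value < best$ic_value
    accepted <- NA_character_
    if (improved) {
      best <- challenger
      accepted <- best$model
      failed_dirs <- character(0)
    } else if (method %in% c("forward", "backward")) {
      failed_dirs <- union(failed_dirs, method)
    }
    last_two_failed <- all(c("forward", "backward") %in% failed_dirs)
    log_rows[[it]] <- data.frame(
      iteration = it, method = method, proposed = length(cands),
      fitted = fitted_now, accepted = accepted, best_ic = best$ic_value,
      stringsAsFactors = FALSE)
    if (options$verbose) {
      message(sprintf("iter %3d  %-8s proposed %3d  fitted %3d  best %s = %s%s",
                      it, method, length(cands), fitted_now, options$ic_type,
                      format(best$ic_value, digits = 8),
                      if (improved) paste0("  -> ", best$model) else ""))
    }
    nm <- next_method(method, improved, last_two_failed, swap_available)
    if (nm == "terminate") break
    method <- nm
  }

  history_out <- as.list(hist_env)
  history_out <- history_out[order(names(history_out))]
  weights <- akaike_weights(history_out)
  res <- list(best = best, history = history_out,
              iterations = do.call(rbind, log_rows),
              weights = weights, start = start_key,
              n_models = length(history_out), n_new_fits = n_new_fits,
              options = options)
  class(res) <- "search_result"
  res
}

#' @export
print.search_result <- function(x, ...) {
  cat("Model-space search result\n")
  cat("  start:  ", x$start, "\n")
  cat("  best:   ", x$best$model, "  (", x$best$ic_type, " = ",
      format(x$best$ic_value, digits = 8), ", k = ", x$best$k, ")\n",
      sep = "")
  inc <- names(x$best$alpha)[x$best$alpha == 1L]
  cat("  included:", paste(inc, collapse = ", "), "\n")
  cat("  iterations:", nrow(x$iterations),
      " models in history:", x$n_models, "\n")
  invisible(x)
}

#' Multi-run search campaign restarting from most distant models
#'
#' Runs `n_runs` sequential searches; each run after the first starts from
#' the admissible model most distant (in Hamming distance) from every model
#' tested in earlier runs, so that later runs probe unexplored regions of the
#' model space. Histories are pooled (best fit kept per model) and the
#' overall best model plus pooled per-parameter Akaike weights are reported.
#' Per-run failures are collected, not fatal.
#'
#' @inheritParams model_search
#' @param n_runs number of sequential runs (>= 1).
#' @param share_history if `TRUE`, later runs also reuse the fits of earlier
#'   runs instead of refitting them (the pooled history is identical either
#'   way up to refits). Defaults to `FALSE`: runs are independent as in a
#'   repeat-with-new-start protocol.
#' @return object of class `search_campaign`: list with `best`, pooled
#'   `history`, `weights`, `runs` (per-run search results or error
#'   conditions) and `starts`.
#' @export
run_campaign <- function(space, cost_fn, options = search_options(),
                         n_runs = 5L, share_history = FALSE, ...) {
  stopifnot(n_runs >= 1)
  runs <- vector("list", n_runs)
  starts <- character(n_runs)
  pooled <- list()
  master_seed <- options$seed %||% 0L
  for (k in seq_len(n_runs)) {
    opt_k <- options
    opt_k$seed <- model_stream_seed(master_seed, paste0("campaign-run-", k))
    if (k > 1L && length(pooled) > 0L) {
      # restart in the least explored region of the model space
      opt_k$start <- most_distant_model(names(pooled), space)
    }
    res <- tryCatch(
      model_search(space, cost_fn, opt_k,
                   history = if (share_history) pooled else NULL, ...),
      error = function(e) e)
    runs[[k]] <- res
    if (inherits(res, "error")) {
      warning("campaign run ", k, " failed: ", conditionMessage(res))
      next
    }
    starts[k] <- res$start
    for (key in names(res$history)) {
      old <- pooled[[key]]
      if (is.null(old) || better_record(res$history[[key]], old)) {
        pooled[[key]] <- res$history[[key]]
      }
    }
  }
  if (length(pooled) == 0L) stop("every campaign run failed")
  pooled <- pooled[order(names(pooled))]
  ics <- vapply(pooled, function(r) r$ic_value, 0)
  best <- pooled[[which.min(ics)]]
  out <- list(best = best, history = pooled,
              weights = akaike_weights(pooled),
              runs = runs, starts = starts, n_models = length(pooled))
  class(out) <- "search_campaign"
  out
}

#' @export
print.search_campaign <- function(x, ...) {
  ok <- sum(!vapply(x$runs, inherits, TRUE, what = "error"))
  cat("Search campaign:", length(x$runs), "run(s),", ok, "successful\n")
  cat("  pooled history:", x$n_models, "models\n")
  cat("  best: ", x$best$model, "  (", x$best$ic_type, " = ",
      format(x$best$ic_value, digits = 8), ", k = ", x$best$k, ")\n",
      sep = "")
  invisible(x)
}
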