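#' Options for the restart-capped multistart fitting scheme
#'
#' Each sub-model is fitted by `optim_runs` independent chains. A chain is a
#' sequence of local-search legs, each capped at `iteration_cap` iterations of
#' the local optimizer (halting and restarting a Nelder-Mead run re-inflates
#' its simplex and so covers a broader region of parameter space); the chain
#' stops once the decrease of the cost between consecutive legs falls below
#' `convergence_tol`, or after `max_legs` legs. Chain 1 may start from
#' inherited estimates of the current best model; all other chains start from
#' values sampled uniformly within the parameter bounds.
#'
#' @param optim_runs number of independent multistart chains (>= 1).
#' @param iteration_cap local-optimizer iterations per leg.
#' @param convergence_tol stop a chain when the between-leg decrease of the
#'   cost (-2 log-likelihood scale) falls below this value.
#' @param max_legs safety cap on legs per chain.
#' @param method local-search method passed to [stats::optim()]
#'   (single-parameter models always use bounded Brent search).
#' @param sampling distribution of random starting values within the bounds:
#'   `"uniform"`, or `"log-uniform"` (uniform on the log scale, appropriate
#'   for rate parameters spanning orders of magnitude; the lower end of the
#'   sampled range is floored at `1e-4` times the upper bound).
#' @param seed master seed; each (seed, model) pair gets its own reproducible
#'   random-number stream, so evaluation order cannot change any result.
#' @return list of class `fit_options`.
#' @export
fit_options <- function(optim_runs = 1L, iteration_cap = 1000L,
                        convergence_tol = 1e-3, max_legs = 100L,
                        method = "Nelder-Mead",
                        sampling = c("uniform", "log-uniform"),
                        seed = NULL) {
  stopifnot(optim_runs >= 1, iteration_cap >= 1, convergence_tol > 0,
            max_legs >= 1)
  structure(list(optim_runs = as.integer(optim_runs),
                 iteration_cap = as.integer(iteration_cap),
                 convergence_tol = convergence_tol,
                 max_legs = as.integer(max_legs),
                 method = method, sampling = match.arg(sampling),
                 seed = seed),
            class = "fit_options")
}

# Deterministic 31-bit stream seed for a (master seed, model string) pair.
model_stream_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate fn with a private RNG stream, restoring the caller's stream after.
with_stream <- function(seed, key, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(model_stream_seed(seed, key))
  fn()
}

#' Fit one sub-model to data
#'
#' Minimizes a user cost function over the included parameters of one model,
#' using the multistart restart-capped scheme described in [fit_options()].
#' The cost function is always evaluated on the output of
#' [resolve_parameters()], so excluded parameters carry their resolved default
#' values. Box bounds are enforced by evaluating the cost at the clamped
#' parameter vector plus a quadratic penalty on the excursion; returned
#' estimates are clamped to the box.
#'
#' @param alpha model inclusion vector (any form accepted by [model_id()]).
#' @param cost_fn function of a full named parameter vector returning the cost
#'   on the -2 log-likelihood scale (or directly an information-criterion
#'   value when `cost_returns = "ic"`). Extra arguments in `...` are passed
#'   through.
#' @param space a [parameter_space()].
#' @param options a [fit_options()] object.
#' @param inherited_start optional named numeric vector of parameter estimates
#'   inherited from a previously fitted model; values for included parameters
#'   shared with that model seed chain 1, newly added parameters are sampled.
#' @param ic_type,n_data information criterion and number of data points used
#'   to score the fit (`n_data` may be `NULL` for plain AIC).
#' @param cost_returns `"minus2LL"` (default; the criterion is computed by the
#'   package) or `"ic"` (the cost function returns the criterion itself).
#' @param ... passed on to `cost_fn`.
#' @return object of class `fit_record`: list with the model string, `alpha`,
#'   free-parameter `estimates`, resolved full `parameters`, `minus2LL`, `k`,
#'   `n`, `ic_type`, `ic_value`, and fit diagnostics (`converged`, `runs`,
#'   `legs`, `fevals`, `failed`).
#' @examples
#' sp <- parameter_space(c("a", "b"), bounds = c(-5, 5))
#' cost <- function(p) (p[["a"]] - 2)^2 + (p[["b"]] + 1)^2
#' fit <- fit_submodel("11", cost, sp, fit_options(seed = 1), ic_type = "AIC")
#' round(fit$estimates, 3)
#' @export
fit_submodel <- function(alpha, cost_fn, space, options = fit_options(),
                         inherited_start = NULL,
                         ic_type = c("AICc", "AIC", "BIC"),
                         n_data = NULL,
                         cost_returns = c("minus2LL", "ic"), ...) {
  ic_type <- match.arg(ic_type)
  cost_returns <- match.arg(cost_returns)
  alpha <- model_id(alpha, space)
  key <- model_string(alpha)
  free <- space$parameters[alpha == 1L]
  k <- length(free)
  lower <- stats::setNames(space$bounds["lower", free], free)
  upper <- stats::setNames(space$bounds["upper", free], free)

  big <- 1e300
  n_eval <- 0L
  resolver <- make_resolver(alpha, space)
  objective <- function(p) {
    n_eval <<- n_eval + 1L
    pc <- pmin(pmax(p, lower), upper)
    names(pc) <- free
    v <- tryCatch(cost_fn(resolver(pc), ...), error = function(e) NA_real_)
    if (!is.finite(v)) return(big)
    v + 1e6 * sum((p - pc)^2)
  }

  sample_start <- function() {
    if (identical(options$sampling, "log-uniform")) {
      lo <- pmax(lower, upper * 1e-4)
      s <- exp(stats::runif(k, log(lo), log(upper)))
    } else {
      s <- stats::runif(k, lower, upper)
    }
    stats::setNames(s, free)
  }

  run_chains <- function() {
    best <- NULL
    for (r in seq_len(options$optim_runs)) {
      start <- sample_start()
      if (r == 1L && !is.null(inherited_start)) {
        shared <- intersect(free, names(inherited_start))
        start[shared] <- pmin(pmax(inherited_start[shared], lower[shared]),
                              upper[shared])
      }
      tries <- 0L
      while (objective(start) >= big && tries < 20L) {
        start <- sample_start()
        tries <- tries + 1L
      }
      if (objective(start) >= big) next  # chain failed: no finite start
      par <- start
      value_prev <- Inf
      legs <- 0L
      converged <- FALSE
      repeat {
        res <- if (k == 1L) {
          stats::optim(par, objective, method = "Brent",
                       lower = lower, upper = upper)
        } else {
          stats::optim(par, objective, method = options$method,
                       control = list(maxit = options$iteration_cap,
                                      warn.1d.NelderMead = FALSE))
        }
        legs <- legs + 1L
        if (value_prev - res$value < options$convergence_tol) {
          converged <- TRUE
          break
        }
        if (legs >= options$max_legs) break
        value_prev <- res$value
        par <- res$par
      }
      if (is.null(best) || res$value < best$value) {
        best <- list(par = res$par, value = res$value,
                     converged = converged, legs = legs)
      }
    }
    best
  }

  best <- with_stream(options$seed, key, run_chains)

  if (is.null(best) || best$value >= big) {
    rec <- list(model = key, alpha = alpha,
                estimates = stats::setNames(rep(NA_real_, k), free),
                parameters = NULL, minus2LL = Inf, k = k,
                n = n_data, ic_type = ic_type, ic_value = Inf,
                converged = FALSE, runs = options$optim_runs,
                legs = 0L, fevals = n_eval, failed = TRUE)
    class(rec) <- "fit_record"
    return(rec)
  }

  est <- pmin(pmax(best$par, lower), upper)
  names(est) <- free
  full <- resolve_parameters(alpha, est, space)
  if (cost_returns == "minus2LL") {
    minus2LL <- best$value
    ic <- information_criterion(minus2LL, k = k, n = n_data,
                                ic_type = ic_type)
  } else {
    minus2LL <- NA_real_
    ic <- best$value
  }
  rec <- list(model = key, alpha = alpha, estimates = est, parameters = full,
              minus2LL = minus2LL, k = k, n = n_data, ic_type = ic_type,
              ic_value = ic, converged = best$converged,
              runs = options$optim_runs, legs = best$legs, fevals = n_eval,
              failed = FALSE)
  class(rec) <- "fit_record"
  rec
}

#' @export
print.fit_record <- function(x, ...) {
  cat("Fitted sub-model ", x$model, " (k = ", x$k, ")\n", sep = "")
  if (x$failed) {
    cat("  fit FAILED (no finite cost at any start)\n")
    return(invisible(x))
  }
  cat("  ", x$ic_type, " = ", format(x$ic_value, digits = 6),
      if (!is.na(x$minus2LL)) paste0(",  -2lnL = ",
                                     format(x$minus2LL, digits = 6)),
      "\n", sep = "")
  cat("  converged: ", x$converged, " (", x$runs, " run(s), ",
      x$legs, " leg(s), ", x$fevals, " cost evaluations)\n", sep = "")
  invisible(x)
}

#' Profile-likelihood confidence interval for one fitted parameter
#'
#' Walks the named parameter away from its estimate in both directions with
#' adaptive steps, re-optimizing all other included parameters at each point
#' (warm-started from the neighbouring profile point). The confidence bound is
#' where the profiled cost crosses `min + qchisq(level, 1)` (3.841 for 95%).
#' If the profile stays below the threshold all the way to the box bound, that
#' side is flagged non-identifiable and the bound itself is reported.
#'
#' @param record a converged [fit_submodel()] result.
#' @param parameter_name name of an included parameter of the record's model.
#' @param cost_fn,space,options as in [fit_submodel()] (the cost must return
#'   -2 log-likelihood values).
#' @param level confidence level (default 0.95).
#' @param ... passed on to `cost_fn`.
#' @return object of class `profile_ci`: list with `lower`, `upper`,
#'   `lower_identifiable`, `upper_identifiable`, the estimate, level and
#'   threshold.
#' @export
profile_likelihood_ci <- function(record, parameter_name, cost_fn, space,
                                  options = fit_options(), level = 0.95,
                                  ...) {
  if (record$failed || !is.finite(record$minus2LL)) {
    stop("profile likelihood requires a converged fit with finite -2lnL")
  }
  if (!(parameter_name %in% names(record$estimates))) {
    stop("'", parameter_name, "' is not an included parameter of the model")
  }
  alpha <- record$alpha
  est <- record$estimates[[parameter_name]]
  others <- setdiff(names(record$estimates), parameter_name)
  lower_o <- stats::setNames(space$bounds["lower", others], others)
  upper_o <- stats::setNames(space$bounds["upper", others], others)
  lo <- space$bounds["lower", parameter_name]
  up <- space$bounds["upper", parameter_name]
  threshold <- record$minus2LL + stats::qchisq(level, df = 1)
  baseline <- record$minus2LL

  big <- 1e300
  resolver <- make_resolver(alpha, space)
  eval_full <- function(v, po) {
    full <- resolver(stats::setNames(c(v, po), c(parameter_name, others)))
    val <- tryCatch(cost_fn(full, ...), error = function(e) NA_real_)
    if (!is.finite(val)) big else val
  }
  # re-optimize the nuisance parameters at fixed profile value v, iterating
  # capped legs until the decrease stalls (an under-optimized nuisance fit
  # inflates the profile and would shrink the interval)
  profile_at <- function(v, warm) {
    if (length(others) == 0L) {
      return(list(value = eval_full(v, numeric(0)), par = numeric(0)))
    }
    obj <- function(po) {
      pc <- pmin(pmax(po, lower_o), upper_o)
      eval_full(v, pc) + 1e6 * sum((po - pc)^2)
    }
    if (length(others) == 1L) {
      res <- stats::optim(warm, obj, method = "Brent",
                          lower = lower_o, upper = upper_o)
      return(list(value = res$value,
                  par = pmin(pmax(res$par, lower_o), upper_o)))
    }
    par <- warm
    value_prev <- Inf
    for (leg in seq_len(options$max_legs)) {
      res <- stats::optim(par, obj, method = options$method,
                          control = list(maxit = options$iteration_cap,
                                         warn.1d.NelderMead = FALSE))
      par <- res$par
      if (value_prev - res$value < options$convergence_tol) break
      value_prev <- res$value
    }
    list(value = res$value, par = pmin(pmax(par, lower_o), upper_o))
  }

  # anchor the threshold at the profile minimum: if re-optimization at the
  # estimate improves on the recorded fit, the interval is computed from
  # the improved baseline
  at_est <- profile_at(est, record$estimates[others])
  if (is.finite(at_est$value) && at_est$value < baseline) {
    baseline <- at_est$value
    threshold <- baseline + stats::qchisq(level, df = 1)
  }

  walk <- function(direction) {
    bound <- if (direction > 0) up else lo
    rng <- up - lo
    step <- rng * 0.02
    min_step <- rng * 1e-6
    v_in <- est           # last point known to be below threshold
    f_in <- baseline
    warm <- record$estimates[others]
    repeat {
      v <- v_in + direction * step
      hit_bound <- FALSE
      if ((direction > 0 && v >= bound) || (direction < 0 && v <= bound)) {
        v <- bound
        hit_bound <- TRUE
      }
      pr <- profile_at(v, warm)
      if (pr$value >= big) {
        # re-optimization failed here: halve the step and retry
        warning("profile re-optimization failed at ", parameter_name,
                " = ", signif(v, 6), "; halving step")
        step <- step / 2
        if (step < min_step) return(list(bound = v_in, identifiable = TRUE))
        next
      }
      if (pr$value > threshold) {
        # bracketed: bisect between v_in and v
        v_out <- v
        for (i in 1:30) {
          if (abs(v_out - v_in) < rng * 1e-5) break
          vm <- (v_in + v_out) / 2
          pm <- profile_at(vm, warm)
          if (pm$value > threshold) {
            v_out <- vm
          } else {
            v_in <- vm
            warm <- pm$par
          }
        }
        return(list(bound = (v_in + v_out) / 2, identifiable = TRUE))
      }
      v_in <- v
      f_in <- pr$value
      warm <- pr$par
      if (hit_bound) return(list(bound = bound, identifiable = FALSE))
      # adapt: accelerate while the profile rises slowly
      rise <- pr$value - baseline
      if (rise < 0.25 * (threshold - baseline)) {
        step <- min(step * 2, rng * 0.2)
      }
    }
  }

  left <- walk(-1)
  right <- walk(+1)
  out <- list(parameter = parameter_name, estimate = est,
              lower = left$bound, upper = right$bound,
              lower_identifiable = left$identifiable,
              upper_identifiable = right$identifiable,
              level = level, threshold = threshold)
  class(out) <- "profile_ci"
  out
}

#' @export
print.profile_ci <- function(x, ...) {
  flag <- function(id) if (id) "" else " (at bound, non-identifiable)"
  cat(sprintf("%g%% profile-likelihood CI for %s\n", 100 * x$level,
              x$parameter))
  cat(sprintf("  estimate %.6g, CI [%.6g%s, %.6g%s]\n", x$estimate,
              x$lower, flag(x$lower_identifiable),
              x$upper, flag(x$upper_identifiable)))
  invisible(x)
}
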