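#' Parameters of the generation-structured proliferation model
#'
#' Cells are tracked by the number of divisions they have undergone
#' (generations 0..9, with generation 9 collecting all later divisions). A
#' cell in generation i divides at rate `rho_i` (producing two generation
#' i+1 cells) and dies at rate `delta_i` (both per hour). After transfer into
#' a culture environment cells cannot divide during an environment-specific
#' adaptation time `tau` (hours): all division rates are 0 while
#' `t <= tau`. Rates may differ between the two culture environments,
#' suspension and collagen.
#'
#' The defaults define the synthetic benchmark truth: a low early division
#' rate (0.04/h, generations 0-2) that rises to 0.10/h from generation 3 on,
#' a uniform death rate of 0.005/h, and adaptation times of 46.1 h in
#' collagen versus 40.6 h in suspension; rates are shared between the
#' environments, so the only environmental difference is the adaptation time.
#'
#' @param rho,delta division and death rates per hour: either a vector of 10
#'   values applied to both environments or a list with elements `collagen`
#'   and `suspension`.
#' @param tau named adaptation times in hours for `collagen` and
#'   `suspension`.
#' @param n_generations number of tracked generations (10: 0..9).
#' @param initial initial distribution over generations (default: all cells
#'   undivided in generation 0, as freshly dye-labelled cells are).
#' @return list of class `proliferation_params`.
#' @export
proliferation_params <- function(rho = c(rep(0.04, 3), rep(0.10, 7)),
                                 delta = rep(0.005, 10),
                                 tau = c(collagen = 46.1, suspension = 40.6),
                                 n_generations = 10L,
                                 initial = c(1, rep(0, n_generations - 1))) {
  envs <- c("collagen", "suspension")
  expand <- function(x, what) {
    if (!is.list(x)) x <- list(collagen = x, suspension = x)
    miss <- setdiff(envs, names(x))
    if (length(miss)) stop("'", what, "' misses environment(s): ",
                           paste(miss, collapse = ", "))
    for (e in envs) {
      if (length(x[[e]]) != n_generations) {
        stop("'", what, "' must have ", n_generations, " values per ",
             "environment")
      }
      if (any(x[[e]] < 0) || any(x[[e]] > 1)) {
        stop("'", what, "' rates must lie in [0, 1] per hour")
      }
    }
    x[envs]
  }
  rho <- expand(rho, "rho")
  delta <- expand(delta, "delta")
  if (any(tau < 0)) stop("adaptation times must be non-negative")
  tau <- tau[envs]
  if (anyNA(tau)) stop("'tau' must name both environments")
  stopifnot(length(initial) == n_generations, all(initial >= 0),
            sum(initial) > 0)
  structure(list(rho = rho, delta = delta, tau = tau,
                 n_generations = as.integer(n_generations),
                 initial = initial),
            class = "proliferation_params")
}

# generation-cascade rate matrix: dT_0 = -(rho_0+delta_0) T_0,
# dT_i = 2 rho_{i-1} T_{i-1} - (rho_i+delta_i) T_i
prolif_rate_matrix <- function(rho, delta, top_generation) {
  n <- length(rho)
  M <- diag(-(rho + delta))
  for (i in 2:n) M[i, i - 1] <- 2 * rho[i - 1]
  if (top_generation == "accumulating") {
    # dividing top-generation cells stay in the top generation
    M[n, n] <- rho[n] - delta[n]
  }
  M
}

#' Generation frequencies predicted by the proliferation model
#'
#' Integrates the generation cascade exactly (matrix exponential over each
#' piece of the piecewise-constant system, split exactly at the adaptation
#' time `tau`, before which all division rates are 0) and returns the model
#' frequencies `m_i(t) = T_i(t) / sum_j T_j(t)` over living modelled cells.
#'
#' @param params a [proliferation_params()] object.
#' @param environment `"suspension"` or `"collagen"`.
#' @param times increasing observation times in hours, starting at or after 0.
#' @param top_generation `"exiting"` (the literal cascade: cells dividing in
#'   the top generation leave the tracked system) or `"accumulating"` (they
#'   return to the top generation).
#' @return matrix `length(times) x n_generations` of frequencies, with the
#'   cell counts in attribute `"counts"`. Rows where the living population
#'   has underflowed are `NA` (with a warning).
#' @examples
#' m <- proliferation_solve(proliferation_params(), "suspension",
#'                          times = c(0, 48, 96, 168))
#' rowSums(m)  # all 1
#' @export
proliferation_solve <- function(params, environment = c("suspension",
                                                        "collagen"),
                                times,
                                top_generation = c("exiting",
                                                   "accumulating")) {
  stopifnot(inherits(params, "proliferation_params"))
  environment <- match.arg(environment)
  top_generation <- match.arg(top_generation)
  stopifnot(all(times >= 0), !is.unsorted(times))
  rho <- params$rho[[environment]]
  delta <- params$delta[[environment]]
  tau <- params$tau[[environment]]
  n <- params$n_generations

  counts <- matrix(NA_real_, length(times), n)
  pre <- times <= tau
  # adaptation phase: no division, the system is diagonal pure death
  if (any(pre)) {
    counts[pre, ] <- t(vapply(times[pre],
                              function(t) params$initial * exp(-delta * t),
                              numeric(n)))
  }
  if (any(!pre)) {
    state_tau <- params$initial * exp(-delta * tau)
    M <- prolif_rate_matrix(rho, delta, top_generation)
    counts[!pre, ] <- lin_ode_traj(M, state_tau, times[!pre] - tau)
  }
  tot <- rowSums(counts)
  dead <- tot < sum(params$initial) * 1e-12
  if (any(dead)) {
    warning("living population underflowed at ", sum(dead),
            " time point(s); frequencies undefined there")
  }
  freq <- counts / tot
  freq[dead, ] <- NA_real_
  colnames(freq) <- paste0("gen", seq_len(n) - 1L)
  rownames(freq) <- format(times)
  attr(freq, "counts") <- counts
  freq
}

#' Parameter space of the proliferation model-selection problem
#'
#' 43 parameters: generation-dependent division (`rho`) and death (`delta`)
#' rates for generations 0..9 in collagen (`_C`) and suspension (`_S`), one
#' adaptation time per environment (`tau_C`, `tau_S`), and the
#' standard-deviation inflation `sigma_tilde` of the cost function. Collagen
#' is the reference environment. Default rules encode the inheritance
#' chains: an unfitted collagen rate inherits the previous generation's rate;
#' an unfitted suspension rate inherits the previous suspension generation if
#' the model selects any environmental difference at that or an earlier
#' generation, and the collagen rate of the same generation otherwise; an
#' unfitted `tau_S` equals `tau_C`, an unfitted `tau_C` is 0. Critical sets
#' force every model to describe the initial generation (`rho_C0` or
#' `delta_C0`) and to contain `sigma_tilde`; the single swap set spans all 42
#' rate/time parameters. Bounds: rates \[0, 1\] per hour, adaptation times
#' \[0, 48\] h, `sigma_tilde` (0, 1\].
#'
#' @return a [parameter_space()] with 43 parameters.
#' @examples
#' sp <- proliferation_space()
#' count_models(42) > 1e12
#' @export
proliferation_space <- function() {
  gens <- 0:9
  rho_C <- paste0("rho_C", gens)
  delta_C <- paste0("delta_C", gens)
  rho_S <- paste0("rho_S", gens)
  delta_S <- paste0("delta_S", gens)
  nm <- c(rho_C, delta_C, "tau_C", rho_S, delta_S, "tau_S", "sigma_tilde")

  rules <- list()
  for (i in 2:10) {
    rules[[rho_C[i]]] <- rho_C[i - 1]
    rules[[delta_C[i]]] <- delta_C[i - 1]
  }
  rules[["rho_S0"]] <- "rho_C0"
  rules[["delta_S0"]] <- "delta_C0"
  for (i in 2:10) {
    rules[[rho_S[i]]] <- list(
      list(ref = rho_S[i - 1], guard = rho_S[1:i]),
      rho_C[i])
    rules[[delta_S[i]]] <- list(
      list(ref = delta_S[i - 1], guard = delta_S[1:i]),
      delta_C[i])
  }
  rules[["tau_S"]] <- "tau_C"

  bounds <- c(
    stats::setNames(rep(list(c(0, 1)), 40), c(rho_C, delta_C, rho_S, delta_S)),
    list(tau_C = c(0, 48), tau_S = c(0, 48), sigma_tilde = c(1e-6, 1))
  )
  parameter_space(
    nm,
    critical_sets = list(c("rho_C0", "delta_C0"), "sigma_tilde"),
    swap_sets = list(setdiff(nm, "sigma_tilde")),
    default_rules = rules,
    bounds = bounds
  )
}

# proliferation_params object from a resolved full 43-parameter vector
prolif_params_from_vector <- function(par) {
  gens <- 0:9
  proliferation_params(
    rho = list(collagen = as.numeric(par[paste0("rho_C", gens)]),
               suspension = as.numeric(par[paste0("rho_S", gens)])),
    delta = list(collagen = as.numeric(par[paste0("delta_C", gens)]),
                 suspension = as.numeric(par[paste0("delta_S", gens)])),
    tau = c(collagen = as.numeric(par[["tau_C"]]),
            suspension = as.numeric(par[["tau_S"]]))
  )
}

#' Synthetic dye-dilution dataset
#'
#' Emulates a dye-dilution proliferation experiment: generation frequencies
#' of the proliferation model in both culture environments at the sampling
#' days, perturbed per replicate with Gaussian noise truncated at 0 and
#' renormalized so each replicate's frequencies sum to 1. This reproduces the
#' shape of the experimental data (frequencies for generations 0..9 at days
#' 0, 2, 4 and 7, three replicates, two culture conditions); it does not
#' emulate flow-cytometry peak deconvolution or counting-bead calibration.
#'
#' @param params a [proliferation_params()] object (the generating truth).
#' @param times_h sampling times in hours (default days 0, 2, 4, 7).
#' @param replicates replicates per environment and time point.
#' @param noise_sd standard deviation of the truncated Gaussian measurement
#'   noise on frequencies.
#' @param seed RNG seed (the caller's RNG state is left untouched).
#' @param cell_type label stored with the dataset.
#' @param top_generation passed to [proliferation_solve()].
#' @return data frame with columns `cell_type`, `environment`, `time_h`,
#'   `generation`, `replicate`, `frequency`.
#' @export
simulate_dye_dilution <- function(params = proliferation_params(),
                                  times_h = c(0, 48, 96, 168),
                                  replicates = 3L, noise_sd = 0.005,
                                  seed = NULL, cell_type = "synthetic",
                                  top_generation = "exiting") {
  stopifnot(replicates >= 1, noise_sd >= 0)
  gens <- seq_len(params$n_generations) - 1L
  run <- function() {
    rows <- list()
    for (env in c("suspension", "collagen")) {
      m <- proliferation_solve(params, env, times_h,
                               top_generation = top_generation)
      for (ti in seq_along(times_h)) {
        for (r in seq_len(replicates)) {
          y <- m[ti, ]
          if (noise_sd > 0) {
            # truncated (not censored) Gaussian: the value stays positive,
            # never ties at exactly 0, by sampling the conditional
            # distribution above the truncation point
            u <- stats::runif(length(y),
                              stats::pnorm(-y / noise_sd), 1)
            y <- y + noise_sd * stats::qnorm(u)
          }
          y <- y / sum(y)
          rows[[length(rows) + 1L]] <- data.frame(
            cell_type = cell_type, environment = env,
            time_h = times_h[ti], generation = gens, replicate = r,
            frequency = as.numeric(y), stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  }
  with_stream(seed, "dye-dilution", run)
}

#' Replicate means and standard deviations of a dye-dilution dataset
#'
#' @param data a dataset in the format of [simulate_dye_dilution()].
#' @return data frame with one row per (environment, time, generation) cell:
#'   `environment`, `time_h`, `generation`, `mean`, `sd`, `n`.
#' @export
dye_dilution_summary <- function(data) {
  key <- interaction(data$environment, data$time_h, data$generation,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(data, key), function(d) {
    data.frame(environment = d$environment[1], time_h = d$time_h[1],
               generation = d$generation[1], mean = mean(d$frequency),
               sd = stats::sd(d$frequency), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$environment, agg$time_h, agg$generation), ]
  rownames(agg) <- NULL
  agg
}

#' Cost function for fitting the proliferation model to dye-dilution data
#'
#' Builds the weighted least-squares -2 log-likelihood (see
#' [dye_dilution_cost()]) of the proliferation model against the replicate
#' means and standard deviations of a dye-dilution dataset, summed over both
#' culture environments. The returned closure takes a full named parameter
#' vector of the [proliferation_space()] (so it is directly usable with
#' [fit_submodel()] and [model_search()]); its `sigma_tilde` component is the
#' standard-deviation inflation.
#'
#' @inheritParams dye_dilution_summary
#' @param top_generation passed to [proliferation_solve()].
#' @return cost function with attribute `n_data` (the number of mean data
#'   cells: time points x generations x environments).
#' @export
dye_dilution_cost_fn <- function(data, top_generation = "exiting") {
  smry <- dye_dilution_summary(data)
  envs <- unique(smry$environment)
  per_env <- lapply(envs, function(env) {
    d <- smry[smry$environment == env, ]
    times <- sort(unique(d$time_h))
    gens <- sort(unique(d$generation))
    mean_m <- matrix(NA_real_, length(times), length(gens))
    sd_m <- mean_m
    for (i in seq_along(times)) {
      di <- d[d$time_h == times[i], ]
      di <- di[order(di$generation), ]
      mean_m[i, ] <- di$mean
      sd_m[i, ] <- di$sd
    }
    list(env = env, times = times, mean = mean_m, sd = sd_m)
  })
  n_data <- sum(vapply(per_env, function(e) length(e$mean), 0))
  fn <- function(par) {
    p <- prolif_params_from_vector(par)
    total <- 0
    for (e in per_env) {
      # underflow of the living population surfaces as a non-finite cost
      m <- suppressWarnings(
        proliferation_solve(p, e$env, e$times,
                            top_generation = top_generation))
      if (anyNA(m)) return(NA_real_)
      total <- total + dye_dilution_cost(e$mean, e$sd, unclass(m)[, ],
                                         par[["sigma_tilde"]])
    }
    total
  }
  attr(fn, "n_data") <- n_data
  fn
}

#' Probability of dividing within a fixed time window
#'
#' Converts a division rate (per hour) into the probability that a cell
#' divides at least once within a time window, `1 - exp(-window_h * rho)`.
#'
#' @param rho division rate(s) per hour, non-negative.
#' @param window_h window length in hours (default 12).
#' @return probability (vectorized over `rho`).
#' @examples
#' division_probability(0.05)   # ~0.45
#' @export
division_probability <- function(rho, window_h = 12) {
  if (any(rho < 0)) stop("'rho' must be non-negative")
  1 - exp(-window_h * rho)
}
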