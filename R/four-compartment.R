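#' The four-compartment benchmark system
#'
#' A population model with four compartments A, B, C, D. Each compartment X
#' may multiply at rate `rho_X` and send members to compartment Y at
#' transition rate `mu_XY` (all rates per unit time, arbitrary units), giving
#' a global model with 4 + 12 = 16 rate parameters. The default
#' parameterization is the benchmark's data-generating sub-model:
#' `mu_AB = 0.1`, `rho_B = 0.1`, `mu_BC = 0.05`, `mu_BD = 0.2`,
#' `rho_C = 0.1`, all other rates 0, starting from 100 members in A.
#'
#' @param rho named numeric, multiplication rates for compartments
#'   `A`, `B`, `C`, `D` (missing entries are 0).
#' @param mu named numeric, transition rates named by ordered compartment
#'   pair, e.g. `AB` for A to B (missing entries are 0).
#' @param initial named numeric, initial compartment sizes.
#' @return list of class `four_compartment_params`.
#' @export
four_compartment_params <- function(rho = c(B = 0.1, C = 0.1),
                                    mu = c(AB = 0.1, BC = 0.05, BD = 0.2),
                                    initial = c(A = 100, B = 0, C = 0, D = 0)) {
  comps <- c("A", "B", "C", "D")
  pairs <- fc_pairs()
  r <- stats::setNames(numeric(4), comps)
  r[names(rho)] <- rho
  m <- stats::setNames(numeric(12), pairs)
  bad <- setdiff(names(mu), pairs)
  if (length(bad)) stop("unknown transition(s): ", paste(bad, collapse = ", "))
  m[names(mu)] <- mu
  if (any(r < 0) || any(m < 0)) stop("rates must be non-negative")
  init <- stats::setNames(numeric(4), comps)
  init[names(initial)] <- initial
  structure(list(rho = r, mu = m, initial = init),
            class = "four_compartment_params")
}

fc_pairs <- function() {
  comps <- c("A", "B", "C", "D")
  out <- character(0)
  for (x in comps) for (y in comps) if (x != y) out <- c(out, paste0(x, y))
  out
}

fc_parameter_names <- function() {
  c(paste0("rho_", c("A", "B", "C", "D")), paste0("mu_", fc_pairs()))
}

# full named 16-vector (space order) from a params object or named vector
fc_param_vector <- function(params) {
  if (inherits(params, "four_compartment_params")) {
    return(stats::setNames(c(params$rho, params$mu), fc_parameter_names()))
  }
  p <- stats::setNames(numeric(16), fc_parameter_names())
  bad <- setdiff(names(params), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(params)] <- params
  p
}

# dx/dt = M x with M[Y,X] = mu_XY (X != Y), M[X,X] = rho_X - sum_Y mu_XY
.fc_names <- fc_parameter_names()
.fc_mu_cells <- cbind(match(substr(fc_pairs(), 2, 2), c("A", "B", "C", "D")),
                      match(substr(fc_pairs(), 1, 1), c("A", "B", "C", "D")))

fc_rate_matrix <- function(pvec) {
  if (!identical(names(pvec), .fc_names)) pvec <- pvec[.fc_names]
  M <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  mu <- as.numeric(pvec[5:16])
  M[.fc_mu_cells] <- mu
  diag(M) <- as.numeric(pvec[1:4]) - colSums(matrix(mu, 3, 4))
  M
}

#' Deterministic solution of the four-compartment system
#'
#' Propagates the linear ODE system exactly via the matrix exponential of the
#' rate matrix over each grid step.
#'
#' @param params a [four_compartment_params()] object or a full named
#'   16-vector of rates (as produced by [resolve_parameters()]).
#' @param times increasing vector of observation times (from 0).
#' @param initial initial compartment sizes; defaults to the value stored in
#'   `params` or 100 members in A.
#' @return data frame with columns `time`, `A`, `B`, `C`, `D`.
#' @examples
#' sol <- four_compartment_solve(four_compartment_params(), times = 0:10)
#' sol[sol$time == 10, ]
#' @export
four_compartment_solve <- function(params, times, initial = NULL) {
  pvec <- fc_param_vector(params)
  if (is.null(initial)) {
    initial <- if (inherits(params, "four_compartment_params")) {
      params$initial
    } else {
      c(A = 100, B = 0, C = 0, D = 0)
    }
  }
  traj <- lin_ode_traj(fc_rate_matrix(pvec), initial, times)
  colnames(traj) <- c("A", "B", "C", "D")
  data.frame(time = times, traj)
}

#' Stochastic benchmark dataset via adaptive tau-leaping
#'
#' Simulates the four-compartment system as a continuous-time Markov jump
#' process with reactions X -> 2X (propensity `rho_X * X`) and X -> Y
#' (propensity `mu_XY * X`), using adaptive tau-leaping with an exact-SSA
#' fallback whenever the leap candidate is smaller than a few expected event
#' times (negative counts are impossible by construction: oversized leaps are
#' halved and redrawn). For each of `n_time_points` equidistant time points,
#' `reps_per_point` fresh trajectories are run from t = 0 and their states at
#' that time recorded, so all data points are independent; per-point means
#' and standard deviations are returned.
#'
#' @inheritParams four_compartment_solve
#' @param horizon simulated time span; observation times are
#'   `seq(horizon/n, horizon, length.out = n)`.
#' @param n_time_points number of equidistant observation times.
#' @param reps_per_point independent trajectories per observation time.
#' @param seed RNG seed (the caller's RNG state is left untouched).
#' @param eps tau-leap accuracy parameter.
#' @return list of class `compartment_data`: `times`, matrices `mean` and
#'   `sd` (time points x compartments), `reps`, `initial`.
#' @export
four_compartment_gillespie <- function(params = four_compartment_params(),
                                       horizon = 10, n_time_points = 30L,
                                       reps_per_point = 10L, seed = NULL,
                                       eps = 0.03) {
  stopifnot(inherits(params, "four_compartment_params"))
  x0 <- params$initial
  if (any(x0 != floor(x0))) stop("initial counts must be integers")
  times <- seq(horizon / n_time_points, horizon, length.out = n_time_points)

  # stoichiometry: 4 birth reactions then 12 transitions
  pairs <- fc_pairs()
  n_rxn <- 16L
  V <- matrix(0L, nrow = 4, ncol = n_rxn)
  for (j in 1:4) V[j, j] <- 1L
  for (k in seq_along(pairs)) {
    from <- match(substr(pairs[k], 1, 1), c("A", "B", "C", "D"))
    to <- match(substr(pairs[k], 2, 2), c("A", "B", "C", "D"))
    V[from, 4L + k] <- -1L
    V[to, 4L + k] <- 1L
  }
  rates <- c(params$rho, params$mu)
  rate_species <- c(1:4, match(substr(pairs, 1, 1), c("A", "B", "C", "D")))

  simulate_to <- function(t_end) {
    x <- as.numeric(x0)
    t <- 0
    repeat {
      a <- rates * x[rate_species]
      a0 <- sum(a)
      if (a0 <= 0 || t >= t_end) break
      # leap size: Cao-style bound on relative propensity change
      mu_s <- as.numeric(V %*% a)
      sg_s <- as.numeric((V * V) %*% a)
      xb <- pmax(x, 1)
      tau <- min(pmax(eps * xb / abs(mu_s), (eps * xb)^2 / sg_s),
                 na.rm = TRUE)
      if (!is.finite(tau)) tau <- t_end - t
      if (tau < 3 / a0) {
        # exact SSA burst
        for (s in 1:10) {
          a <- rates * x[rate_species]
          a0 <- sum(a)
          if (a0 <= 0) break
          dt <- stats::rexp(1, a0)
          if (t + dt > t_end) {
            t <- t_end
            break
          }
          t <- t + dt
          j <- sample.int(n_rxn, 1L, prob = a)
          x <- x + V[, j]
        }
        if (t >= t_end) break
        next
      }
      tau <- min(tau, t_end - t)
      repeat {
        k <- stats::rpois(n_rxn, a * tau)
        xn <- x + as.numeric(V %*% k)
        if (all(xn >= 0)) break
        tau <- tau / 2
      }
      x <- xn
      t <- t + tau
    }
    x
  }

  run <- function() {
    mean_m <- matrix(NA_real_, n_time_points, 4,
                     dimnames = list(NULL, c("A", "B", "C", "D")))
    sd_m <- mean_m
    for (i in seq_along(times)) {
      states <- replicate(reps_per_point, simulate_to(times[i]))
      mean_m[i, ] <- rowMeans(states)
      sd_m[i, ] <- apply(states, 1, stats::sd)
    }
    list(mean = mean_m, sd = sd_m)
  }
  ms <- with_stream(seed, "four-compartment-gillespie", run)
  structure(list(times = times, mean = ms$mean, sd = ms$sd,
                 reps = reps_per_point, initial = x0,
                 source = "tau-leaping"),
            class = "compartment_data")
}

#' Noiseless benchmark dataset from the deterministic solution
#'
#' Same container as [four_compartment_gillespie()] but with the exact ODE
#' solution as means and zero standard deviations; used for deterministic
#' search benchmarks.
#'
#' @inheritParams four_compartment_gillespie
#' @return a `compartment_data` object.
#' @export
four_compartment_noiseless_data <- function(params = four_compartment_params(),
                                            horizon = 10,
                                            n_time_points = 30L) {
  times <- seq(horizon / n_time_points, horizon, length.out = n_time_points)
  sol <- four_compartment_solve(params, times)
  m <- as.matrix(sol[, c("A", "B", "C", "D")])
  structure(list(times = times, mean = m, sd = 0 * m, reps = 1L,
                 initial = params$initial, source = "ode"),
            class = "compartment_data")
}

#' @export
print.compartment_data <- function(x, ...) {
  cat("Four-compartment dataset (", x$source, "): ",
      length(x$times), " time points x 4 compartments, ",
      x$reps, " replicate(s) per point\n", sep = "")
  invisible(x)
}

#' Gaussian cost function for the four-compartment benchmark
#'
#' Builds a -2 log-likelihood cost over the per-time-point compartment means:
#' squared residuals weighted by the uncertainty of each mean, plus the
#' corresponding log-variance terms. The data points are means over `reps`
#' independent simulations, so the default weight is the standard error of
#' the mean, `(sd + sd_floor)/sqrt(reps)`; `weighting = "sd"` uses the raw
#' replicate standard deviation instead (the weighting of the dye-dilution
#' cost, where replicate counts are very small). The additive floor — one
#' count on the individual-measurement scale — keeps the weights finite for
#' noiseless data; it is held fixed so the benchmark space keeps exactly its
#' 16 rate parameters.
#'
#' @param data a `compartment_data` object.
#' @param sd_floor additive floor on the per-point replicate standard
#'   deviations (counts; default 1).
#' @param weighting `"sem"` (default) or `"sd"`.
#' @param engine `"cpp"` (compiled kernel) or `"r"` (reference
#'   implementation); both give identical values.
#' @return function of a full named 16-parameter vector returning the cost;
#'   its attribute `n_data` is the number of data cells (time points x 4).
#' @export
four_compartment_cost <- function(data, sd_floor = 1,
                                  weighting = c("sem", "sd"),
                                  engine = c("cpp", "r")) {
  stopifnot(inherits(data, "compartment_data"), sd_floor > 0)
  weighting <- match.arg(weighting)
  engine <- match.arg(engine)
  s <- data$sd + sd_floor
  if (weighting == "sem") s <- s / sqrt(data$reps)
  log_term <- sum(log(s^2))
  times <- data$times
  y <- data$mean
  x0 <- as.numeric(data$initial)
  fn <- if (engine == "cpp") {
    function(par) {
      if (!identical(names(par), .fc_names)) par <- par[.fc_names]
      .fc_cost_cpp(as.numeric(par), times, y, s, x0) + log_term
    }
  } else {
    function(par) {
      M <- fc_rate_matrix(par)
      m <- lin_ode_traj(M, x0, times)
      sum(((y - m) / s)^2) + log_term
    }
  }
  attr(fn, "n_data") <- length(y)
  fn
}

#' Parameter space of the four-compartment benchmark
#'
#' All 16 rates of the global model are selectable (no critical sets),
#' bounded to \[0, 10\]. The swap-set mode reproduces the benchmark's
#' structurally similar parameter groupings: `"influx"` groups, for each
#' compartment X, its multiplication rate with all transitions into X (the
#' grouping that rescues searches from the benchmark's local minimum);
#' `"efflux"` groups the multiplication rate with the transitions out of X
#' (the counterexample grouping); `"all"` makes every rate swappable;
#' `"none"` defines no swap sets.
#'
#' @param swap_mode one of `"none"`, `"influx"`, `"efflux"`, `"all"`.
#' @return a [parameter_space()] with 16 parameters.
#' @examples
#' sp <- four_compartment_space("influx")
#' sp$swap_sets[[1]]
#' @export
four_compartment_space <- function(swap_mode = c("none", "influx", "efflux",
                                                 "all")) {
  swap_mode <- match.arg(swap_mode)
  comps <- c("A", "B", "C", "D")
  nm <- fc_parameter_names()
  swap_sets <- switch(
    swap_mode,
    none = list(),
    influx = lapply(comps, function(x) {
      c(paste0("rho_", x), paste0("mu_", setdiff(comps, x), x))
    }),
    efflux = lapply(comps, function(x) {
      c(paste0("rho_", x), paste0("mu_", x, setdiff(comps, x)))
    }),
    all = list(nm)
  )
  parameter_space(nm, swap_sets = swap_sets, bounds = c(0, 10))
}

#' The data-generating sub-model of the benchmark
#'
#' @param space the space returned by [four_compartment_space()].
#' @return model inclusion vector selecting `mu_AB`, `rho_B`, `mu_BC`,
#'   `mu_BD`, `rho_C`.
#' @export
four_compartment_true_model <- function(space = four_compartment_space()) {
  model_id(c("mu_AB", "rho_B", "mu_BC", "mu_BD", "rho_C"), space)
}
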