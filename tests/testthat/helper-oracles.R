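# Brute-force oracles and small fixture builders used across the test files.

# all 2^n inclusion vectors of a space (as a list), optionally only valid ones
enumerate_models <- function(space, valid_only = FALSE) {
  n <- length(space$parameters)
  out <- list()
  for (i in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(i)[1:n])
    if (any(bits[space$parameters %in% names(space$fixed)] == 1L)) next
    alpha <- stats::setNames(bits, space$parameters)
    if (valid_only && !is_valid_model(alpha, space)) next
    out[[length(out) + 1L]] <- alpha
  }
  out
}

# neighbourhoods by exhaustive filtering of all 2^n vectors
oracle_neighbors <- function(alpha, space, method) {
  alpha <- model_id(alpha, space)
  sets <- c(space$swap_sets, space$critical_sets)
  keep <- function(beta) {
    d <- sum(beta != alpha)
    if (method == "forward") {
      return(d == 1L && sum(beta) == sum(alpha) + 1L)
    }
    if (method == "backward") {
      return(d == 1L && sum(beta) == sum(alpha) - 1L &&
               is_valid_model(beta, space))
    }
    if (d != 2L || sum(beta) != sum(alpha)) return(FALSE)
    if (!is_valid_model(beta, space)) return(FALSE)
    dropped <- space$parameters[alpha == 1L & beta == 0L]
    added <- space$parameters[alpha == 0L & beta == 1L]
    any(vapply(sets, function(s) dropped %in% s && added %in% s, TRUE))
  }
  Filter(keep, enumerate_models(space))
}

sorted_strings <- function(models) {
  sort(unname(vapply(models, model_string, "")))
}

# random small space with critical and swap sets, reproducible
random_space <- function(n, seed, with_rules = FALSE) {
  set.seed(seed)
  nm <- paste0("p", seq_len(n))
  crit <- list(sample(nm, min(n, sample(2:3, 1))))
  swap <- list(sample(nm, min(n, sample(2:4, 1))))
  parameter_space(nm, critical_sets = crit, swap_sets = swap,
                  bounds = c(0, 1))
}

# classic fixed-step RK4 integrator, used as an independent ODE oracle
rk4 <- function(deriv, x0, t_end, dt) {
  x <- x0
  t <- 0
  while (t < t_end - 1e-12) {
    h <- min(dt, t_end - t)
    k1 <- deriv(x)
    k2 <- deriv(x + h / 2 * k1)
    k3 <- deriv(x + h / 2 * k2)
    k4 <- deriv(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  x
}

# minimal stand-in fit records for weight computations
fake_record <- function(alpha, ic, model = paste(alpha, collapse = "")) {
  structure(list(model = model, alpha = alpha, ic_value = ic,
                 k = sum(alpha), ic_type = "AICc", failed = FALSE),
            class = "fit_record")
}
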