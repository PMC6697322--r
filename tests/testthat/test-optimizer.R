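quad_space <- parameter_space(c("a", "b"), bounds = c(-5, 5))
quad_cost <- function(p) 50 * ((p[["a"]] - 2)^2 + (p[["b"]] + 1)^2)

test_that("a convex quadratic is recovered from any seed", {
  for (seed in 1:3) {
    fit <- fit_submodel("11", quad_cost, quad_space,
                        fit_options(seed = seed, convergence_tol = 1e-8),
                        ic_type = "AIC")
    expect_equal(unname(fit$estimates), c(2, -1), tolerance = 1e-4)
    expect_true(fit$converged)
    expect_equal(fit$k, 2)
  }
})

test_that("an optimal inherited start is never made worse", {
  fit <- fit_submodel("11", quad_cost, quad_space, fit_options(seed = 1),
                      inherited_start = c(a = 2, b = -1), ic_type = "AIC")
  expect_lte(fit$minus2LL, quad_cost(c(a = 2, b = -1)) + 1e-12)
})

test_that("identical inputs and seed give identical fit records", {
  f1 <- fit_submodel("11", quad_cost, quad_space,
                     fit_options(seed = 7, optim_runs = 3), ic_type = "AIC")
  f2 <- fit_submodel("11", quad_cost, quad_space,
                     fit_options(seed = 7, optim_runs = 3), ic_type = "AIC")
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$minus2LL, f2$minus2LL)
  expect_identical(f1$fevals, f2$fevals)
})

test_that("estimates are clamped to the box", {
  sp <- parameter_space("a", bounds = c(0, 1))
  cost <- function(p) (p[["a"]] - 3)^2  # optimum outside the box
  fit <- fit_submodel("1", cost, sp, fit_options(seed = 1), ic_type = "AIC")
  expect_equal(unname(fit$estimates), 1, tolerance = 1e-6)
})

test_that("a cost with no finite value yields a flagged failed record", {
  sp <- parameter_space(c("a", "b"), bounds = c(0, 1))
  fit <- fit_submodel("11", function(p) NaN, sp, fit_options(seed = 1),
                      ic_type = "AIC")
  expect_true(fit$failed)
  expect_false(fit$converged)
  expect_identical(fit$ic_value, Inf)
})

test_that("the benchmark's generating rates are recovered from noiseless data", {
  dat <- four_compartment_noiseless_data()
  cost <- four_compartment_cost(dat)
  sp <- four_compartment_space()
  fit <- fit_submodel(four_compartment_true_model(sp), cost, sp,
                      fit_options(seed = 2, optim_runs = 4, max_legs = 8,
                                  sampling = "log-uniform",
                                  convergence_tol = 1e-6),
                      ic_type = "AICc", n_data = attr(cost, "n_data"))
  truth <- c(mu_AB = 0.1, rho_B = 0.1, mu_BC = 0.05, mu_BD = 0.2,
             rho_C = 0.1)
  expect_lt(max(abs(fit$estimates[names(truth)] - truth) / truth), 0.05)
})

test_that("profile CI matches the analytic one-parameter quadratic", {
  sp <- parameter_space("theta", bounds = c(0, 6))
  cost <- function(p) ((p[["theta"]] - 3) / 0.5)^2
  fit <- fit_submodel("1", cost, sp, fit_options(seed = 1), ic_type = "AIC")
  ci <- profile_likelihood_ci(fit, "theta", cost, sp)
  expect_equal(ci$lower, 3 - 0.5 * sqrt(qchisq(0.95, 1)), tolerance = 1e-3)
  expect_equal(ci$upper, 3 + 0.5 * sqrt(qchisq(0.95, 1)), tolerance = 1e-3)
  expect_true(ci$lower_identifiable && ci$upper_identifiable)
  expect_true(ci$lower < fit$estimates[["theta"]],
              ci$upper > fit$estimates[["theta"]])
})

test_that("widening the level widens the profile CI", {
  sp <- parameter_space("theta", bounds = c(0, 6))
  cost <- function(p) ((p[["theta"]] - 3) / 0.5)^2
  fit <- fit_submodel("1", cost, sp, fit_options(seed = 1), ic_type = "AIC")
  ci95 <- profile_likelihood_ci(fit, "theta", cost, sp, level = 0.95)
  ci99 <- profile_likelihood_ci(fit, "theta", cost, sp, level = 0.99)
  expect_lt(ci99$lower, ci95$lower)
  expect_gt(ci99$upper, ci95$upper)
})

test_that("a flat profile is reported at the bound and flagged", {
  sp <- parameter_space(c("a", "b"), bounds = list(a = c(0, 6),
                                                   b = c(0, 1)))
  cost <- function(p) ((p[["a"]] - 3) / 0.2)^2  # b unconstrained by data
  fit <- fit_submodel("11", cost, sp,
                      fit_options(seed = 1, convergence_tol = 1e-8),
                      ic_type = "AIC")
  ci <- profile_likelihood_ci(fit, "b", cost, sp)
  expect_equal(ci$upper, 1)
  expect_false(ci$upper_identifiable)
  expect_equal(ci$lower, 0)
  expect_false(ci$lower_identifiable)
})

test_that("profile CI matches a grid-scan oracle on a correlated quadratic", {
  sp <- parameter_space(c("a", "b"), bounds = c(-5, 5))
  A <- matrix(c(8, 4, 4, 8), 2)
  ctr <- c(1, 2)
  cost <- function(p) {
    z <- c(p[["a"]], p[["b"]]) - ctr
    sum(z * (A %*% z))
  }
  fit <- fit_submodel("11", cost, sp,
                      fit_options(seed = 3, convergence_tol = 1e-10,
                                  optim_runs = 2), ic_type = "AIC")
  ci <- profile_likelihood_ci(fit, "a", cost, sp,
                              options = fit_options(iteration_cap = 2000))
  # oracle: dense scan of a, minimizing over b numerically at each point
  thr <- fit$minus2LL + qchisq(0.95, 1)
  grid <- seq(-1, 3, by = 1e-4)
  prof <- vapply(grid, function(a) {
    optimize(function(b) cost(c(a = a, b = b)), c(-5, 5))$objective
  }, 0)
  inside <- grid[prof <= thr]
  expect_equal(ci$lower, min(inside), tolerance = 2e-3)
  expect_equal(ci$upper, max(inside), tolerance = 2e-3)
  # analytic cross-check: half-width sqrt(qchisq/ (a11 - a12^2/a22))
  hw <- sqrt(qchisq(0.95, 1) / (A[1, 1] - A[1, 2]^2 / A[2, 2]))
  expect_equal(ci$upper - ci$lower, 2 * hw, tolerance = 5e-3)
})
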