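# engine-level tests use a cost that returns the criterion directly, keyed on
# the model structure, so the combinatorial behaviour is fully controlled
ic_table_cost <- function(table, space) {
  function(par) {
    alpha <- as.integer(par[space$parameters] != 0)
    table[[paste(alpha, collapse = "")]]
  }
}

test_that("the method schedule follows the search automaton", {
  expect_equal(next_method("forward", TRUE, FALSE, TRUE), "forward")
  expect_equal(next_method("backward", TRUE, FALSE, TRUE), "backward")
  expect_equal(next_method("swap", TRUE, FALSE, TRUE), "forward")
  expect_equal(next_method("forward", FALSE, FALSE, TRUE), "backward")
  expect_equal(next_method("backward", FALSE, FALSE, TRUE), "forward")
  expect_equal(next_method("forward", FALSE, TRUE, TRUE), "swap")
  expect_equal(next_method("backward", FALSE, TRUE, TRUE), "swap")
  expect_equal(next_method("forward", FALSE, TRUE, FALSE), "terminate")
  expect_equal(next_method("swap", FALSE, FALSE, TRUE), "terminate")
  expect_equal(next_method("swap", FALSE, TRUE, FALSE), "terminate")
})

test_that("ties prefer fewer parameters, then the canonical string", {
  sp <- parameter_space(c("a", "b", "c"), bounds = c(0, 1))
  tab <- c("111" = 10, "110" = 5, "101" = 5, "011" = 8,
           "100" = 7, "010" = 9, "001" = 7)
  res <- model_search(sp, ic_table_cost(tab, sp),
                      search_options(start = "111", cost_returns = "ic",
                                     seed = 1))
  # "101" and "110" tie at 5 with equal size; canonical order picks "101"
  expect_equal(res$best$model, "101")
  acc <- res$iterations$accepted
  expect_equal(acc[!is.na(acc)], "101")
  # every proposed model was fitted exactly once
  expect_equal(res$n_new_fits, res$n_models)
})

test_that("equal criterion values are not accepted (strict improvement)", {
  sp <- parameter_space(c("a", "b", "c"), bounds = c(0, 1))
  tab <- c("111" = 10, "110" = 10, "101" = 10, "011" = 10,
           "100" = 10, "010" = 10, "001" = 10)
  res <- model_search(sp, ic_table_cost(tab, sp),
                      search_options(start = "111", cost_returns = "ic",
                                     seed = 1))
  expect_equal(res$best$model, "111")
  expect_true(all(is.na(res$iterations$accepted)))
})

test_that("accepted models strictly decrease the criterion and search halts", {
  set.seed(42)
  for (rep in 1:5) {
    sp <- random_space(n = 6, seed = rep * 13)
    models <- enumerate_models(sp, valid_only = TRUE)
    tab <- stats::setNames(sample(100, length(models)),
                           vapply(models, model_string, ""))
    res <- model_search(sp, ic_table_cost(tab, sp),
                        search_options(start = "random", cost_returns = "ic",
                                       seed = rep, max_iterations = 200))
    accepted <- res$iterations$best_ic
    expect_true(all(diff(accepted) <= 0))
    kept <- res$iterations$accepted
    ics <- c(tab[res$start], tab[kept[!is.na(kept)]])
    expect_true(all(diff(ics) < 0))
    # best is the minimum over the whole history
    hist_ics <- vapply(res$history, function(r) r$ic_value, 0)
    expect_equal(res$best$ic_value, min(hist_ics))
    expect_false(anyDuplicated(names(res$history)) > 0)
    expect_lt(nrow(res$iterations), 200)
  }
})

test_that("previously tested models are not refitted but still compete", {
  sp <- parameter_space(c("a", "b", "c"), bounds = c(0, 1))
  tab <- c("111" = 3, "110" = 5, "101" = 6, "011" = 7,
           "100" = 8, "010" = 8, "001" = 8)
  n_calls <- 0
  counting_cost <- function(par) {
    n_calls <<- n_calls + 1
    alpha <- as.integer(par[sp$parameters] != 0)
    tab[[paste(alpha, collapse = "")]]
  }
  res <- model_search(sp, counting_cost,
                      search_options(start = "110", cost_returns = "ic",
                                     seed = 1))
  # global model wins; later iterations re-propose fitted models only
  expect_equal(res$best$model, "111")
  expect_equal(res$n_new_fits, res$n_models)
  expect_true(any(res$iterations$proposed > res$iterations$fitted))
})

test_that("results are independent of candidate evaluation order", {
  sp <- parameter_space(c("a", "b", "c", "d"), bounds = c(-5, 5))
  truth <- c(a = 2, b = -1, c = 0, d = 0)
  cost <- function(p) 50 * sum((p[sp$parameters] - truth)^2)
  res <- model_search(sp, cost,
                      search_options(ic_type = "AIC", seed = 11,
                                     fit_options = fit_options(
                                       optim_runs = 2, seed = 11)))
  # refit every history model in reverse order, in isolation: records match
  for (key in rev(names(res$history))) {
    solo <- fit_submodel(key, cost, sp,
                         fit_options(optim_runs = 2, seed = 11),
                         inherited_start = NULL, ic_type = "AIC")
    if (is.null(res$history[[key]])) next
    # models fitted with inheritance may only be better, never worse
    expect_lte(res$history[[key]]$ic_value, solo$ic_value + 1e-6)
  }
  # and a rerun with the same seed reproduces the identical trace
  res2 <- model_search(sp, cost,
                       search_options(ic_type = "AIC", seed = 11,
                                      fit_options = fit_options(
                                        optim_runs = 2, seed = 11)))
  expect_identical(res$iterations, res2$iterations)
  expect_identical(res$best$estimates, res2$best$estimates)
})

test_that("the toy search selects exactly the generating subset", {
  sp <- parameter_space(c("a", "b", "c", "d"), bounds = c(-5, 5))
  truth <- c(a = 2, b = -1, c = 0, d = 0)
  cost <- function(p) 50 * sum((p[sp$parameters] - truth)^2)
  for (seed in 1:3) {
    res <- model_search(sp, cost,
                        search_options(ic_type = "AIC", start = "random",
                                       seed = seed))
    expect_equal(res$best$model, "1100")
  }
})

test_that("starting-model handling: global, user, repair, and errors", {
  sp <- parameter_space(c("a", "b", "c"), critical_sets = list(c("a", "b")),
                        bounds = c(0, 1))
  tab <- c("100" = 5, "010" = 6, "110" = 4, "101" = 7, "011" = 8,
           "111" = 9)
  cost <- ic_table_cost(tab, sp)
  expect_error(model_search(sp, cost,
                            search_options(start = "001",
                                           cost_returns = "ic")),
               "not admissible")
  res <- model_search(sp, cost,
                      search_options(start = "001", cost_returns = "ic",
                                     auto_repair = TRUE, seed = 1))
  expect_equal(res$start, "101")  # lowest-index critical member added
  expect_error(model_search(parameter_space(c("a", "b")), function(p) 1,
                            search_options(initial_method = "swap",
                                           cost_returns = "ic")),
               "swap")
  # the global start makes the first forward neighbourhood empty
  res2 <- model_search(sp, cost, search_options(start = "global",
                                                cost_returns = "ic",
                                                seed = 1))
  expect_equal(res2$iterations$method[1:2], c("forward", "backward"))
  expect_equal(res2$iterations$proposed[1], 0)
  expect_equal(res2$best$model, "110")
})
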