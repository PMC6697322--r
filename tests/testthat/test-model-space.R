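test_that("space construction enforces its invariants", {
  expect_error(parameter_space(c("a", "a")), "unique")
  expect_error(parameter_space("a", critical_sets = list("b")), "unknown")
  expect_error(parameter_space(c("a", "b"), critical_sets = list("a"),
                               fixed = c(a = 1)), "both fixed and critical")
  expect_error(parameter_space(c("a", "b"), bounds = list(a = c(1, 1))),
               "lower bound")
  expect_error(parameter_space(c("a", "b"),
                               default_rules = list(a = "b", b = "a")),
               "cyclic")
})

test_that("model admissibility follows the critical-set rule", {
  sp <- parameter_space(c("mu_AB", "mu_CB", "rho_B"),
                        critical_sets = list(c("mu_AB", "mu_CB")))
  expect_true(is_valid_model("100", sp))   # one critical member suffices
  expect_true(is_valid_model("011", sp))
  expect_false(is_valid_model("001", sp))  # critical set untouched
  expect_false(is_valid_model("000", sp))  # empty model never admissible
  expect_error(is_valid_model("01", sp), "length")
  sp2 <- parameter_space(c("a", "b"))
  expect_false(is_valid_model("00", sp2))
})

test_that("fixed parameters cannot enter a model", {
  sp <- parameter_space(c("a", "b", "c"), fixed = c(c = 0.5))
  expect_error(model_id("101", sp), "fixed")
  nb <- forward_neighbors(model_id("100", sp), sp)
  expect_equal(sorted_strings(nb), "110")  # c is never proposed
})

test_that("forward neighbourhoods add exactly one excluded parameter", {
  sp <- parameter_space(c("a", "b", "c"))
  nb <- forward_neighbors(model_id("000", sp), sp)
  expect_equal(sorted_strings(nb), c("001", "010", "100"))
  expect_length(forward_neighbors(model_id("111", sp), sp), 0)

  sp16 <- four_compartment_space()
  alpha <- four_compartment_true_model(sp16)
  expect_length(forward_neighbors(alpha, sp16), 11)  # 16 - 5 remaining
})

test_that("backward neighbourhoods respect validity", {
  sp <- parameter_space(c("a", "b", "c"))
  expect_equal(sorted_strings(backward_neighbors(model_id("110", sp), sp)),
               c("010", "100"))
  # removing the single included parameter would give the empty model
  expect_length(backward_neighbors(model_id("100", sp), sp), 0)
  # sole representative of a critical set cannot be dropped
  spc <- parameter_space(c("mu_AB", "mu_CB", "rho_B"),
                         critical_sets = list(c("mu_AB", "mu_CB")))
  nb <- backward_neighbors(model_id("101", spc), spc)
  expect_equal(sorted_strings(nb), "100")
})

test_that("swap neighbourhoods exchange within swap and critical sets", {
  sp <- parameter_space(c("mu_AB", "rho_B", "x"),
                        swap_sets = list(c("mu_AB", "rho_B")))
  nb <- swap_neighbors(model_id("101", sp), sp)
  expect_equal(sorted_strings(nb), "011")  # rho_B replaces mu_AB
  # no swap and no critical sets: nothing to exchange
  sp0 <- parameter_space(c("a", "b"))
  expect_length(swap_neighbors(model_id("10", sp0), sp0), 0)
  # one swap set spanning all 4 parameters, 2 included: 2x2 exchanges
  sp4 <- parameter_space(paste0("p", 1:4),
                         swap_sets = list(paste0("p", 1:4)))
  nb4 <- swap_neighbors(model_id("1100", sp4), sp4)
  expect_equal(sorted_strings(nb4),
               sorted_strings(oracle_neighbors("1100", sp4, "swap")))
  expect_length(nb4, 4)
  # critical sets act as swap sets
  spc <- parameter_space(c("a", "b", "c"), critical_sets = list(c("a", "b")))
  expect_equal(sorted_strings(swap_neighbors(model_id("100", spc), spc)),
               "010")
})

test_that("neighbourhoods match the brute-force oracle on random spaces", {
  for (seed in 1:4) {
    sp <- random_space(n = 7, seed = seed)
    models <- enumerate_models(sp, valid_only = TRUE)
    set.seed(seed + 100)
    for (alpha in models[sample(length(models), 12)]) {
      for (method in c("forward", "backward", "swap")) {
        expect_equal(sorted_strings(neighbor_models(alpha, sp, method)),
                     sorted_strings(oracle_neighbors(alpha, sp, method)),
                     info = paste(model_string(alpha), method, seed))
      }
    }
  }
})

test_that("forward and backward moves are symmetric and all neighbors valid", {
  sp <- random_space(n = 8, seed = 9)
  models <- enumerate_models(sp, valid_only = TRUE)
  set.seed(1)
  for (alpha in models[sample(length(models), 15)]) {
    for (beta in forward_neighbors(alpha, sp)) {
      expect_equal(sum(beta != alpha), 1)
      if (is_valid_model(alpha, sp)) {
        back <- sorted_strings(backward_neighbors(beta, sp))
        expect_true(model_string(alpha) %in% back)
      }
    }
    for (beta in c(backward_neighbors(alpha, sp),
                   swap_neighbors(alpha, sp))) {
      expect_true(is_valid_model(beta, sp))
    }
    for (beta in swap_neighbors(alpha, sp)) {
      expect_equal(sum(beta != alpha), 2)
      expect_equal(sum(beta), sum(alpha))
    }
  }
})

test_that("model counting is exact", {
  expect_identical(count_models(16), 65535)
  expect_identical(count_models(25), 2^25 - 1)
  expect_gt(count_models(25), 3.3e7)
  expect_identical(count_models(1), 1)
  expect_error(count_models(0))
  expect_error(count_models(2.5))
})

test_that("most distant model maximizes the minimum Hamming distance", {
  sp <- parameter_space(paste0("p", 1:4), bounds = c(0, 1))
  # complement of the global model is empty, so distance 3 is the optimum;
  # canonical string order breaks the four-way tie
  md <- most_distant_model(list(model_id("1111", sp)), sp)
  expect_equal(model_string(md), "0001")
  sp2 <- parameter_space(c("a", "b"))
  md2 <- most_distant_model(c("10", "01"), sp2)
  expect_equal(model_string(md2), "11")  # brute force over the 3 valid models
  expect_error(most_distant_model(list(), sp), "at least one")
})

test_that("most distant model respects critical sets", {
  sp <- parameter_space(paste0("p", 1:5),
                        critical_sets = list(c("p1", "p2")))
  md <- most_distant_model(c("11111"), sp)
  expect_true(is_valid_model(md, sp))
})

test_that("heuristic hill climb reaches the exhaustive optimum", {
  for (seed in 1:5) {
    sp <- random_space(n = 12, seed = seed * 7)
    set.seed(seed)
    tested <- lapply(1:4, function(i) {
      stats::setNames(as.integer(runif(12) < 0.5), sp$parameters)
    })
    tested <- lapply(tested, function(a) {
      a[sp$critical_sets[[1]][1]] <- 1L
      a
    })
    ex <- most_distant_model(tested, sp, method = "exhaustive")
    set.seed(seed + 1)
    he <- most_distant_model(tested, sp, method = "heuristic",
                             restarts = 30)
    dist_to <- function(alpha) {
      min(vapply(tested, function(t) sum(t != alpha), 0))
    }
    expect_equal(dist_to(he), dist_to(ex), info = paste("seed", seed))
  }
})

test_that("excluded parameters resolve through inheritance chains", {
  sp <- proliferation_space()
  alpha <- model_id(c("rho_C0", "rho_C3", "delta_C0", "sigma_tilde"), sp)
  full <- resolve_parameters(alpha, c(rho_C0 = 0.04, rho_C3 = 0.2,
                                      delta_C0 = 0.01, sigma_tilde = 0.05),
                             sp)
  # generation chain: unfitted rates inherit the previous generation
  expect_equal(unname(full[c("rho_C1", "rho_C2")]), c(0.04, 0.04))
  expect_equal(unname(full[paste0("rho_C", 4:9)]), rep(0.2, 6))
  # no suspension rate selected: suspension copies collagen per generation
  expect_equal(unname(full[paste0("rho_S", 0:9)]),
               unname(full[paste0("rho_C", 0:9)]))
  expect_equal(unname(full[paste0("delta_S", 0:9)]), rep(0.01, 10))
  # unfitted adaptation times: tau_C defaults to 0 and tau_S follows it
  expect_equal(unname(full[c("tau_C", "tau_S")]), c(0, 0))
})

test_that("guarded rules switch the suspension chain on", {
  sp <- proliferation_space()
  alpha <- model_id(c("rho_C0", "delta_C0", "rho_S3", "sigma_tilde"), sp)
  full <- resolve_parameters(alpha, c(rho_C0 = 0.1, delta_C0 = 0.01,
                                      rho_S3 = 0.5, sigma_tilde = 0.05), sp)
  # below the first selected suspension generation: equal to collagen
  expect_equal(unname(full[paste0("rho_S", 0:2)]), rep(0.1, 3))
  # from it on: inherit down the suspension chain
  expect_equal(unname(full[paste0("rho_S", 3:9)]), rep(0.5, 7))
})

test_that("resolution handles literals, absent rules and bad input", {
  sp <- parameter_space(c("a", "b", "c"),
                        default_rules = list(b = 0.7),
                        fixed = c(c = 2.5))
  full <- resolve_parameters(model_id("100", sp), c(a = 1), sp)
  expect_equal(unname(full), c(1, 0.7, 2.5))
  sp2 <- parameter_space(c("a", "b"))
  full2 <- resolve_parameters(model_id("10", sp2), c(a = 3), sp2)
  expect_equal(unname(full2["b"]), 0)  # no rule: process off
  expect_error(resolve_parameters(model_id("10", sp2), c(b = 1), sp2),
               "misses")
  expect_error(resolve_parameters(model_id("11", sp2), c(a = 1, b = 2,
                                                         z = 3), sp2))
})

test_that("the precompiled resolver agrees with resolve_parameters", {
  sp <- proliferation_space()
  set.seed(4)
  for (i in 1:10) {
    alpha <- stepswap:::sample_valid_model(sp)
    inc <- included_parameters(alpha, sp)
    fv <- stats::setNames(runif(length(inc)), inc)
    expect_identical(stepswap:::make_resolver(alpha, sp)(fv),
                     resolve_parameters(alpha, fv, sp))
  }
})
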