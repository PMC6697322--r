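#' Define a combinatorial model space
#'
#' A parameter space describes the global model from which all candidate
#' sub-models are drawn. Every parameter of the global model occupies one
#' position of a binary inclusion vector; a sub-model switches each parameter
#' on (fitted) or off (resolved to a default value). Critical sets restrict
#' which sub-models are admissible, swap sets group structurally similar
#' parameters between which the swap move may exchange members, and default
#' rules state what value an excluded parameter takes.
#'
#' @param parameters character vector of unique parameter names, in the order
#'   used by all model identifiers.
#' @param critical_sets list of character vectors. A model is only admissible
#'   if it includes at least one member of every critical set.
#' @param swap_sets list of character vectors of mutually exchangeable
#'   parameters. All critical sets are additionally treated as swap sets when
#'   swap neighbourhoods are generated.
#' @param fixed named numeric vector of parameters that are never fitted;
#'   their inclusion bit is always 0 and they resolve to the given value.
#' @param default_rules named list giving, for each parameter, an ordered list
#'   of fallback entries used when the parameter is excluded from a model.
#'   Each entry is either a numeric literal, a character string naming another
#'   parameter whose resolved value is inherited, or
#'   `list(ref = "name", guard = c(...))` where the reference only applies if
#'   at least one member of `guard` is included in the model. The first
#'   applicable entry wins; a parameter without any applicable rule resolves
#'   to 0 (process switched off).
#' @param bounds box constraints used for fitting and random starting values.
#'   Either a single `c(lower, upper)` pair applied to every parameter, or a
#'   named list of such pairs (parameters not named fall back to
#'   `default_bounds`).
#' @param default_bounds the pair used for parameters without explicit bounds.
#'
#' @return An object of class `parameter_space`.
#' @examples
#' sp <- parameter_space(
#'   c("mu_AB", "mu_CB", "rho_B"),
#'   critical_sets = list(c("mu_AB", "mu_CB")),
#'   swap_sets = list(c("mu_AB", "rho_B"))
#' )
#' is_valid_model(c(1, 0, 0), sp)
#' @export
parameter_space <- function(parameters,
                            critical_sets = list(),
                            swap_sets = list(),
                            fixed = numeric(0),
                            default_rules = list(),
                            bounds = NULL,
                            default_bounds = c(0, 10)) {
  parameters <- as.character(parameters)
  if (length(parameters) < 1L) {
    stop("a parameter space needs at least one parameter")
  }
  if (anyDuplicated(parameters)) {
    stop("parameter names must be unique: ",
         paste(unique(parameters[duplicated(parameters)]), collapse = ", "))
  }
  check_members <- function(x, what) {
    bad <- setdiff(x, parameters)
    if (length(bad)) {
      stop(what, " references unknown parameter(s): ",
           paste(bad, collapse = ", "))
    }
  }
  critical_sets <- lapply(critical_sets, as.character)
  swap_sets <- lapply(swap_sets, as.character)
  for (s in critical_sets) check_members(s, "critical set")
  for (s in swap_sets) check_members(s, "swap set")
  if (length(fixed)) {
    if (is.null(names(fixed)) || any(!nzchar(names(fixed)))) {
      stop("'fixed' must be a named numeric vector")
    }
    check_members(names(fixed), "fixed values")
    in_crit <- intersect(names(fixed), unlist(critical_sets))
    if (length(in_crit)) {
      stop("parameter(s) both fixed and critical: ",
           paste(in_crit, collapse = ", "))
    }
  }
  rules <- normalize_rules(default_rules, parameters, check_members)
  check_rule_acyclic(rules, parameters)

  bmat <- matrix(rep(as.numeric(default_bounds), length(parameters)),
                 nrow = 2, dimnames = list(c("lower", "upper"), parameters))
  if (!is.null(bounds)) {
    if (is.numeric(bounds) && length(bounds) == 2L) {
      bmat[1, ] <- bounds[1]
      bmat[2, ] <- bounds[2]
    } else if (is.list(bounds)) {
      check_members(names(bounds), "bounds")
      for (nm in names(bounds)) bmat[, nm] <- as.numeric(bounds[[nm]])
    } else {
      stop("'bounds' must be a length-2 numeric or a named list")
    }
  }
  if (any(bmat["lower", ] >= bmat["upper", ])) {
    bad <- parameters[bmat["lower", ] >= bmat["upper", ]]
    stop("lower bound must be below upper bound for: ",
         paste(bad, collapse = ", "))
  }

  structure(
    list(parameters = parameters,
         critical_sets = critical_sets,
         swap_sets = swap_sets,
         fixed = fixed,
         default_rules = rules,
         bounds = bmat),
    class = "parameter_space"
  )
}

# Normalize default-rule entries to list(type=, value=/ref=, guard=).
normalize_rules <- function(default_rules, parameters, check_members) {
  if (length(default_rules) && (is.null(names(default_rules)) ||
                                any(!nzchar(names(default_rules))))) {
    stop("'default_rules' must be a named list")
  }
  check_members(names(default_rules), "default rules")
  out <- lapply(default_rules, function(rule) {
    if (is.numeric(rule) && length(rule) == 1L ||
        is.character(rule) && length(rule) == 1L ||
        (is.list(rule) && !is.null(rule$ref))) {
      rule <- list(rule)  # single entry, not wrapped
    }
    lapply(rule, function(entry) {
      if (is.numeric(entry) && length(entry) == 1L) {
        return(list(type = "literal", value = as.numeric(entry)))
      }
      if (is.character(entry) && length(entry) == 1L) {
        check_members(entry, "default-rule reference")
        return(list(type = "ref", ref = entry, guard = NULL))
      }
      if (is.list(entry) && !is.null(entry$ref)) {
        check_members(entry$ref, "default-rule reference")
        guard <- entry$guard
        if (!is.null(guard)) {
          guard <- as.character(guard)
          check_members(guard, "default-rule guard")
        }
        return(list(type = "ref", ref = as.character(entry$ref),
                    guard = guard))
      }
      stop("malformed default-rule entry: must be a number, a parameter ",
           "name, or list(ref=, guard=)")
    })
  })
  out
}

# The reference graph (ignoring guards) must be acyclic; this is sufficient
# for acyclicity under every possible model.
check_rule_acyclic <- function(rules, parameters) {
  state <- new.env(parent = emptyenv())
  visit <- function(p, stack) {
    if (p %in% stack) {
      stop("cyclic default-rule reference: ",
           paste(c(stack, p), collapse = " -> "))
    }
    if (isTRUE(state[[p]])) return(invisible())
    for (entry in rules[[p]]) {
      if (entry$type == "ref") visit(entry$ref, c(stack, p))
    }
    state[[p]] <- TRUE
    invisible()
  }
  for (p in names(rules)) visit(p, character(0))
  invisible()
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("Model space with", length(x$parameters), "parameters\n")
  cat("  parameters:   ", paste(utils::head(x$parameters, 8), collapse = ", "),
      if (length(x$parameters) > 8) ", ..." else "", "\n", sep = "")
  cat("  critical sets:", length(x$critical_sets), "\n")
  cat("  swap sets:    ", length(x$swap_sets), "\n")
  if (length(x$fixed)) cat("  fixed:        ",
                           paste(names(x$fixed), collapse = ", "), "\n")
  nsel <- length(x$parameters) - length(x$fixed)
  cat("  candidate sub-models: ", format(count_models(nsel), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Number of non-empty sub-models of a global model
#'
#' Each of the `n` selectable parameters is either included or excluded, and
#' the empty model is never evaluated, giving `2^n - 1` candidates.
#'
#' @param n_parameters number of selectable parameters (>= 1).
#' @return `2^n - 1` as a double holding an exact integer (exact up to
#'   `n = 53`).
#' @examples
#' count_models(16)  # 65535
#' @export
count_models <- function(n_parameters) {
  n <- n_parameters
  if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop("'n_parameters' must be a single integer >= 1")
  }
  2^n - 1
}

#' Model identifiers
#'
#' A sub-model is identified by a binary inclusion vector with one position
#' per parameter of the space, in parameter order; its canonical text form is
#' the left-to-right 0/1 string. `model_id()` accepts a 0/1 string, a logical
#' vector, a 0/1 numeric vector, or a character vector of included parameter
#' names, and returns the named integer inclusion vector.
#'
#' @param x model in any of the accepted forms.
#' @param space a [parameter_space()].
#' @return named integer vector of 0/1, one entry per parameter.
#' @examples
#' sp <- parameter_space(c("a", "b", "c"))
#' model_id("101", sp)
#' model_id(c("a", "c"), sp)
#' @export
model_id <- function(x, space) {
  n <- length(space$parameters)
  if (is.character(x) && length(x) == 1L && grepl("^[01]+$", x)) {
    x <- as.integer(strsplit(x, "")[[1]])
  } else if (is.character(x)) {
    bad <- setdiff(x, space$parameters)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    x <- as.integer(space$parameters %in% x)
  } else if (is.logical(x)) {
    x <- as.integer(x)
  } else if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("model identifier entries must be 0 or 1")
    x <- as.integer(x)
  } else {
    stop("cannot interpret 'x' as a model identifier")
  }
  if (length(x) != n) {
    stop("model identifier has length ", length(x),
         " but the space has ", n, " parameters")
  }
  if (length(space$fixed) && any(x[match(names(space$fixed),
                                         space$parameters)] == 1L)) {
    stop("fixed parameters cannot be included in a model")
  }
  names(x) <- space$parameters
  x
}

#' @rdname model_id
#' @param alpha a model inclusion vector.
#' @export
model_string <- function(alpha) paste(as.integer(alpha), collapse = "")

#' Names of the parameters included in a model
#' @inheritParams model_string
#' @param space a [parameter_space()].
#' @return character vector of included parameter names.
#' @export
included_parameters <- function(alpha, space) {
  space$parameters[as.integer(alpha) == 1L]
}

#' Is a model admissible?
#'
#' A model is admissible if it includes at least one parameter overall (the
#' empty model is never evaluated) and at least one member of every critical
#' set.
#'
#' @inheritParams model_id
#' @param alpha model inclusion vector (or any form accepted by [model_id()]).
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_model <- function(alpha, space) {
  alpha <- model_id(alpha, space)
  if (sum(alpha) == 0L) return(FALSE)
  for (s in space$critical_sets) {
    if (!any(alpha[s] == 1L)) return(FALSE)
  }
  TRUE
}

fixed_mask <- function(space) {
  space$parameters %in% names(space$fixed)
}

#' Neighbourhood generation for the three search moves
#'
#' `forward_neighbors()` adds one currently excluded parameter,
#' `backward_neighbors()` removes one currently included parameter, and
#' `swap_neighbors()` exchanges an included for an excluded parameter where
#' both belong to a common swap set (critical sets count as swap sets).
#' Candidates violating a critical set, the empty model, and duplicates are
#' dropped; the order of the returned list is deterministic.
#'
#' @inheritParams is_valid_model
#' @return list of model inclusion vectors.
#' @examples
#' sp <- parameter_space(c("a", "b", "c"))
#' forward_neighbors(model_id("100", sp), sp)
#' @export
forward_neighbors <- function(alpha, space) {
  alpha <- model_id(alpha, space)
  idx <- which(alpha == 0L & !fixed_mask(space))
  lapply(idx, function(i) { b <- alpha; b[i] <- 1L; b })
}

#' @rdname forward_neighbors
#' @export
backward_neighbors <- function(alpha, space) {
  alpha <- model_id(alpha, space)
  idx <- which(alpha == 1L)
  out <- lapply(idx, function(i) { b <- alpha; b[i] <- 0L; b })
  Filter(function(b) is_valid_model(b, space), out)
}

#' @rdname forward_neighbors
#' @export
swap_neighbors <- function(alpha, space) {
  alpha <- model_id(alpha, space)
  sets <- c(space$swap_sets, space$critical_sets)
  fixed <- fixed_mask(space)
  out <- list()
  seen <- character(0)
  for (s in sets) {
    pos <- match(s, space$parameters)
    ins <- pos[alpha[pos] == 1L]
    outs <- pos[alpha[pos] == 0L & !fixed[pos]]
    for (j in ins) {
      for (i in outs) {
        b <- alpha
        b[j] <- 0L
        b[i] <- 1L
        key <- model_string(b)
        if (!(key %in% seen) && is_valid_model(b, space)) {
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- b
        }
      }
    }
  }
  out
}

#' @rdname forward_neighbors
#' @param method one of `"forward"`, `"backward"`, `"swap"`.
#' @export
neighbor_models <- function(alpha, space,
                            method = c("forward", "backward", "swap")) {
  method <- match.arg(method)
  switch(method,
         forward = forward_neighbors(alpha, space),
         backward = backward_neighbors(alpha, space),
         swap = swap_neighbors(alpha, space))
}

#' Resolve a model to a full parameter vector
#'
#' Included parameters take their fitted values; excluded parameters take
#' their fixed value if fixed, otherwise the first applicable entry of their
#' default rule (guards are evaluated against the model, references are
#' resolved recursively), otherwise 0. This is how inheritance chains such as
#' "an unfitted generation rate inherits the previous generation's rate" are
#' expressed.
#'
#' @inheritParams is_valid_model
#' @param fitted_values named numeric vector covering exactly the included
#'   parameters.
#' @return named numeric vector over all parameters of the space.
#' @export
resolve_parameters <- function(alpha, fitted_values, space) {
  alpha <- model_id(alpha, space)
  inc <- space$parameters[alpha == 1L]
  if (is.null(names(fitted_values)) && length(fitted_values) == length(inc)) {
    names(fitted_values) <- inc
  }
  missing <- setdiff(inc, names(fitted_values))
  if (length(missing)) {
    stop("fitted_values misses included parameter(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(fitted_values), inc)
  if (length(extra)) {
    stop("fitted_values contains excluded parameter(s): ",
         paste(extra, collapse = ", "))
  }
  # fast path: no rules and nothing fixed, every excluded parameter is 0
  if (length(space$default_rules) == 0L && length(space$fixed) == 0L) {
    out <- stats::setNames(numeric(length(space$parameters)),
                           space$parameters)
    out[inc] <- as.numeric(fitted_values[inc])
    return(out)
  }
  out <- stats::setNames(rep(NA_real_, length(space$parameters)),
                         space$parameters)
  out[inc] <- as.numeric(fitted_values[inc])
  resolve_one <- function(p, stack) {
    if (!is.na(out[p])) return(out[p])
    if (p %in% stack) {
      stop("cyclic default-rule reference while resolving: ",
           paste(c(stack, p), collapse = " -> "))
    }
    val <- 0
    if (p %in% names(space$fixed)) {
      val <- space$fixed[[p]]
    } else {
      for (entry in space$default_rules[[p]]) {
        if (entry$type == "literal") {
          val <- entry$value
          break
        }
        applicable <- is.null(entry$guard) || any(alpha[entry$guard] == 1L)
        if (applicable) {
          val <- resolve_one(entry$ref, c(stack, p))
          break
        }
      }
    }
    out[p] <<- val
    val
  }
  for (p in space$parameters) resolve_one(p, character(0))
  out
}

# Precompiled resolver for one model: because guard applicability and
# reference chains depend only on the inclusion vector, each excluded
# parameter's value is either a constant or a copy of one included
# parameter's fitted value. Tracing this once per model turns each
# resolve into two vectorized assignments (hot path of fitting).
make_resolver <- function(alpha, space) {
  alpha <- model_id(alpha, space)
  pn <- space$parameters
  inc <- pn[alpha == 1L]
  template <- stats::setNames(numeric(length(pn)), pn)
  src <- stats::setNames(rep(NA_character_, length(pn)), pn)
  trace_one <- function(p, stack) {
    if (p %in% stack) {
      stop("cyclic default-rule reference while resolving: ",
           paste(c(stack, p), collapse = " -> "))
    }
    if (alpha[[p]] == 1L) return(list(kind = "free", ref = p))
    if (p %in% names(space$fixed)) {
      return(list(kind = "const", value = space$fixed[[p]]))
    }
    for (entry in space$default_rules[[p]]) {
      if (entry$type == "literal") {
        return(list(kind = "const", value = entry$value))
      }
      if (is.null(entry$guard) || any(alpha[entry$guard] == 1L)) {
        return(trace_one(entry$ref, c(stack, p)))
      }
    }
    list(kind = "const", value = 0)
  }
  for (p in pn) {
    tr <- trace_one(p, character(0))
    if (tr$kind == "const") template[p] <- tr$value else src[p] <- tr$ref
  }
  copy_to <- which(!is.na(src))
  copy_from <- src[copy_to]
  function(free_values) {
    out <- template
    out[copy_to] <- free_values[copy_from]
    out
  }
}

#' Model most distant from a set of already-tested models
#'
#' Returns an admissible model maximizing the minimum Hamming distance (over
#' selectable parameters) to every tested model. With at most 20 selectable
#' parameters the model space is enumerated exhaustively; above that a seeded
#' multi-restart bit-flip hill climb is used. Ties are broken by canonical
#' 0/1-string order. Used to restart a search in an unexplored region of the
#' model space.
#'
#' @param tested previously tested models: a character vector of 0/1 strings
#'   or a list of inclusion vectors; must be non-empty.
#' @param space a [parameter_space()].
#' @param restarts number of hill-climb restarts used in the heuristic regime.
#' @param method `"auto"` (exhaustive up to 20 selectable parameters, else
#'   heuristic) or an explicit choice of regime.
#' @return a model inclusion vector.
#' @export
most_distant_model <- function(tested, space, restarts = 20L,
                               method = c("auto", "exhaustive",
                                          "heuristic")) {
  method <- match.arg(method)
  if (length(tested) == 0L) stop("'tested' must contain at least one model")
  if (is.character(tested)) tested <- lapply(tested, model_id, space = space)
  tested <- lapply(tested, model_id, space = space)
  free <- which(!fixed_mask(space))
  nf <- length(free)
  tmat <- do.call(rbind, lapply(tested, function(a) as.integer(a[free])))
  crit_idx <- lapply(space$critical_sets,
                     function(s) match(match(s, space$parameters), free))
  to_full <- function(bits) {
    a <- stats::setNames(integer(length(space$parameters)), space$parameters)
    a[free] <- as.integer(bits)
    a
  }
  min_dist <- function(bits) min(colSums(abs(t(tmat) - bits)))
  bits_valid <- function(bits) {
    sum(bits) > 0L && all(vapply(crit_idx,
                                 function(ix) any(bits[ix] == 1L), TRUE))
  }

  exhaustive <- switch(method, auto = nf <= 20L,
                       exhaustive = TRUE, heuristic = FALSE)
  if (exhaustive) {
    if (nf > 24L) stop("exhaustive search infeasible for ", nf,
                       " selectable parameters")
    best_d <- -1L
    best_str <- NULL
    best_bits <- NULL
    total <- 2^nf - 1
    chunk <- 2^14
    pow <- 2^(seq_len(nf) - 1)
    done <- 0
    while (done < total) {
      ids <- seq(done + 1, min(done + chunk, total))
      done <- done + length(ids)
      bm <- sapply(pow, function(p) (ids %/% p) %% 2)
      if (is.null(dim(bm))) bm <- matrix(bm, nrow = 1)
      keep <- rep(TRUE, nrow(bm))
      for (ix in crit_idx) {
        keep <- keep & (rowSums(bm[, ix, drop = FALSE]) > 0)
      }
      if (!any(keep)) next
      bm <- bm[keep, , drop = FALSE]
      d <- bm %*% t(1 - 2 * tmat)
      d <- sweep(d, 2, rowSums(tmat), "+")
      md <- apply(d, 1, min)
      m <- max(md)
      if (m >= best_d) {
        rows <- which(md == m)
        strs <- apply(bm[rows, , drop = FALSE], 1, paste, collapse = "")
        o <- order(strs)[1]
        cand_str <- strs[o]
        if (m > best_d || cand_str < best_str) {
          best_d <- m
          best_str <- cand_str
          best_bits <- bm[rows[o], ]
        }
      }
    }
    if (is.null(best_bits)) stop("no admissible model exists in this space")
    return(to_full(best_bits))
  }

  # heuristic hill climb over single-bit flips
  best_d <- -1L
  best_str <- NULL
  best_bits <- NULL
  for (r in seq_len(restarts)) {
    bits <- as.integer(stats::runif(nf) < 0.5)
    for (ix in crit_idx) {
      if (!any(bits[ix] == 1L)) bits[ix[sample.int(length(ix), 1L)]] <- 1L
    }
    if (sum(bits) == 0L) bits[sample.int(nf, 1L)] <- 1L
    repeat {
      d0 <- min_dist(bits)
      improved <- FALSE
      for (k in seq_len(nf)) {
        cand <- bits
        cand[k] <- 1L - cand[k]
        if (!bits_valid(cand)) next
        if (min_dist(cand) > d0) {
          bits <- cand
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    d <- min_dist(bits)
    s <- paste(bits, collapse = "")
    if (d > best_d || (d == best_d && s < best_str)) {
      best_d <- d
      best_str <- s
      best_bits <- bits
    }
  }
  to_full(best_bits)
}
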