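#' Read and write model-space definition files
#'
#' A space is stored as a YAML document with keys `parameters`,
#' `critical_sets`, `swap_sets`, `fixed`, `default_rules` and `bounds`.
#' Default-rule entries are numbers (literals), strings (references), or
#' maps `{ref: name, guard: [names]}`. The round trip
#' `read_space_config(write_space_config(space))` reproduces the space in
#' canonical form; malformed files are rejected with the offending entry
#' named.
#'
#' @param space a [parameter_space()].
#' @param path file path.
#' @return `read_space_config()` returns a [parameter_space()];
#'   `write_space_config()` returns `path` invisibly.
#' @export
write_space_config <- function(space, path) {
  stopifnot(inherits(space, "parameter_space"))
  rules <- lapply(space$default_rules, function(rule) {
    lapply(rule, function(entry) {
      if (entry$type == "literal") return(entry$value)
      if (is.null(entry$guard)) return(list(ref = entry$ref))
      list(ref = entry$ref, guard = as.list(entry$guard))
    })
  })
  doc <- list(
    parameters = as.list(space$parameters),
    critical_sets = lapply(space$critical_sets, as.list),
    swap_sets = lapply(space$swap_sets, as.list),
    fixed = as.list(space$fixed),
    default_rules = rules,
    bounds = stats::setNames(
      lapply(space$parameters, function(p) as.list(space$bounds[, p])),
      space$parameters)
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_space_config
#' @export
read_space_config <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("cannot parse space config '", path, "': ", conditionMessage(e))
  })
  if (is.null(doc$parameters)) {
    stop("space config '", path, "' has no 'parameters' key")
  }
  rules <- lapply(doc$default_rules %||% list(), function(rule) {
    lapply(rule, function(entry) {
      if (is.list(entry) && !is.null(entry$ref)) {
        list(ref = entry$ref,
             guard = if (is.null(entry$guard)) NULL else
               unlist(entry$guard))
      } else {
        entry
      }
    })
  })
  fixed <- unlist(doc$fixed %||% list())
  bounds <- lapply(doc$bounds %||% list(), unlist)
  parameter_space(
    parameters = unlist(doc$parameters),
    critical_sets = lapply(doc$critical_sets %||% list(), unlist),
    swap_sets = lapply(doc$swap_sets %||% list(), unlist),
    fixed = if (length(fixed)) fixed else numeric(0),
    default_rules = rules,
    bounds = if (length(bounds)) bounds else NULL
  )
}

#' Write and read the evaluated-model history table
#'
#' Serializes every fitted model of a search (model string, criterion type
#' and value, -2 log-likelihood, parameter count, convergence flag, and one
#' column per parameter with its resolved value) as CSV. Numeric values are
#' written with 17 significant digits, so criterion values survive the round
#' trip bit for bit.
#'
#' @param x a `search_result`, `search_campaign`, or named list of fit
#'   records.
#' @param path file path.
#' @param space the [parameter_space()] the history belongs to (for
#'   reading).
#' @return `write_history_csv()` returns `path` invisibly;
#'   `read_history_csv()` returns a named list of fit records.
#' @export
write_history_csv <- function(x, path) {
  history <- if (inherits(x, c("search_result", "search_campaign"))) {
    x$history
  } else {
    x
  }
  stopifnot(length(history) > 0)
  pnames <- names(history[[1]]$alpha)
  num <- function(v) {
    ifelse(is.na(v), "NA", sprintf("%.17g", v))
  }
  rows <- lapply(history, function(r) {
    pv <- if (is.null(r$parameters)) rep(NA_real_, length(pnames)) else
      r$parameters[pnames]
    c(model = r$model, ic_type = r$ic_type, ic_value = num(r$ic_value),
      minus2LL = num(r$minus2LL), k = as.character(r$k),
      n = if (is.null(r$n)) "NA" else as.character(r$n),
      converged = as.character(r$converged),
      stats::setNames(num(pv), pnames))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_history_csv
#' @export
read_history_csv <- function(path, space) {
  df <- utils::read.csv(path, colClasses = c(model = "character"),
                        stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(df)), function(i) {
    alpha <- model_id(df$model[i], space)
    pv <- as.numeric(df[i, space$parameters])
    names(pv) <- space$parameters
    inc <- space$parameters[alpha == 1L]
    rec <- list(model = df$model[i], alpha = alpha,
                estimates = pv[inc], parameters = pv,
                minus2LL = as.numeric(df$minus2LL[i]), k = df$k[i],
                n = if (is.na(df$n[i])) NULL else df$n[i],
                ic_type = df$ic_type[i],
                ic_value = as.numeric(df$ic_value[i]),
                converged = as.logical(df$converged[i]),
                runs = NA_integer_, legs = NA_integer_,
                fevals = NA_integer_,
                failed = !is.finite(as.numeric(df$ic_value[i])))
    class(rec) <- "fit_record"
    rec
  })
  names(records) <- df$model
  records
}
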