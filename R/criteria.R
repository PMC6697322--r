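#' Information criteria on the -2 log-likelihood scale
#'
#' Computes the criterion used to compare fitted sub-models:
#' `AIC  = -2lnL + 2k`,
#' `AICc = AIC + 2k(k+1)/(n-k-1)` (small-sample correction),
#' `BIC  = -2lnL + k log(n)`.
#' Lower values indicate better support.
#'
#' @param minus2LL cost value on the -2 log-likelihood scale.
#' @param k number of fitted parameters.
#' @param n number of data points entering the likelihood. Required for AICc
#'   and BIC; for AICc it must exceed `k + 1` or the criterion is undefined.
#' @param ic_type one of `"AICc"`, `"AIC"`, `"BIC"`.
#' @return the criterion value.
#' @examples
#' information_criterion(10, k = 2, n = 10, ic_type = "AICc")
#' @export
information_criterion <- function(minus2LL, k, n = NULL,
                                  ic_type = c("AICc", "AIC", "BIC")) {
  ic_type <- match.arg(ic_type)
  if (k < 0 || k != floor(k)) stop("'k' must be a non-negative integer")
  if (ic_type != "AIC") {
    if (is.null(n) || is.na(n) || n < 1) {
      stop("'n' (number of data points) is required for ", ic_type)
    }
  }
  switch(ic_type,
         AIC = minus2LL + 2 * k,
         AICc = {
           if (n <= k + 1) {
             stop("AICc is undefined for n <= k + 1 (n = ", n,
                  ", k = ", k, ")")
           }
           minus2LL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
         },
         BIC = minus2LL + k * log(n))
}

#' Weighted least-squares cost for dye-dilution generation frequencies
#'
#' Twice the negative Gaussian log-likelihood (dropping the constant
#' `log(2*pi)` term) of model-predicted generation frequencies against
#' replicate means, with the empirical standard deviation of each data cell
#' inflated by a global additive factor `sigma_tilde` that accounts for the
#' small number of replicates:
#' \deqn{C = \sum_{t,i} \left(\frac{\bar y_i(t) - m_i(t)}{\sigma_i(t) +
#'   \tilde\sigma}\right)^2 + \sum_{t,i} \log\left((\sigma_i(t) +
#'   \tilde\sigma)^2\right).}
#' All arguments are summed over every cell present (time points, generations
#' and, if stacked, environments).
#'
#' @param means,sds,predictions numeric arrays of identical shape: replicate
#'   means, replicate standard deviations, and model predictions on the same
#'   (time, generation) grid.
#' @param sigma_tilde additive standard-deviation inflation (> -min(sds)).
#' @return the cost value (a -2 log-likelihood up to a constant).
#' @export
dye_dilution_cost <- function(means, sds, predictions, sigma_tilde) {
  if (length(means) != length(sds) || length(means) != length(predictions)) {
    stop("'means', 'sds' and 'predictions' must have identical shape")
  }
  s <- sds + sigma_tilde
  if (any(s <= 0)) {
    bad <- which(s <= 0)[1]
    stop("sigma + sigma_tilde must be positive everywhere; first offending ",
         "cell at position ", bad, " (sd = ", sds[bad],
         ", sigma_tilde = ", sigma_tilde, ")")
  }
  sum(((means - predictions) / s)^2) + sum(log(s^2))
}

#' Akaike weights and per-parameter support
#'
#' Converts the information-criterion values of a set of evaluated models into
#' relative model weights, `w_m = exp(-Delta_m/2) / sum exp(-Delta/2)` with
#' `Delta_m = IC_m - min IC`, and aggregates them into per-parameter support:
#' the summed weight of all models that include the parameter. Support close
#' to 1 marks a parameter the data consistently demand.
#'
#' @param records a list of fit records (as returned by [fit_submodel()] or
#'   stored in a search history), one per distinct model. Records with
#'   non-finite criterion values are dropped.
#' @return list with `models` (data frame: model string, ic, delta, weight)
#'   and `parameter_support` (named numeric, one entry per parameter).
#' @export
akaike_weights <- function(records) {
  if (inherits(records, "fit_record")) records <- list(records)
  if (length(records) == 0L) stop("'records' must contain at least one fit")
  ic <- vapply(records, function(r) as.numeric(r$ic_value), 0)
  keep <- is.finite(ic)
  if (!any(keep)) stop("no record has a finite criterion value")
  records <- records[keep]
  ic <- ic[keep]
  if (anyDuplicated(vapply(records, function(r) r$model, ""))) {
    stop("'records' must contain one record per distinct model")
  }
  delta <- ic - min(ic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  amat <- do.call(rbind, lapply(records, function(r) as.integer(r$alpha)))
  support <- as.numeric(t(amat) %*% w)
  pnames <- names(records[[1]]$alpha)
  if (!is.null(pnames)) names(support) <- pnames
  list(
    models = data.frame(
      model = vapply(records, function(r) r$model, ""),
      ic = ic, delta = delta, weight = w,
      stringsAsFactors = FALSE
    ),
    parameter_support = support
  )
}
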