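#' Exact Poisson (Garwood) confidence interval for a rate ratio
#'
#' Bounds on observed/expected when observed ~ Poisson(expected), treating
#' the expectation as fixed.
#'
#' @param observed non-negative integer count
#' @param expected positive expectation under neutrality
#' @param level confidence level (default 0.95)
#' @return numeric vector `c(low, high)`
#' @export
poisson_ratio_ci <- function(observed, expected, level = 0.95) {
  stopifnot(expected > 0, observed >= 0)
  a <- (1 - level) / 2
  low <- if (observed == 0) 0 else stats::qgamma(a, shape = observed) / expected
  high <- stats::qgamma(1 - a, shape = observed + 1) / expected
  c(low = low, high = high)
}

#' Two-sided exact Poisson p-value
#'
#' Doubles the smaller tail probability of `observed` under
#' Poisson(`expected`), capped at 1.
#'
#' @inheritParams poisson_ratio_ci
#' @return p-value in (0, 1]
#' @export
poisson_p_two_sided <- function(observed, expected) {
  stopifnot(expected > 0, observed >= 0)
  lower <- stats::ppois(observed, expected)
  upper <- stats::ppois(observed - 1, expected, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Upper-tail exact Poisson p-value, P(X >= observed)
#' @inheritParams poisson_ratio_ci
#' @export
poisson_p_upper <- function(observed, expected) {
  stopifnot(expected >= 0, observed >= 0)
  if (observed == 0) return(1)
  stats::ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Round half away from zero
#'
#' `round()` in R rounds halves to even; driver-count selection uses the
#' plain half-up rule so that an excess of 2.5 selects 3 mutations.
#'
#' @param x numeric vector
#' @return integer vector
#' @export
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Assemble a selection-result row
#' @noRd
selection_row <- function(gene, mclass, scope, observed, expected, level = 0.95) {
  if (!is.finite(expected) || expected <= 0) {
    return(tibble::tibble(
      gene = gene, mclass = mclass, scope = scope,
      observed = as.integer(observed), expected = expected,
      dnds = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p_value = NA_real_, driver_excess = NA_real_, driver_fraction = NA_real_
    ))
  }
  ci <- poisson_ratio_ci(observed, expected, level)
  excess <- max(observed - expected, 0)
  tibble::tibble(
    gene = gene, mclass = mclass, scope = scope,
    observed = as.integer(observed), expected = expected,
    dnds = observed / expected,
    ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
    p_value = poisson_p_two_sided(observed, expected),
    driver_excess = excess,
    driver_fraction = if (observed > 0) excess / observed else 0
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
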