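#' Beneficial-mutation fitness spectra as generative objects
#'
#' A DFE (distribution of fitness effects) model is a list of components, each
#' contributing beneficial mutations at a per-cell per-generation rate with a
#' fitness coefficient drawn from the component's law. Two component kinds are
#' supported: a point mass (e.g. autodiploidization, which behaves as a single
#' adaptive "mutation" with s around 0.03-0.045 per generation) and a truncated
#' exponential tail of spontaneous beneficial mutations.
#'
#' @param rate Mutation rate of the component, mutations per cell per
#'   generation. Must be >= 0.
#' @param s Fitness coefficient (per generation) of the point mass. Must be > 0.
#' @param mean_s Mean fitness coefficient of the (untruncated) exponential tail
#'   measured from `s_min`: draws are `s_min + Exp(mean_s - s_min)`, truncated
#'   at `s_max` by inverse-CDF sampling.
#' @param s_min,s_max Truncation bounds of the tail (per generation), ordered.
#'
#' @return `dfe_point()` and `dfe_tail()` return single component lists;
#'   `dfe_model()` collects components into an object of class `"dfe_model"`.
#'   A one-row-per-component tibble view is available through [tidy()].
#'
#' @examples
#' dfe <- dfe_model(dfe_point(rate = 1e-5, s = 0.035),
#'                  dfe_tail(rate = 1e-5, mean_s = 0.03, s_min = 0.02, s_max = 0.16))
#' dfe_total_rate(dfe)
#' @export
dfe_model <- function(...) {
  components <- list(...)
  if (length(components) == 1L && is.null(components[[1]])) components <- list()
  for (cmp in components) {
    if (!is.list(cmp) || is.null(cmp$kind)) {
      stop_lineagedfe("dfe_model() components must be built with dfe_point() or dfe_tail()")
    }
  }
  structure(list(components = components), class = "dfe_model")
}

#' @rdname dfe_model
#' @export
dfe_point <- function(rate, s) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  if (!is.numeric(s) || length(s) != 1L || s <= 0) {
    stop_lineagedfe("point-mass fitness `s` must be a single positive number")
  }
  list(kind = "point", rate = rate, s0 = s, s_min = s, s_max = s)
}

#' @rdname dfe_model
#' @export
dfe_tail <- function(rate, mean_s, s_min, s_max) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  if (s_min <= 0 || s_max <= s_min) {
    stop_lineagedfe("tail truncation bounds must satisfy 0 < s_min < s_max")
  }
  if (mean_s <= s_min) {
    stop_lineagedfe("tail `mean_s` must exceed `s_min`")
  }
  list(kind = "exponential_tail", rate = rate, s0 = mean_s, s_min = s_min, s_max = s_max)
}

#' @rdname dfe_model
#' @export
dfe_total_rate <- function(dfe) {
  sum(vapply(dfe$components, function(cmp) cmp$rate, numeric(1)))
}

#' Draw fitness coefficients from a DFE model
#'
#' Component identity is chosen proportionally to component rates, then the
#' fitness coefficient is drawn from that component (degenerate for a point
#' mass; truncated-exponential inverse CDF for a tail).
#'
#' @param dfe A [dfe_model()].
#' @param n Number of draws.
#' @return Numeric vector of `n` selection coefficients (per generation).
#' @export
dfe_sample <- function(dfe, n) {
  if (n == 0L) return(numeric(0))
  rates <- vapply(dfe$components, function(cmp) cmp$rate, numeric(1))
  if (length(rates) == 0L || sum(rates) <= 0) {
    stop_lineagedfe("cannot sample from a DFE with zero total rate")
  }
  idx <- sample.int(length(rates), n, replace = TRUE, prob = rates)
  out <- numeric(n)
  for (k in seq_along(dfe$components)) {
    sel <- idx == k
    if (!any(sel)) next
    cmp <- dfe$components[[k]]
    if (cmp$kind == "point") {
      out[sel] <- cmp$s0
    } else {
      # inverse CDF of Exp(mean = s0 - s_min) truncated to [0, s_max - s_min]
      scale <- cmp$s0 - cmp$s_min
      pmax_ <- 1 - exp(-(cmp$s_max - cmp$s_min) / scale)
      u <- runif(sum(sel)) * pmax_
      out[sel] <- cmp$s_min - scale * log(1 - u)
    }
  }
  out
}

#' @export
tidy.dfe_model <- function(x, ...) {
  purrr::map_dfr(x$components, ~ tibble::tibble(
    kind = .x$kind, rate = .x$rate, s0 = .x$s0, s_min = .x$s_min, s_max = .x$s_max
  ))
}

#' @export
print.dfe_model <- function(x, ...) {
  cat("<dfe_model> total rate", format(dfe_total_rate(x), digits = 3),
      "per cell per generation\n")
  print(tidy(x))
  invisible(x)
}
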