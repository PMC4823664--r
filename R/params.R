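#' Odor-receptor response parameters
#'
#' An `odor` object bundles the three parameters that identify the sigmoidal
#' dose-response curve of one OSN type to one odorant: the Hill coefficient
#' `n` (a property of the odor-receptor pair, not of the neuron alone), the
#' efficacy `eta` which sets the asymptote relative to the shared maximal
#' response, and the midpoint concentration `K`. The inverse concentration
#' scale `s = 1/K` is carried alongside, because the odor-space algebra
#' (composition, scaling, embedding) is naturally expressed in terms of the
#' triple `(n, eta, s)`.
#'
#' @param n Hill coefficient (dimensionless, > 0). Steepness of the curve.
#' @param eta Efficacy (dimensionless, > 0). Controls the asymptote
#'   `F_max * eta^n / (1 + eta^n)`.
#' @param K Midpoint concentration (> 0), in whatever concentration unit the
#'   analysis uses. Exactly one of `K` and `s` must be given.
#' @param s Inverse concentration scale, `s = 1/K` (> 0).
#' @param name Optional odor name used in printed output and tables.
#'
#' @return An object of class `odor`: a list with fields `n`, `eta`, `K`,
#'   `s` and `name`, with `s * K == 1` exactly.
#' @examples
#' men <- odor(n = 1.5, eta = 1.7, K = 0.2, name = "demo")
#' men
#' @export
odor <- function(n, eta, K = NULL, s = NULL, name = NULL) {
  if (is.null(K) && is.null(s)) stop("one of `K` or `s` must be supplied", call. = FALSE)
  if (!is.null(K) && !is.null(s) && abs(s * K - 1) > 1e-12 * max(1, abs(s * K))) {
    stop("`K` and `s` are inconsistent: s * K must equal 1", call. = FALSE)
  }
  if (is.null(s)) s <- 1 / K
  if (is.null(K)) K <- 1 / s
  for (val in list(n = n, eta = eta, K = K, s = s)) {
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop("odor parameters must be single finite positive numbers", call. = FALSE)
    }
  }
  structure(list(n = n, eta = eta, K = K, s = s, name = name), class = "odor")
}

#' @export
print.odor <- function(x, ...) {
  nm <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  cat(sprintf("<odor%s> n = %g, eta = %g, K = %g (s = %g)\n", nm, x$n, x$eta, x$K, x$s))
  invisible(x)
}

#' @export
format.odor <- function(x, ...) {
  sprintf("odor(n = %g, eta = %g, K = %g)", x$n, x$eta, x$K)
}

is_odor <- function(x) inherits(x, "odor")

as_odor <- function(x) {
  if (is_odor(x)) return(x)
  if (is.list(x) || is.data.frame(x)) {
    x <- as.list(x)
    if (!is.null(x$n) && !is.null(x$eta) && (!is.null(x$K) || !is.null(x$s))) {
      return(odor(n = x$n, eta = x$eta, K = x$K %||% NULL, s = x$s %||% NULL,
                  name = if (is.null(x$name)) NULL else as.character(x$name)))
    }
  }
  stop("cannot interpret object as an odor parameter set", call. = FALSE)
}

#' Convert odors to a parameter tibble
#'
#' @param x An `odor` or list of odors.
#' @param ... Unused.
#' @return A tibble with one row per odor and columns `name`, `n`, `eta`,
#'   `K`, `s`.
#' @export
odor_table <- function(x, ...) {
  odors <- if (is_odor(x)) list(x) else lapply(x, as_odor)
  tibble::tibble(
    name = purrr::map_chr(odors, function(o) o$name %||% NA_character_),
    n = purrr::map_dbl(odors, "n"),
    eta = purrr::map_dbl(odors, "eta"),
    K = purrr::map_dbl(odors, "K"),
    s = purrr::map_dbl(odors, "s")
  )
}

#' Legacy shared-Hill-coefficient parameter sets
#'
#' Parameters for the two earlier mixture models kept here as baselines: the
#' competitive syntopic model with per-odor asymptote `F_M` (`rospars`), and
#' the shared-`F_max` efficacy model (`cruz_lowe`). Both use a single Hill
#' coefficient common to all odors sensed by the neuron.
#'
#' @param K Midpoint concentration (> 0).
#' @param F_M Per-odor asymptote, used by the `rospars` model only.
#' @param eta Efficacy, used by the `cruz_lowe` model only.
#' @param name Optional odor name.
#' @return An object of class `legacy_odor`.
#' @export
legacy_odor <- function(K, F_M = NULL, eta = NULL, name = NULL) {
  stopifnot(is.numeric(K), length(K) == 1L, is.finite(K), K > 0)
  if (!is.null(F_M)) stopifnot(is.finite(F_M), F_M > 0)
  if (!is.null(eta)) stopifnot(is.finite(eta), eta > 0)
  structure(list(K = K, F_M = F_M, eta = eta, name = name), class = "legacy_odor")
}

check_conc <- function(conc) {
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  conc
}

check_f_max <- function(f_max) {
  if (!is.numeric(f_max) || length(f_max) != 1L || !is.finite(f_max) || f_max <= 0) {
    stop("`f_max` must be a single positive number", call. = FALSE)
  }
  f_max
}

`%||%` <- function(a, b) if (is.null(a)) b else a
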