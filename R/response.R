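#' Single-odor dose-response
#'
#' Evaluates the generalized Hill response of one OSN type to a single odor,
#' \deqn{F(X) = \frac{F_{max}}{1 + \left(\frac{1 + sX}{\eta\, sX}\right)^{n}},}
#' with `s = 1/K`. The curve is zero at zero concentration, strictly
#' increasing, and saturates at `F_max * eta^n / (1 + eta^n) < F_max`, so the
#' efficacy `eta` sets a per-odor asymptote under a shared physiological
#' ceiling `F_max`. The exponent is evaluated in log space, so Hill
#' coefficients up to the tens (as observed for steep odor responses) do not
#' overflow.
#'
#' @param params An [odor()] parameter set (or anything coercible: a list or
#'   one-row data frame with `n`, `eta` and `K` or `s`).
#' @param conc Concentration vector (>= 0), in the same units as `K`.
#' @param f_max Shared maximal physiological response. Defaults to 1
#'   (normalized responses).
#' @return Numeric vector of responses in `[0, f_max)`.
#' @examples
#' u <- odor(n = 3.6, eta = 1.7, K = 3.16e-4)
#' single_response(u, 10^seq(-6, -2, length.out = 5))
#' @seealso [mixture_response()], [response_curve()]
#' @export
single_response <- function(params, conc, f_max = 1) {
  p <- as_odor(params)
  check_conc(conc)
  check_f_max(f_max)
  hill_eval(conc * p$s, p$n, p$eta, f_max)
}

# core sigmoid on the dimensionless scale z = s * X; log-space exponentiation
hill_eval <- function(z, n, eta, f_max) {
  out <- numeric(length(z))
  pos <- z > 0
  logq <- log1p(z[pos]) - log(z[pos]) - log(eta)
  out[pos] <- f_max / (1 + exp(n * logq))
  out
}

#' Single-odor curve as a table
#'
#' Convenience wrapper returning a tibble, ready for plotting or export.
#'
#' @inheritParams single_response
#' @return A tibble with columns `conc` and `response`.
#' @export
response_curve <- function(params, conc, f_max = 1) {
  p <- as_odor(params)
  tibble::tibble(
    odor = p$name %||% NA_character_,
    conc = as.numeric(conc),
    response = single_response(p, conc, f_max)
  )
}

#' Asymptote of a single-odor curve
#'
#' @inheritParams single_response
#' @return `f_max * eta^n / (1 + eta^n)`, the limiting response.
#' @export
response_asymptote <- function(params, f_max = 1) {
  p <- as_odor(params)
  check_f_max(f_max)
  f_max / (1 + exp(-p$n * log(p$eta)))
}

#' Legacy dose-response models
#'
#' The two earlier formulations kept as baselines. `model = "rospars"` is the
#' competitive syntopic form with per-odor asymptote,
#' \deqn{F = \frac{\sum_i F_{Mi} (c_i/K_i)^n}{1 + \sum_i (c_i/K_i)^n},}
#' and `model = "cruz_lowe"` is the shared-ceiling efficacy form
#' \deqn{F = \frac{F_{max}}{1 + \left(\frac{1 + \sum_i c_i/K_i}
#'   {\sum_i \eta_i c_i/K_i}\right)^{n}}.}
#' Both use one Hill coefficient `n` for every odor sensed by the neuron; as a
#' consequence their mixture asymptote always lies between the single-odor
#' asymptotes, so neither can produce synergy or inhibition near the maximal
#' response. With a single component the `cruz_lowe` form coincides with
#' [single_response()] for the same parameter values.
#'
#' @param params A [legacy_odor()] (single odor) or list of them (mixture).
#' @param conc Concentration vector (single odor) or a list/matrix of
#'   per-component concentrations matching `params`.
#' @param model `"rospars"` or `"cruz_lowe"`.
#' @param n Shared Hill coefficient (> 0).
#' @param f_max Shared maximal response (used by `cruz_lowe`).
#' @return Numeric response vector.
#' @export
legacy_response <- function(params, conc, model = c("rospars", "cruz_lowe"),
                            n = 1, f_max = 1) {
  model <- match.arg(model)
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n), n > 0)
  if (inherits(params, "legacy_odor")) params <- list(params)
  conc <- legacy_conc_matrix(conc, length(params))
  apply(conc, 1L, function(cc) legacy_eval(params, cc, model, n, f_max))
}

legacy_conc_matrix <- function(conc, n_comp) {
  if (is.matrix(conc)) {
    if (ncol(conc) != n_comp) stop("concentration columns must match components", call. = FALSE)
    check_conc(conc)
    return(conc)
  }
  if (is.list(conc)) conc <- do.call(cbind, conc)
  else conc <- matrix(conc, ncol = n_comp)
  if (ncol(conc) != n_comp) stop("concentration columns must match components", call. = FALSE)
  check_conc(conc)
  conc
}

legacy_eval <- function(params, cc, model, n, f_max) {
  z <- vapply(seq_along(params), function(i) cc[i] / params[[i]]$K, numeric(1))
  if (model == "rospars") {
    fm <- vapply(params, function(p) {
      if (is.null(p$F_M)) stop("rospars model requires `F_M` for every odor", call. = FALSE)
      p$F_M
    }, numeric(1))
    if (all(z == 0)) return(0)
    # log-space scaling keeps z^n finite for steep curves at high concentration
    a <- ifelse(z > 0, n * log(z), -Inf)
    m <- max(a)
    w <- exp(a - m)
    sum(fm * w) / (exp(-m) + sum(w))
  } else {
    eta <- vapply(params, function(p) {
      if (is.null(p$eta)) stop("cruz_lowe model requires `eta` for every odor", call. = FALSE)
      p$eta
    }, numeric(1))
    check_f_max(f_max)
    S <- sum(z); H <- sum(eta * z)
    if (H == 0) return(0)
    f_max / (1 + exp(n * (log1p(S) - log(H))))
  }
}
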