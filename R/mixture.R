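#' Mixture dose-response
#'
#' Evaluates the OSN response to a mixture of N odorants with odor-specific
#' Hill coefficients. Writing \eqn{z_i = s_i c_i} for each component, the
#' response is
#' \deqn{F = \frac{F_{max}}{1 + \left(\frac{1 + S}{H}\right)^{N/H}}, \quad
#'   S = \sum_i z_i,\; H = \sum_i \eta_i z_i,\; N = \sum_i n_i \eta_i z_i.}
#' This is the unique formulation (within the efficacy-Hill family) that
#' satisfies the self-mixture consistency \eqn{F_{U+U}(U,U) = F_U(2U)},
#' reduces to the shared-coefficient Cruz-Lowe model when all \eqn{n_i} are
#' equal, and composes linearly under the \eqn{(n\eta s, \eta s, s)}
#' embedding. It is symmetric under permutation of the components and reduces
#' exactly to [single_response()] for one component.
#'
#' @param odors A list of [odor()] parameter sets (length N >= 1).
#' @param conc Per-component concentrations: a numeric vector of length N, a
#'   matrix with N columns (one row per evaluation point), or a list of N
#'   equal-length vectors.
#' @param f_max Shared maximal physiological response.
#' @return Numeric vector of mixture responses in `[0, f_max)`.
#' @examples
#' u <- odor(n = 3.6, eta = 1.7, K = 3.16e-4)
#' v <- odor(n = 19.6, eta = 1.1, K = 1e-4)
#' mixture_response(list(u, v), c(1e-4, 1e-4))
#' @export
mixture_response <- function(odors, conc, f_max = 1) {
  if (is_odor(odors)) odors <- list(odors)
  odors <- lapply(odors, as_odor)
  if (length(odors) < 1L) stop("at least one component is required", call. = FALSE)
  conc <- legacy_conc_matrix(conc, length(odors))
  check_f_max(f_max)
  n <- vapply(odors, `[[`, numeric(1), "n")
  eta <- vapply(odors, `[[`, numeric(1), "eta")
  s <- vapply(odors, `[[`, numeric(1), "s")
  z <- sweep(conc, 2L, s, `*`)
  S <- rowSums(z)
  H <- rowSums(sweep(z, 2L, eta, `*`))
  N <- rowSums(sweep(z, 2L, n * eta, `*`))
  out <- numeric(nrow(z))
  pos <- H > 0
  out[pos] <- f_max / (1 + exp((N[pos] / H[pos]) * (log1p(S[pos]) - log(H[pos]))))
  out
}

#' Effective sigmoid of a fixed-ratio mixture
#'
#' A mixture whose components are held at a fixed concentration ratio traces
#' a sigmoid of the same family as a single odor. For a binary mixture with
#' `U = r * V`, parameterized by the concentration of `V`, the effective
#' triple is the odor-space composition of `V` with `U` scaled by `r`:
#' \deqn{s_{eff} = r s_U + s_V,\quad
#'   \eta_{eff} = \frac{r \eta_U s_U + \eta_V s_V}{s_{eff}},\quad
#'   n_{eff} = \frac{r n_U \eta_U s_U + n_V \eta_V s_V}
#'                  {r \eta_U s_U + \eta_V s_V}.}
#' Evaluating the returned [odor()] at `V` equals [mixture_response()] at
#' `(rV, V)` exactly. With `r = 0` the result is `V` itself.
#'
#' @param U,V [odor()] parameter sets.
#' @param r Concentration ratio (>= 0) defining the ray `U = r * V`.
#' @return An [odor()] holding the effective parameters
#'   `(n_eff, eta_eff, K_eff)`.
#' @export
effective_fixed_ratio <- function(U, V, r) {
  U <- as_odor(U); V <- as_odor(V)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r >= 0)
  if (r == 0) return(V)
  odor_compose(odor_scale(U, r), V)
}

#' Fixed-ratio mixture of N components
#'
#' Generalization of [effective_fixed_ratio()]: the effective sigmoid of a
#' mixture whose component concentrations are `weights * X` as the common
#' scale `X` varies.
#'
#' @param odors List of [odor()] sets.
#' @param weights Non-negative ratio weights, at least one positive.
#' @return The effective [odor()].
#' @export
mix_fixed_ratio <- function(odors, weights) {
  odors <- lapply(odors, as_odor)
  stopifnot(length(weights) == length(odors), all(is.finite(weights)), all(weights >= 0))
  keep <- weights > 0
  if (!any(keep)) stop("at least one component must have positive weight", call. = FALSE)
  parts <- purrr::map2(odors[keep], weights[keep], odor_scale)
  purrr::reduce(parts, odor_compose)
}

#' Summary features of a sigmoidal response curve
#'
#' Reports the three experimentally measurable characteristics of a response
#' curve in this family: the asymptote
#' \eqn{a = F_{max}\,\eta^n/(1+\eta^n)}, the midpoint (the concentration at
#' half the asymptote, available in closed form as
#' \eqn{m = 1/(s(\eta q - 1))} with \eqn{q = ((2+\eta^n)/\eta^n)^{1/n}}), and
#' the steepness, reported as the Hill coefficient of the (effective) curve.
#' For a fixed-ratio mixture pass the result of [effective_fixed_ratio()].
#'
#' @param params An [odor()] (or effective sigmoid from
#'   [effective_fixed_ratio()]).
#' @param f_max Shared maximal response.
#' @return A one-row tibble with columns `asymptote`, `midpoint`,
#'   `steepness`.
#' @export
curve_summary <- function(params, f_max = 1) {
  p <- as_odor(params)
  check_f_max(f_max)
  a <- response_asymptote(p, f_max)
  # response(m) = a/2  =>  ((1+z)/(eta z))^n = (2 + eta^n)/eta^n, solved for z;
  # q = ((2+h)/h)^(1/n) computed as exp(log1p(2/h)/n) to stay finite for large n
  q <- exp(log1p(2 * exp(-p$n * log(p$eta))) / p$n)
  if (!is.finite(q) || p$eta * q <= 1) {
    # numerical fallback for extreme parameters
    f <- function(x) single_response(p, x, f_max) - a / 2
    m <- stats::uniroot(f, lower = p$K * 1e-12, upper = p$K * 1e12, tol = 1e-14)$root
  } else {
    m <- 1 / (p$s * (p$eta * q - 1))
  }
  tibble::tibble(asymptote = a, midpoint = m, steepness = p$n)
}

#' Can a same-ratio mixture show synergy at this concentration?
#'
#' Under the fixed-ratio (same dilution) paradigm, in which all three curves
#' are compared on a common concentration axis, the mixture response cannot
#' exceed both single-odor responses at axis concentrations below the
#' midpoint of the component with the lower Hill coefficient (its
#' half-asymptote concentration, see [curve_summary()]). This analytic
#' feasibility bound lets one rule out synergy without classifying the full
#' curve.
#'
#' @param U,V [odor()] parameter sets.
#' @param conc Concentration (vector allowed) on the shared plotting axis,
#'   in the units of `K`.
#' @param f_max Shared maximal response.
#' @return Logical vector: `TRUE` where synergy is feasible (concentration at
#'   or above the bound), `FALSE` below it.
#' @export
synergy_feasible <- function(U, V, conc, f_max = 1) {
  U <- as_odor(U); V <- as_odor(V)
  check_conc(conc)
  low <- if (U$n <= V$n) U else V
  conc >= curve_summary(low, f_max)$midpoint
}

#' Predict a mixture measured at a shared dilution
#'
#' Adapter for the protocol in which both odorants are presented at the same
#' dilution `d` of their saturated vapor, so the gas-phase concentrations are
#' `c_U = d * svp_U` and `c_V = d * svp_V` (svp = saturated-vapor-phase
#' molarity). This is a fixed-ratio mixture with `r = svp_U / svp_V`.
#'
#' @param U,V [odor()] parameter sets.
#' @param svp_U,svp_V Saturated-vapor molarity of each odorant (> 0), in the
#'   concentration units of `K`.
#' @param dilutions Vector of dilution factors (>= 0).
#' @param f_max Shared maximal response.
#' @param abscissa `"total"` (default) tabulates the curve against the total
#'   mixture concentration `d * (svp_U + svp_V)`; `"dilution"` against `d`.
#' @return A tibble with columns `dilution`, `conc_U`, `conc_V`, `conc`
#'   (the plotting abscissa, per `abscissa`) and `response`, carrying the
#'   abscissa convention in attribute `"abscissa"`.
#' @export
predict_same_dilution <- function(U, V, svp_U, svp_V, dilutions, f_max = 1,
                                  abscissa = c("total", "dilution")) {
  U <- as_odor(U); V <- as_odor(V)
  abscissa <- match.arg(abscissa)
  for (sv in c(svp_U, svp_V)) {
    if (!is.numeric(sv) || length(sv) != 1L || !is.finite(sv) || sv <= 0) {
      stop("saturated-vapor molarities must be single positive numbers", call. = FALSE)
    }
  }
  check_conc(dilutions)
  cU <- dilutions * svp_U
  cV <- dilutions * svp_V
  resp <- mixture_response(list(U, V), cbind(cU, cV), f_max)
  out <- tibble::tibble(
    dilution = as.numeric(dilutions),
    conc_U = cU, conc_V = cV,
    conc = if (abscissa == "total") cU + cV else as.numeric(dilutions),
    response = resp
  )
  attr(out, "abscissa") <- abscissa
  out
}

#' Predict a mixture with one odor at a fixed background
#'
#' Adapter for the protocol in which the concentration of odor `U` is swept
#' while odor `V` is held at a fixed background concentration. At zero
#' background this is the single-odor curve of `U`; at zero `U` it is the
#' constant response of `V` at the background.
#'
#' @param U,V [odor()] parameter sets.
#' @param background Fixed concentration of `V` (>= 0).
#' @param conc Concentration sweep for `U` (>= 0).
#' @param f_max Shared maximal response.
#' @return A tibble with columns `conc` (of `U`), `conc_background` and
#'   `response`.
#' @export
predict_fixed_background <- function(U, V, background, conc, f_max = 1) {
  U <- as_odor(U); V <- as_odor(V)
  stopifnot(is.numeric(background), length(background) == 1L,
            is.finite(background), background >= 0)
  check_conc(conc)
  resp <- mixture_response(list(U, V), cbind(conc, rep(background, length(conc))), f_max)
  tibble::tibble(conc = as.numeric(conc), conc_background = background,
                 response = resp)
}
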