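#' Generate a synthetic dose-response table
#'
#' Draws a noisy dose-response fixture from the single-odor model:
#' concentrations on a log-spaced grid, responses perturbed by
#' multiplicative Gaussian noise with coefficient of variation `noise`,
#' truncated to `[0, f_max]`. With `noise = 0` the table reproduces the
#' model curve exactly; with a fixed `seed` the draw is bit-reproducible.
#' The default grid -- 12 log-spaced points over 4 decades centered on the
#' midpoint `K` -- mirrors the sampling density of typical OSN
#' dose-response recordings.
#'
#' @param params An [odor()] parameter set.
#' @param conc Optional concentration grid; defaults to
#'   `n_points` log-spaced points over `decades` decades centered on `K`.
#' @param n_points,decades Grid design when `conc` is not given.
#' @param noise Multiplicative Gaussian coefficient of variation (>= 0).
#' @param seed Integer seed.
#' @param f_max Shared maximal response.
#' @return A tibble with columns `conc` and `response`, plus attribute
#'   `"params"` holding the generating odor.
#' @examples
#' generate_curve(odor(n = 1.5, eta = 1.7, K = 0.2), noise = 0.05, seed = 7)
#' @export
generate_curve <- function(params, conc = NULL, n_points = 12, decades = 4,
                           noise = 0, seed = 1, f_max = 1) {
  p <- as_odor(params)
  stopifnot(is.numeric(noise), length(noise) == 1L, is.finite(noise), noise >= 0)
  if (is.null(conc)) {
    if (n_points < 3L) stop("at least 3 grid points are required", call. = FALSE)
    conc <- 10^seq(log10(p$K) - decades / 2, log10(p$K) + decades / 2,
                   length.out = n_points)
  }
  check_conc(conc)
  if (length(conc) < 3L) stop("at least 3 grid points are required", call. = FALSE)
  mu <- single_response(p, conc, f_max)
  if (noise > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(as.integer(seed) %% .Machine$integer.max)
    resp <- mu * (1 + noise * stats::rnorm(length(mu)))
    resp <- pmin(pmax(resp, 0), f_max)
  } else {
    resp <- mu
  }
  out <- tibble::tibble(conc = as.numeric(conc), response = resp)
  attr(out, "params") <- p
  out
}

#' Built-in demonstration parameter sets
#'
#' The printed parameter sets used throughout the package's examples and
#' tests: six binary-mixture sets, one per canonical behavior (collection
#' `"behaviors"`), the control set used for parameter-sensitivity sweeps
#' (collection `"control"`), and the fixed parameters of the efficacy sweep
#' behind the behavior phase map (collection `"eta_sweep"`). Where a set
#' does not state its own ratio, odors are mixed at the default fixed
#' concentration ratio `r = 0.2`.
#'
#' @return A tibble with columns `collection`, `set`, `n_U`, `n_V`,
#'   `eta_U`, `eta_V`, `K_U`, `K_V`, `r` and `expected` (the slash-separated
#'   behavior label(s) the set demonstrates, `NA` where not applicable).
#' @examples
#' builtin_parameter_sets()
#' @export
builtin_parameter_sets <- function() {
  tibble::tribble(
    ~collection, ~set, ~n_U, ~n_V, ~eta_U, ~eta_V, ~K_U, ~K_V, ~r, ~expected,
    "behaviors", "suppression", 1.5, 3.5, 1.7, 0.7, 0.2, 0.2, 0.2,
      "suppression",
    "behaviors", "synergy", 3.6, 19.6, 1.7, 1.1, 3.16e-4, 1e-4, 1,
      "synergy",
    "behaviors", "overshadowing_hypoadditivity", 3.5, 0.5, 0.7, 1.7, 0.2, 0.2, 0.2,
      "overshadowing/hypoadditivity",
    "behaviors", "inhibition", 4.5, 0.5, 1.3, 0.3, 0.2, 0.2, 0.2,
      "inhibition",
    "behaviors", "overshadowing_suppression", 0.5, 10, 16, 0.95, 0.51e-3, 0.9e-2, 1.6,
      "overshadowing/suppression",
    "behaviors", "overshadowing", 0.5, 10, 16, 0.95, 0.8e-2, 0.9e-2, 2e-4,
      "overshadowing",
    "control", "control", 3.6, 19.6, 1.7, 1.1, 3.16e-4, 1e-4, 1,
      NA_character_,
    "eta_sweep", "fixed", 1, 12, NA, NA, 0.5e-4, 1e-3, 1,
      NA_character_
  )
}

#' Extract one builtin set as a pair of odors
#'
#' @param set Set name from [builtin_parameter_sets()].
#' @return A list with elements `U`, `V` ([odor()] objects) and `r`.
#' @export
builtin_pair <- function(set) {
  tab <- builtin_parameter_sets()
  row <- tab[tab$set == set, ]
  if (nrow(row) != 1L) stop(sprintf("unknown builtin set '%s'", set), call. = FALSE)
  if (any(is.na(c(row$eta_U, row$eta_V)))) {
    stop(sprintf("set '%s' does not define complete odor pairs", set), call. = FALSE)
  }
  list(U = odor(n = row$n_U, eta = row$eta_U, K = row$K_U, name = paste0(set, "_U")),
       V = odor(n = row$n_V, eta = row$eta_V, K = row$K_V, name = paste0(set, "_V")),
       r = row$r)
}
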