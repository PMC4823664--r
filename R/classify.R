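#' Mixture behavior labels
#'
#' The five empirical behaviors of a mixture curve relative to its component
#' curves: *suppression* (mixture strictly between the components),
#' *hypoadditivity* (mixture similar to the more effective component),
#' *synergy* (mixture above both), *inhibition* (mixture below both) and
#' *overshadowing* (mixture similar to one component that is not the more
#' effective one over part of the analysed range). "Similar" means within a
#' tolerance band of `tol * f_max` (default 5%); because the prose
#' definitions overlap -- similarity to the most effective component is a
#' special case of similarity to one component -- hypoadditivity is treated
#' as the refinement of overshadowing that applies when the matched
#' component dominates the other everywhere on the analysed grid.
#'
#' @name behavior_labels
#' @keywords internal
NULL

behavior_levels <- c("suppression", "hypoadditivity", "synergy",
                     "inhibition", "overshadowing")

# pointwise labels; equality bands take precedence over strict inequalities
pointwise_labels <- function(fU, fV, fmix, tol_abs, u_dominates_everywhere,
                             v_dominates_everywhere) {
  hi <- pmax(fU, fV)
  lo <- pmin(fU, fV)
  u_is_hi <- fU >= fV
  sim_u <- abs(fmix - fU) <= tol_abs
  sim_v <- abs(fmix - fV) <= tol_abs
  # matched component: the closer of the two, among those within the band
  match_u <- sim_u & (!sim_v | abs(fmix - fU) <= abs(fmix - fV))
  match_v <- sim_v & !match_u
  lab <- character(length(fmix))
  matched_dominates <- (match_u & u_dominates_everywhere) |
    (match_v & v_dominates_everywhere)
  lab[match_u | match_v] <- ifelse(matched_dominates[match_u | match_v],
                                   "hypoadditivity", "overshadowing")
  rest <- !(match_u | match_v)
  lab[rest & fmix > hi] <- "synergy"
  lab[rest & fmix < lo] <- "inhibition"
  lab[rest & lab == ""] <- "suppression"
  lab
}

#' Classify mixture behavior on a concentration grid
#'
#' Compares a mixture curve against its two component curves, all evaluated
#' on a shared concentration grid, and assigns one of the five behavior
#' labels to each maximal contiguous region of the grid.
#'
#' @param fU,fV,fmix Responses of odor U, odor V and the mixture on the
#'   shared grid `conc`.
#' @param conc Shared concentration grid (positive, increasing).
#' @param tol Similarity band as a fraction of `f_max`.
#' @param f_max Shared maximal response.
#' @return A tibble with one row per contiguous region: `label`,
#'   `conc_min`, `conc_max`, `n_points`.
#' @export
classify_full_curve <- function(fU, fV, fmix, conc, tol = 0.05, f_max = 1) {
  stopifnot(length(fU) == length(conc), length(fV) == length(conc),
            length(fmix) == length(conc))
  if (length(conc) == 0L) stop("empty region", call. = FALSE)
  u_dom <- all(fU >= fV - 1e-12 * f_max)
  v_dom <- all(fV >= fU - 1e-12 * f_max)
  lab <- pointwise_labels(fU, fV, fmix, tol * f_max, u_dom, v_dom)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(
    label = factor(r$values, levels = behavior_levels),
    conc_min = conc[starts],
    conc_max = conc[ends],
    n_points = r$lengths
  )
}

#' Classify one concentration region
#'
#' Assigns a single behavior label to a region of the shared grid. With the
#' default `region = NULL` the whole grid is used. The label is the modal
#' pointwise label in the region (ties resolved toward the
#' highest-concentration label).
#'
#' @inheritParams classify_full_curve
#' @param region Optional length-2 numeric `c(lo, hi)` restricting the grid.
#' @return A length-1 factor over the five behavior levels.
#' @export
classify_region <- function(fU, fV, fmix, conc, region = NULL, tol = 0.05,
                            f_max = 1) {
  stopifnot(length(fU) == length(conc), length(fV) == length(conc),
            length(fmix) == length(conc))
  keep <- rep(TRUE, length(conc))
  if (!is.null(region)) {
    stopifnot(length(region) == 2L)
    keep <- conc >= region[1] & conc <= region[2]
  }
  if (!any(keep)) stop("empty region", call. = FALSE)
  # dominance is judged on the full analysed grid, not only the region
  u_dom <- all(fU >= fV - 1e-12 * f_max)
  v_dom <- all(fV >= fU - 1e-12 * f_max)
  lab <- pointwise_labels(fU[keep], fV[keep], fmix[keep], tol * f_max,
                          u_dom, v_dom)
  counts <- table(lab)
  modal <- names(counts)[counts == max(counts)]
  pick <- if (length(modal) == 1L) modal else lab[max(which(lab %in% modal))]
  factor(pick, levels = behavior_levels)
}

#' Default log-spaced analysis grid for a mixture
#'
#' 200 log-spaced points spanning three decades around the smallest and
#' largest midpoints of the three curves involved (U, V and the effective
#' mixture sigmoid).
#'
#' @param U,V [odor()] sets.
#' @param r Concentration ratio `U = r * V`.
#' @param n_points Number of grid points.
#' @param span_decades Half-width, in decades, added beyond the extreme
#'   midpoints.
#' @return Increasing positive numeric vector.
#' @export
default_grid <- function(U, V, r, n_points = 200, span_decades = 1.5) {
  U <- as_odor(U); V <- as_odor(V)
  mix <- effective_fixed_ratio(U, V, r)
  k_mix_total <- mix$K * (1 + r)  # effective midpoint on the total-conc axis
  k <- c(U$K, V$K, k_mix_total)
  10^seq(log10(min(k)) - span_decades, log10(max(k)) + span_decades,
         length.out = n_points)
}

#' Classify a fixed-ratio binary mixture
#'
#' High-level entry point: evaluates the two single-odor curves on a common
#' concentration axis and the mixture as a function of total concentration
#' (components `r/(1+r)` and `1/(1+r)` of the total), classifies the
#' asymptotic region and the full curve, and returns both.
#'
#' The asymptotic region is where all three curves exceed `asym_frac`
#' (default 95%) of their own asymptotes; if the grid does not reach it the
#' top grid point is used.
#'
#' @param U,V [odor()] sets.
#' @param r Concentration ratio `U = r * V` (> 0).
#' @param conc Optional concentration grid; defaults to [default_grid()].
#' @param tol Similarity band fraction.
#' @param f_max Shared maximal response.
#' @param asym_frac Fraction of each curve's own asymptote defining the
#'   asymptotic region.
#' @return A list of class `mixture_classification` with elements
#'   `asymptotic` (length-1 factor), `regions` (tibble from
#'   [classify_full_curve()]), `curves` (long tibble of the three curves)
#'   and `params` (inputs).
#' @examples
#' sets <- builtin_parameter_sets()
#' p <- sets[sets$set == "synergy", ]
#' cls <- classify_mixture(odor(n = p$n_U, eta = p$eta_U, K = p$K_U),
#'                         odor(n = p$n_V, eta = p$eta_V, K = p$K_V), p$r)
#' cls$asymptotic
#' @export
classify_mixture <- function(U, V, r, conc = NULL, tol = 0.05, f_max = 1,
                             asym_frac = 0.95) {
  U <- as_odor(U); V <- as_odor(V)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r > 0)
  if (is.null(conc)) conc <- default_grid(U, V, r)
  check_conc(conc)
  wU <- r / (1 + r)
  fU <- single_response(U, conc, f_max)
  fV <- single_response(V, conc, f_max)
  fmix <- mixture_response(list(U, V), cbind(conc * wU, conc * (1 - wU)), f_max)
  mix_eff <- effective_fixed_ratio(U, V, r)
  asym <- c(response_asymptote(U, f_max), response_asymptote(V, f_max),
            response_asymptote(mix_eff, f_max))
  in_asym <- fU >= asym_frac * asym[1] & fV >= asym_frac * asym[2] &
    fmix >= asym_frac * asym[3]
  if (!any(in_asym)) in_asym[length(conc)] <- TRUE
  asym_label <- classify_region(fU, fV, fmix, conc,
                                region = range(conc[in_asym]),
                                tol = tol, f_max = f_max)
  regions <- classify_full_curve(fU, fV, fmix, conc, tol = tol, f_max = f_max)
  n_grid <- length(conc)
  curves <- tibble::tibble(
    conc = rep(conc, 3L),
    curve = rep(c("U", "V", "mixture"), each = n_grid),
    response = c(fU, fV, fmix)
  )
  structure(list(asymptotic = asym_label, regions = regions, curves = curves,
                 params = list(U = U, V = V, r = r, tol = tol, f_max = f_max)),
            class = "mixture_classification")
}

#' @export
print.mixture_classification <- function(x, ...) {
  cat("Mixture behavior classification\n")
  cat("  asymptotic region:", as.character(x$asymptotic), "\n")
  cat("  regions:\n")
  print(x$regions)
  invisible(x)
}

#' Phase map of mixture behavior over a two-parameter sweep
#'
#' Classifies the near-asymptote behavior of a binary mixture for every
#' combination of two swept parameters, holding all others fixed. The
#' default classification is strict (tolerance 0): each cell is labelled by
#' comparing the analytic asymptotes of the mixture and of the two single
#' odors, which partitions cells into suppression, synergy and inhibition
#' (similarity labels appear only if `tol > 0`).
#'
#' @param sweep Named list of two numeric grids; names are parameter names
#'   among `n_U`, `n_V`, `eta_U`, `eta_V`, `K_U`, `K_V`, `r`.
#' @param fixed Named list giving every remaining parameter.
#' @param tol Similarity band fraction (default 0 = strict ordering).
#' @param f_max Shared maximal response.
#' @return A tibble of class `phase_map` in long format: one row per cell
#'   with the two swept parameters and `label`.
#' @examples
#' pm <- phase_map(sweep = list(eta_U = c(0.5, 1.5), eta_V = c(0.5, 1.5)),
#'                 fixed = list(n_U = 1, n_V = 12, K_U = 0.5e-4,
#'                              K_V = 1e-3, r = 1))
#' table(pm$label)
#' @export
phase_map <- function(sweep, fixed, tol = 0, f_max = 1) {
  stopifnot(is.list(sweep), length(sweep) == 2L, !is.null(names(sweep)))
  par_names <- c("n_U", "n_V", "eta_U", "eta_V", "K_U", "K_V", "r")
  stopifnot(all(names(sweep) %in% par_names))
  grid <- tidyr::expand_grid(!!!sweep)
  if (any(!is.finite(unlist(sweep))) || any(unlist(sweep) <= 0)) {
    stop("sweep grids must be positive and finite", call. = FALSE)
  }
  labels <- purrr::pmap_chr(grid, function(...) {
    cell <- c(list(...), fixed)
    U <- odor(n = cell$n_U, eta = cell$eta_U, K = cell$K_U)
    V <- odor(n = cell$n_V, eta = cell$eta_V, K = cell$K_V)
    aU <- response_asymptote(U, f_max)
    aV <- response_asymptote(V, f_max)
    aM <- response_asymptote(effective_fixed_ratio(U, V, cell$r), f_max)
    band <- tol * f_max
    if (band > 0 && abs(aM - max(aU, aV)) <= band) "hypoadditivity"
    else if (band > 0 && abs(aM - min(aU, aV)) <= band) "overshadowing"
    else if (aM > max(aU, aV) + band) "synergy"
    else if (aM < min(aU, aV) - band) "inhibition"
    else "suppression"
  })
  out <- dplyr::mutate(grid, label = factor(labels, levels = behavior_levels))
  class(out) <- c("phase_map", class(out))
  out
}
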