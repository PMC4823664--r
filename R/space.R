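#' Odor-response-space algebra
#'
#' A dose-response curve in this family is identified by the triple
#' `(n, eta, s)`. The set of triples carries two operations: scaling, which
#' maps a response to the same odor delivered at `alpha`-fold concentration,
#' and composition, which maps two responses to the response of their
#' equal-concentration mixture. Both become ordinary linear operations after
#' the embedding
#' \deqn{(n, \eta, s) \mapsto (n\eta s,\; \eta s,\; s)}
#' into the positive octant of 3-space: scaling is scalar multiplication and
#' composition is vector addition. The embedding is a bijection onto the
#' positive octant, with inverse `n = x1/x2`, `eta = x2/x3`, `s = x3`.
#'
#' @param t,t1,t2 [odor()] response triples.
#' @param alpha Positive scalar.
#' @return `odor_scale()` and `odor_compose()` return [odor()] triples;
#'   `embed_odor()` returns a named numeric vector `(x1, x2, x3)`;
#'   `unembed_odor()` returns an [odor()].
#' @examples
#' t1 <- odor(n = 2, eta = 1.5, s = 10)
#' embed_odor(odor_compose(t1, t1))  # equals 2 * embed_odor(t1)
#' @name odor_space
NULL

#' @rdname odor_space
#' @export
odor_scale <- function(t, alpha) {
  t <- as_odor(t)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  odor(n = t$n, eta = t$eta, s = t$s * alpha, name = t$name)
}

#' @rdname odor_space
#' @export
odor_compose <- function(t1, t2) {
  v <- embed_odor(as_odor(t1)) + embed_odor(as_odor(t2))
  unembed_odor(v)
}

#' @rdname odor_space
#' @export
embed_odor <- function(t) {
  t <- as_odor(t)
  c(x1 = t$n * t$eta * t$s, x2 = t$eta * t$s, x3 = t$s)
}

#' @rdname odor_space
#' @export
unembed_odor <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0)) {
    stop("embedded vectors must have three finite positive coordinates", call. = FALSE)
  }
  odor(n = v[1] / v[2], eta = v[2] / v[3], s = v[3])
}

#' Basis validity in the embedded odor space
#'
#' Three embedded response vectors form a basis exactly when they are
#' linearly independent; the test is a determinant with a scale-relative
#' tolerance, so near-degenerate vertex choices are rejected.
#'
#' @param e1,e2,e3 Embedded vectors (from [embed_odor()]) or [odor()]
#'   triples, which are embedded first.
#' @param tol Relative determinant tolerance.
#' @return `TRUE` if the three vectors are linearly independent.
#' @export
is_valid_basis <- function(e1, e2, e3, tol = 1e-12) {
  M <- basis_matrix(e1, e2, e3)
  scale <- prod(sqrt(colSums(M^2)))
  if (scale == 0) return(FALSE)
  abs(det(M)) > tol * scale
}

basis_matrix <- function(e1, e2, e3) {
  cols <- lapply(list(e1, e2, e3), function(e) {
    if (is_odor(e) || is.list(e)) embed_odor(e) else {
      e <- as.numeric(e)
      if (length(e) != 3L) stop("basis elements must be length-3 vectors or odors", call. = FALSE)
      e
    }
  })
  matrix(unlist(cols), nrow = 3L)
}

#' Decompose a target response over a basis of primary responses
#'
#' Solves the embedded linear system
#' \eqn{\alpha_1 e_1 + \alpha_2 e_2 + \alpha_3 e_3 = v(target)} explicitly by
#' Cramer's rule. A target is representable by the basis only when all three
#' scalars are positive: negative coefficients mean the target's `(n, eta)`
#' lies outside the region the basis can generate (see [hull_coverage()]).
#' Coefficients within `-pos_tol` of zero are clamped to zero and flagged as
#' boundary cases.
#'
#' @param target An [odor()] triple.
#' @param basis A list of three [odor()] triples or embedded vectors.
#' @param pos_tol Positivity tolerance for boundary targets.
#' @param strict If `TRUE` (default) a genuinely negative coefficient raises
#'   a not-representable error; if `FALSE` the coefficients are returned
#'   with `representable = FALSE`.
#' @return A one-row tibble with columns `alpha1`, `alpha2`, `alpha3`,
#'   `representable` and `on_boundary`.
#' @export
decompose_odor <- function(target, basis, pos_tol = 1e-12, strict = TRUE) {
  M <- basis_matrix(basis[[1]], basis[[2]], basis[[3]])
  if (!is_valid_basis(M[, 1], M[, 2], M[, 3])) {
    stop("the supplied vectors do not form a valid basis", call. = FALSE)
  }
  v <- embed_odor(as_odor(target))
  d <- det(M)
  alpha <- vapply(1:3, function(j) {
    Mj <- M; Mj[, j] <- v
    det(Mj) / d
  }, numeric(1))
  scale <- max(abs(alpha), 1)
  boundary <- alpha <= 0 & alpha > -pos_tol * scale
  negative <- alpha <= -pos_tol * scale
  alpha[boundary] <- 0
  if (any(negative) && strict) {
    stop(sprintf(
      "target is not representable by this basis: coefficient %d is negative (%.6g)",
      which(negative)[1], alpha[which(negative)[1]]), call. = FALSE)
  }
  tibble::tibble(
    alpha1 = alpha[1], alpha2 = alpha[2], alpha3 = alpha[3],
    representable = !any(negative),
    on_boundary = any(boundary)
  )
}

#' Recompose a response from basis coefficients
#'
#' Inverse of [decompose_odor()]: forms
#' \eqn{\alpha_1 e_1 \oplus \alpha_2 e_2 \oplus \alpha_3 e_3} in the odor
#' space (vector combination in the embedding).
#'
#' @param alpha Numeric coefficients (length 3, non-negative, not all zero),
#'   or the tibble returned by [decompose_odor()].
#' @param basis List of three [odor()] triples or embedded vectors.
#' @return The recomposed [odor()].
#' @export
recompose_odor <- function(alpha, basis) {
  if (is.data.frame(alpha)) alpha <- c(alpha$alpha1, alpha$alpha2, alpha$alpha3)
  stopifnot(length(alpha) == 3L, all(is.finite(alpha)), all(alpha >= 0), any(alpha > 0))
  M <- basis_matrix(basis[[1]], basis[[2]], basis[[3]])
  unembed_odor(as.numeric(M %*% alpha))
}

#' Is a response inside the region a basis can generate?
#'
#' Because scaling changes only `s` (the same odor at a different
#' concentration), representability depends on `(n, eta)` alone. A query is
#' covered when the decomposition over the basis has non-negative
#' coefficients, i.e. when `(n*eta, eta)` lies in the convex hull of the
#' basis images under the map `(n, eta) -> (n*eta, eta)`.
#'
#' @param basis List of three [odor()] triples or embedded vectors.
#' @param n,eta Query coordinates (vectors of equal length, > 0).
#' @param s Scale used to embed the query; irrelevant to the answer.
#' @return Logical vector.
#' @export
hull_coverage <- function(basis, n, eta, s = 1e6) {
  stopifnot(length(n) == length(eta), all(n > 0), all(eta > 0))
  vapply(seq_along(n), function(i) {
    dec <- decompose_odor(odor(n = n[i], eta = eta[i], s = s), basis,
                          strict = FALSE)
    dec$representable
  }, logical(1))
}

#' Canonical corner bases covering a bounded odor space
#'
#' The experimentally relevant odor responses occupy a bounded rectangle
#' `[n_min, n_max] x [eta_min, eta_max]` in the `(n, eta)` plane. Its image
#' under the hull map `(n, eta) -> (n*eta, eta)` is a convex quadrilateral
#' with the four corner responses as vertices, so two corner triples -- the
#' split along the `(n_min, eta_min)`--`(n_max, eta_max)` diagonal -- cover
#' the whole rectangle between them, while neither triple covers it alone.
#' All vectors share the scale `s`.
#'
#' @param n_min,n_max,eta_min,eta_max Positive bounds with
#'   `n_min < n_max`, `eta_min < eta_max`.
#' @param s Shared inverse concentration scale of the basis vectors.
#' @return A list with elements `E1` and `E2`, each a list of three
#'   [odor()] triples (both pass [is_valid_basis()]).
#' @export
canonical_bases <- function(n_min, n_max, eta_min, eta_max, s = 1e6) {
  ok <- is.finite(c(n_min, n_max, eta_min, eta_max, s))
  if (!all(ok) || n_min <= 0 || eta_min <= 0 || s <= 0 ||
      n_min >= n_max || eta_min >= eta_max) {
    stop("bounds must satisfy 0 < n_min < n_max and 0 < eta_min < eta_max", call. = FALSE)
  }
  corner <- function(n, eta) odor(n = n, eta = eta, s = s)
  A <- corner(n_min, eta_min)
  B <- corner(n_min, eta_max)
  C <- corner(n_max, eta_min)
  D <- corner(n_max, eta_max)
  list(E1 = list(A, C, D), E2 = list(A, B, D))
}

#' Synthesize a target response profile from available odors
#'
#' Given, for each OSN type, a target response triple and the triples the
#' available odorants elicit in that OSN, finds one set of positive mixture
#' coefficients (one per odorant, shared across OSN types) such that the
#' composed mixture reproduces every OSN's target. Stacking the embedded
#' images gives the linear system
#' \eqn{\sum_j \beta_j v_{ij} = v(target_i)} for all OSN types `i`, solved by
#' least squares and checked for positivity and per-OSN residual.
#'
#' @param targets A list of [odor()] targets, one per OSN type (names are
#'   used in error messages).
#' @param available A list (same length) whose element `i` is the list of
#'   [odor()] triples elicited in OSN `i` by each available odorant; every
#'   element must have the same length (number of odorants).
#' @param tol Relative residual tolerance for a per-OSN match.
#' @param pos_tol Positivity tolerance on coefficients.
#' @return A tibble with columns `odorant` (index) and `beta`.
#' @export
synthesize_target <- function(targets, available, tol = 1e-8, pos_tol = 1e-10) {
  stopifnot(length(targets) == length(available), length(targets) >= 1L)
  n_odor <- length(available[[1]])
  if (n_odor < 1L || !all(vapply(available, length, integer(1)) == n_odor)) {
    stop("every OSN must list the same odorants", call. = FALSE)
  }
  A <- do.call(rbind, lapply(available, function(av) {
    do.call(cbind, lapply(av, function(o) embed_odor(as_odor(o))))
  }))
  b <- unlist(lapply(targets, function(t) embed_odor(as_odor(t))))
  beta <- as.numeric(qr.solve(qr(A), b))
  scale <- max(abs(beta), 1)
  beta[beta < 0 & beta > -pos_tol * scale] <- 0
  if (any(beta < 0)) {
    stop("target profile is not representable: a mixture coefficient is negative",
         call. = FALSE)
  }
  fit <- as.numeric(A %*% beta)
  for (i in seq_along(targets)) {
    idx <- (3 * i - 3) + 1:3
    rel <- sqrt(sum((fit[idx] - b[idx])^2)) / sqrt(sum(b[idx]^2))
    if (rel > tol) {
      nm <- names(targets)[i] %||% as.character(i)
      stop(sprintf("target for OSN %s cannot be matched (relative residual %.3g)",
                   nm, rel), call. = FALSE)
    }
  }
  tibble::tibble(odorant = seq_len(n_odor), beta = beta)
}
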