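#' Fit the single-odor model to dose-response data
#'
#' Least-squares estimation of `(n, eta, K)` for one odor under the
#' generalized Hill model, with the shared ceiling `f_max` held fixed.
#' The objective is multimodal in `n`, so the fit is multistarted from a
#' coarse log-spaced grid over `(n, eta, K)` (jittered deterministically
#' from `seed`); each start runs bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) and the best converged solution is kept.
#'
#' @param data A data frame with columns `conc` and `response` (at least 3
#'   rows; responses in `[0, f_max]`).
#' @param f_max Shared maximal response (fixed during fitting).
#' @param n_starts Number of multistart initializations.
#' @param seed Integer seed for the deterministic start jitter.
#' @param lower,upper Named bounds for `n`, `eta`, `K`. Defaults:
#'   `n` in `[0.1, 30]`, `eta` in `[1e-3, 1e3]`, `K` within
#'   `[min(conc)/100, max(conc)*100]` -- wide enough to span all Hill
#'   coefficients and efficacies reported for OSN responses, with margin.
#' @return An object of class `osn_fit`: a list with `params` ([odor()]),
#'   `mse`, `mape`, `converged`, `bounds_hit`, `data`, `f_max`, `fitted`.
#'   Use [tidy()] / [glance()] to extract results as tibbles.
#' @examples
#' u <- odor(n = 1.5, eta = 1.7, K = 0.2)
#' d <- generate_curve(u, noise = 0, seed = 1)
#' fit <- fit_single_odor(d)
#' tidy(fit)
#' @export
fit_single_odor <- function(data, f_max = 1, n_starts = 20, seed = 1,
                            lower = NULL, upper = NULL) {
  stopifnot(is.data.frame(data), all(c("conc", "response") %in% names(data)))
  conc <- as.numeric(data$conc)
  resp <- as.numeric(data$response)
  check_conc(conc)
  check_f_max(f_max)
  if (length(conc) < 3L) stop("at least 3 points are needed to fit 3 parameters", call. = FALSE)
  if (any(!is.finite(resp)) || any(resp < 0) || any(resp > f_max + 1e-9)) {
    stop("responses must be finite and within [0, f_max]", call. = FALSE)
  }
  if (all(resp <= 0) || stats::var(resp) == 0) {
    stop("degenerate data: responses are constant, the model is unidentifiable",
         call. = FALSE)
  }
  lo <- c(n = 0.1, eta = 1e-3, K = min(conc[conc > 0]) / 100)
  hi <- c(n = 30, eta = 1e3, K = max(conc) * 100)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)

  starts <- fit_start_grid(lo, hi, n_starts, seed)
  df <- data.frame(conc = conc, response = resp)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ odormix_model(conc, n, eta, K, f_max),
        data = df,
        start = as.list(starts[i, ]),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("fit did not converge from any start; check the data and bounds", call. = FALSE)
  }
  est <- stats::coef(best$fit)
  params <- odor(n = est[["n"]], eta = est[["eta"]], K = est[["K"]])
  pred <- single_response(params, conc, f_max)
  bounds_hit <- est <= lo * (1 + 1e-6) | est >= hi * (1 - 1e-6)
  structure(list(
    params = params,
    mse = mse(resp, pred),
    mape = suppressWarnings(mape(resp, pred)),
    converged = TRUE,
    bounds_hit = bounds_hit,
    data = tibble::tibble(conc = conc, response = resp),
    fitted = pred,
    f_max = f_max
  ), class = "osn_fit")
}

# model wrapper visible to nlsLM's formula environment
odormix_model <- function(conc, n, eta, K, f_max) {
  hill_eval(conc / K, n, eta, f_max)
}

fit_start_grid <- function(lo, hi, n_starts, seed) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  base <- expand.grid(
    n = exp(seq(log(lo["n"]), log(hi["n"]), length.out = 4)),
    eta = exp(seq(log(max(lo["eta"], 0.1)), log(min(hi["eta"], 20)), length.out = 3)),
    K = exp(seq(log(lo["K"] * 100), log(hi["K"] / 100), length.out = 4))
  )
  idx <- rep_len(sample.int(nrow(base)), n_starts)
  jitter <- matrix(stats::runif(3 * n_starts, 0.9, 1.1), ncol = 3)
  out <- as.matrix(base[idx, , drop = FALSE]) * jitter
  out[, 1] <- pmin(pmax(out[, 1], lo["n"]), hi["n"])
  out[, 2] <- pmin(pmax(out[, 2], lo["eta"]), hi["eta"])
  out[, 3] <- pmin(pmax(out[, 3], lo["K"]), hi["K"])
  colnames(out) <- c("n", "eta", "K")
  out
}

#' @export
print.osn_fit <- function(x, ...) {
  cat("<osn_fit>", format(x$params), "\n")
  cat(sprintf("  MSE = %.4g, MAPE = %.4g%%, n_points = %d\n",
              x$mse, x$mape, nrow(x$data)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_single_odor
#' @param x An `osn_fit` object.
#' @param ... Unused.
#' @export
tidy.osn_fit <- function(x, ...) {
  tibble::tibble(
    term = c("n", "eta", "K"),
    estimate = c(x$params$n, x$params$eta, x$params$K),
    bound_hit = as.logical(x$bounds_hit)
  )
}

#' @rdname fit_single_odor
#' @export
glance.osn_fit <- function(x, ...) {
  tibble::tibble(
    mse = x$mse, mape = x$mape, converged = x$converged,
    n_points = nrow(x$data), f_max = x$f_max
  )
}

#' Goodness-of-fit metrics
#'
#' `mse()` is the mean squared error; `mape()` is the mean absolute
#' percentage error, reported in percent. Points with zero observed
#' response are excluded from MAPE (it is undefined there) with a warning;
#' they are kept in MSE.
#'
#' @param obs,pred Equal-length numeric vectors.
#' @param zero_action For `mape()`: `"exclude"` (default, warns) or
#'   `"error"` when zero observations are present.
#' @return A single number; `mse(x, x)` and `mape(x, x)` are 0.
#' @examples
#' mse(c(1, 2), c(2, 2))   # 0.5
#' mape(c(1, 2), c(2, 2))  # 50
#' @export
mse <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  mean((obs - pred)^2)
}

#' @rdname mse
#' @export
mape <- function(obs, pred, zero_action = c("exclude", "error")) {
  stopifnot(length(obs) == length(pred))
  zero_action <- match.arg(zero_action)
  zero <- obs == 0
  if (any(zero)) {
    if (zero_action == "error") stop("zero observations make MAPE undefined", call. = FALSE)
    warning(sprintf("%d zero observation(s) excluded from MAPE", sum(zero)), call. = FALSE)
  }
  if (all(zero)) return(NaN)
  100 * mean(abs((obs[!zero] - pred[!zero]) / obs[!zero]))
}

#' Predict a mixture curve from two single-odor fits
#'
#' Pure prediction: only the fitted single-odor parameters and the protocol
#' description are used -- no mixture observations enter.
#'
#' @param fit_U,fit_V `osn_fit` objects for the two odors.
#' @param protocol `"same_dilution"` or `"fixed_background"`.
#' @param svp_U,svp_V Saturated-vapor molarities (same-dilution protocol).
#' @param dilutions Dilution grid (same-dilution protocol).
#' @param background Background concentration of `V` (fixed-background).
#' @param conc Concentration sweep for `U` (fixed-background).
#' @param ... Passed to the protocol adapter.
#' @return The tibble from [predict_same_dilution()] or
#'   [predict_fixed_background()].
#' @export
predict_mixture_from_fits <- function(fit_U, fit_V,
                                      protocol = c("same_dilution", "fixed_background"),
                                      svp_U = NULL, svp_V = NULL, dilutions = NULL,
                                      background = NULL, conc = NULL, ...) {
  protocol <- match.arg(protocol)
  for (f in list(fit_U, fit_V)) {
    if (!inherits(f, "osn_fit") || !isTRUE(f$converged)) {
      stop("both fits must be converged `osn_fit` objects", call. = FALSE)
    }
  }
  if (fit_U$f_max != fit_V$f_max) stop("fits use different f_max values", call. = FALSE)
  if (protocol == "same_dilution") {
    if (is.null(svp_U) || is.null(svp_V) || is.null(dilutions)) {
      stop("same-dilution prediction needs `svp_U`, `svp_V` and `dilutions`", call. = FALSE)
    }
    predict_same_dilution(fit_U$params, fit_V$params, svp_U, svp_V, dilutions,
                          f_max = fit_U$f_max, ...)
  } else {
    if (is.null(background) || is.null(conc)) {
      stop("fixed-background prediction needs `background` and `conc`", call. = FALSE)
    }
    predict_fixed_background(fit_U$params, fit_V$params, background, conc,
                             f_max = fit_U$f_max)
  }
}

#' Shift a curve along log-concentration
#'
#' Multiplies the abscissa by `10^delta`, leaving responses untouched. Used
#' to correct mixture predictions when the delivered mixture concentration
#' differs from the nominal one (e.g. vapor-phase calculation errors).
#'
#' @param curve A data frame with a `conc` column.
#' @param delta Signed shift in log10 concentration units.
#' @return The curve with shifted `conc`.
#' @export
apply_log_shift <- function(curve, delta) {
  stopifnot(is.data.frame(curve), "conc" %in% names(curve),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (any(curve$conc <= 0)) stop("concentrations must be positive to shift", call. = FALSE)
  dplyr::mutate(curve, conc = .data$conc * 10^delta)
}

#' Estimate the log-concentration shift between a prediction and data
#'
#' Finds the `delta` minimizing the MSE between the prediction shifted by
#' `delta` (interpolated on log-concentration) and the observed mixture
#' points, over a bounded interval.
#'
#' @param data_mix Data frame with `conc`, `response` (observed mixture).
#' @param predicted Data frame with `conc`, `response` (model prediction).
#' @param interval Search interval for `delta` (log10 units).
#' @return A list with `delta` and `mse`.
#' @export
fit_shift <- function(data_mix, predicted, interval = c(-1, 1)) {
  stopifnot(all(c("conc", "response") %in% names(data_mix)),
            all(c("conc", "response") %in% names(predicted)))
  lp <- log10(predicted$conc)
  obj <- function(delta) {
    shifted <- lp + delta
    keep <- log10(data_mix$conc) >= min(shifted) & log10(data_mix$conc) <= max(shifted)
    if (!any(keep)) return(Inf)
    pr <- stats::approx(shifted, predicted$response, xout = log10(data_mix$conc[keep]))$y
    mean((data_mix$response[keep] - pr)^2)
  }
  if (!is.finite(obj(0)) && !is.finite(obj(interval[1])) && !is.finite(obj(interval[2]))) {
    stop("no overlap between prediction and data under any admissible shift", call. = FALSE)
  }
  opt <- stats::optimize(obj, interval = interval, tol = 1e-8)
  list(delta = opt$minimum, mse = opt$objective)
}
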