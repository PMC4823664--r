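test_that("mixture response: zero input, single-component reduction, symmetry", {
  u <- odor(n = 3.6, eta = 1.7, K = 3.16e-4)
  v <- odor(n = 19.6, eta = 1.1, K = 1e-4)
  expect_identical(mixture_response(list(u, v), c(0, 0)), 0)
  grid <- 10^seq(-6, -2, length.out = 40)
  expect_rel_equal(
    mixture_response(list(u, v), cbind(grid, 0)),
    single_response(u, grid), tol = 1e-12
  )
  expect_equal(
    mixture_response(list(u, v), cbind(grid, grid / 3)),
    mixture_response(list(v, u), cbind(grid / 3, grid))
  )
  expect_error(mixture_response(list(u, v), cbind(grid, grid, grid)), "match")
})

test_that("self-mixture identity F(U,U) = F(2U,0) holds over random draws", {
  set.seed(21)
  for (i in 1:200) {
    p <- random_odor()
    cc <- 10^runif(3, log10(p$K) - 3, log10(p$K) + 3)
    lhs <- mixture_response(list(p, p), cbind(cc, cc))
    rhs <- single_response(p, 2 * cc)
    expect_rel_equal(lhs, rhs, tol = 1e-9)
  }
})

test_that("with equal Hill coefficients the mixture reduces to the legacy efficacy model", {
  set.seed(22)
  for (i in 1:20) {
    n <- runif(1, 0.4, 6)
    U <- odor(n = n, eta = runif(1, 0.3, 4), K = 10^runif(1, -3, 0))
    V <- odor(n = n, eta = runif(1, 0.3, 4), K = 10^runif(1, -3, 0))
    cU <- 10^seq(-4, 1, length.out = 30)
    cV <- cU * 0.37
    expect_rel_equal(
      mixture_response(list(U, V), cbind(cU, cV)),
      oracle_cruz_lowe_binary(cU, cV, n, U$eta, V$eta, U$K, V$K),
      tol = 1e-10
    )
  }
})

test_that("effective fixed-ratio sigmoid equals the mixture along its ray", {
  u <- odor(n = 3.6, eta = 1.7, K = 3.16e-4)
  v <- odor(n = 19.6, eta = 1.1, K = 1e-4)
  eff <- effective_fixed_ratio(u, v, 1)
  grid <- 10^seq(log10(v$K) - 3, log10(v$K) + 3, length.out = 200)
  expect_rel_equal(
    single_response(eff, grid),
    mixture_response(list(u, v), cbind(grid, grid)),
    tol = 1e-9
  )
  # r = 0 degenerates to V itself
  eff0 <- effective_fixed_ratio(u, v, 0)
  expect_equal(eff0$n, v$n)
  expect_equal(eff0$K, v$K)
  # swapping (U, r) with (V, 1/r) reparameterizes the same curve: at V-conc x
  # the ray (rx, x) equals the ray seen from U at U-conc r*x
  r <- 0.2
  eff_uv <- effective_fixed_ratio(u, v, r)
  eff_vu <- effective_fixed_ratio(v, u, 1 / r)
  expect_rel_equal(single_response(eff_uv, grid),
                   single_response(eff_vu, r * grid), tol = 1e-9)
})

test_that("N-odor fixed-ratio mixture matches direct evaluation", {
  set.seed(23)
  odors <- replicate(4, random_odor(), simplify = FALSE)
  w <- runif(4, 0.1, 2)
  eff <- mix_fixed_ratio(odors, w)
  x <- 10^seq(-4, 1, length.out = 50)
  expect_rel_equal(
    single_response(eff, x),
    mixture_response(odors, outer(x, w)),
    tol = 1e-9
  )
})

test_that("curve summary: analytic asymptote, midpoint and steepness", {
  set.seed(24)
  for (i in 1:15) {
    p <- random_odor()
    cs <- curve_summary(p)
    # numeric limit far into saturation
    expect_rel_equal(cs$asymptote, single_response(p, 1e8 * p$K), tol = 1e-6)
    expect_rel_equal(single_response(p, cs$midpoint), cs$asymptote / 2, tol = 1e-9)
    expect_identical(cs$steepness, p$n)
  }
  # asymptote strictly increasing in eta, all else fixed
  etas <- seq(0.2, 5, length.out = 20)
  asym <- vapply(etas, function(e) curve_summary(odor(n = 2.4, eta = e, K = 0.1))$asymptote,
                 numeric(1))
  expect_true(all(diff(asym) > 0))
})

test_that("mixture asymptote rises with the shallow component's efficacy", {
  # along the shallow odor's efficacy the mixture asymptote is ordered
  # monotonically; the steep odor's efficacy acts through both eta_eff and
  # n_eff and need not be monotone
  etaU <- seq(0.2, 2, length.out = 10)
  etaV <- seq(0.2, 2, length.out = 10)
  a <- outer(etaU, etaV, Vectorize(function(eu, ev) {
    eff <- effective_fixed_ratio(odor(n = 1, eta = eu, K = 0.5e-4),
                                 odor(n = 12, eta = ev, K = 1e-3), 1)
    response_asymptote(eff)
  }))
  expect_true(all(apply(a, 2, function(col) all(diff(col) > 0))))
})

test_that("same-dilution prediction reduces to fixed ratio and respects log shifts", {
  u <- odor(n = 1.5, eta = 1.7, K = 0.2)
  v <- odor(n = 3.5, eta = 0.7, K = 0.2)
  d <- 10^seq(-4, 2, length.out = 40)
  pred <- predict_same_dilution(u, v, svp_U = 1, svp_V = 1, dilutions = d)
  eff <- effective_fixed_ratio(u, v, 1)
  expect_rel_equal(pred$response, single_response(eff, d), tol = 1e-9)
  expect_identical(predict_same_dilution(u, v, 1, 1, 0)$response, 0)
  # shifting the prediction equals evaluating at rescaled concentrations
  delta <- -0.06
  shifted <- apply_log_shift(pred, delta)
  expect_equal(shifted$conc, pred$conc * 10^delta)
  expect_equal(shifted$response, pred$response)
  expect_error(predict_same_dilution(u, v, -1, 1, d), "positive")
})

test_that("fixed-background prediction has the right limits and monotone offset", {
  u <- odor(n = 2, eta = 1.2, K = 0.01)
  v <- odor(n = 1.1, eta = 0.8, K = 0.05)
  cc <- 10^seq(-5, 1, length.out = 50)
  p0 <- predict_fixed_background(u, v, background = 0, conc = cc)
  expect_rel_equal(p0$response, single_response(u, cc), tol = 1e-12)
  b <- 0.03
  pb <- predict_fixed_background(u, v, background = b, conc = 0)
  expect_rel_equal(pb$response, single_response(v, b), tol = 1e-12)
  # raising the background never lowers the low-concentration end
  low <- vapply(c(0, b, 2 * b), function(bg) {
    predict_fixed_background(u, v, bg, cc[1])$response
  }, numeric(1))
  expect_true(all(diff(low) > 0))
})

test_that("synergy is infeasible below the lower-coefficient component midpoint", {
  u <- odor(n = 3.6, eta = 1.7, K = 3.16e-4)
  v <- odor(n = 19.6, eta = 1.1, K = 1e-4)
  expect_false(synergy_feasible(u, v, 1e-6))
  expect_true(synergy_feasible(u, v, 1e-2))
  # brute force: over random draws, no strictly synergistic grid point lies
  # below the lower-coefficient component's midpoint on the shared axis
  set.seed(25)
  for (i in 1:200) {
    U <- random_odor(); V <- random_odor()
    r <- 10^runif(1, -1, 1)
    conc <- default_grid(U, V, r, n_points = 80)
    w <- r / (1 + r)
    fU <- single_response(U, conc)
    fV <- single_response(V, conc)
    fm <- mixture_response(list(U, V), cbind(conc * w, conc * (1 - w)))
    syn <- fm > pmax(fU, fV) + 0.05
    if (any(syn)) {
      expect_true(all(synergy_feasible(U, V, conc[syn])))
    }
  }
})
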