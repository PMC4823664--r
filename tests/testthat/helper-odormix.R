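# shared fixtures: random parameter draws over the physiologically relevant
# ranges spanned by the builtin sets (n up to ~20, eta up to ~16)
random_odor <- function(n_range = c(0.3, 8), eta_range = c(0.2, 5),
                        logK_range = c(-4, 0)) {
  odor(n = runif(1, n_range[1], n_range[2]),
       eta = runif(1, eta_range[1], eta_range[2]),
       K = 10^runif(1, logK_range[1], logK_range[2]))
}

random_triple <- function() {
  odor(n = runif(1, 0.1, 10), eta = runif(1, 0.1, 10), s = runif(1, 0.1, 10))
}

# direct transcription of the single-odor curve as a one-line expression,
# kept independent of the package's log-space evaluation path
oracle_single <- function(conc, n, eta, K, f_max = 1) {
  z <- conc / K
  ifelse(conc == 0, 0, f_max / (1 + ((1 + z) / (eta * z))^n))
}

# direct transcription of the shared-coefficient legacy binary mixture
oracle_cruz_lowe_binary <- function(cU, cV, n, etaU, etaV, KU, KV, f_max = 1) {
  S <- cU / KU + cV / KV
  H <- etaU * cU / KU + etaV * cV / KV
  ifelse(H == 0, 0, f_max / (1 + ((1 + S) / H)^n))
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
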