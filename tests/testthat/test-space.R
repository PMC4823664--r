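test_that("scaling identifies the response at alpha-fold concentration", {
  t1 <- odor(n = 2.3, eta = 1.4, s = 25)
  x <- 10^seq(-4, 2, length.out = 60)
  expect_identical(unlist(odor_scale(t1, 1)[c("n", "eta", "s")]),
                   unlist(t1[c("n", "eta", "s")]))
  expect_rel_equal(single_response(odor_scale(t1, 2), x),
                   single_response(t1, 2 * x), tol = 1e-12)
  s1 <- odor_scale(odor_scale(t1, 1.7), 3.1)
  s2 <- odor_scale(t1, 1.7 * 3.1)
  expect_rel_equal(s1$s, s2$s, tol = 1e-12)
  # left shift by log10(2) on the log-concentration axis
  expect_rel_equal(single_response(odor_scale(t1, 2), x / 2),
                   single_response(t1, x), tol = 1e-12)
  expect_error(odor_scale(t1, 0), "positive")
})

test_that("composition is the equal-concentration mixture and is commutative", {
  set.seed(31)
  for (i in 1:20) {
    t1 <- random_triple(); t2 <- random_triple()
    c12 <- odor_compose(t1, t2)
    c21 <- odor_compose(t2, t1)
    expect_rel_equal(unlist(c12[c("n", "eta", "s")]),
                     unlist(c21[c("n", "eta", "s")]), tol = 1e-12)
    x <- 10^seq(-2, 2, length.out = 25)
    expect_rel_equal(single_response(c12, x),
                     mixture_response(list(t1, t2), cbind(x, x)), tol = 1e-10)
    # embedding linearizes composition
    expect_rel_equal(embed_odor(c12), embed_odor(t1) + embed_odor(t2), tol = 1e-12)
    # self-composition is scaling by 2
    expect_rel_equal(unlist(odor_compose(t1, t1)[c("n", "eta", "s")]),
                     unlist(odor_scale(t1, 2)[c("n", "eta", "s")]), tol = 1e-12)
  }
})

test_that("composition is associative and scaling distributes over it", {
  set.seed(32)
  t1 <- random_triple(); t2 <- random_triple(); t3 <- random_triple()
  a <- odor_compose(odor_compose(t1, t2), t3)
  b <- odor_compose(t1, odor_compose(t2, t3))
  expect_rel_equal(unlist(a[c("n", "eta", "s")]), unlist(b[c("n", "eta", "s")]),
                   tol = 1e-12)
  lhs <- odor_scale(odor_compose(t1, t2), 2.5)
  rhs <- odor_compose(odor_scale(t1, 2.5), odor_scale(t2, 2.5))
  expect_rel_equal(unlist(lhs[c("n", "eta", "s")]), unlist(rhs[c("n", "eta", "s")]),
                   tol = 1e-12)
})

test_that("embedding is a bijection with the algebraic inverse", {
  expect_identical(unname(embed_odor(odor(n = 1, eta = 1, s = 1))), c(1, 1, 1))
  set.seed(33)
  for (i in 1:300) {
    t1 <- random_triple()
    back <- unembed_odor(embed_odor(t1))
    expect_rel_equal(unlist(back[c("n", "eta", "s")]),
                     unlist(t1[c("n", "eta", "s")]), tol = 1e-12)
  }
  expect_error(unembed_odor(c(1, -1, 1)), "positive")
})

test_that("images of random triples and compositions span exactly rank 3", {
  set.seed(34)
  triples <- replicate(20, random_triple(), simplify = FALSE)
  imgs <- t(vapply(triples, embed_odor, numeric(3)))
  comps <- t(vapply(1:10, function(i) {
    embed_odor(odor_compose(triples[[2 * i - 1]], triples[[2 * i]]))
  }, numeric(3)))
  expect_identical(qr(rbind(imgs, comps))$rank, 3L)
})

test_that("basis validity agrees with the determinant criterion", {
  e <- embed_odor(odor(n = 2, eta = 1, s = 5))
  expect_false(is_valid_basis(e, e, e))
  cb <- canonical_bases(0.5, 20, 0.3, 16)
  expect_true(is_valid_basis(cb$E1[[1]], cb$E1[[2]], cb$E1[[3]]))
  expect_true(is_valid_basis(cb$E2[[1]], cb$E2[[2]], cb$E2[[3]]))
  set.seed(35)
  for (i in 1:100) {
    M <- matrix(runif(9, 0.1, 5), 3)
    expect_identical(is_valid_basis(M[, 1], M[, 2], M[, 3]),
                     abs(det(M)) > 1e-12 * prod(sqrt(colSums(M^2))))
  }
})

test_that("decomposition recombines to the target and flags boundaries", {
  cb <- canonical_bases(0.5, 20, 0.3, 16)
  # a basis element decomposes to a unit coefficient on itself
  dec <- decompose_odor(cb$E1[[2]], cb$E1, strict = FALSE)
  expect_equal(c(dec$alpha1, dec$alpha2, dec$alpha3), c(0, 1, 0), tolerance = 1e-9)
  expect_true(dec$on_boundary)
  # random in-hull targets round-trip below 1e-9 relative error
  set.seed(36)
  n_ok <- 0
  for (i in 1:300) {
    tgt <- odor(n = runif(1, 0.5, 20), eta = runif(1, 0.3, 16), s = 1e6)
    for (basis in cb) {
      dec <- decompose_odor(tgt, basis, strict = FALSE)
      if (dec$representable && all(c(dec$alpha1, dec$alpha2, dec$alpha3) > 0)) {
        rec <- recompose_odor(dec, basis)
        expect_rel_equal(embed_odor(rec), embed_odor(tgt), tol = 1e-9)
        n_ok <- n_ok + 1
      }
    }
  }
  expect_gt(n_ok, 100)
  # a clearly out-of-hull target raises a not-representable error
  expect_error(decompose_odor(odor(n = 0.5, eta = 16, s = 1e6), cb$E1),
               "not representable")
  expect_error(decompose_odor(odor(n = 2, eta = 2, s = 1), list(cb$E1[[1]],
               cb$E1[[1]], cb$E1[[2]])), "valid basis")
})

test_that("hull coverage matches decomposition positivity and is s-independent", {
  cb <- canonical_bases(0.5, 20, 0.3, 16)
  expect_true(hull_coverage(cb$E1, cb$E1[[1]]$n, cb$E1[[1]]$eta))
  # centroid of the mapped vertices
  verts <- vapply(cb$E1, function(o) c(o$n * o$eta, o$eta), numeric(2))
  cen <- rowMeans(verts)
  expect_true(hull_coverage(cb$E1, cen[1] / cen[2], cen[2]))
  set.seed(37)
  n <- runif(200, 0.5, 20); eta <- runif(200, 0.3, 16)
  cov1 <- hull_coverage(cb$E1, n, eta, s = 1e6)
  cov2 <- hull_coverage(cb$E1, n, eta, s = 3.7)
  expect_identical(cov1, cov2)
  dec <- vapply(seq_along(n), function(i) {
    decompose_odor(odor(n = n[i], eta = eta[i], s = 1e6), cb$E1,
                   strict = FALSE)$representable
  }, logical(1))
  expect_identical(cov1, dec)
})

test_that("the two canonical corner bases cover the bounded space together", {
  cb <- canonical_bases(0.5, 20, 0.3, 16)
  g <- expand.grid(n = seq(0.5, 20, length.out = 50),
                   eta = seq(0.3, 16, length.out = 50))
  c1 <- hull_coverage(cb$E1, g$n, g$eta)
  c2 <- hull_coverage(cb$E2, g$n, g$eta)
  expect_true(all(c1 | c2))
  expect_false(all(c1))
  expect_false(all(c2))
  expect_error(canonical_bases(2, 1, 0.3, 16), "n_min < n_max")
})

test_that("target synthesis recovers known mixture coefficients", {
  # a target equal to one available odor takes that odor alone
  t1 <- odor(n = 2, eta = 1.5, s = 10)
  t2 <- odor(n = 0.7, eta = 3, s = 100)
  out <- synthesize_target(list(t1), list(list(t1)))
  expect_equal(out$beta, 1, tolerance = 1e-10)
  # two OSN types, two odorants, coefficients recovered by inversion
  set.seed(38)
  avail <- list(
    list(random_triple(), random_triple()),
    list(random_triple(), random_triple())
  )
  beta_true <- c(0.4, 1.3)
  targets <- lapply(avail, function(a) {
    odor_compose(odor_scale(a[[1]], beta_true[1]), odor_scale(a[[2]], beta_true[2]))
  })
  out <- synthesize_target(targets, avail)
  expect_equal(out$beta, beta_true, tolerance = 1e-8)
  # four OSN types activated by two odorants admits an exact solution when
  # the targets are genuine mixtures of the two
  avail4 <- lapply(1:4, function(i) list(random_triple(), random_triple()))
  beta4 <- c(0.8, 0.25)
  targets4 <- lapply(avail4, function(a) {
    odor_compose(odor_scale(a[[1]], beta4[1]), odor_scale(a[[2]], beta4[2]))
  })
  out4 <- synthesize_target(targets4, avail4)
  expect_equal(out4$beta, beta4, tolerance = 1e-8)
  # an infeasible target errors and names the offending receptor
  bad <- targets4
  bad[[2]] <- odor(n = 100, eta = 100, s = 1e-3)
  expect_error(synthesize_target(bad, avail4), "not representable|cannot be matched")
})
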