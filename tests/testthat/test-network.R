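test_that("propensities match hand-evaluated rate laws", {
  p <- eco_params()
  a <- eco_propensities(eco_state(c1 = 1, c2 = 0), p)
  expect_equal(a[["r3"]], 4e6 * 3e-7 * 1)         # k3 * Gc * c1, Res1 = 0

  a <- eco_propensities(eco_state(c1 = 0, c2 = 1e9), p)
  expect_equal(a[["r6"]], 5e-6 * 1e9)             # k5 * c2 = 5e3 per hour
  expect_equal(a[["r2"]], 0)                      # at capacity

  # logistic terms vanish at and above capacity
  a <- eco_propensities(eco_state(c1 = 6e8, c2 = 4e8), p)
  expect_equal(a[["r1"]], 0)
  expect_equal(a[["r2"]], 0)
  a <- eco_propensities(eco_state(c1 = 8e8, c2 = 4e8), p)
  expect_equal(a[["r1"]], 0)

  # no signal, no binding, no induction
  a <- eco_propensities(eco_state(AHL2 = 0, C2 = 0), p)
  expect_equal(a[["r7"]], 0)
  expect_equal(a[["r8"]], 0)

  # fourth-order binding and Hill induction, hand-evaluated
  d <- eco_derived(p)
  a <- eco_propensities(eco_state(AHL2 = 4000, C2 = 500), p)
  expect_equal(a[["r7"]], d$k6_eff * 4000^2 / d$om1)
  x <- 500 / d$om1
  expect_equal(a[["r8"]], d$om1 * p$k7 * x / (p$k7b + x))

  # bacterial lysis channel
  a <- eco_propensities(eco_state(c2 = 1e6),
                        eco_update(p, d = 0.5))
  expect_equal(a[["r18"]], 0.5 * 1e6)
})

test_that("propensities are nonnegative and finite over random states", {
  set.seed(42)
  p <- eco_update(eco_params(), d = 0.3)
  for (i in 1:50) {
    a <- eco_propensities(random_state(), p)
    expect_true(all(is.finite(a)))
    expect_true(all(a >= 0))
  }
})

test_that("drift equals the independent per-reaction accumulation", {
  set.seed(7)
  p <- eco_update(eco_params(), d = 0.2)
  for (i in 1:25) {
    s <- random_state()
    expect_equal(eco_drift(s, p), accumulate_drift(s, p),
                 tolerance = 1e-12)
  }
})

test_that("drift hand-checks at simple states", {
  p <- eco_params()
  # origin: every propensity vanishes
  expect_equal(unname(eco_drift(eco_state(c1 = 0, c2 = 0), p)),
               rep(0, 9))

  # only AHL1 = 100: first-order decay plus fourth-order receptor binding
  # (the receptor is a constant pool, so binding fires at any AHL1 > 0)
  f <- eco_drift(eco_state(c1 = 0, c2 = 0, AHL1 = 100), p)
  d <- eco_derived(p)
  a10 <- d$k9_eff * 100^2 / d$om2
  expect_equal(f[["AHL1"]], -2 * a10 - 1.19 * 100, tolerance = 1e-12)
  expect_equal(f[["C1"]], a10, tolerance = 1e-12)
  expect_equal(f[["AHL1"]], -368.0453, tolerance = 1e-6)

  # one unprotected bacterium: net death under the default Gc
  f <- eco_drift(eco_state(c1 = 0, c2 = 1), p)
  expect_equal(f[["c2"]], 0.936 * (1 - 1 / 1e9) - 1.2, tolerance = 1e-12)
  expect_lt(f[["c2"]], 0)
  expect_equal(f[["c2"]], -0.264, tolerance = 1e-6)
})

test_that("noise matrix is noise_scale * nu_ij * sqrt(a_j)", {
  p <- eco_params()
  s <- eco_state(c1 = 1e5, c2 = 1e6, AHL1 = 10, AHL2 = 20)

  B0 <- eco_noise_matrix(s, eco_update(p, noise_scale = 0))
  expect_true(all(B0 == 0))

  B1 <- eco_noise_matrix(s, p)
  Bq <- eco_noise_matrix(s, eco_update(p, noise_scale = 0.0125))
  expect_equal(Bq, 0.0125 * B1, tolerance = 1e-12)

  # a channel with propensity 4 and stoichiometry -2 gives entry -4
  d <- eco_derived(p)
  ahl1 <- sqrt(4 * d$om2 / d$k9_eff)
  B <- eco_noise_matrix(eco_state(c1 = 0, c2 = 0, AHL1 = ahl1), p)
  expect_equal(B["AHL1", "r10"], -4, tolerance = 1e-12)
  expect_equal(B["C1", "r10"], 2, tolerance = 1e-12)
})

test_that("derived constants are recomputed, never stale", {
  p <- eco_params()
  d <- eco_derived(p)
  expect_equal(d$k6_eff, 7.5e6)
  expect_equal(d$k9_eff, 7.5e6)
  expect_equal(d$k3_eff, 1.2)
  expect_equal(d$om1, 3.7e-14 * 6.023e23)
  expect_equal(eco_derived(eco_update(p, Gc = 6e-8))$k3_eff, 0.24)

  pn <- eco_params(alpha = 25, alpha_unit = "per_nM")
  dn <- eco_derived(pn)
  expect_equal(dn$alpha1, 25 / (1e-9 * dn$om1))
  expect_equal(dn$alpha2, 25 / (1e-9 * dn$om2))
})

test_that("stoichiometry has the declared structure", {
  S <- eco_stoichiometry()
  expect_equal(dim(S), c(9, 18))
  # binding consumes two signal molecules per complex
  expect_equal(S[, "r7"][S[, "r7"] != 0],
               c(AHL2 = -2L, C2 = 1L))
  expect_equal(S[, "r10"][S[, "r10"] != 0],
               c(AHL1 = -2L, C1 = 1L))
  # Hill induction is catalytic in the inducing complex
  expect_equal(S[, "r8"][S[, "r8"] != 0], c(preRes1 = 1L))
  expect_equal(S[, "r11"][S[, "r11"] != 0], c(Res2 = 1L))
  # maturation converts preRes1 into Res1
  expect_equal(S[, "r9"][S[, "r9"] != 0],
               c(preRes1 = -1L, Res1 = 1L))
  # all remaining reactions touch exactly one species by +/- 1
  for (j in paste0("r", c(1:6, 12:18)))
    expect_equal(sum(abs(S[, j])), 1L)
})

test_that("invalid parameters and states are rejected", {
  expect_error(eco_params(k2 = -1), ">= 0")
  expect_error(eco_params(n1 = 0.5), "Hill")
  expect_error(eco_params(noise_scale = 1.5), "noise_scale")
  expect_error(eco_params(k99 = 1), "unknown parameter")
  expect_error(eco_state(c1 = -5), ">= 0")
  expect_error(eco_propensities(c(1, 2, 3), eco_params()), "length 9")
})
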