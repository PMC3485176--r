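test_that("zero noise reduces the stochastic path to the ODE path", {
  p0 <- eco_update(eco_params(), noise_scale = 0)
  tr_s <- eco_simulate(eco_state(), p0, t_end = 5, seed = 99,
                       mode = "stochastic")
  tr_d <- eco_simulate(eco_state(), eco_params(), t_end = 5,
                       mode = "deterministic")
  expect_equal(as.data.frame(tr_s)[eco_species()],
               as.data.frame(tr_d)[eco_species()])
})

test_that("compiled integrator agrees with the pure-R reference step", {
  p <- eco_params()
  tr <- eco_simulate(eco_state(), p, t_end = 0.05, dt = 0.005,
                     record_every = 1L, mode = "deterministic")
  x <- eco_state()
  for (i in 2:nrow(tr)) {
    x <- eco_step(x, p, dt = 0.005)
    expect_equal(unname(unlist(tr[i, eco_species()])), unname(x),
                 tolerance = 1e-13)
  }
})

test_that("single-decay species follows the closed-form Euler iterate", {
  p <- decay_only_params(k11 = 1.19)
  tr <- eco_simulate(eco_state(c1 = 0, c2 = 0, AHL1 = 100), p,
                     t_end = 0.05, dt = 0.005, record_every = 1L,
                     mode = "deterministic")
  expect_equal(tr$AHL1, 100 * (1 - 1.19 * 0.005)^(0:10),
               tolerance = 1e-12)
  # one reference step
  x1 <- eco_step(eco_state(c1 = 0, c2 = 0, AHL1 = 100), p, dt = 0.005)
  expect_equal(x1[["AHL1"]], 100 * (1 - 1.19 * 0.005))
})

test_that("the origin is absorbing for any noise realization", {
  zero <- eco_state(c1 = 0, c2 = 0)
  tr <- eco_simulate(zero, eco_params(), t_end = 2, seed = 5)
  expect_true(all(as.matrix(tr[, eco_species()]) == 0))
  x1 <- eco_step(zero, eco_params(), dt = 0.01, draws = rnorm(18))
  expect_equal(unname(x1), rep(0, 9))
})

test_that("identical seeds give identical trajectories", {
  a <- eco_simulate(t_end = 2, seed = 123)
  b <- eco_simulate(t_end = 2, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- eco_simulate(t_end = 2, seed = 124)
  expect_false(identical(a$c1, c$c1))
})

test_that("no recorded state is ever negative", {
  for (seed in 1:5) {
    tr <- eco_simulate(eco_state(c1 = 20, c2 = 20),
                       eco_update(eco_params(), d = 0.5),
                       t_end = 50, seed = seed)
    expect_true(all(as.matrix(tr[, eco_species()]) >= 0))
  }
})

test_that("halving the step changes the deterministic endpoint by < 0.5%", {
  t1 <- eco_simulate(t_end = 50, dt = 0.005, mode = "deterministic")
  t2 <- eco_simulate(t_end = 50, dt = 0.0025, record_every = 20L,
                     mode = "deterministic")
  for (sp in c("c1", "c2")) {
    a <- t1[[sp]][nrow(t1)]; b <- t2[[sp]][nrow(t2)]
    expect_lt(abs(a - b) / b, 0.005)
  }
})

test_that("deterministic path agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- eco_params()
  rhs <- function(t, y, parms) {
    names(y) <- eco_species()
    list(unname(eco_drift(pmax(y, 0), p)))
  }
  out <- deSolve::ode(unname(eco_state()), seq(0, 30, 5), rhs, NULL,
                      method = "lsoda")
  tr <- eco_simulate(t_end = 30, mode = "deterministic")
  for (k in 1:2) {
    ours <- tr[[c("c1", "c2")[k]]][nrow(tr)]
    ref <- out[nrow(out), k + 1]
    expect_lt(abs(ours - ref) / ref, 0.01)
  }
})

test_that("ensemble mean approaches the ODE path as noise shrinks", {
  det <- eco_simulate(t_end = 10, mode = "deterministic")
  d_end <- det$c1[nrow(det)]
  disc <- sapply(c(0.1, 0.01, 1e-4), function(eps) {
    p <- eco_update(eco_params(), noise_scale = eps)
    g <- glance(eco_ensemble(eco_state(), p, n = 30, t_end = 10,
                             base_seed = 9))
    abs(g$c1_mean - d_end) / d_end
  })
  expect_true(all(diff(disc) < 0))
  expect_lt(disc[3], 0.02)
})

test_that("unprotected monocultures are absorbed and flagged extinct", {
  tr <- eco_simulate(eco_state(c1 = 5e4, c2 = 0), eco_params(),
                     t_end = 50, mode = "deterministic")
  expect_equal(tr$c1[nrow(tr)], 0)
  ext <- attr(tr, "extinct_at")
  expect_true(is.finite(ext))
  # both populations stay at zero from the extinction time on
  after <- tr$time >= ext
  expect_true(all(tr$c1[after] == 0) && all(tr$c2[after] == 0))
  # decay rate k3*Gc - k1 = 0.966 per hour from 5e4 cells to < 1 cell
  expect_equal(ext, log(5e4) / (1.2 - 0.234), tolerance = 0.05)
})

test_that("steady-state detector handles canonical shapes", {
  const <- data.frame(time = seq(0, 30, 0.05), c1 = 100, c2 = 200)
  expect_equal(steady_state_time(const), 5)

  # still-growing logistic signal is not called steady
  tt <- seq(0, 30, 0.05)
  grow <- data.frame(time = tt,
                     c1 = 1e9 / (1 + 1e5 * exp(-0.3 * tt)),
                     c2 = 1e9 / (1 + 1e5 * exp(-0.3 * tt)))
  expect_true(is.na(steady_state_time(grow)))

  expect_error(steady_state_time(const, window = 50), "window")

  # baseline deterministic run settles
  tr <- eco_simulate(t_end = 50, mode = "deterministic")
  tss <- steady_state_time(as.data.frame(tr)[c("time", "c1", "c2")])
  expect_true(is.finite(tss) && tss < 30)
})

test_that("baseline deterministic co-culture persists with c2 above c1", {
  tr <- eco_simulate(t_end = 50, mode = "deterministic")
  last <- nrow(tr)
  expect_gt(tr$c1[last], 0)
  expect_gt(tr$c2[last], tr$c1[last])
})

test_that("trajectories tidy and write in long form", {
  tr <- eco_simulate(t_end = 1, seed = 3)
  long <- tidy(tr)
  expect_named(long, c("time", "species", "value", "seed", "mode"))
  expect_equal(nrow(long), nrow(tr) * 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(long))
  expect_equal(unique(back$mode), "stochastic")
})
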