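test_that("hill function matches its closed form and stays in its bounds", {
  spec <- hill_spec(theta = 200, lam = 10, n = 2)
  expect_identical(hill(0, spec), 1)
  expect_equal(hill(200, spec), 5.5) # half-saturation: (lam + 1)/2
  expect_equal(hill(1e12, hill_spec(30, 0, 2)), 0, tolerance = 1e-12)

  # bounds and monotonicity over random shapes
  for (s in 1:20) {
    sp <- withr::with_seed(s, hill_spec(theta = runif(1, 1, 500),
                                        lam = runif(1, 0, 12),
                                        n = runif(1, 0.5, 4)))
    x <- seq(0, 2000, length.out = 200)
    hx <- hill(x, sp)
    expect_true(all(hx >= min(1, sp$lam) - 1e-12))
    expect_true(all(hx <= max(1, sp$lam) + 1e-12))
    d <- diff(hx)
    if (sp$lam > 1) expect_true(all(d >= -1e-12))
    if (sp$lam < 1) expect_true(all(d <= 1e-12))
  }
  expect_error(hill(-1, spec), "nonnegative")
  expect_error(hill_spec(0, 10, 2))
})

test_that("parameter constructor validates and baseline is Table-1-like", {
  p <- baseline
  expect_equal(p$bD, 100)
  expect_equal(p$bN, 500)
  expect_equal(p$khe, 1e-3)
  expect_equal(p$hill_R$lam, 0)
  expect_error(signalling_params(beta = 0))
  expect_error(signalling_params(alpha = 2), "alpha")
  expect_error(update_params(p, nonsense = 1), "unknown")
  p2 <- update_params(p, khe = 0, lam_D = 5)
  expect_equal(p2$khe, 0)
  expect_equal(p2$hill_D$lam, 5)
  expect_equal(p2$bD, p$bD)
})

test_that("model-1 derivatives follow the mass-action balance", {
  p <- baseline
  expect_equal(rhs_model1(cell_state(), p),
               c(D = 100, J = 100, C = 0, N = 500, S = 0))
  # bD - beta*D - 2*kho*D^2 = 0 at D = 500 (bJ plays no role when J = 0)
  expect_equal(rhs_model1(cell_state(D = 500), p)[["D"]], 0)
  expect_equal(rhs_model1(cell_state(S = 10), p)[["S"]], -5)
  # trans terms: Dext drives S release through N
  d <- rhs_model1(cell_state(N = 1000), p,
                  trans_input(Dext = 200, Jext = 100), Next = 50)
  expect_equal(d[["S"]], p$kt * 200 * 1000 + p$alpha * p$kt * 100 * 1000)
  expect_equal(d[["N"]],
               p$bN - p$beta * 1000 - p$kt * 200 * 1000 -
                 p$alpha * p$kt * 100 * 1000)
})

test_that("model-2 couples VEGF through the two Hill regulations", {
  p <- baseline
  # V = 0: DLL4 production is exactly bD
  d0 <- rhs_model2(cell_state2(), p, V_local = 0)
  expect_equal(d0[["D"]], p$bD)
  expect_equal(d0[["R"]], p$bR)
  # S at the VEGFR2 half-saturation with lam_R = 0 halves production
  dh <- rhs_model2(cell_state2(S = 30), p, V_local = 0)
  expect_equal(dh[["R"]], 0.5 * p$bR) # 400 molecules/h
  # V-equation balances binding and decay
  dv <- rhs_model2(cell_state2(R = 100, V = 10), p, V_local = 2500)
  expect_equal(dv[["V"]], p$kv * 2500 * 100 - p$betaS * 10)
  expect_error(rhs_model2(cell_state(), p, V_local = 0), "R")
})

test_that("reversible-heterodimer derivatives follow the mass balance", {
  p <- baseline
  rev <- reversible_binding(kplus = 2e-3, kminus = 0.1)
  d0 <- rhs_reversible(cell_state_rev(), p, reversible_binding(1e-3, 0))
  expect_equal(d0[c("D", "J", "DJ")], c(D = p$bD, J = p$bJ, DJ = 0))
  d1 <- rhs_reversible(cell_state_rev(D = 100, J = 100), p, rev)
  expect_equal(d1[["DJ"]], 2e-3 * 100 * 100) # 20 molecules/h
})

test_that("RK4 reproduces exponential decay and is fourth order", {
  rhs <- function(x) c(x = -0.1 * x[["x"]])
  tr <- rk4_integrate(rhs, c(x = 100), h = 0.01, t_end = 10,
                      steady_tol = 0)
  expect_equal(tr$final_state[["x"]], 100 * exp(-1), tolerance = 1e-6)
  expect_lt(abs(tr$final_state[["x"]] - 100 * exp(-1)), 1e-4)
  # halving h shrinks the error ~16x (order 4); a stiffer rate makes the
  # error measurable above round-off
  err <- function(h) {
    f <- function(x) c(x = -2 * x[["x"]])
    abs(rk4_integrate(f, c(x = 1e6), h = h, t_end = 5,
                      steady_tol = 0)$final_state[["x"]] - 1e6 * exp(-10))
  }
  ratio <- err(0.1) / err(0.05)
  expect_gt(ratio, 12)
  expect_lt(ratio, 20)
})

test_that("RK4 handles steady detection, clamps and pathologies", {
  # identically zero RHS: constant and converged at the first check
  tr <- rk4_integrate(function(x) c(a = 0, b = 0), c(a = 3, b = 4),
                      h = 0.1, t_end = 100)
  expect_true(tr$converged)
  expect_equal(tr$final_state, c(a = 3, b = 4))
  expect_lt(tr$t_final, 100)

  # clamped species never move, free species see the clamp value
  p <- baseline
  tr2 <- rk4_integrate(function(s) rhs_model1(s, p), cell_state(),
                       h = 0.01, t_end = 30, clamps = c(D = 1234),
                       record_every = 500L)
  expect_true(all(tr2$states$D == 1234))
  expect_gt(tr2$final_state[["C"]], 0) # homodimers formed from clamped D

  # divergence and genuine negativity are errors, not silent states
  expect_error(rk4_integrate(function(x) c(x = x[["x"]]^2), c(x = 1),
                             h = 0.5, t_end = 50), "non-finite")
  expect_error(rk4_integrate(function(x) c(x = -100), c(x = 1),
                             h = 0.5, t_end = 50), "negative")
})

test_that("model-1 steady state from the package RK4 agrees with lsoda", {
  skip_if_not_installed("deSolve")
  p <- update_params(baseline, khe = 0.1, bD = 100, bJ = 50)
  rhs <- function(s) rhs_model1(s, p, trans_input(Dext = 300, Jext = 100),
                                Next = 500)
  mine <- rk4_integrate(rhs, cell_state(), h = 0.01, t_end = 400,
                        steady_tol = 0)$final_state
  ds <- deSolve::lsoda(
    y = cell_state(),
    times = c(0, 400),
    func = function(t, y, parms) list(rhs(y)),
    rtol = 1e-10, atol = 1e-10)
  expect_equal(mine, ds[2, -1], tolerance = 1e-6)
})

test_that("positivity is preserved for random nonnegative systems", {
  for (s in 1:5) {
    p <- random_params(s)
    tr <- rk4_integrate(
      function(st) rhs_model1(st, p, trans_input(Dext = 200, Jext = 200),
                              Next = 300),
      cell_state(D = 10, J = 10, C = 5, N = 50, S = 5),
      h = 0.01, t_end = 60, steady_tol = 0, record_every = 200L)
    expect_true(all(as.matrix(tr$states[, -1]) >= 0))
  }
})

test_that("model 2 without VEGFR2 production reduces to model 1", {
  p0 <- update_params(baseline, bR = 0)
  trans <- trans_input(Dext = 500, Jext = 300)
  rhs2 <- function(s) rhs_model2(s, p0, V_local = 2500, trans, Next = 200)
  rhs1 <- function(s) rhs_model1(s, baseline, trans, Next = 200)
  tr2 <- rk4_integrate(rhs2, cell_state2(), h = 0.01, t_end = 50,
                       steady_tol = 0, record_every = 100L)
  tr1 <- rk4_integrate(rhs1, cell_state(), h = 0.01, t_end = 50,
                       steady_tol = 0, record_every = 100L)
  shared <- c("D", "J", "C", "N", "S")
  expect_equal(as.matrix(tr2$states[, shared]),
               as.matrix(tr1$states[, shared]), tolerance = 1e-12)
  expect_true(all(tr2$states$R == 0))
  expect_true(all(tr2$states$V == 0))
})

test_that("trajectory tidiers return the documented shapes", {
  tr <- rk4_integrate(function(s) rhs_model1(s, baseline), cell_state(),
                      h = 0.1, t_end = 5, record_every = 10L,
                      steady_tol = 0)
  long <- tidy(tr)
  expect_named(long, c("time_h", "species", "level"))
  expect_setequal(unique(long$species), c("D", "J", "C", "N", "S"))
  g <- glance(tr)
  expect_equal(g$t_final, 5)
  expect_s3_class(autoplot(tr), "ggplot")
})
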