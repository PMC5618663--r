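test_that("the closed form solves the rate equations", {
  skip_if_not_installed("deSolve")
  set.seed(202)  # local to this property check
  for (i in 1:25) {
    pp <- popdyn_params(k_AB = runif(1, 0, 0.05), k_dA = runif(1, 0, 0.02),
                        k_dB = runif(1, 0, 0.02), a0 = runif(1, 0.2, 2),
                        b0 = runif(1, 0, 0.5))
    n <- seq(0, 400, by = 20)
    cf <- population_closed_form(pp, n)
    ode <- deSolve::lsoda(
      y = c(a = pp$a0, b = pp$b0), times = n,
      func = function(t, y, p) {
        list(c(-(p$k_AB + p$k_dA) * y[1],
               p$k_AB * y[1] - p$k_dB * y[2]))
      }, parms = pp, rtol = 1e-12, atol = 1e-12)
    expect_lt(max(abs(cf$a - ode[, "a"]), abs(cf$b - ode[, "b"])), 1e-8)
  }
})

test_that("closed-form anchors: initial condition, conservation, degeneracy", {
  pp <- popdyn_params(k_AB = 0.01, k_dA = 0.004, k_dB = 0.002,
                      a0 = 0.7, b0 = 0.2)
  at0 <- population_closed_form(pp, 0)
  expect_equal(c(at0$a, at0$b), c(0.7, 0.2))
  cons <- popdyn_params(k_AB = 0.03, k_dA = 0, k_dB = 0, a0 = 0.7, b0 = 0.2)
  tr <- population_closed_form(cons, 0:500)
  expect_lt(max(abs(tr$a + tr$b - 0.9)), 1e-10)
  # alpha == k_dB: the analytic limit takes over smoothly
  deg <- popdyn_params(k_AB = 0.003, k_dA = 0.002, k_dB = 0.005,
                       a0 = 1, b0 = 0)
  near <- popdyn_params(k_AB = 0.003, k_dA = 0.002, k_dB = 0.005 + 1e-10,
                        a0 = 1, b0 = 0)
  expect_equal(population_closed_form(deg, 0:300)$b,
               population_closed_form(near, 0:300)$b, tolerance = 1e-7)
})

test_that("a(n) decreases and b(n) is unimodal with the predicted peak", {
  pp <- popdyn_params(k_AB = 0.004, k_dA = 0.002, k_dB = 0.003,
                      a0 = 1, b0 = 0)
  n <- 0:999
  tr <- population_closed_form(pp, n)
  expect_true(all(diff(tr$a) < 0))
  pk <- which.max(tr$b)
  expect_true(all(diff(tr$b[1:pk]) > 0))
  expect_true(all(diff(tr$b[pk:length(n)]) < 0))
  n_star <- b_peak_cycle(pp)
  expect_equal(n_star, log(0.006 / 0.003) / (0.006 - 0.003), tolerance = 1e-12)
  expect_lt(abs((pk - 1) - n_star), 1)  # grid resolution
})

test_that("population fits round-trip exactly on noiseless amplitudes", {
  pp <- popdyn_params(k_AB = 0.006, k_dA = 0.003, k_dB = 0.004,
                      a0 = 1.2, b0 = 0.15)
  tr <- population_closed_form(pp, 0:299)
  amps <- data.frame(cycle = 1:300, a = tr$a, b = tr$b)
  fit <- fit_population_dynamics(amps)
  expect_rel_equal(coef(fit)[c("k_AB", "k_dA", "k_dB")],
                   c(0.006, 0.003, 0.004), 1e-4)
  expect_rel_equal(coef(fit)[c("a0", "b0")], c(1.2, 0.15), 1e-5)
  expect_error(fit_population_dynamics(
    data.frame(cycle = 1:10, a = 0, b = 0)), "zero")
  expect_error(fit_population_dynamics(amps[1:3, ]), "5 cycles")
})

test_that("fatigue metrics read on-level, baseline, contrast and half-life", {
  # no destruction, no interconversion: flat on-level and baseline
  tr0 <- ground_truth(two_state_kinetics(10, 1.2, f_B = 0.2, c = 0.01),
                      popdyn_params(0, 0, 0, a0 = 0.9, b0 = 0.1),
                      seed = 2)
  ex0 <- simulate_switching(protocol_hela(20), tr0)
  f0 <- fatigue_metrics(ex0)
  expect_equal(f0$per_cycle$on_level, rep(1, 20))
  expect_lt(diff(range(f0$per_cycle$baseline)), 1e-12)
  expect_true(all(f0$per_cycle$contrast > 1))
  expect_true(is.na(f0$cycles_to_half))

  # rising-then-falling baseline driven by B accumulation
  trb <- ground_truth(two_state_kinetics(10, 1.2, f_B = 0.15, c = 0.02),
                      popdyn_params(0.01, 0.002, 0.006, a0 = 1, b0 = 0),
                      seed = 3)
  exb <- simulate_switching(protocol_hela(400), trb)
  fb <- fatigue_metrics(exb)
  base <- fb$per_cycle$baseline
  pk <- which.max(base)
  expect_gt(pk, 10); expect_lt(pk, 390)
  expect_gt(base[pk], base[1])
  expect_gt(base[pk], base[400])

  # pure species A: cycles-to-half equals ln 2 / alpha
  alpha <- 0.02
  tra <- ground_truth(two_state_kinetics(10, 0.1, c = 0),
                      popdyn_params(k_AB = 0, k_dA = alpha, k_dB = 0,
                                    a0 = 1, b0 = 0),
                      seed = 4)
  exa <- simulate_switching(protocol_hela(80), tra)
  fa <- fatigue_metrics(exa)
  expect_equal(fa$cycles_to_half, log(2) / alpha, tolerance = 5e-3)
})

test_that("the photon-dose proxy matches quadrature and its limits", {
  D <- function(k, f, T_off) {
    integrate(function(t) (1 - f) * exp(-k * t) + f, 0, T_off,
              rel.tol = 1e-12)$value
  }
  for (ps in list(c(3, 0.1, 2.5), c(0.5, 0, 12), c(8, 0.3, 1))) {
    es <- expected_stabilization_from_speed(ps[1], ps[1] * 2, f = ps[2],
                                            T_off = ps[3])
    expect_equal(es$dose_free, D(ps[1], ps[2], ps[3]), tolerance = 1e-10)
    expect_equal(es$dose_fusion, D(2 * ps[1], ps[2], ps[3]), tolerance = 1e-10)
  }
  same <- expected_stabilization_from_speed(2, 2, T_off = 2.5)
  expect_equal(same$ratio, 1)
  expect_equal(same$percent_stabilization, 0)
  # f = 0, kT >> 1: ratio approaches k_fusion / k_free
  lim <- expected_stabilization_from_speed(50, 200, f = 0, T_off = 10)
  expect_equal(lim$ratio, 4, tolerance = 1e-3)
})

test_that("observed stabilization is the destruction-rate fold change", {
  pf <- popdyn_params(0.004, 0.008, 0.003, 1, 0.1)
  pu <- popdyn_params(0.004, 0.001, 0.003, 1, 0.1)
  expect_equal(observed_stabilization(pf, pu)$fold, 8)
  expect_equal(observed_stabilization(pf, pf)$fold, 1)
  zero <- popdyn_params(0.004, 0, 0.003, 1, 0.1)
  expect_identical(observed_stabilization(pf, zero)$fold, Inf)
  both <- observed_stabilization(pf, pu, k_free = 5, k_fusion = 10,
                                 T_off = 2.5)
  es <- expected_stabilization_from_speed(5, 10, T_off = 2.5)
  expect_equal(both$intrinsic_fold, 8 / es$ratio)
})

test_that("baseline trajectory tracks the B plateau prediction", {
  tr <- ground_truth(two_state_kinetics(10, 1.2, f_B = 0.15, c = 0.02),
                     popdyn_params(0.006, 0.002, 0.004, a0 = 1, b0 = 0.05),
                     seed = 11)
  ex <- simulate_switching(protocol_hela(300), tr)
  base <- fatigue_metrics(ex)$per_cycle$baseline
  pred <- ex$amplitudes$b * 0.15 + 0.02
  expect_gte(cor(base, pred, method = "spearman"), 0.95)
})
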