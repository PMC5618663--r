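test_that("seeded generation is deterministic and seeds matter", {
  tr <- default_truth(seed = 42)
  e1 <- simulate_switching(protocol_hela(10), tr)
  e2 <- simulate_switching(protocol_hela(10), tr)
  expect_identical(e1$traces, e2$traces)
  e3 <- simulate_switching(protocol_hela(10), default_truth(seed = 43))
  expect_false(identical(e1$traces$intensity, e3$traces$intensity))
  # recovery and titration generators share the contract
  r1 <- simulate_recovery(0.01, 0.1, 1, noise = noise_model(read_sigma = 0.05),
                          seed = 5)
  r2 <- simulate_recovery(0.01, 0.1, 1, noise = noise_model(read_sigma = 0.05),
                          seed = 5)
  expect_identical(r1, r2)
  t1 <- simulate_titration(6.2, noise_sigma = 0.02, seed = 9)
  t2 <- simulate_titration(6.2, noise_sigma = 0.02, seed = 9)
  expect_identical(t1, t2)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(runif(1))
  invisible(simulate_switching(protocol_hela(3), default_truth(seed = 9)))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("noiseless off-frames equal the analytic two-species decay", {
  tr <- short_truth(seed = 1, noisy = FALSE)
  proto <- protocol_hela(40)
  ex <- simulate_switching(proto, tr)
  sched <- ex$schedule
  off <- sched$half_cycle == "off"
  pred <- unlist(lapply(seq_len(proto$n_cycles), function(i) {
    decay_model(sched$t_half[off & sched$cycle == i], tr$kinetics,
                ex$amplitudes$a[i], ex$amplitudes$b[i])
  }))
  expect_lt(max(abs(ex$traces$intensity[off] - pred) / pred), 1e-10)
  # and on-frames sit at the fully recovered level
  on <- sched$half_cycle == "on"
  lev <- (ex$amplitudes$a + ex$amplitudes$b + tr$kinetics$c)[sched$cycle[on]]
  expect_equal(ex$traces$intensity[on], lev, tolerance = 1e-12)
})

test_that("degenerate single-species truth repeats one mono-exponential cycle", {
  ex <- simulate_switching(protocol_hela(6), single_species_truth(seed = 2))
  Y <- matrix(ex$traces$intensity[ex$schedule$half_cycle == "off"], nrow = 25)
  for (i in 2:6) expect_equal(Y[, i], Y[, 1], tolerance = 1e-12)
  # mono-exponential: log-linear with the species rate
  t_off <- ex$schedule$t_half[ex$schedule$half_cycle == "off" &
                                ex$schedule$cycle == 1]
  slope <- coef(lm(log(Y[, 1]) ~ t_off))[[2]]
  expect_equal(slope, -5, tolerance = 1e-6)
})

test_that("with interconversion and B destruction, b_n rises then falls", {
  tr <- ground_truth(
    kinetics = two_state_kinetics(k_A = 10, k_B = 1.2, f_B = 0.15, c = 0),
    popdyn = popdyn_params(k_AB = 0.01, k_dA = 0.002, k_dB = 0.006,
                           a0 = 1, b0 = 0),
    seed = 3)
  ex <- simulate_switching(protocol_hela(500), tr)
  b <- ex$amplitudes$b
  pk <- which.max(b)
  expect_gt(pk, 5)
  expect_lt(pk, 495)
  expect_true(all(diff(b[1:pk]) > 0))
  expect_true(all(diff(b[pk:500]) < 0))
})

test_that("conservation holds without photodestruction", {
  pp <- popdyn_params(k_AB = 0.02, k_dA = 0, k_dB = 0, a0 = 0.8, b0 = 0.2)
  tr <- population_closed_form(pp, 0:300)
  expect_lt(max(abs(tr$a + tr$b - 1)), 1e-10)
})

test_that("mean of noisy replicates converges to the noiseless value", {
  # one frame, 1000 replicates of shot + read noise
  nm <- noise_model(shot_scale = 500, read_sigma = 0.02)
  signal <- 0.7
  reps <- vapply(seq_len(1000), function(i) {
    simulate_recovery(k_th = 0, F0 = signal, Finf = signal, duration = 30,
                      sampling = 30, noise = nm, seed = i)$intensity[1]
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - signal), 3 * se)
})

test_that("recovery traces obey the relaxation form", {
  # flat when k_th = 0
  r <- simulate_recovery(k_th = 0, F0 = 0.2, Finf = 0.9)
  expect_equal(r$intensity, rep(0.2, 21))
  # half-life identity at t = ln(2)/k
  k <- 0.004
  r2 <- simulate_recovery(k_th = k, F0 = 0.1, Finf = 0.9,
                          duration = 2 * log(2) / k, sampling = log(2) / k)
  expect_equal(r2$intensity[2], 0.5, tolerance = 1e-12)
  # 10 min sampled every 30 s -> 21 samples including t = 0
  r3 <- simulate_recovery(k_th = 0.005, F0 = 0.1, Finf = 1,
                          duration = 600, sampling = 30)
  expect_identical(nrow(r3), 21L)
  expect_identical(r3$time_s[1], 0)
  expect_error(simulate_recovery(k_th = -1, F0 = 0, Finf = 1), "k_th")
})

test_that("titration tables follow the sigmoid", {
  tt <- simulate_titration(pKa = 6.5, A_max = 0.8, hill = 1,
                           pH_grid = c(3, 6.5, 11))
  expect_equal(tt$absorbance[2], 0.4, tolerance = 1e-12)  # inflection
  expect_equal(tt$absorbance[3], 0.8, tolerance = 1e-3)   # saturation
  full <- simulate_titration(pKa = 6.2)
  expect_true(all(diff(full$absorbance) > 0))
})

test_that("rendered colony stacks match direct per-pixel evaluation", {
  tr <- single_species_truth(seed = 4)
  proto <- switching_protocol(1, 4, 8, 0.2)
  ex <- simulate_switching(proto, tr, n_objects = 2)
  lay <- colony_layout(c(40, 60), rbind(c(10, 15), c(25, 44)),
                       radii = c(5, 4), intensity_scale = c(1, 2.5),
                       background_level = 0.1)
  stack <- render_colony_stack(ex, lay)
  # brute-force oracle render
  traces <- matrix(ex$traces$intensity, ncol = 2)
  for (f in c(1, 5, 12)) {
    ref <- matrix(0.1, 40, 60)
    for (r in 1:40) for (cc in 1:60) for (i in 1:2) {
      if ((r - 1 - lay$centers[i, 1])^2 + (cc - 1 - lay$centers[i, 2])^2 <=
          lay$radii[i]^2) {
        ref[r, cc] <- ref[r, cc] + lay$intensity_scale[i] * traces[f, i]
      }
    }
    expect_equal(stack[, , f], ref, tolerance = 1e-12)
  }
  # object/trace count mismatch is an error
  expect_error(render_colony_stack(ex, colony_layout(c(40, 60),
                                                     rbind(c(10, 15)), 5)),
               "object")
  # a zero-brightness disk leaves a pure background stack
  ex1 <- simulate_switching(proto, tr, n_objects = 1)
  lay0 <- colony_layout(c(16, 16), rbind(c(8, 8)), 3, intensity_scale = 0,
                        background_level = 0.3)
  st0 <- render_colony_stack(ex1, lay0)
  expect_true(all(st0 == 0.3))
})

test_that("non-finite or invalid generator parameters are rejected", {
  expect_error(two_state_kinetics(k_A = NaN, k_B = 1), "finite")
  expect_error(two_state_kinetics(k_A = 1, k_B = 2), "k_A must exceed")
  expect_error(popdyn_params(k_AB = -1, k_dA = 0, k_dB = 0, a0 = 1, b0 = 0),
               "range")
  expect_error(noise_model(shot_scale = -5), "range")
  expect_error(ground_truth(two_state_kinetics(2, 1),
                            popdyn_params(0, 0, 0, 1, 0)),
               "seed")
  expect_error(colony_layout(c(10, 10), rbind(c(5, 5), c(6, 6)), 3),
               "overlap")
  expect_error(colony_layout(c(10, 10), rbind(c(1, 5)), 3), "bounds")
})
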