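test_that("peaks of a clean sinusoid are located to sub-sample accuracy", {
  s <- sinusoid_series(22, 110, dt = 0.1)
  pk <- detect_peaks(s, min_prominence = 0.2)
  expect_equal(as.numeric(pk), c(5.5, 27.5, 49.5, 71.5, 93.5),
               tolerance = 0.1 / 5.5)
})

test_that("constant series and endpoints yield no peaks", {
  s <- data.frame(time = 0:20, value = rep(1, 21))
  expect_length(detect_peaks(s), 0)
  ramp <- data.frame(time = 0:20, value = 0:20) # max at the endpoint
  expect_length(detect_peaks(ramp), 0)
})

test_that("low-prominence spikes are rejected", {
  s <- sinusoid_series(22, 110, dt = 0.1)
  # single-sample spikes of 10% of the range, on the flanks between peaks
  spike_at <- which(s$time %in% c(11, 33, 55, 77, 99))
  s$value[spike_at] <- s$value[spike_at] + 0.2
  pk <- detect_peaks(s, min_prominence = 0.5)
  expect_length(pk, 5)
  expect_equal(as.numeric(pk), c(5.5, 27.5, 49.5, 71.5, 93.5),
               tolerance = 0.02)
})

test_that("plateau maxima break ties toward earlier time", {
  sq <- data.frame(time = seq(0, 48, by = 0.5),
                   value = light_at(symmetric_ld(6), seq(0, 48, by = 0.5)))
  pk <- detect_peaks(sq, min_prominence = 0.5)
  expect_equal(as.numeric(pk) %% 12, rep(0, length(pk)))
})

test_that("period estimation recovers a pure sinusoid exactly", {
  s <- sinusoid_series(22, 220, dt = 0.1)
  pe <- estimate_period(s)
  expect_true(pe$defined)
  expect_equal(pe$mean, 22, tolerance = 0.1 / 22)
  expect_equal(pe$sd, 0, tolerance = 0.01)
  expect_equal(pe$spectral, 22, tolerance = 0.5 / 22)
})

test_that("undefined period is flagged when too few peaks remain", {
  s <- sinusoid_series(22, 40, dt = 0.1) # < 2 full cycles
  pe <- estimate_period(s)
  expect_false(pe$defined)
  expect_true(is.na(pe$mean))
})

test_that("noisy periods are recovered within 2% (exhaustive oracle)", {
  # oracle: argmax of a brute-force periodogram at 0.01 h resolution
  for (P in c(2, 6, 16, 22, 27)) {
    s <- sinusoid_series(P, 12 * P, dt = P / 40, noise_sd = 0.1,
                         seed = 100 + P)
    # prominence raised to a third of the range: noise wiggles must not
    # masquerade as cycle peaks
    pe <- estimate_period(s, min_prominence = 0.3)
    grid <- seq(max(0.5, 0.5 * P), 2 * P, by = 0.01)
    pw <- frqclock:::periodogram_cpp(s$time, s$value - mean(s$value), grid)
    oracle <- grid[which.max(pw)]
    expect_equal(pe$mean, oracle, tolerance = 0.02)
    expect_equal(pe$mean, P, tolerance = 0.02)
  }
})

test_that("the forcing signal shows a perfectly stable phase angle", {
  prot <- symmetric_ld(6)
  t <- seq(0, 400, by = 0.25)
  s <- data.frame(time = t, value = light_at(prot, t))
  ph <- phase_angle(s, prot)
  expect_gte(length(ph), 3)
  expect_equal(sd(ph), 0, tolerance = 1e-9)
  expect_error(phase_angle(s, ld_constant(0)), "non-periodic")
})

test_that("onset reference crosses the cycle mid-range upward", {
  prot <- symmetric_ld(6)
  t <- seq(0, 400, by = 0.1)
  s <- data.frame(time = t, value = sin(2 * pi * t / 12))
  on <- phase_angle(s, prot, reference = "onset")
  # sine rises through 0 (its mid-range) at each cycle start
  expect_equal(mean(on), 0, tolerance = 0.1)
})

test_that("phase angles are stable under LD6:6 and drift under LD2:2", {
  p <- default_parameters()
  tr6 <- cached("ld6_long", simulate_clock(p, symmetric_ld(6), 640))
  ph <- phase_angle(trajectory_series(tr6, "F"), symmetric_ld(6),
                    reference = "fundamental", discard = 400)
  expect_gte(length(ph), 3)
  # circular SD: the converged offsets sit right at the cycle boundary
  expect_lte(frqclock:::circular_sd(ph, 12), 0.5)
  r2 <- rhythm_report(trajectory_series(ld_traj(2), "F"), symmetric_ld(2),
                      discard = std_discard(2))
  expect_gt(r2$phase_sd, 0.5) # above the entrainment threshold for T = 4
  expect_false(r2$classification == "entrained")
})

test_that("entrained series carry strong forcing-band power", {
  tr <- ld_traj(6)
  prot <- symmetric_ld(6)
  rep <- rhythm_report(trajectory_series(tr, "F"), prot,
                       discard = std_discard(6))
  expect_identical(rep$classification, "entrained")
  expect_gte(rep$forcing_band_power_ratio, 3)
})

test_that("insufficient data is refused with the required duration", {
  s <- sinusoid_series(12, 150, dt = 0.25)
  expect_error(rhythm_report(s, symmetric_ld(6), discard = 96),
               "insufficient data")
})

test_that("a series flat across light and dark has zero light response", {
  prot <- symmetric_ld(6)
  t <- seq(0, 400, by = 0.25)
  s <- data.frame(time = t, value = rep(2, length(t)))
  expect_equal(light_response_amplitude(s, prot), 0)
  expect_error(light_response_amplitude(s, ld_constant(1)), "periodic")
})

test_that("doubling v_light doubles the induction in the low-saturation regime", {
  # a parameter set with FRQ far below K_I (repression gate open) and no
  # FRQ support of wc-1 (k_fw = 0), so the response is linear in the drive
  q0 <- unclass(default_parameters())
  q0$K_I <- 50
  q0$k_fw <- 0
  p1 <- frqclock:::validate_parameters(q0)
  q0$v_light <- q0$v_light * 2
  p2 <- frqclock:::validate_parameters(q0)
  prot <- symmetric_ld(12)
  amp <- function(p) {
    tr <- simulate_clock(p, prot, 96 + 24 * 6, dt = 0.02)
    light_response_amplitude(trajectory_series(tr, "M_frq"), prot,
                             discard = 96)
  }
  expect_equal(amp(p2) / amp(p1), 2, tolerance = 0.25)
})

test_that("identical protein and mRNA series give smoothness ratio 1", {
  prot <- symmetric_ld(3)
  t <- seq(0, 200, by = 0.1)
  s <- data.frame(time = t, value = 1 + 0.5 * sin(2 * pi * t / 6) +
                    0.1 * sin(2 * pi * t / 22))
  expect_equal(smoothness_ratio(s, s, prot), 1)
  s2 <- s; s2$time <- s2$time + 0.05
  expect_error(smoothness_ratio(s, s2, prot), "same time grid")
})

test_that("classification survives 5% multiplicative noise (20 seeds)", {
  thin <- function(tr, comp) {
    s <- trajectory_series(tr, comp)
    s[seq(1, nrow(s), by = 25), ] # 0.25 h sampling
  }
  s6 <- thin(ld_traj(6), "F")
  s2 <- thin(ld_traj(2), "F")
  for (seed in 1:20) {
    set.seed(seed)
    n6 <- s6; n6$value <- n6$value * exp(rnorm(nrow(n6), 0, 0.05))
    n2 <- s2; n2$value <- n2$value * exp(rnorm(nrow(n2), 0, 0.05))
    expect_identical(classify_entrainment(n6, symmetric_ld(6),
                                          discard = std_discard(6)),
                     "entrained")
    expect_identical(classify_entrainment(n2, symmetric_ld(2),
                                          discard = std_discard(2)),
                     "free_running")
  }
})
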