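test_that("derivative reduces to synthesis terms at the zero state", {
  p <- default_parameters()
  zero <- rep(0, 6)
  d <- clock_derivative(zero, zero, light = 0, p)
  expect_equal(unname(d["M_wc1"]), p$v_w)
  expect_equal(unname(d[c("M_frq", "F", "W_dark", "W_light", "V")]),
               rep(0, 5))
  # with light on, the zero state still has nothing to activate
  d1 <- clock_derivative(zero, zero, light = 1, p)
  expect_equal(unname(d1["W_light"]), 0)
})

test_that("in darkness the light-activation inflow vanishes", {
  p <- default_parameters()
  st <- c(0.4, 1.2, 0.3, 0.8, 0.5, 0.7)
  d <- clock_derivative(st, st, light = 0, p)
  # W_light only loses mass: reversion plus clearance, no activation term
  expect_equal(unname(d["W_light"]), -(p$k_rel + p$d_Wl) * st[5])
  expect_equal(unname(d["V"]), p$k_v * st[5] - p$d_V * st[6])
})

test_that("derivative vanishes at the independently solved dark fixed point", {
  # low Hill exponent puts the dark system in its non-oscillatory regime;
  # the steady state reduces to a scalar root problem in F solved by uniroot
  p <- default_parameters()
  q <- unclass(p); q$h <- 1
  p1 <- frqclock:::validate_parameters(q)
  f_of_F <- function(F) {
    Mw <- (p1$v_w + p1$k_fw * F) / p1$d_Mw
    Wd <- p1$k_w * Mw / p1$d_Wd
    M <- p1$v_dark * Wd * p1$K_I / (p1$K_I + F) / p1$d_M
    p1$k_s * M / p1$d_F - F
  }
  Fstar <- uniroot(f_of_F, c(1e-9, 1e4), tol = 1e-14)$root
  Mw <- (p1$v_w + p1$k_fw * Fstar) / p1$d_Mw
  Wd <- p1$k_w * Mw / p1$d_Wd
  M <- p1$v_dark * Wd * p1$K_I / (p1$K_I + Fstar) / p1$d_M
  x <- c(M, Fstar, Mw, Wd, 0, 0)
  expect_lt(max(abs(clock_derivative(x, x, 0, p1))), 1e-9)
})

test_that("derivative validates its inputs", {
  p <- default_parameters()
  st <- rep(0.1, 6)
  expect_error(clock_derivative(c(st[-6], NaN), st, 0, p), "non-finite")
  expect_error(clock_derivative(st, st, 1.5, p), "light")
  expect_error(clock_derivative(st[-1], st, 0, p), "length 6")
  expect_error(model_parameters(
    v_dark = -1, v_light = 1, K_I = 1, h = 2, d_M = .3, k_s = .5, tau = 6,
    d_F = .3, v_w = .1, k_fw = .1, d_Mw = .3, k_w = .3, d_Wd = .2, d_Wl = .3,
    k_act = 1, k_rel = .2, K_V = 1, k_v = .3, d_V = .2), "negative")
})

test_that("knockouts modify only their own targets", {
  p <- default_parameters()
  pv <- apply_knockout(p, "vvd")
  expect_true(pv$vvd_null)
  for (f in setdiff(names(p), "vvd_null")) expect_identical(pv[[f]], p[[f]])
  expect_identical(p$vvd_null, FALSE) # original untouched
  expect_error(apply_knockout(p, "cry"), "supported")
})

test_that("frq-null loses the dark rhythm; frq7/frq2 straddle the wild type", {
  p <- default_parameters()
  ko <- simulate_clock(apply_knockout(p, "frq"), ld_constant(0), 600)
  f <- trajectory_series(ko, "F")
  expect_lt(diff(range(f$value[f$time > 300])), 1e-6)
  per <- function(q) {
    tr <- simulate_clock(q, ld_constant(0), 600)
    estimate_period(trajectory_series(tr, "F"), discard = 150)$mean
  }
  p7 <- per(apply_knockout(p, "frq7"))
  p2 <- per(apply_knockout(p, "frq2"))
  pw <- per(p)
  expect_gt(p7, pw)
  expect_lt(p2, pw)
})

test_that("the committed parameter set is deterministic and physiological", {
  p1 <- default_parameters()
  p2 <- default_parameters()
  expect_identical(p1, p2)
  expect_gte(p1$tau, 2)
  expect_lte(p1$tau, 8)
})

test_that("JSON round trip preserves parameters and rejects unknown keys", {
  p <- apply_knockout(default_parameters(), "vvd")
  txt <- params_to_json(p)
  expect_equal(params_from_json(txt), p)
  bad <- jsonlite::toJSON(c(unclass(p), list(mystery = 1)),
                          auto_unbox = TRUE)
  expect_error(params_from_json(bad), "unknown parameter keys")
  expect_error(params_from_json(jsonlite::toJSON(list(v_dark = 1),
                                                 auto_unbox = TRUE)),
               "missing")
})

test_that("trajectories stay nonnegative from nonnegative histories", {
  p <- default_parameters()
  set.seed(11)
  for (i in 1:4) {
    hist <- runif(6, 0, 3)
    prot <- if (i %% 2) symmetric_ld(3) else ld_constant(0)
    tr <- simulate_clock(p, prot, 600, dt = 0.02, history = hist)
    expect_gte(min(tr$states), 0)
  }
})

test_that("dark dynamics are independent of the light-input parameters", {
  p <- default_parameters()
  per_dd <- function(q) {
    tr <- simulate_clock(q, ld_constant(0), 600, dt = 0.02)
    estimate_period(trajectory_series(tr, "F"), discard = 150)$mean
  }
  base <- per_dd(p)
  q <- unclass(p)
  q$k_act <- q$k_act * 10; q$k_rel <- q$k_rel * 10
  q$K_V <- q$K_V * 10; q$k_v <- q$k_v * 10
  pert <- per_dd(frqclock:::validate_parameters(q))
  expect_lt(abs(pert - base), 1e-3)
})

test_that("shrinking the delay breaks or strongly shortens the rhythm", {
  # the delay is the oscillation-enabling element: at the shortest
  # admissible lag the free run must die or shorten by more than 20%
  p <- default_parameters()
  q <- unclass(p); q$tau <- 2
  tr <- simulate_clock(frqclock:::validate_parameters(q), ld_constant(0),
                       600, dt = 0.01)
  s <- trajectory_series(tr, "F")
  amp <- diff(range(s$value[s$time > 300]))
  pe <- estimate_period(s, discard = 150)
  lost <- amp < 0.05 || !pe$defined
  shortened <- pe$defined && pe$mean < 0.8 * 22
  expect_true(lost || shortened)
})
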