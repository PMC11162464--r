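test_that("the Franck-Condon wavepacket is a pure state at the origin", {
  m <- random_small_model(21, ns = 3, nm = 2)
  b <- basis_spec(c(6L, 6L))
  expect_error(initial_wavepacket(m, b, "X"), "unknown state")
  tr <- propagate(m, b, initial_state = "S2", t_final = 0.5, dt_out = 0.5)
  expect_equal(unname(tr$pop[1, ]), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(unname(tr$coh[1, ]), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(tr$qexp[1, ]), c(0, 0), tolerance = 1e-12)
  # zero-point closed form for the uncoupled model
  mu <- vibronic_model(c("A", "B"), c(0.5, 0.1), c(900, 1600))
  tru <- propagate(mu, b, initial_state = "A", t_final = 1, dt_out = 0.5)
  expect_equal(tru$energy[1],
               0.5 + sum(cm1_to_ev(c(900, 1600))) / 2, tolerance = 1e-12)
})

test_that("Rabi oscillations match the two-level closed form", {
  V0 <- 0.1
  m <- rabi_model(V0)
  tr <- propagate(m, basis_spec(integer(0)), initial_state = "D",
                  t_final = 25, dt_out = 0.05)
  th <- V0 * tr$time / HBAR_EV_FS
  expect_lt(max(abs(tr$pop[, "A"] - sin(th)^2)), 1e-6)
  expect_lt(max(abs(coherences(tr, c("D", "A")) - abs(sin(2 * th)) / 2)),
            1e-6)
  # full population inversion at t = pi*hbar/(2 V0) ~ 10.34 fs
  i <- which.min(abs(tr$time - pi * HBAR_EV_FS / (2 * V0)))
  expect_gt(tr$pop[i, "A"], 1 - 1e-4)
})

test_that("a displaced oscillator follows the Ehrenfest closed form", {
  kap <- 0.1
  m <- vibronic_model("S", 0, 1600, kappa = matrix(kap, 1, 1))
  tr <- propagate(m, basis_spec(25L), initial_state = "S",
                  t_final = 42, dt_out = 0.05)
  w <- cm1_to_ev(1600)
  period <- vib_period_fs(1600)
  expect_equal(period, 20.85, tolerance = 1e-3)          # 33356.4 / 1600
  qth <- (kap / w) * (cos(2 * pi * tr$time / period) - 1)
  expect_lt(max(abs(tr$qexp[, 1] - qth)), 1e-6)
})

test_that("Krylov propagation matches the dense-exponential oracle", {
  cases <- list(list(seed = 31, ns = 2, nm = 2, sizes = c(6L, 5L)),
                list(seed = 32, ns = 3, nm = 2, sizes = c(5L, 5L)),
                list(seed = 33, ns = 2, nm = 3, sizes = c(4L, 4L, 4L)))
  for (cs in cases) {
    m <- random_small_model(cs$seed, ns = cs$ns, nm = cs$nm)
    b <- basis_spec(cs$sizes)
    tr <- suppressWarnings(propagate(m, b, initial_state = m$state_labels[1],
                    t_final = 60, dt_out = 2))  # small ladders on purpose
    ref <- dense_reference(m, b, m$state_labels[1], tr$time)
    expect_lt(max(abs(tr$pop - ref)), 1e-8)
  }
})

test_that("norm and energy are conserved over 200 fs", {
  m <- random_small_model(41, ns = 3, nm = 2)
  tr <- suppressWarnings(propagate(m, basis_spec(c(8L, 8L)), initial_state = "S1",
                  t_final = 200, dt_out = 1))
  expect_lt(max(abs(tr$norm - 1)), 1e-6)
  expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-6)
  expect_lt(max(abs(rowSums(tr$pop) - 1)), 1e-6)
})

test_that("coherences obey the Cauchy-Schwarz population bound", {
  m <- random_small_model(42, ns = 3, nm = 2)
  tr <- suppressWarnings(propagate(m, basis_spec(c(7L, 7L)), initial_state = "S1",
                  t_final = 80, dt_out = 0.5))
  labs <- colnames(tr$pop)
  for (i in 1:2) for (j in (i + 1):3) {
    bound <- sqrt(tr$pop[, i] * tr$pop[, j]) + 1e-8
    expect_true(all(coherences(tr, c(labs[i], labs[j])) <= bound))
  }
  expect_true(all(tr$coh <= 0.5 + 1e-8))
  expect_error(coherences(tr, c("S1", "nope")), "unknown state")
})

test_that("per-state phase flips leave populations and coherences alone", {
  m <- random_small_model(43, ns = 3, nm = 2)
  flipped <- m
  i <- 2  # flip the sign of every coupling into state 2
  flipped$V0[i, ] <- -flipped$V0[i, ]; flipped$V0[, i] <- -flipped$V0[, i]
  flipped$V0[i, i] <- 0
  flipped$lam[i, , ] <- -flipped$lam[i, , ]
  flipped$lam[, i, ] <- -flipped$lam[, i, ]
  for (k in seq_len(2)) flipped$lam[i, i, k] <- 0
  b <- basis_spec(c(6L, 6L))
  t1 <- suppressWarnings(propagate(m, b, initial_state = "S1", t_final = 50,
                                   dt_out = 1))
  t2 <- suppressWarnings(propagate(flipped, b, initial_state = "S1",
                                   t_final = 50, dt_out = 1))
  expect_equal(t1$pop, t2$pop, tolerance = 1e-9)
  expect_equal(t1$coh, t2$coh, tolerance = 1e-9)
})

test_that("population error decreases monotonically with ladder size", {
  m <- vibronic_model(c("D", "A"), c(0.25, 0), 1400,
                      kappa = matrix(c(-0.2, 0.05), 2, 1),
                      V0 = matrix(c(0, 0.03, 0.03, 0), 2))
  ref <- propagate(m, basis_spec(40L), initial_state = "D",
                   t_final = 60, dt_out = 1)$pop
  errs <- vapply(c(6L, 10L, 16L), function(n) {
    p <- suppressWarnings(propagate(m, basis_spec(n), initial_state = "D",
                                    t_final = 60, dt_out = 1))$pop
    max(abs(p - ref))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the leakage monitor flags an undersized basis", {
  m <- vibronic_model("S", 0, 1600, kappa = matrix(0.35, 1, 1))
  expect_warning(propagate(m, basis_spec(4L), initial_state = "S",
                           t_final = 30, dt_out = 1), "leakage")
})

test_that("halving the step tolerance does not move the populations", {
  m <- random_small_model(44, ns = 2, nm = 2)
  b <- basis_spec(c(6L, 6L))
  t1 <- suppressWarnings(propagate(m, b, initial_state = "S1", t_final = 50,
                                   dt_out = 1, tol = 1e-8))
  t2 <- suppressWarnings(propagate(m, b, initial_state = "S1", t_final = 50,
                                   dt_out = 1, tol = 1e-10))
  expect_lt(max(abs(t1$pop - t2$pop)), 10 * 1e-8)
})

test_that("pathway classification follows the doorway thresholds", {
  mk <- function(pct_peak, pct_final) {
    nt <- 5
    pop <- cbind(La = rep(0.5, nt), CT = seq(pct_peak, pct_final,
                                             length.out = nt),
                 Nic = 0)
    pop[, "La"] <- 1 - pop[, "CT"]
    structure(list(time = 1:nt, pop = pop), class = "lvc_trajectory")
  }
  expect_identical(classify_pathway(mk(0.05, 0.02)), "direct")
  expect_identical(classify_pathway(mk(0.6, 0.8)), "ct_trapped")
  expect_identical(classify_pathway(mk(0.4, 0.1)), "ct_mediated")
  expect_error(classify_pathway(mk(0.1, 0.1), "QQ"), "no state")
})

test_that("burst spacing of a tuning-driven crossing is half the period", {
  tr <- propagate(crossing_model(), basis_spec(50L), initial_state = "D",
                  t_final = 100, dt_out = 0.25)
  spacing <- mean(diff(burst_times(tr, "A")))
  expect_equal(spacing, vib_period_fs(1600) / 2, tolerance = 1.5 / 10.4)
})
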