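test_that("disorder sampling is seeded, Gaussian, and leaves the base alone", {
  base <- make_nadh_model()
  same <- sample_disorder(base, 5, ct_fwhm = 0, coupling_jitter = 0, seed = 3)
  for (m in same) {
    attr(m, "dE") <- NULL
    expect_identical(m, base)
  }
  a <- sample_disorder(base, 50, 1.0, 0.1, seed = 11)
  b <- sample_disorder(base, 50, 1.0, 0.1, seed = 11)
  expect_identical(a, b)                             # bit-identical per seed
  # realized CT spread reproduces the requested 1 eV FWHM
  big <- sample_disorder(base, 1e4, 1.0, seed = 5)
  ects <- vapply(big, function(m) m$E[2], numeric(1))
  fwhm <- 2 * sqrt(2 * log(2)) * stats::sd(ects)
  expect_lt(abs(fwhm - 1.0) / 1.0, 0.03)
  # only CT entries are jittered
  j <- sample_disorder(base, 1, 0.5, 0.25, seed = 8)[[1]]
  expect_identical(j$V0[1, 3], base$V0[1, 3])
  expect_identical(j$lam[1, 3, ], base$lam[1, 3, ])
  expect_false(isTRUE(all.equal(j$V0[1, 2], base$V0[1, 2])))
  expect_error(sample_disorder(base, 0, 1), "n must be")
  expect_error(sample_disorder(base, 3, 1, ct_label = "QQ"), "no state")
})

test_that("a one-member ensemble reduces to a single propagation", {
  m <- make_nadh_model()
  b <- basis_spec(c(8L, 8L, 6L, 6L))
  ens <- suppressWarnings(run_ensemble(list(m), b, t_final = 30,
                                       initial_state = "La", dt_out = 1))
  tr <- suppressWarnings(propagate(m, b, t_final = 30, initial_state = "La",
                                   dt_out = 1, track_q = FALSE))
  expect_equal(ens$pop_maps$Nic[1, ], unname(tr$pop[, "Nic"]),
               tolerance = 1e-12)
  expect_equal(ens$snapshots$dE_eV, -0.5)
})

test_that("ensemble rows are sorted by the CT gap and order-invariant", {
  base <- make_nadh_model()
  mods <- sample_disorder(base, 4, 1.0, seed = 21)
  b <- basis_spec(c(6L, 6L, 5L, 5L))
  e1 <- suppressWarnings(run_ensemble(mods, b, t_final = 20,
                                      initial_state = "La", dt_out = 1))
  e2 <- suppressWarnings(run_ensemble(rev(mods), b, t_final = 20,
                                      initial_state = "La", dt_out = 1))
  expect_true(!is.unsorted(e1$snapshots$dE_eV))
  expect_equal(e1$snapshots$dE_eV, e2$snapshots$dE_eV)
  expect_equal(e1$pop_maps$CT, e2$pop_maps$CT, tolerance = 1e-10)
})

test_that("with CT couplings switched off the doorway never populates", {
  base <- ablate_state_couplings(make_nadh_model(), "CT")
  mods <- sample_disorder(base, 3, 1.0, seed = 31)
  ens <- suppressWarnings(run_ensemble(mods, basis_spec(c(8L, 8L, 6L, 6L)),
                                       t_final = 50, initial_state = "La",
                                       dt_out = 0.5))
  expect_lt(max(ens$pop_maps$CT), 1e-6)
})

test_that("the CT gap decides between doorway and direct transfer", {
  b <- basis_spec(c(10L, 10L, 7L, 7L))
  # CT well below the donor: transient doorway, populated early
  low <- make_nadh_model(synth_config(ct_offset = -0.5))
  tr_low <- suppressWarnings(propagate(low, b, t_final = 80,
                                       initial_state = "La", dt_out = 0.5,
                                       track_q = FALSE))
  expect_identical(classify_pathway(tr_low), "ct_mediated")
  tpk <- tr_low$time[tr_low$pop[, "CT"] >= 0.2]
  expect_lt(min(tpk), 60)                # doorway populated early
  # CT far above the donor: direct pathway, CT stays dark
  high <- make_nadh_model(synth_config(ct_offset = 0.8))
  tr_high <- suppressWarnings(propagate(high, b, t_final = 80,
                                        initial_state = "La", dt_out = 0.5,
                                        track_q = FALSE))
  expect_identical(classify_pathway(tr_high), "direct")
  expect_lt(max(tr_high$pop[, "CT"]), 0.2)
})

test_that("ensemble summaries serialize one row per snapshot", {
  base <- make_nadh_model()
  mods <- sample_disorder(base, 3, 0.8, seed = 41)
  ens <- suppressWarnings(run_ensemble(mods, basis_spec(c(6L, 6L, 5L, 5L)),
                                       t_final = 20, initial_state = "La",
                                       dt_out = 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble_summary(ens, f, sample_times = c(10, 20))
  d <- utils::read.delim(f)
  expect_equal(nrow(d), 3)
  expect_true(all(c("dE_eV", "class", "pop_Nic_20fs") %in% names(d)))
})
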