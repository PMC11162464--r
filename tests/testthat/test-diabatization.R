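test_that("a diagonal excitation-difference matrix is a fixed point", {
  r <- fed_diabatize(fed_input(c(5.0, 4.8, 4.5), diag(c(1, -1, 0))))
  # gauge: columns ordered by descending delta_x eigenvalue (+1, 0, -1), so
  # U is the identity up to that column permutation
  expect_equal(abs(r$U), diag(3)[, c(1, 3, 2)], tolerance = 1e-12)
  expect_identical(r$labels, c("LE+", "CT", "LE-"))
  expect_equal(diag(r$H_dia), c(5.0, 4.5, 4.8), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(r$V)), 1e-12)
})

test_that("the two-state homodimer recovers the textbook half-splitting", {
  r <- fed_diabatize(fed_input(c(4.0, 5.0), matrix(c(0, 1, 1, 0), 2)))
  expect_equal(unname(diag(r$H_dia)), c(4.5, 4.5), tolerance = 1e-12)
  expect_equal(abs(r$H_dia[1, 2]), 0.5, tolerance = 1e-12)
  expect_equal(sort(r$eigenvalues), c(-1, 1), tolerance = 1e-12)
})

test_that("rotated planted LE/LE/CT problems are recovered up to gauge", {
  for (seed in c(101, 202)) {
    cs <- planted_fed_case(seed)
    r <- fed_diabatize(cs$input)
    expect_equal(sort(r$eigenvalues), c(-1, 0, 1), tolerance = 1e-10)
    expect_identical(r$labels[which.min(abs(r$eigenvalues))], "CT")
    # spectrum and trace preserved by the similarity transform
    expect_lt(max(abs(sort(eigen(r$H_dia)$values) -
                        sort(eigen(cs$H_dia)$values))), 1e-10)
    expect_equal(sum(diag(r$H_dia)), sum(diag(cs$H_dia)), tolerance = 1e-10)
    # energies and |couplings| match the planted diabatic data
    perm <- match(c("LE+", "LE-", "CT"), r$labels)
    expect_equal(diag(r$H_dia)[perm], diag(cs$H_dia), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(abs(r$H_dia[perm, perm]), abs(cs$H_dia), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # rotated gradients give back the planted diabatic kappa/lambda tables
    for (k in seq_along(cs$grads_dia)) {
      G <- cs$grads_dia[[k]]
      expect_equal(r$kappa[perm, k], diag(G), tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_equal(abs(r$lam[perm, perm, k]), abs(G - diag(diag(G))),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("ambiguous or degenerate diabatic characters are refused", {
  expect_error(fed_diabatize(fed_input(c(4, 5), matrix(c(0.5, 0, 0, 0), 2))),
               "ambiguous")
  expect_error(fed_diabatize(fed_input(c(4, 5, 6), diag(c(1, 1, 0)))),
               "degenerate")
  expect_error(fed_input(c(4, 5), matrix(c(0, 1, 0.5, 0), 2)), "symmetric")
})

test_that("|V/Delta| is the plain mean of absolute ratios", {
  expect_equal(coupling_gap_ratio(0.268, 1.0), 0.268)
  expect_equal(coupling_gap_ratio(c(0.1, 0.3), c(1, 1)), 0.2)
  set.seed(9)
  V <- rnorm(50, 0, 0.2); g <- runif(50, 0.2, 1.5) * sample(c(-1, 1), 50, TRUE)
  brute <- sum(vapply(seq_len(50), function(i) abs(V[i] / g[i]),
                      numeric(1))) / 50
  expect_equal(coupling_gap_ratio(V, g), brute, tolerance = 1e-12)
  expect_error(coupling_gap_ratio(c(0.1, 0.2), c(1, 0)), "zero")
  expect_error(coupling_gap_ratio(c(0.1), c(1, 2)), "length")
})

test_that("electron-hole distances are Euclidean, symmetric, translation-invariant", {
  expect_equal(eh_distance(c(0, 0, 0), c(0, 0, 3.5)), 3.5)
  expect_equal(eh_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(4)
  a <- rnorm(3); b <- rnorm(3); shift <- rnorm(3)
  expect_equal(eh_distance(a, b), eh_distance(b, a))
  expect_equal(eh_distance(a + shift, b + shift), eh_distance(a, b))
  # synthetic stacked geometries: interplane separation 3.3-4.2 A with
  # bounded lateral slip, as in closely stacked dimers
  d <- vapply(1:20, function(i) {
    hole <- c(runif(2, -0.4, 0.4), 0)
    elec <- c(runif(2, -0.4, 0.4), runif(1, 3.3, 4.2))
    eh_distance(hole, elec)
  }, numeric(1))
  expect_true(all(d >= 3 & d <= 5))
  expect_error(eh_distance(c(0, 0), c(1, 1, 1)), "length-3")
})

test_that("the 0.5 eV solvent-accessibility rule is applied to the gap", {
  expect_false(ct_accessible(5.3, 4.7))            # gap 0.6 eV
  expect_true(ct_accessible(4.7, 4.7))             # degenerate
  expect_true(ct_accessible(4.2, 4.7))             # CT 0.5 eV below
  expect_true(ct_accessible(5.2, 4.7))             # exactly at threshold
  expect_false(ct_accessible(5.2, 4.7, threshold = 0.4))
})
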