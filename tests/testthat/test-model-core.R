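test_that("parameter construction validates and defaults to the reference set", {
  p <- model_parameters()
  expect_equal(unclass(p), c(k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 1, N = 4))
  expect_error(model_parameters(k3 = 0), "positive")
  expect_error(model_parameters(k1 = -1), "positive")
  expect_error(model_parameters(N = Inf), "positive")
  expect_s3_class(as_model_parameters(list(k3 = 2)), "model_parameters")
})

test_that("right-hand side matches direct substitution", {
  p <- model_parameters()
  expect_equal(unname(model_rhs(c(0, 0, 0), p)), c(0, 0, 0))
  expect_equal(unname(model_rhs(c(1, 1, 1), p)), c(2, 0, 0))
  expect_equal(unname(model_rhs(c(3, 3, 3), p)), c(0, 0, 0))
  expect_error(model_rhs(c(-1, 1, 1), p), "non-negative")
  expect_error(model_rhs(c(NaN, 1, 1), p), "finite")
})

test_that("closed-form steady states annihilate the right-hand side", {
  cases <- list(model_parameters(),
                model_parameters(k3 = 10),
                model_parameters(k1 = 0.6, k2 = 0.4, k4 = 1.3, k5 = 0.8, N = 5))
  for (p in cases) {
    ss <- steady_states(p)
    for (s in ss) expect_lt(max(abs(model_rhs(s, p))), 1e-12)
  }
  expect_equal(steady_states(model_parameters(k3 = 10))[[2]],
               c(R = 30, P = 3, M = 30))
  # positive branch requires k1*N > k4
  expect_length(steady_states(model_parameters(k1 = 0.1)), 1)
})

test_that("analytic Jacobian agrees with a central-difference oracle", {
  p <- model_parameters()
  expect_equal(unname(jacobian_at(c(0, 0, 0), p)),
               matrix(c(3, 0, 0, 0, -1, 1, 1, 0, -1), 3, byrow = TRUE))
  expect_equal(unname(jacobian_at(c(3, 3, 3), p)),
               matrix(c(0, -3, 0, 0, -1, 1, 1, 0, -1), 3, byrow = TRUE))
  set.seed(11)
  for (i in 1:10) {
    pr <- random_params()
    st <- runif(3, 0, 5)
    expect_lt(max(abs(jacobian_at(st, pr) - fd_jacobian(st, pr))), 1e-6)
  }
})

test_that("characteristic coefficients match the closed form and eigenvalues", {
  expect_equal(characteristic_coefficients(model_parameters()),
               c(a1 = 2, a2 = 1, a3 = 3))
  expect_equal(characteristic_coefficients(model_parameters(k3 = 10)),
               c(a1 = 11, a2 = 10, a3 = 30))
  # Routh-Hurwitz marginal case: a1*a2 = a3 and eigenvalues -3, +/- i sqrt(2)
  a <- characteristic_coefficients(model_parameters(k3 = 2))
  expect_equal(a, c(a1 = 3, a2 = 2, a3 = 6))
  expect_equal(a[["a1"]] * a[["a2"]], a[["a3"]])
  ev <- eigen(jacobian_at(c(6, 3, 6), model_parameters(k3 = 2)))$values
  expect_equal(sort(Re(ev)), c(-3, 0, 0), tolerance = 1e-9)
  expect_equal(max(Im(ev)), sqrt(2), tolerance = 1e-9)
  expect_error(characteristic_coefficients(model_parameters(k1 = 0.1)),
               "positive steady state")
})

test_that("characteristic polynomial identity holds on random parameter sets", {
  set.seed(101)
  for (i in 1:100) {
    p <- random_params()
    J <- jacobian_at(steady_states(p)[[2]], p)
    from_matrix <- char_coefs_from_matrix(J)
    closed <- char_coefs_closed_form(p)
    expect_lt(max(abs(from_matrix - closed)), 1e-9)
    # roots of the polynomial are the Jacobian eigenvalues
    roots <- polyroot(c(closed[["a3"]], closed[["a2"]], closed[["a1"]], 1))
    ev <- eigen(J, only.values = TRUE)$values
    expect_lt(max(abs(sort(Re(roots)) - sort(Re(ev)))), 1e-9)
  }
})

test_that("Hopf point: closed form, bisection, and eigenvalue sign structure", {
  p <- model_parameters()
  expect_equal(hopf_k3_critical(p), 2)
  expect_lt(abs(hopf_k3_numeric(p) - 2), 1e-6)
  p2 <- model_parameters(k4 = 0.5)
  expect_equal(hopf_k3_critical(p2), 2.5)
  expect_lt(abs(hopf_k3_numeric(p2) - 2.5), 1e-6)
  expect_message(res <- hopf_k3_critical(model_parameters(k1 = 0.25)),
                 "no Hopf point")
  expect_true(is.na(res))

  # complex pair crosses the axis at the critical value (checked +/- 10%)
  set.seed(5)
  for (i in 1:5) {
    pr <- random_params(hopf = TRUE)
    crit <- hopf_k3_critical(pr)
    below <- stability_report(as_model_parameters(replace(unclass(pr), 3, 0.9 * crit)))
    above <- stability_report(as_model_parameters(replace(unclass(pr), 3, 1.1 * crit)))
    expect_equal(below$steady_states[[2]]$classification, "unstable_focus")
    expect_equal(above$steady_states[[2]]$classification, "stable_focus")
  }
})

test_that("the Hopf point does not depend on the cost of resistance k2", {
  set.seed(31)
  base <- hopf_k3_critical(model_parameters())
  for (k2 in exp(runif(10, log(0.01), log(100)))) {
    p <- model_parameters(k2 = k2)
    expect_equal(hopf_k3_critical(p), base)
    expect_lt(abs(hopf_k3_numeric(p) - base), 1e-6)
  }
})

test_that("stability classification covers node, focus, saddle and marginal cases", {
  rep0 <- stability_report(model_parameters())
  expect_equal(rep0$steady_states[[1]]$classification, "saddle")     # origin
  expect_equal(rep0$steady_states[[2]]$classification, "unstable_focus")
  expect_equal(stability_report(model_parameters(k3 = 10))$steady_states[[2]]$classification,
               "stable_focus")
  expect_equal(stability_report(model_parameters(k3 = 2))$steady_states[[2]]$classification,
               "nonhyperbolic")
  # eigenvalue residual in the characteristic polynomial
  for (e in rep0$steady_states) {
    a <- char_coefs_from_matrix(jacobian_at(e$state, model_parameters()))
    res <- e$eigenvalues^3 + a[["a1"]] * e$eigenvalues^2 +
      a[["a2"]] * e$eigenvalues + a[["a3"]]
    expect_lt(max(abs(res)), 1e-9)
  }
})

test_that("parameter sets round-trip through key-value and JSON formats", {
  p <- model_parameters(k1 = 1.25, k3 = 0.1, N = 4)
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, f1)
  write_parameters(p, f2, format = "json")
  expect_equal(unclass(read_parameters(f1)), unclass(p))
  expect_equal(unclass(read_parameters(f2, format = "json")), unclass(p))
})
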