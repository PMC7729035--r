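test_that("the cyclic three-strategy game is the reference zero-sum matrix", {
  g <- payoff_rps()
  expect_equal(g$strategies_p1, c("R", "M", "P"))
  expect_equal(unname(g$payoff_p1),
               matrix(c(0, -1, 1, 1, 0, -1, -1, 1, 0), 3, byrow = TRUE))
  expect_equal(g$payoff_p1["R", "P"], 1)
  expect_equal(g$payoff_p2["R", "P"], -1)
  expect_true(all(diag(g$payoff_p1) == 0) && all(diag(g$payoff_p2) == 0))
  expect_true(g$zero_sum)
  expect_equal(unname(g$payoff_p1 + g$payoff_p2), matrix(0, 3, 3))
})

test_that("the stress shift rule reproduces all printed two-strategy payoffs", {
  # moderate stress (cost of public goods equals cost of resistance)
  g <- payoff_two_strategy("moderate")
  expect_equal(g$payoff_p1["R", "P"], 2)
  expect_equal(g$payoff_p2["R", "P"], 0)
  expect_equal(unname(g$payoff_p1), matrix(c(1, 0.5, 2, 0), 2, byrow = TRUE))
  expect_equal(unname(g$payoff_p2), matrix(c(2, 1.5, 0, 2), 2, byrow = TRUE))
  # +1 to every payoff earned while playing P (no antibiotic stress)
  b <- payoff_two_strategy("no_stress")
  expect_equal(unname(b$payoff_p1), matrix(c(2, 1.5, 2, 0), 2, byrow = TRUE))
  expect_equal(unname(b$payoff_p2), matrix(c(3, 1.5, 1, 2), 2, byrow = TRUE))
  expect_equal(b$payoff_p2["P", "P"], 3)
  # -1 under high stress
  r <- payoff_two_strategy("high")
  expect_equal(unname(r$payoff_p1), matrix(c(0, -0.5, 2, 0), 2, byrow = TRUE))
  expect_equal(unname(r$payoff_p2), matrix(c(1, 1.5, -1, 2), 2, byrow = TRUE))
  expect_equal(r$payoff_p2["P", "P"], 1)
  expect_error(payoff_two_strategy("extreme"))
})

test_that("pure Nash structure tracks the stress level", {
  expect_equal(nrow(pure_nash(payoff_rps())), 0)
  expect_equal(nrow(pure_nash(payoff_two_strategy("moderate"))), 0)
  ns <- pure_nash(payoff_two_strategy("no_stress"))
  expect_equal(nrow(ns), 1)
  expect_equal(c(ns$strategy_p1, ns$strategy_p2), c("P", "P"))
  expect_false(ns$strict)  # the nascent R-deviation ties at 2
  hi <- pure_nash(payoff_two_strategy("high"))
  expect_equal(nrow(hi), 1)
  expect_equal(c(hi$strategy_p1, hi$strategy_p2), c("R", "R"))
  expect_true(hi$strict)
})

test_that("the cyclic game has the unique uniform mixed equilibrium", {
  res <- mixed_nash(payoff_rps())
  expect_length(res$profiles, 1)
  expect_equal(res$profiles[[1]]$x, rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(res$profiles[[1]]$y, rep(1 / 3, 3), tolerance = 1e-9)
  # the zero-sum minimax LP agrees
  expect_equal(res$lp$x, rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(res$lp$y, rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(res$lp$value, 0, tolerance = 1e-9)
})

test_that("mixed equilibria of the two-strategy games match hand calculations", {
  # moderate: p2 mixes to equalize 0.5 + 0.5 q = 2q; p1 to equalize 2p = 2 - 0.5p
  res <- mixed_nash(payoff_two_strategy("moderate"))
  expect_length(res$profiles, 1)
  expect_equal(res$profiles[[1]]$x, c(0.8, 0.2), tolerance = 1e-9)
  expect_equal(res$profiles[[1]]$y, c(1 / 3, 2 / 3), tolerance = 1e-9)
  # no stress: degenerate continuum x = (p, 1-p) vs P for p in [0.4, 1]
  ns <- mixed_nash(payoff_two_strategy("no_stress"))
  expect_true(ns$degenerate)
  xs <- vapply(ns$profiles, function(p) p$x[1], numeric(1))
  expect_true(all(vapply(ns$profiles, function(p) p$y[1], numeric(1)) == 1))
  expect_setequal(round(xs, 6), c(0.4, 1))
})

test_that("matching pennies solves to the uniform profile by both routes", {
  g <- bimatrix_game(matrix(c(1, -1, -1, 1), 2), matrix(c(-1, 1, 1, -1), 2))
  expect_true(g$zero_sum)
  res <- mixed_nash(g)
  expect_length(res$profiles, 1)
  expect_equal(res$profiles[[1]]$x, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(res$profiles[[1]]$y, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(res$lp$x, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("all reported equilibria survive a brute-force deviation oracle", {
  set.seed(12)
  fx <- generate_fixtures(seed = 12, n_games = 15)
  checked <- 0
  for (g in fx$games) {
    res <- mixed_nash(g)
    for (pr in res$profiles) {
      expect_lt(random_deviation_gain(g, pr$x, pr$y), 1e-9)
      checked <- checked + 1
    }
    pn <- pure_nash(g)
    if (nrow(pn) > 0) {
      for (r in seq_len(nrow(pn))) {
        x <- as.numeric(seq_len(nrow(g$payoff_p1)) == pn$i[r])
        y <- as.numeric(seq_len(ncol(g$payoff_p1)) == pn$j[r])
        expect_lt(random_deviation_gain(g, x, y), 1e-9)
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 20)
})

test_that("support enumeration and the LP agree on random zero-sum games", {
  set.seed(91)
  for (i in 1:10) {
    A <- matrix(round(runif(9, -3, 3), 2), 3)
    g <- bimatrix_game(A, -A)
    lp <- minimax_lp(g)
    # the LP strategies themselves form an equilibrium
    expect_lt(random_deviation_gain(g, lp$x, lp$y, n_dev = 2000), 1e-8)
    # and some enumerated profile attains the same game value
    res <- mixed_nash(g)
    vals <- vapply(res$profiles, function(p)
      drop(crossprod(p$x, g$payoff_p1 %*% p$y)), numeric(1))
    expect_true(any(abs(vals - lp$value) < 1e-7))
  }
  expect_error(minimax_lp(payoff_two_strategy("moderate")), "zero-sum")
})
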