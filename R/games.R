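#' Two-player bimatrix game container
#'
#' @param payoff_p1,payoff_p2 numeric payoff matrices of identical shape;
#'   rows are player-1 strategies, columns player-2 strategies, and entry
#'   `[i, j]` is the payoff when player 1 plays `i` against `j`.
#' @param strategies_p1,strategies_p2 strategy labels (default from the
#'   matrix dimnames or `s1, s2, ...`).
#' @param condition optional stress tag: one of `"no_stress"`,
#'   `"moderate"`, `"high"`.
#' @return Object of class `bimatrix_game`, with a `zero_sum` flag set when
#'   `payoff_p2 == -payoff_p1` entrywise.
#' @export
bimatrix_game <- function(payoff_p1, payoff_p2,
                          strategies_p1 = NULL, strategies_p2 = NULL,
                          condition = NULL) {
  payoff_p1 <- as.matrix(payoff_p1)
  payoff_p2 <- as.matrix(payoff_p2)
  if (!all(dim(payoff_p1) == dim(payoff_p2))) {
    stop("payoff matrices must have identical shape", call. = FALSE)
  }
  if (is.null(strategies_p1)) {
    strategies_p1 <- rownames(payoff_p1)
    if (is.null(strategies_p1)) strategies_p1 <- paste0("s", seq_len(nrow(payoff_p1)))
  }
  if (is.null(strategies_p2)) {
    strategies_p2 <- colnames(payoff_p1)
    if (is.null(strategies_p2)) strategies_p2 <- paste0("s", seq_len(ncol(payoff_p1)))
  }
  stopifnot(length(strategies_p1) == nrow(payoff_p1),
            length(strategies_p2) == ncol(payoff_p1))
  if (!is.null(condition)) {
    condition <- match.arg(condition, c("no_stress", "moderate", "high"))
  }
  dimnames(payoff_p1) <- dimnames(payoff_p2) <-
    list(strategies_p1, strategies_p2)
  structure(list(payoff_p1 = payoff_p1, payoff_p2 = payoff_p2,
                 strategies_p1 = strategies_p1, strategies_p2 = strategies_p2,
                 condition = condition,
                 zero_sum = max(abs(payoff_p1 + payoff_p2)) < 1e-12),
            class = "bimatrix_game")
}

#' @export
print.bimatrix_game <- function(x, ...) {
  cat(sprintf("Bimatrix game (%d x %d)%s%s\n",
              nrow(x$payoff_p1), ncol(x$payoff_p1),
              if (x$zero_sum) ", zero-sum" else "",
              if (is.null(x$condition)) "" else paste0(", condition: ", x$condition)))
  comb <- matrix(sprintf("%g\\%g", x$payoff_p1, x$payoff_p2),
                 nrow = nrow(x$payoff_p1), dimnames = dimnames(x$payoff_p1))
  print(comb, quote = FALSE)
  invisible(x)
}

#' The cyclic three-strategy community game
#'
#' Resistant (R), motile (M) and producer (P) cells as the three strategies
#' of a symmetric zero-sum game with rock-paper-scissors structure: each
#' phenotype beats exactly one other (winner +1, loser -1, ties 0), so no
#' strategy dominates and no pure Nash equilibrium exists.
#'
#' @return A zero-sum `bimatrix_game` with strategies `R, M, P`.
#' @examples
#' payoff_rps()
#' @export
payoff_rps <- function() {
  A <- matrix(c(0, -1, 1,
                1, 0, -1,
                -1, 1, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("R", "M", "P"), c("R", "M", "P")))
  bimatrix_game(A, -A)
}

#' The stress-conditioned two-strategy game
#'
#' Nascent cell (player 1, rows) against the mature community (player 2,
#' columns), each playing resistant (R) or producer (P). The moderate-stress
#' payoffs (public-goods cost equal to resistance cost) are the base case:
#'
#' \tabular{lcc}{
#'           \tab P (mature) \tab R (mature) \cr
#' P (nascent) \tab 1\\2  \tab 0.5\\1.5 \cr
#' R (nascent) \tab 2\\0  \tab 0\\2
#' }
#'
#' Without antibiotic stress producing public goods is comparatively
#' favourable: every payoff a player earns while playing P gains one point.
#' Under high stress it loses one point. These shifts generate the other
#' two conditions.
#'
#' @param condition `"no_stress"`, `"moderate"` or `"high"`.
#' @return A `bimatrix_game` with strategies `P, R` and the condition tag.
#' @examples
#' payoff_two_strategy("high")
#' @export
payoff_two_strategy <- function(condition = c("moderate", "no_stress", "high")) {
  condition <- match.arg(condition)
  strategies <- c("P", "R")
  A <- matrix(c(1, 0.5,
                2, 0), nrow = 2, byrow = TRUE,
              dimnames = list(strategies, strategies))
  B <- matrix(c(2, 1.5,
                0, 2), nrow = 2, byrow = TRUE,
              dimnames = list(strategies, strategies))
  shift <- switch(condition, no_stress = 1, moderate = 0, high = -1)
  A["P", ] <- A["P", ] + shift  # player 1 playing P
  B[, "P"] <- B[, "P"] + shift  # player 2 playing P
  bimatrix_game(A, B, condition = condition)
}

#' Pure-strategy Nash equilibria by exhaustive best-response enumeration
#'
#' A cell (i, j) is an equilibrium iff neither player has a strictly
#' improving unilateral deviation; it is strict iff every deviation is
#' strictly worse.
#'
#' @param game a [bimatrix_game()].
#' @param tol numeric tolerance for payoff comparisons.
#' @return A data frame with one row per pure equilibrium: integer columns
#'   `i`, `j`, label columns `strategy_p1`, `strategy_p2`, and logical
#'   `strict`. Zero rows when no pure equilibrium exists.
#' @examples
#' pure_nash(payoff_rps())                    # none: cyclic dominance
#' pure_nash(payoff_two_strategy("high"))     # (R, R), strict
#' @export
pure_nash <- function(game, tol = 1e-9) {
  stopifnot(inherits(game, "bimatrix_game"))
  A <- game$payoff_p1; B <- game$payoff_p2
  res <- list()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      dev1 <- A[-i, j, drop = TRUE] - A[i, j]
      dev2 <- B[i, -j, drop = TRUE] - B[i, j]
      if (all(dev1 <= tol) && all(dev2 <= tol)) {
        strict <- all(dev1 < -tol) && all(dev2 < -tol)
        res[[length(res) + 1]] <- data.frame(
          i = i, j = j,
          strategy_p1 = game$strategies_p1[i],
          strategy_p2 = game$strategies_p2[j],
          strict = strict)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      strategy_p1 = character(0), strategy_p2 = character(0),
                      strict = logical(0)))
  }
  do.call(rbind, res)
}

# Payoff gain of the best unilateral deviation from (x, y); an equilibrium
# has gain <= 0 for both players (up to tolerance).
deviation_gain <- function(game, x, y) {
  Ay <- drop(game$payoff_p1 %*% y)
  xB <- drop(crossprod(x, game$payoff_p2))
  c(p1 = max(Ay) - sum(x * Ay), p2 = max(xB) - sum(xB * y))
}

#' Mixed Nash equilibria by support enumeration
#'
#' Enumerates all pairs of supports (including unequal sizes, so that
#' degenerate games with equilibrium continua are detected) and solves the
#' indifference conditions on each support by least squares: player 2's
#' mixture must equalize player 1's payoffs across player 1's support, and
#' vice versa. Candidate profiles are kept only if they are proper
#' probability vectors and pass a no-profitable-deviation check. For
#' zero-sum games the minimax linear programme ([minimax_lp()]) is solved
#' as an independent cross-check and its value attached.
#'
#' @param game a [bimatrix_game()] with at most 4 strategies per player.
#' @param tol feasibility/deviation tolerance.
#' @return A list of class `nash_result` with elements `profiles` (list of
#'   `list(x, y)` probability-vector pairs, deduplicated at 1e-7),
#'   `degenerate` (TRUE when some support system was underdetermined, i.e.
#'   the reported profiles are representatives of a continuum) and, for
#'   zero-sum games, `lp` (the minimax solution).
#' @examples
#' mixed_nash(payoff_rps())   # unique: (1/3, 1/3, 1/3) for both players
#' @export
mixed_nash <- function(game, tol = 1e-9) {
  stopifnot(inherits(game, "bimatrix_game"))
  A <- game$payoff_p1; B <- game$payoff_p2
  m <- nrow(A); n <- ncol(A)
  if (m > 4 || n > 4) stop("support enumeration limited to 4 strategies", call. = FALSE)
  supports <- function(k) {
    unlist(lapply(seq_len(k), function(sz) utils::combn(k, sz, simplify = FALSE)),
           recursive = FALSE)
  }
  profiles <- list()
  for (I in supports(m)) {
    for (J in supports(n)) {
      # player 2's mixture y on J equalizes A-payoffs over I at value v
      sol_y <- solve_support(A[I, J, drop = FALSE], length(J))
      # player 1's mixture x on I equalizes B-payoffs over J at value u
      sol_x <- solve_support(t(B[I, J, drop = FALSE]), length(I))
      if (is.null(sol_y) || is.null(sol_x)) next
      x <- numeric(m); x[I] <- sol_x$p
      y <- numeric(n); y[J] <- sol_y$p
      if (any(x < -1e-8) || any(y < -1e-8)) next
      x <- pmax(x, 0); x <- x / sum(x)
      y <- pmax(y, 0); y <- y / sum(y)
      if (max(deviation_gain(game, x, y)) > 1e-7) next
      profiles[[length(profiles) + 1]] <- list(x = x, y = y)
    }
  }
  profiles <- dedup_profiles(profiles, 1e-7)
  # Degeneracy in the standard sense: some equilibrium strategy admits more
  # pure best responses than its own support size (the hallmark of an
  # equilibrium continuum, of which the profiles above are representatives).
  degenerate <- any(vapply(profiles, function(p) {
    Ay <- drop(A %*% p$y)
    xB <- drop(crossprod(p$x, B))
    sum(Ay > max(Ay) - 1e-9) > sum(p$y > 1e-9) ||
      sum(xB > max(xB) - 1e-9) > sum(p$x > 1e-9)
  }, logical(1)))
  out <- list(profiles = profiles, degenerate = degenerate, lp = NULL)
  if (game$zero_sum) out$lp <- minimax_lp(game)
  structure(out, class = "nash_result")
}

# Solve M p = v 1, sum(p) = 1 for (p, v) in the least-squares sense (SVD
# pseudoinverse, which also yields a particular solution of underdetermined
# systems); M is the payoff submatrix restricted to the opponent-facing
# support. Returns NULL when the system is inconsistent beyond tolerance.
solve_support <- function(M, k) {
  r <- nrow(M)
  lhs <- rbind(cbind(M, -1), c(rep(1, k), 0))
  rhs <- c(rep(0, r), 1)
  sv <- svd(lhs)
  pos <- sv$d > max(dim(lhs)) * max(sv$d) * 1e-12
  sol <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
  sol <- drop(sol)
  if (max(abs(lhs %*% sol - rhs)) > 1e-8) return(NULL)
  list(p = sol[seq_len(k)], v = sol[k + 1])
}

dedup_profiles <- function(profiles, tol) {
  keep <- list()
  for (p in profiles) {
    dup <- any(vapply(keep, function(q) {
      max(abs(p$x - q$x)) < tol && max(abs(p$y - q$y)) < tol
    }, logical(1)))
    if (!dup) keep[[length(keep) + 1]] <- p
  }
  keep
}

#' @export
print.nash_result <- function(x, ...) {
  cat(sprintf("Mixed Nash equilibria: %d profile(s)%s\n", length(x$profiles),
              if (x$degenerate) " (degenerate game; representatives of a continuum)" else ""))
  for (p in x$profiles) {
    cat("  x = (", paste(format(p$x, digits = 6), collapse = ", "),
        "), y = (", paste(format(p$y, digits = 6), collapse = ", "), ")\n")
  }
  if (!is.null(x$lp)) {
    cat(sprintf("  zero-sum minimax cross-check: game value %.6g\n", x$lp$value))
  }
  invisible(x)
}

#' Minimax solution of a zero-sum game by linear programming
#'
#' Solves max_x min_y x'Ay over the probability simplices via the standard
#' linear programme (payoffs shifted to be positive, then maximizing the
#' guaranteed value), using the simplex method. The column player's optimal
#' mixture is obtained from the symmetric programme on the transposed game.
#'
#' @param game a zero-sum [bimatrix_game()].
#' @return List with `x`, `y` (optimal mixtures) and `value` (game value to
#'   player 1).
#' @examples
#' minimax_lp(payoff_rps())$value   # 0
#' @export
minimax_lp <- function(game) {
  stopifnot(inherits(game, "bimatrix_game"))
  if (!game$zero_sum) stop("minimax_lp requires a zero-sum game", call. = FALSE)
  A <- game$payoff_p1
  x <- minimax_row(A)
  y <- minimax_row(-t(A))
  list(x = x$p, y = y$p, value = x$v)
}

# Optimal mixture for the row player of a zero-sum payoff matrix, via the
# classic reduction: shift payoffs positive, minimize sum(q) subject to
# t(As) q >= 1, q >= 0; then x = q/sum(q) and the value is 1/sum(q) - shift.
# A slack upper bound on sum(q) is included because the simplex routine
# mishandles problems with only >=-constraints; it never binds (sum(q) <= 1
# for any optimum of the shifted game).
minimax_row <- function(A) {
  m <- nrow(A); n <- ncol(A)
  shift <- max(abs(A)) + 1
  As <- A + shift
  sol <- boot::simplex(a = rep(1, m), A1 = matrix(1, 1, m), b1 = 2,
                       A2 = t(As), b2 = rep(1, n), maxi = FALSE)
  if (sol$solved != 1) stop("minimax LP failed to solve", call. = FALSE)
  q <- unname(sol$soln)
  list(p = q / sum(q), v = 1 / sum(q) - shift)
}

#' Single-population replicator dynamics on a symmetric game
#'
#' Integrates \eqn{\dot x_i = x_i\,((Ax)_i - x^\top A x)} for strategy
#' frequencies `x` on the simplex, with `A` the row-player payoff matrix of
#' a symmetric game (one whose player-2 matrix is the transpose of its
#' player-1 matrix). For the cyclic three-strategy game this is the
#' standard model of oscillatory coexistence: interior orbits are closed
#' and conserve the product of the three frequencies.
#'
#' @param game a symmetric [bimatrix_game()] (e.g. [payoff_rps()]).
#' @param x0 initial frequency vector on the simplex (sum 1 within 1e-9).
#' @param t_end horizon in dimensionless game time.
#' @param dt_out output step.
#' @return A data frame of class `replicator_trajectory` with column `time`
#'   and one frequency column per strategy.
#' @examples
#' tr <- replicator_dynamics(payoff_rps(), c(0.5, 0.3, 0.2), t_end = 10)
#' @export
replicator_dynamics <- function(game, x0, t_end = 100, dt_out = 0.1) {
  stopifnot(inherits(game, "bimatrix_game"))
  A <- game$payoff_p1
  if (max(abs(game$payoff_p2 - t(A))) > 1e-12) {
    stop("replicator dynamics requires a symmetric game", call. = FALSE)
  }
  x0 <- as.numeric(x0)
  if (length(x0) != nrow(A) || any(x0 < 0) || abs(sum(x0) - 1) > 1e-9) {
    stop("x0 must lie on the probability simplex (within 1e-9)", call. = FALSE)
  }
  rhs <- function(t, x, parms) {
    fitness <- drop(A %*% x)
    list(x * (fitness - sum(x * fitness)))
  }
  out <- deSolve::lsoda(x0, seq(0, t_end, by = dt_out), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  traj <- as.data.frame(out)
  names(traj) <- c("time", game$strategies_p1)
  class(traj) <- c("replicator_trajectory", "data.frame")
  traj
}
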