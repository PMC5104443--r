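test_that("fitness_step matches hand example and the loop oracle", {
  W <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  st <- foodfitness:::fitness_init(W)
  s1 <- fitness_step(W, st)
  expect_equal(s1$F, c(4 / 3, 2 / 3))
  expect_equal(s1$Q, c(2 / 3, 4 / 3))
  expect_equal(s1$F_raw, c(2, 1))
  expect_equal(s1$Q_raw, c(1 / 2, 1))

  # uniform W: all-ones is a fixed point by symmetry
  Wu <- matrix(1, 3, 4)
  su <- fitness_step(Wu, foodfitness:::fitness_init(Wu))
  expect_equal(su$F, rep(1, 3))
  expect_equal(su$Q, rep(1, 4))

  # scale invariance: doubling W leaves the normalized state unchanged
  s2 <- fitness_step(2 * W, st)
  expect_equal(s2$F, s1$F)
  expect_equal(s2$Q, s1$Q)

  # elementwise loop oracle on random matrices and random states
  set.seed(41)
  for (i in 1:20) {
    Wr <- matrix(rexp(20), 5, 4) * rbinom(20, 1, 0.8)
    Wr <- Wr + 1e-6  # keep rows/cols non-zero for the bare step
    Fp <- rlnorm(5); Fp <- Fp / mean(Fp)
    Qp <- rlnorm(4); Qp <- Qp / mean(Qp)
    st <- list(F = Fp, Q = Qp, iteration = 0L)
    got <- fitness_step(Wr, st)
    want <- fitness_step_brute(Wr, Fp, Qp)
    expect_equal(got$F, want$F, tolerance = 1e-12)
    expect_equal(got$Q, want$Q, tolerance = 1e-12)
    # mean-one normalization after the step
    expect_lt(abs(mean(got$F) - 1), 1e-12)
    expect_lt(abs(mean(got$Q) - 1), 1e-12)
  }
  expect_error(fitness_step(W, list(F = c(0, 1), Q = c(1, 1),
                                    iteration = 0L)), "zero")
})

test_that("fixed point is reached, diagnosed, and initial-condition free", {
  # the 2x2 example is the degenerate case of this map: country 2 is
  # strictly dominated, its exact fixed-point fitness is 0 and the
  # iterate decays only algebraically (~2/n), so the run hits the
  # iteration cap rather than the step tolerance; the limit itself
  # (F = (2, 0), Q = (0, 2)) is still approached from any start
  W <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  res <- fitness_fixed_point(W)
  expect_s3_class(res, "fitness_result")
  expect_equal(unname(res$F), c(2, 0), tolerance = 1e-3)
  expect_equal(unname(res$Q), c(0, 2), tolerance = 1e-3)
  expect_lt(abs(mean(res$F) - 1), 1e-12)
  expect_lt(abs(mean(res$Q) - 1), 1e-12)

  # the same end state from 20 random initializations (agreement at
  # the level the algebraic decay permits under the default stopping
  # rule; the 1e-8 check on non-degenerate matrices is in the
  # acceptance suite)
  for (s in 1:20) {
    r2 <- fitness_fixed_point(W, init = "random", seed = s)
    expect_lt(max(abs(r2$F - res$F)), 1e-6)
    expect_lt(max(abs(r2$Q - res$Q)), 1e-6)
  }
  # a longer run does converge by the step criterion
  deep <- fitness_fixed_point(W, max_iter = 2e5)
  expect_true(deep$converged)
  expect_lte(deep$delta_final, 1e-10)

  # uniform matrix converges immediately
  ru <- fitness_fixed_point(matrix(1, 4, 5))
  expect_true(ru$converged)
  expect_equal(ru$n_iterations, 1L)
  expect_equal(unname(ru$F), rep(1, 4))

  # non-convergence within a tiny cap is flagged, not thrown
  set.seed(2)
  Wb <- matrix(rexp(56), 8, 7) * rbinom(56, 1, 0.5)
  Wb[rowSums(Wb) == 0, 1] <- 1; Wb[1, colSums(Wb) == 0] <- 1
  rn <- fitness_fixed_point(Wb, tolerance = 1e-14, max_iter = 2)
  expect_false(rn$converged)
  expect_equal(rn$n_iterations, 2L)
})

test_that("all-zero rows/columns are dropped and reported", {
  W <- rbind(A = c(2, 1, 0), B = c(1, 0, 0), Z = c(0, 0, 0))
  colnames(W) <- c("p1", "p2", "p0")
  res <- fitness_fixed_point(W)
  expect_equal(res$dropped_countries, "Z")
  expect_equal(res$dropped_products, "p0")
  expect_named(res$F, c("A", "B"))
  expect_error(fitness_fixed_point(matrix(0, 2, 2)), "non-zero")
  expect_error(fitness_fixed_point(matrix(-1, 2, 2)), "non-negative")
})

test_that("permutation symmetry of the fixed point", {
  set.seed(10)
  W <- matrix(rexp(48), 8, 6) * rbinom(48, 1, 0.7)
  W[rowSums(W) == 0, 1] <- 1
  W[1, colSums(W) == 0] <- 1
  rownames(W) <- paste0("c", 1:8); colnames(W) <- paste0("p", 1:6)
  base <- fitness_fixed_point(W)
  pr <- sample(8); pc <- sample(6)
  perm <- fitness_fixed_point(W[pr, pc])
  expect_equal(perm$F[rownames(W)], base$F[rownames(W)], tolerance = 1e-8)
  expect_equal(perm$Q[colnames(W)], base$Q[colnames(W)], tolerance = 1e-8)
})

test_that("an exclusive product raises its producer's fitness", {
  set.seed(6)
  W0 <- matrix(rexp(50), 10, 5) * rbinom(50, 1, 0.8)
  W0[rowSums(W0) == 0, 1] <- 1
  W0[1, colSums(W0) == 0] <- 1
  # add a product produced only by country 1
  W1 <- cbind(W0, exclusive = c(1, rep(0, 9)))
  colnames(W0) <- paste0("p", 1:5)
  colnames(W1) <- c(paste0("p", 1:5), "p6")
  r0 <- fitness_fixed_point(W0)
  r1 <- fitness_fixed_point(W1)
  expect_gt(unname(r1$F[1]), unname(r0$F[1]))
})

test_that("rank_scores handles order, ties and rescaling", {
  v <- c(x = 0.5, y = 2.0, z = 1.0)
  rk <- rank_scores(v)
  expect_equal(rk$label, c("y", "z", "x"))
  expect_equal(rk$rank, c(1L, 2L, 3L))
  expect_equal(rank_scores(v, descending = FALSE)$label, c("x", "z", "y"))
  # ties share the minimum rank, lexicographic display
  rt <- rank_scores(c(b = 1, a = 1, c = 0.5))
  expect_equal(rt$rank, c(1L, 1L, 3L))
  expect_equal(rt$label, c("a", "b", "c"))
  # invariant under positive rescaling
  expect_equal(rank_scores(10 * v)$rank, rk$rank)
  expect_error(rank_scores(numeric(0)), "empty")
  expect_error(rank_scores(c(a = Inf)), "finite")
})

test_that("fitness_trajectory aligns per-year runs and percent change", {
  w1 <- simulate_panel(12, 10, noise = 0.1, seed = 4, year = 2000)
  # identical panel relabelled as a second year
  p2 <- w1$panel
  p2$year <- 2001L
  traj <- fitness_trajectory(list(w1$panel, p2))
  f0 <- traj$F_table[traj$F_table$year == 2000, ]
  f1 <- traj$F_table[traj$F_table$year == 2001, ]
  expect_equal(f0$F, f1$F)
  expect_equal(percent_change(traj, f0$country[1], 2000, 2001), 0)

  # shrinking one country's basket cannot raise its fitness
  p3 <- w1$panel
  row <- which.max(rowSums(p3$M))
  keep <- which(p3$M[row, ] == 1)
  drop <- keep[seq_len(ceiling(length(keep) / 2))]
  p3$M[row, drop] <- 0L
  p3$W[row, drop] <- 0
  p3$year <- 2002L
  traj2 <- fitness_trajectory(list(w1$panel, p3))
  cn <- w1$panel$countries[row]
  expect_lte(percent_change(traj2, cn, 2000, 2002), 0)

  # hand percent change
  tr <- list(F_table = data.frame(country = "A", year = c(1, 2),
                                  F = c(2, 1.5)))
  class(tr) <- "fitness_trajectory"
  expect_equal(percent_change(tr, "A", 1, 2), -25)
})

test_that("fitness writer emits ranked tables and a convergence log", {
  W <- rbind(A = c(2, 1, 0), B = c(1, 0, 0), Z = c(0, 0, 0))
  colnames(W) <- c("p1", "p2", "p0")
  res <- fitness_fixed_point(W)
  prefix <- tempfile()
  write_fitness(res, prefix)
  ctab <- read.delim(paste0(prefix, "_countries.tsv"),
                     colClasses = "character")
  expect_equal(ctab$country, c("A", "B", "Z"))  # Z appended after ranks
  expect_equal(ctab$rank[1:2], c("1", "2"))
  conv <- read.delim(paste0(prefix, "_convergence.tsv"))
  expect_equal(nrow(conv), res$n_iterations)
  expect_equal(conv$delta[nrow(conv)],
               as.numeric(sprintf("%.6g", res$delta_final)))
})
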