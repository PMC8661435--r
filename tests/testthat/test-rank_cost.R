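test_that("rank transform assigns average ranks with ties, zeros included", {
  m <- toy_expr(0, 3, 4)
  m[1, ] <- c(0, 0, 5, 7)
  m[2, ] <- c(5, 1, 1, 7)
  m[3, ] <- c(2, 2, 2, 2)
  rk <- rank_transform(m)
  expect_equal(unname(rk[1, ]), c(1.5, 1.5, 3, 4))
  expect_equal(unname(rk[2, ]), c(3, 1.5, 1.5, 4))
  expect_equal(unname(rk[3, ]), c(2.5, 2.5, 2.5, 2.5))
  expect_equal(unname(rowSums(rk)), rep(4 * 5 / 2, 3))
})

test_that("gene_cost matches an independent OLS oracle and floors perfect fits", {
  # noisy row, identity ordering: compare against explicit design matrices
  row <- c(2, 1, 3, 5, 4, 6)
  got <- gene_cost(row, 1:6)
  expect_equal(got$bic, oracle_gene_cost(row, 1:6), tolerance = 1e-8)

  # random rows and orderings
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    row <- rank(rnorm(n))
    ordn <- sample.int(n)
    expect_equal(gene_cost(row, ordn)$bic, oracle_gene_cost(row, ordn),
                 tolerance = 1e-7)
  }

  # perfectly linear ranks: sigma2 floored, finite large-negative BIC
  got <- gene_cost(1:6, 1:6)
  expect_equal(got$degree, 1L)
  expect_equal(got$resid_var, 1e-8 * 36)
  expect_equal(got$bic, 6 * log(1e-8 * 36) + log(6))
  # reversed ordering gives the identical cost (polynomials closed under flip)
  expect_equal(gene_cost(1:6, 6:1)$bic, got$bic)
})

test_that("residual variance is non-increasing in polynomial degree", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    row <- rank(rnorm(n))
    ordn <- sample.int(n)
    y <- row[ordn]
    s <- (seq_len(n) - (n + 1) / 2) / n
    X <- cbind(1, s, s^2, s^3)
    rss <- sapply(1:3, function(d)
      mean(stats::lm.fit(X[, 1:(d + 1), drop = FALSE], y)$residuals^2))
    expect_true(all(diff(rss) <= 1e-9))
  }
})

test_that("total cost sums per-gene costs and doubles under row duplication", {
  st <- sim_monotone(8, 3, seed = 11)
  rk <- rank_transform(st$counts)
  ordn <- sample(8)
  tc <- total_cost(rk, ordn)
  expect_equal(tc$total, sum(tc$per_gene))
  expect_equal(tc$total, oracle_total_cost(rk, ordn), tolerance = 1e-7)
  # single gene: total equals that gene's cost
  one <- total_cost(rk[1, , drop = FALSE], ordn)
  expect_equal(one$total, unname(tc$per_gene[1]))
  # duplicating every row doubles the total exactly
  dup <- rbind(rk, rk)
  rownames(dup) <- sprintf("g%d", seq_len(nrow(dup)))
  expect_equal(total_cost(dup, ordn)$total, 2 * tc$total)
})

test_that("cost is invariant to ordering reversal and to cell relabelling", {
  st <- sim_monotone(9, 4, seed = 3)
  rk <- rank_transform(st$counts)
  set.seed(5)
  for (i in 1:10) {
    ordn <- sample.int(9)
    expect_equal(total_cost(rk, ordn)$total, total_cost(rk, rev(ordn))$total,
                 tolerance = 1e-9)
    # permutation covariance: relabel cells and compose the ordering
    relab <- sample.int(9)
    rk2 <- rk[, relab]
    ord2 <- match(ordn, relab)
    expect_equal(total_cost(rk2, ord2)$total, total_cost(rk, ordn)$total,
                 tolerance = 1e-9)
  }
})

test_that("cost is invariant to strictly monotone transforms of expression", {
  st <- sim_monotone(10, 5, seed = 13)
  expr <- st$counts
  ordn <- sample(10)
  base <- total_cost(rank_transform(expr), ordn)$total
  for (f in list(function(x) log1p(x), function(x) x^3, function(x) 2 * x + 7)) {
    expect_equal(total_cost(rank_transform(f(expr)), ordn)$total, base,
                 tolerance = 1e-9)
  }
})

test_that("brute force finds the monotone optimum and flags degeneracy", {
  # 1 perfectly monotone gene over 5 cells: identity or its reverse wins
  rk <- toy_expr(0, 1, 5)
  rk[1, ] <- 1:5
  bf <- argmin_bruteforce(rk)
  expect_true(all(bf$ordering == 1:5) || all(bf$ordering == 5:1))
  expect_false(bf$degenerate)

  # 2 monotone genes consistent with a hidden order on 6 cells
  pi6 <- c(3, 1, 6, 2, 5, 4)
  rk2 <- toy_expr(0, 2, 6)
  rk2[1, pi6] <- 1:6
  rk2[2, pi6] <- c(1, 2, 3, 4.5, 4.5, 6)
  bf2 <- argmin_bruteforce(rk2)
  expect_true(all(bf2$ordering == pi6) || all(bf2$ordering == rev(pi6)))

  # constant genes: every permutation ties
  rk3 <- toy_expr(3.5, 2, 5)
  expect_true(argmin_bruteforce(rk3)$degenerate)

  expect_error(argmin_bruteforce(toy_expr(1, 1, 10)), "at most 9")
})

test_that("undersized inputs are rejected with the minimum-size message", {
  expect_error(gene_cost(c(1, 2, 3, 4), 1:4), "5 cells")
  expect_error(evolve(toy_expr(1, 2, 4)), "5 cells")
})
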