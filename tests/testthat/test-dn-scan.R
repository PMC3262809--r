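test_that("scan equals the brute-force oracle on small profiles", {
  set.seed(11)
  cases <- list(c(5, 5), c(8, 10), c(12, 9), c(15, 15), c(4, 3))
  for (sz in cases) {
    p <- expression_profile(rnorm(sz[1]), rnorm(sz[2]))
    sc <- dn_scan(p)
    expect_equal(sc$dn, brute_dn(p$control, p$case), tolerance = 1e-12)
  }
  # with heavy ties
  p <- expression_profile(sample(1:3, 10, TRUE), sample(1:3, 8, TRUE))
  expect_equal(dn_scan(p)$dn, brute_dn(p$control, p$case), tolerance = 1e-12)
  # with a shifted tail block
  p <- expression_profile(rnorm(12), c(rnorm(8), rnorm(4) + 3))
  expect_equal(dn_scan(p)$dn, brute_dn(p$control, p$case), tolerance = 1e-12)
})

test_that("scan grid structure and degenerate inputs behave as specified", {
  p <- expression_profile(rnorm(10), rnorm(10))
  sc <- weighted_dn_scan(p)
  expect_equal(nrow(sc), 10)                   # positions n1 .. n-1
  expect_equal(sc$position, 10:19)
  expect_equal(sc$t, sc$position / 20)
  expect_true(all(lengths(list(sc$dn, sc$weight, sc$weighted)) == nrow(sc)))
  expect_true(all(sc$dn >= 0))
  expect_true(all(max(sc$weighted) >= sc$weighted))  # max contract

  # constant sequence: all-zero scan, no error, not significant
  pc <- expression_profile(rep(2, 6), rep(2, 7))
  expect_equal(dn_scan(pc)$dn, rep(0, 7))
  rc <- detect(pc)
  expect_false(rc$significant)
  expect_equal(rc$direction, "none")

  # profiles below the minimum size cannot even be constructed
  expect_error(expression_profile(1:2, 3), "at least 2")
  expect_error(expression_profile(1, 3:4), "at least 2")
})

test_that("the grid-approximated sup converges to the exact sup", {
  set.seed(3)
  p <- expression_profile(rnorm(20), c(rnorm(15), rnorm(5) + 2))
  exact <- dn_scan(p)$dn
  fine <- dn_scan(p, sup_method = "grid", y_step = 1 / 400)$dn
  expect_true(all(fine <= exact + 1e-12))  # grid can only miss sup
  expect_equal(fine, exact, tolerance = 0.05)
})

test_that("statistic is invariant under strictly increasing transforms", {
  set.seed(19)
  p <- expression_profile(rnorm(15), c(rnorm(10), rnorm(5) + 2))
  base <- weighted_dn_scan(p)
  for (f in list(function(x) exp(x), function(x) atan(x),
                 function(x) x^3 + 2 * x)) {
    q <- expression_profile(f(p$control), f(p$case))
    tr <- weighted_dn_scan(q)
    expect_equal(tr$dn, base$dn, tolerance = 1e-12)
    expect_equal(tr$weighted, base$weighted, tolerance = 1e-12)
  }
})

test_that("control order is irrelevant; case order is honoured by sorting", {
  set.seed(23)
  ctrl <- rnorm(12); case <- c(rnorm(8), rnorm(4) + 2)
  base <- dn_scan(expression_profile(ctrl, case))$dn
  perm <- dn_scan(expression_profile(sample(ctrl), case))$dn
  expect_equal(perm, base, tolerance = 1e-14)
  # sorted profiles give identical results whatever the case input order
  s1 <- detect(expression_profile(ctrl, case, sort_case = TRUE))
  s2 <- detect(expression_profile(ctrl, sample(case), sort_case = TRUE))
  expect_equal(s1$statistic, s2$statistic)
  expect_equal(s1$cp_fraction, s2$cp_fraction)
})

test_that("weight function is an ascending compensation curve", {
  lefts <- numeric(0)
  for (n1 in c(10, 25, 50)) {
    w <- weight_function(2 * n1, n1)
    expect_true(all(w >= 1))
    expect_true(all(diff(w) >= 0))          # non-decreasing left to right
    expect_gt(w[length(w)], w[1])           # rises toward the right bound
    lefts <- c(lefts, w[1])
  }
  # the left-end value stays near 1 and tightens as the grid grows
  expect_true(all(diff(lefts) < 0))
  expect_lte(lefts[2], 1.1)                 # n1 = 25 and larger
  expect_lte(lefts[1], 1.2)
  expect_error(weight_function(3, 2), "at least 4")
  # forcing w == 1 collapses the weighted scan onto the plain scan
  p <- expression_profile(rnorm(10), rnorm(10))
  sc <- weighted_dn_scan(p, c = 0)
  expect_equal(sc$weighted, sc$dn)
})

test_that("weighted scan shows no artificial spike at the right bound under the null", {
  set.seed(31)
  acc <- 0
  reps <- 300
  for (i in seq_len(reps)) {
    sc <- weighted_dn_scan(generate_gene(25, 25))
    acc <- acc + sc$weighted
  }
  mw <- acc / reps
  mid <- mean(mw[8:17])  # middle of the 25-position grid
  expect_lt(mw[length(mw)], 2 * mid)
})
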