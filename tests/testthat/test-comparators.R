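test_that("t score agrees with the pooled two-sample t test", {
  set.seed(2)
  p <- expression_profile(rnorm(12), rnorm(15) + 1)
  tt <- t.test(p$case_original, p$control, var.equal = TRUE)
  expect_equal(as.numeric(score_t(p)), abs(unname(tt$statistic)),
               tolerance = 1e-12)
  expect_equal(attr(score_t(p), "sign"), 1)

  ident <- expression_profile(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(as.numeric(score_t(ident)), 0, tolerance = 1e-12)

  flat <- expression_profile(rep(1, 4), rep(1, 4))
  expect_warning(s <- score_t(flat), "pooled variance")
  expect_equal(as.numeric(s), 0)

  sep <- expression_profile(rep(0, 4) + rnorm(4, sd = 1e-3),
                            rep(1, 4) + rnorm(4, sd = 1e-3))
  expect_gt(score_t(sep), 50)
})

test_that("COPA behaves like a scaled case percentile", {
  set.seed(4)
  # symmetric null gene: score near the standard normal 0.75 quantile
  sc <- replicate(400, score_copa(expression_profile(rnorm(25), rnorm(25))))
  expect_lt(abs(mean(sc) - qnorm(0.75)), 0.1)
  # MAD = 0 falls back with a warning instead of dividing by zero
  expect_warning(score_copa(expression_profile(rep(1, 5), rep(1, 5))), "MAD")
})

test_that("all scores are invariant to adding a constant and to rescaling", {
  set.seed(6)
  p <- expression_profile(rnorm(20), c(rnorm(15), rnorm(5) + 2))
  shifted <- expression_profile(p$control + 7, p$case_original + 7)
  doubled <- expression_profile(p$control * 2, p$case_original * 2)
  for (m in names(dge_methods())) {
    f <- dge_methods()[[m]]
    expect_equal(as.numeric(f(shifted)), as.numeric(f(p)), tolerance = 1e-8,
                 label = paste(m, "shift"))
    expect_equal(as.numeric(f(doubled)), as.numeric(f(p)), tolerance = 1e-8,
                 label = paste(m, "scale"))
  }
})

test_that("MOST equals an exhaustive maximum over ordered subset sizes", {
  set.seed(9)
  p <- expression_profile(rnorm(4), c(0.5, 2.5, -0.3, 1.8))
  all <- c(p$control, p$case_original)
  z <- sort((p$case_original - median(all)) / mad(all), decreasing = TRUE)
  k <- wcps:::.most_constants(4)
  brute <- -Inf
  for (j in 1:4) brute <- max(brute, (sum(z[1:j]) - k$mean[j]) / k$sd[j])
  expect_equal(score_most(p), brute, tolerance = 1e-12)
})

test_that("LRS is oriented and stable on degenerate genes", {
  set.seed(10)
  null_scores <- replicate(60, score_lrs(expression_profile(rnorm(15), rnorm(15))))
  dge_scores <- replicate(60, score_lrs(
    expression_profile(rnorm(15), c(rnorm(10), rnorm(5) + 3))))
  expect_gt(mean(dge_scores), mean(null_scores))
  expect_true(all(is.finite(null_scores)))
  expect_equal(score_lrs(expression_profile(rep(1, 5), rep(1, 5))), 0)
})

test_that("the method registry is complete and validated", {
  reg <- dge_methods()
  expect_setequal(names(reg),
                  c("t", "copa", "os", "ort", "tri_ort", "most", "tri_most",
                    "lrs", "npcps", "wcps"))
  p <- expression_profile(rnorm(10), rnorm(10))
  row <- score_gene(p, "copa")
  expect_equal(row$method, "copa")
  expect_true(is.finite(row$score))
  expect_error(score_gene(p, "nope"), "available")
})

test_that("no method separates null genes from null genes", {
  set.seed(12)
  for (m in c("wcps", "t", "os", "most")) {
    a <- cell_auc(15, 0, 0, n_genes = 300, method = m)
    expect_lt(abs(a - 0.5), 0.09)
  }
})
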