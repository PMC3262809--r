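test_that("direction is assigned from the winning orientation", {
  set.seed(5)
  over <- expression_profile(rnorm(25), c(rnorm(17), rnorm(8) + 3),
                             sort_case = TRUE)
  r <- detect(over, alpha = 0.01)
  expect_true(r$significant)
  expect_equal(r$direction, "over")

  under <- expression_profile(rnorm(25), c(rnorm(17), rnorm(8) - 3),
                              sort_case = TRUE)
  ru <- detect(under, alpha = 0.01)
  expect_true(ru$significant)
  expect_equal(ru$direction, "under")
  # the change-point fraction still points at the affected subset size
  expect_gt(ru$cp_fraction, 0.5)

  # sequence-order profiles get direction from the discrepancy sign
  seq_under <- generate_gene(25, 25, k = 9, mu = -3)
  rs <- detect(seq_under, alpha = 0.01)
  expect_true(rs$significant)
  expect_equal(rs$direction, "under")
})

test_that("result invariants hold", {
  set.seed(8)
  g <- generate_gene(20, 20, k = 6, mu = 2)
  for (mode in c("wcps", "npcps")) {
    r <- detect(g, alpha = 0.01, mode = mode)
    expect_equal(r$significant, r$statistic > r$critical_value)
    expect_equal(r$cp_fraction, r$cp_index / g$n)
    expect_true(r$cp_fraction > 0 && r$cp_fraction < 1)
    expect_equal(r$statistic, max(if (mode == "wcps") r$scan$weighted
                                  else r$scan$dn))
  }
})

test_that("sample flagging crosses the change-point value correctly", {
  p <- expression_profile(c(0.1, -0.1, 0, 0.05, -0.05), c(0, 0, 0, 5, 6),
                          sort_case = TRUE)
  r <- detect(p, alpha = 0.05)
  expect_true(r$significant)
  expect_equal(r$direction, "over")
  expect_true(r$cp_value < 5 && r$cp_value >= 0)
  expect_equal(flag_dge_samples(p, r), c(0L, 0L, 0L, 1L, 1L))

  # flags follow the original case order, not the sorted order
  p2 <- expression_profile(c(0.1, -0.1, 0, 0.05, -0.05), c(5, 0, 6, 0, 0),
                           sort_case = TRUE)
  r2 <- detect(p2, alpha = 0.05)
  expect_equal(flag_dge_samples(p2, r2), c(1L, 0L, 1L, 0L, 0L))

  # non-significant gene: all zeros plus a warning, not an error
  null <- expression_profile(rep(c(1, 2), 5), rep(c(1, 2), 5))
  rn <- detect(null)
  expect_false(rn$significant)
  expect_warning(fl <- flag_dge_samples(null, rn), "not significant")
  expect_equal(fl, integer(10))
})

test_that("flagged-sample counts concentrate near the injected subset size", {
  set.seed(13)
  counts <- replicate(150, {
    g <- generate_gene(25, 25, k = 9, mu = 2)
    # microarray-style profile: case sorted ascending before scanning
    p <- expression_profile(g$control, g$case_original, sort_case = TRUE)
    r <- detect(p, alpha = 0.05)
    if (r$significant) sum(flag_dge_samples(p, r)) else NA_real_
  })
  counts <- counts[!is.na(counts)]
  expect_gt(length(counts), 130)          # k = 9 is detected almost always
  expect_lt(abs(mean(counts) - 9), 2)
  expect_gt(mean(abs(counts - 9) <= 3), 0.8)
})
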