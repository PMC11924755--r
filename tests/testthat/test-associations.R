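test_that("contingency tallies shared samples and guards the empty case", {
  a <- c(s1 = "L", s2 = "L", s3 = "H", s4 = "H")
  b <- c(s1 = "A", s2 = "N", s3 = "A", s4 = "N")
  tab <- contingency(a, b)
  expect_equal(unclass(unname(as.matrix(tab))),
               matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(attr(tab, "n_dropped"), 0L)

  expect_message(tab2 <- contingency(a, c(b, s9 = "A")), "1 sample")
  expect_equal(sum(tab2), 4)
  expect_error(contingency(a, c(x1 = "A")), "no shared samples")
  expect_error(contingency(c(s1 = "L", s1 = "H"), b), "duplicate")

  # data-frame input is accepted
  tab3 <- contingency(tibble::tibble(sample = names(a), cat = a),
                      tibble::tibble(sample = names(b), cat = b))
  expect_equal(as.matrix(tab3), as.matrix(tab))
})

test_that("chi-square handles independence and perfect association exactly", {
  even <- chisq_mc(matrix(5, 2, 2), n_sim = 100, seed = 1)
  expect_equal(even$statistic, 0)
  expect_equal(max(abs(even$residuals)), 0)
  expect_equal(even$p_asymptotic, 1)

  diag <- chisq_mc(matrix(c(10, 0, 0, 10), 2, 2), n_sim = 2000, seed = 1)
  expect_equal(diag$statistic, 20)
  expect_equal(diag$df, 1L)
  expect_equal(unname(diag$residuals[1, 1]), sqrt(5), tolerance = 1e-9)
  expect_equal(unname(diag$residuals[1, 2]), -sqrt(5), tolerance = 1e-9)
  expect_lte(diag$p_simulated, 0.005)
  expect_gte(diag$p_simulated, 1 / 2001)
})

test_that("chi-square machinery satisfies its structural invariants", {
  for (seed in 1:10) {
    tab <- withr::with_seed(seed, matrix(stats::rpois(12, 8) + 1, 3, 4))
    res <- chisq_mc(tab, n_sim = 200, seed = seed)
    # residual squares sum to the statistic
    expect_equal(sum(res$residuals^2), res$statistic, tolerance = 1e-9)
    # expected margins equal observed margins
    expect_equal(rowSums(res$expected), rowSums(tab), ignore_attr = TRUE)
    expect_equal(colSums(res$expected), colSums(tab), ignore_attr = TRUE)
    # statistic and asymptotic p match the standard implementation
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_asymptotic, ref$p.value)
  }
  expect_error(chisq_mc(matrix(c(1, 0, 2, 0), 2, 2)), "zero row or column")
  expect_error(chisq_mc(matrix(1:4, 2, 2), n_sim = 0), "n_sim")
  expect_error(chisq_mc(matrix(c(6, 0, 0, 0, 0, 0), 2, 3)), "zero")
})

test_that("simulated p agrees with exact enumeration on small 2x2 tables", {
  tables <- list(
    matrix(c(8, 2, 3, 7), 2, 2),
    matrix(c(6, 6, 2, 10), 2, 2),
    matrix(c(5, 1, 4, 8), 2, 2),
    matrix(c(2, 9, 7, 3), 2, 2)
  )
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    p_exact <- exact_chisq_p_2x2(tab)
    res <- chisq_mc(tab, n_sim = 4000, seed = i)
    mc_se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(res$p_simulated - p_exact), 3 * mc_se + 2 / 4001)
  }
})

test_that("tidy/glance expose chi-square cells and summary", {
  tab <- contingency(c(s1 = "L", s2 = "L", s3 = "H", s4 = "H"),
                     c(s1 = "A", s2 = "A", s3 = "N", s4 = "N"))
  res <- chisq_mc(tab, n_sim = 500, seed = 0)
  cells <- tidy(res)
  expect_equal(nrow(cells), 4)
  expect_equal(sum(cells$observed), 4)
  expect_equal(sum(cells$residual^2), res$statistic, tolerance = 1e-9)
  g <- glance(res)
  expect_equal(g$statistic, res$statistic)
  expect_equal(g$n_sim, 500L)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("pairwise Wilcoxon reproduces exact small-sample results", {
  df <- tibble::tibble(
    value = c(1, 2, 3, 10, 11, 12),
    group = rep(c("a", "b"), each = 3)
  )
  res <- pairwise_wilcoxon(df, value, group)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1) # 2/20 rank assignments as extreme
  expect_false(res$significant)

  # identical groups: symmetric exact two-sided p of 1
  same <- tibble::tibble(value = rep(c(1, 2, 3), 2),
                         group = rep(c("a", "b"), each = 3))
  expect_equal(pairwise_wilcoxon(same, value, group)$p_value, 1)

  # swapping group order leaves the two-sided p unchanged
  df2 <- dplyr::mutate(df, group = factor(group, levels = c("b", "a")))
  expect_equal(pairwise_wilcoxon(df2, value, group)$p_value, res$p_value)
})

test_that("paired Wilcoxon handles degenerate and malformed input", {
  df <- tibble::tibble(value = c(1, 2, 3, 1, 2, 3),
                       group = rep(c("pre", "post"), each = 3))
  expect_warning(res <- pairwise_wilcoxon(df, value, group, paired = TRUE),
                 "zero")
  expect_equal(res$p_value, 1)

  uneven <- tibble::tibble(value = c(1, 2, 3, 4, 5),
                           group = c("a", "a", "a", "b", "b"))
  expect_error(pairwise_wilcoxon(uneven, value, group, paired = TRUE),
               "equal-length")

  expect_error(
    pairwise_wilcoxon(tibble::tibble(value = 1:3, group = c("a", "a", "a")),
                      value, group),
    "at least 2 groups"
  )
  three <- tibble::tibble(value = stats::rnorm(9), group = rep(letters[1:3], 3))
  expect_error(pairwise_wilcoxon(three, value, group, paired = TRUE),
               "exactly 2 groups")
  adj <- pairwise_wilcoxon(three, value, group, adjust = TRUE)
  expect_equal(nrow(adj), 3)
  expect_true("p_adjusted" %in% names(adj))
})

test_that("score_by_cluster summarizes and compares scores across labels", {
  m <- matrix(rep(c(-2, 0, 2), each = 8), nrow = 2,
              dimnames = list(c("P1", "P2"), sprintf("S%02d", 1:12)))
  m[1, ] <- m[1, ] + rep(c(-0.1, 0.1), 6)
  sol <- we_cluster(fake_scores(m), k = 3, restarts = 5, seed = 1)

  # scores equal to cluster index: medians strictly increase with label
  scores <- stats::setNames(sol$assignments$cluster +
                              0.01 * seq_len(12), sol$assignments$sample)
  res <- score_by_cluster(scores, sol)
  expect_equal(res$summary$label,
               factor(c("DDR Low", "DDR Intermediate", "DDR High"),
                      levels = levels(sol$assignments$label)))
  expect_true(all(diff(res$summary$median) > 0))

  # constant scores: every pairwise p is 1
  const <- stats::setNames(rep(1, 12), sol$assignments$sample)
  expect_true(all(score_by_cluster(const, sol)$comparisons$p_value == 1))

  expect_error(score_by_cluster(unname(scores), sol), "named")
  expect_error(
    score_by_cluster(stats::setNames(1:3, c("x", "y", "z")), sol),
    "no clustered samples"
  )
})
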