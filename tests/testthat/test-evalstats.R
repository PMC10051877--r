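test_that("score_study handles degenerate answer strategies exactly", {
  truth <- rep(c("conventional", "synthetic"), c(25, 35))
  tab <- simulate_raters(truth, 1, seed = 1)
  tab$answer <- "conventional"   # one rater answering conventional throughout
  sc <- score_study(tab)
  expect_equal(sc$pct_fn, 100)
  expect_equal(sc$pct_fp, 0)
  expect_equal(sc$pct_correct, 42)  # round(100 * 25/60)
  # missing answers are rejected with a gap listing
  tab2 <- simulate_raters(truth, c(1, 1), seed = 1)
  expect_error(score_study(tab2[-1, ]), "exactly once")
})

test_that("concordance is 100/0 at the extremes and rater-exchangeable", {
  truth <- rep(c("conventional", "synthetic"), 10)
  tab <- simulate_raters(truth, c(1, 1), seed = 2)
  expect_equal(concordance(tab, "ten_year"), 100)
  opp <- simulate_raters(truth, c(1, 0), seed = 2)
  expect_equal(concordance(opp, "ten_year"), 0)
  tab4 <- simulate_raters(truth, c(0.9, 0.6, 0.4, 0.8), seed = 3)
  ref <- concordance(tab4, "ten_year")
  # relabeling raters and permuting rows changes nothing
  perm <- tab4[sample(nrow(tab4)), ]
  perm$rater_id <- chartr("1234", "4321", perm$rater_id)
  expect_equal(concordance(perm, "ten_year"), ref)
  expect_error(concordance(simulate_raters(truth, 1, seed = 1), "ten_year"),
               "2 raters")
})

test_that("independent chance raters concord near 50% (Monte-Carlo null)", {
  truth <- rep(c("conventional", "synthetic"), 30)
  reps <- vapply(1:300, function(r)
    concordance(simulate_raters(truth, rep(0.5, 4), seed = 4000 + r),
                "ten_year"), numeric(1))
  expect_lt(abs(mean(reps) - 50), 3)
})

test_that("chi-square matches the direct Pearson formula", {
  expect_equal(chi_square_independence(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  same <- matrix(c(30, 60, 20, 40), 2)  # identical row distributions
  r <- chi_square_independence(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  set.seed(5)
  for (i in 1:25) {
    m <- matrix(rpois(6, 20) + 1, 3, 2)
    got <- chi_square_independence(m)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    stat <- sum((m - e)^2 / e)
    expect_equal(got$statistic, stat, tolerance = 1e-10)
    expect_equal(got$df, 2)
    expect_equal(got$p, pchisq(stat, 2, lower.tail = FALSE), tolerance = 1e-10)
  }
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("wilcoxon signed-rank matches exhaustive sign enumeration at n = 8", {
  set.seed(6)
  for (rep in 1:5) {
    a <- round(rnorm(8), 3)
    b <- round(rnorm(8), 3)
    d <- a - b
    if (any(d == 0) || any(duplicated(abs(d)))) next
    got <- wilcoxon_signed_rank(a, b)
    rk <- rank(abs(d))
    v <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
    vs <- signs %*% rk
    p_exact <- min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
    expect_equal(got$statistic, v)
    expect_equal(got$p, p_exact, tolerance = 1e-12)
    expect_true(got$exact)
  }
  # one differing pair: the statistic is that pair's rank contribution
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 3)
  expect_equal(wilcoxon_signed_rank(a, b)$statistic, 1)
  # symmetric differences give a two-sided p of 1 (normal approximation)
  sym <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3), rep(0, 6))
  expect_equal(sym$p, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("two-sample t matches the pooled-variance formula", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(9, 0.4)
    got <- two_sample_t(a, b)
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    df <- length(a) + length(b) - 2
    expect_equal(got$statistic, tt, tolerance = 1e-12)
    expect_equal(got$df, df)
    expect_equal(got$p, 2 * pt(-abs(tt), df), tolerance = 1e-12)
  }
  sep <- two_sample_t(c(1, 1.01, 0.99), c(11, 11.01, 10.99))
  expect_lt(sep$p, 0.01)
  expect_error(two_sample_t(c(1), c(1, 2)), "n >= 2")
  welch <- two_sample_t(rnorm(5), rnorm(8, 1), variant = "welch")
  expect_false(welch$df == 11)  # fractional Welch df
})

test_that("study designs sample without replacement, reproducibly", {
  pool <- data.frame(
    image_id = c(sprintf("c%03d", 1:40), sprintf("s%03d", 1:253)),
    class = rep(c("conventional", "synthetic"), c(40, 253)))
  d <- design_study(pool, 26, 34, seed = 9)
  sel <- d$selection
  expect_equal(sum(sel$true_class == "conventional"), 26)
  expect_equal(sum(sel$true_class == "synthetic"), 34)
  expect_false(any(duplicated(sel$image_id)))
  expect_identical(design_study(pool, 26, 34, seed = 9)$selection, sel)
  # requesting the whole pool returns it in full under any seed
  all_d <- design_study(pool, 40, 253, seed = 1)
  expect_setequal(all_d$selection$image_id, pool$image_id)
  expect_error(design_study(pool, 41, 10, seed = 1), "too small")
})
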