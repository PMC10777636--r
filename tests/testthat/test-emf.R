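test_that("min-max standardization matches its formula and invariances", {
  expect_equal(minmax_standardize(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(8)
  v <- rnorm(25)
  expect_equal(minmax_standardize(v), (v - min(v)) / (max(v) - min(v)))
  # strictly increasing affine transforms change nothing
  expect_equal(minmax_standardize(3 * v + 7), minmax_standardize(v))
  expect_error(minmax_standardize(rep(1, 5)), "degenerate")
  expect_error(minmax_standardize(3), "at least 2")
})

test_that("normality screening picks the expected transform", {
  set.seed(42)
  lognorm <- exp(rnorm(100))
  gauss <- rnorm(100, mean = 50, sd = 3)
  m <- cbind(LN = lognorm, G = gauss, C = rep(2, 100))
  rownames(m) <- paste0("s", 1:100)
  tr <- transform_for_normality(function_table(m))
  lg <- tr$log
  expect_identical(lg$transform[lg$fn == "LN"], "log")
  expect_gte(lg$shapiro_p_final[lg$fn == "LN"], 0.05)
  expect_identical(lg$transform[lg$fn == "G"], "none")
  expect_identical(lg$transform[lg$fn == "C"], "none")  # degenerate untouched
  expect_equal(tr$fx$values[, "LN"], log(lognorm), ignore_attr = TRUE)
})

test_that("EMF is the mean of standardized functions with the right bounds", {
  m <- cbind(F1 = c(1, 2, 3, 4), F2 = c(10, 30, 20, 40), F3 = c(5, 1, 3, 9))
  rownames(m) <- paste0("s", 1:4)
  res <- emf_index(function_table(m))
  # hand calculation: per-column min-max, then row means
  hand <- rowMeans(cbind(c(0, 1, 2, 3) / 3,
                         c(0, 2, 1, 3) / 3,
                         c(4, 0, 2, 8) / 8))
  expect_equal(unname(res$emf), hand)
  # sample 4 attains every maximum -> EMF exactly 1
  expect_equal(unname(res$emf["s4"]), 1)
  expect_true(all(res$emf >= 0 & res$emf <= 1))

  # duplicated function acts as a doubled weight
  m2 <- cbind(m, F1b = m[, "F1"])
  res2 <- emf_index(function_table(m2))
  s <- res$standardized
  expect_equal(unname(res2$emf),
               unname((2 * s[, "F1"] + s[, "F2"] + s[, "F3"]) / 4))

  # degenerate functions are excluded with a warning
  m3 <- cbind(m, K = rep(7, 4))
  expect_warning(res3 <- emf_index(function_table(m3)), "degenerate")
  expect_equal(res3$emf, res$emf)
  mk <- cbind(K = rep(1, 4))
  rownames(mk) <- paste0("s", 1:4)
  expect_error(emf_index(function_table(mk)), "all functions")
})

test_that("exact rank-sum enumeration reproduces known floors and wilcox.test", {
  # complete separation, 4 vs 4: two-sided floor 2/70
  ts <- rank_sum_test(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(ts$p.value, 2 / 70)
  expect_true(ts$exact)
  # 5 vs 5: 2/252
  expect_equal(rank_sum_test(11:15, 1:5)$p.value, 2 / 252)
  # all-tied data: p = 1 under mid-rank exactness
  expect_equal(rank_sum_test(rep(2, 3), rep(2, 4))$p.value, 1)
  # tie-free cases agree with the exact Mann-Whitney distribution
  set.seed(99)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(rank_sum_test(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(rank_sum_test(x, y, "greater")$p.value,
                 wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value)
  }
})

test_that("EMF group comparison reports exact pairwise tests and percent change", {
  set.seed(5)
  meta <- make_meta(12)
  emf <- c(runif(4, 0.40, 0.46), runif(4, 0.10, 0.16), runif(4, 0.25, 0.31))
  names(emf) <- meta$sample_id  # AL high, RZ low, TZ middle
  cmp <- compare_emf_groups(emf, meta)
  expect_true(cmp$kruskal$p.value < 0.05)
  pw <- cmp$pairwise
  al_rz <- pw[pw$group_a == "AL" & pw$group_b == "RZ", ]
  expect_equal(al_rz$p.value, 2 / 70)  # complete separation
  # percent change convention: reference is the second-named group
  expect_equal(al_rz$pct_change,
               100 * (mean(emf[1:4]) - mean(emf[5:8])) / mean(emf[5:8]))
  # the reported direction reproduces a 0.43-vs-0.13 contrast as +230.8%
  expect_equal(round(100 * (0.43 - 0.13) / 0.13, 1), 230.8)
})

test_that("EMF invariance under affine rescaling of raw functions", {
  fx <- make_fx(10, 4, seed = 17)
  e1 <- emf_index(fx)
  m2 <- fx$values
  m2[, 2] <- 100 * m2[, 2] + 5
  e2 <- emf_index(function_table(m2))
  expect_equal(e1$emf, e2$emf)
})
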