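test_that("exact one-sample Wilcoxon matches sign-flip enumeration", {
  enum_p <- function(values, mu) {
    d <- values - mu
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    n <- length(d)
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    v_all <- apply(subsets, 1, function(s) sum(r[s]))
    center <- n * (n + 1) / 4
    mean(abs(v_all - center) >= abs(v_obs - center))
  }
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(6:10, 1)
    values <- round(rnorm(n, 52, 6), 3)  # continuous: no ties/zeros
    res <- one_sample_wilcoxon(values, mu = 50)
    expect_equal(res$p_value, enum_p(values, 50), tolerance = 1e-12)
  }
})

test_that("strong unanimous side preference is highly significant", {
  occ <- c(100, 100, 100, 100, 100, 100, 100, 100, 100, 100,
           98.5, 96.2, 91.7, 88.4, 83.0, 79.0)  # 16 fish, all >= 79 %
  res <- one_sample_wilcoxon(occ, mu = 50)
  expect_lt(res$p_value, 0.001)
  # symmetric values about mu are far from significant
  sym <- c(40, 60, 45, 55, 35, 65, 49, 51)
  expect_gte(one_sample_wilcoxon(sym, 50)$p_value, 0.5)
  expect_error(one_sample_wilcoxon(rep(50, 8), 50), "degenerate")
})

test_that("Friedman test behaves at both extremes and under monotone maps", {
  mat <- matrix(7, nrow = 4, ncol = 5)  # identical columns
  res <- friedman_test(mat)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1)

  # strictly increasing across the 17 intervals for every fish
  inc <- t(replicate(16, sort(runif(17))))
  res2 <- friedman_test(inc)
  expect_equal(unname(res2$statistic), 16 * 16)  # n * (k - 1), no ties
  expect_lt(res2$p_value, 1e-10)

  set.seed(21)
  m <- matrix(rnorm(48), nrow = 6)
  expect_equal(friedman_test(m)$statistic,
               friedman_test(exp(m))$statistic)  # monotone-transform invariant
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("Friedman p is consistent with a joint column permutation null", {
  set.seed(31)
  m <- matrix(rnorm(40), nrow = 8)  # H0: no interval effect
  obs <- friedman_test(m)$statistic
  perm <- replicate(400, {
    mp <- t(apply(m, 1, sample))
    friedman_test(mp)$statistic
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_perm - friedman_test(m)$p_value), 0.15)
})

test_that("Holm step-down matches the hand-worked example", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(41)
  p <- runif(16)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))  # monotone in the raw ordering
})

test_that("paired Wilcoxon family finds no effect under identical distributions", {
  set.seed(51)
  base <- rnorm(16, 90, 5)
  mat <- sapply(1:6, function(j) base + rnorm(16, 0, 3))  # same location
  res <- pairwise_wilcoxon_holm(base, mat, family = "residence")
  expect_true(all(res$p_adjusted >= 0.05, na.rm = TRUE))
  expect_true(all(res$p_adjusted >= res$p_value, na.rm = TRUE))
  # fewer than 5 informative pairs
  degenerate <- cbind(base, base + c(1, 1, 1, rep(0, 13)))
  expect_warning(res2 <- pairwise_wilcoxon_holm(base, degenerate),
                 "fewer than 5")
  expect_true(is.na(res2$p_value[2]))
})

test_that("Holm keeps family-wise error near nominal under the global null", {
  set.seed(61)
  fwe <- mean(replicate(4000, {
    base <- rnorm(8)
    p <- vapply(1:3, function(j) {
      suppressWarnings(stats::wilcox.test(rnorm(8), base, paired = TRUE,
                                          exact = TRUE)$p.value)
    }, numeric(1))
    any(holm_adjust(p) < 0.05)
  }))
  expect_lte(fwe, 0.055)
})

test_that("EOD mixed model estimates vanish on a null response", {
  set.seed(91)
  dat <- tidyr::expand_grid(fish_id = sprintf("F%02d", 1:8), time = 1:10)
  dat$do <- 100 - 9 * dat$time
  dat$residence_frac <- runif(nrow(dat))  # breaks collinearity with time
  dat$percent_change <- 0
  fit <- suppressMessages(suppressWarnings(fit_eod_lmm(dat)))
  expect_true(all(abs(fit$coefficients$estimate) < 1e-8))
})

test_that("EOD model recovers a negative time effect and a null interaction", {
  gen <- function(s) {
    set.seed(s)
    dat <- tidyr::expand_grid(fish_id = sprintf("F%02d", 1:16), time = 1:16)
    dat$do <- rep(seq(85, 10, length.out = 16), times = 16)
    dat$residence_frac <- runif(nrow(dat))
    slope <- rnorm(16, -0.05, 0.01)[match(dat$fish_id, sprintf("F%02d", 1:16))]
    dat$percent_change <- slope * dat$time + rnorm(nrow(dat), 0, 0.1)
    dat
  }
  res <- vapply(1:100, function(s) {
    fit <- suppressMessages(suppressWarnings(fit_eod_lmm(gen(s))))
    co <- fit$coefficients
    tt <- co[co$term == "time", ]
    ii <- co[co$term == "interaction", ]
    c(neg_sig = tt$estimate < 0 && tt$p_value < 0.05,
      int_null = abs(ii$estimate) <= 2 * ii$std_error)
  }, c(neg_sig = FALSE, int_null = FALSE))
  expect_gte(mean(res["neg_sig", ]), 0.9)
  expect_gte(mean(res["int_null", ]), 0.9)
})

test_that("EOD model guards against collinear fixed effects", {
  dat <- tidyr::expand_grid(fish_id = sprintf("F%02d", 1:4), time = 1:6)
  dat$do <- 50
  dat$residence_frac <- 0  # interaction column identically zero
  dat$percent_change <- rnorm(nrow(dat))
  expect_error(suppressMessages(fit_eod_lmm(dat)), "collinear|rank")
})

test_that("AIC comparison ranks candidate EOD models", {
  set.seed(71)
  dat <- tidyr::expand_grid(fish_id = sprintf("F%02d", 1:10), time = 1:12)
  dat$do <- rep(seq(85, 10, length.out = 12), times = 10)
  dat$residence_frac <- runif(nrow(dat))
  dat$percent_change <- -0.04 * dat$time + rnorm(nrow(dat), 0, 0.1)
  cmp <- suppressMessages(suppressWarnings(compare_eod_models(dat)))
  expect_setequal(cmp$fixed_effects,
                  c("time", "time + interaction", "interaction"))
  expect_equal(cmp$delta_aic[1], 0)
  expect_true(all(diff(cmp$aic) >= 0))
  expect_true(grepl("time", cmp$fixed_effects[1]))
})

test_that("repeatability ANOVA: identical days give F ~ 0, permutation agrees", {
  dat <- tidyr::expand_grid(fish_id = sprintf("F%02d", 1:6),
                            do = c(10, 15, 20), day = c(1, 2))
  set.seed(81)
  base <- rnorm(nrow(dat) / 2, 60, 15)
  dat$residence <- base[rep(seq_len(nrow(dat) / 2), each = 2)]
  res <- rm_anova_repeatability(dat)
  expect_lt(res$statistic, 1e-20)
  expect_gt(res$p_value, 0.99)

  dat$residence <- dat$residence + rnorm(nrow(dat), 0, 8)
  res2 <- rm_anova_repeatability(dat)
  perm_f <- replicate(300, {
    datp <- dat |>
      dplyr::group_by(fish_id, do) |>
      dplyr::mutate(residence = sample(residence)) |>
      dplyr::ungroup()
    rm_anova_repeatability(datp)$statistic
  })
  p_perm <- mean(perm_f >= res2$statistic - 1e-12)
  expect_lt(abs(p_perm - res2$p_value), 0.15)

  expect_error(rm_anova_repeatability(dat[-1, ]), "unbalanced")
})
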