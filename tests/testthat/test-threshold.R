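test_that("with no between-fish variance the LMM collapses to OLS", {
  rows <- segmented_rows(n_fish = 4, noise_sd = 3, fish_sd = 0, seed = 2)
  lmm <- fit_random_intercept_lmm(rows)
  ols <- fit_random_intercept_lmm(rows, mode = "ols")
  expect_true(lmm$singular_fallback)
  expect_equal(lmm$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("perfect linear data fits exactly", {
  rows <- tibble::tibble(fish_id = rep(c("a", "b"), each = 5),
                         do = rep(seq(10, 50, 10), 2))
  rows$residence <- 20 + 0.5 * rows$do
  fit <- fit_random_intercept_lmm(rows)
  expect_lt(fit$rss, 1e-12)
  expect_equal(unname(nakagawa_r2(fit)[1]), 1, tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate, c(20, 0.5), tolerance = 1e-8)
})

test_that("mixed-model estimates recover simulated fixed effects", {
  hit <- vapply(1:200, function(s) {
    rows <- linear_rows(n_fish = 16, b0 = 90, b1 = 0.05, fish_sd = 5,
                        noise_sd = 8, seed = s)
    fit <- fit_random_intercept_lmm(rows)
    abs(fit$coefficients$estimate - c(90, 0.05)) <=
      2 * fit$coefficients$std_error
  }, logical(2))
  expect_gte(mean(hit[1, ]), 0.9)  # intercept within 2 SE
  expect_gte(mean(hit[2, ]), 0.9)  # slope within 2 SE
})

test_that("Satterthwaite df and p-values are reported for fixed effects", {
  rows <- linear_rows(n_fish = 8, fish_sd = 6, noise_sd = 5, seed = 3)
  fit <- fit_random_intercept_lmm(rows)
  expect_false(fit$singular_fallback)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "do"))
  expect_true(all(is.finite(td$df)) && all(td$df > 0))
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
  g <- glance(fit)
  expect_true(g$r2_marginal <= g$r2_conditional)
  expect_gte(g$var_random, 0)
})

test_that("degenerate inputs are rejected", {
  rows <- tibble::tibble(fish_id = c("a", "a"), do = c(10, 10),
                         residence = c(1, 2))
  expect_error(fit_random_intercept_lmm(rows), "distinct DO")
  zero_fit <- structure(list(var_fixed = 0, var_random = 0, var_residual = 0),
                        class = "lmm_fit")
  expect_error(nakagawa_r2(zero_fit), "zero")
})

test_that("line intersection reproduces the reported threshold arithmetic", {
  # fixed-effect estimates of the two segments as printed in the reporting
  # table round to a 22 % air-saturation threshold
  expect_equal(intersect_lines(93.639, 0.049, -27.938, 5.6), 21.9, tolerance = 0.005)
  expect_equal(round(intersect_lines(93.639, 0.049, -27.938, 5.6)), 22)
  expect_equal(intersect_lines(0, 0, -10, 1), 10)
  expect_error(intersect_lines(1, 2, 5, 2), "parallel")
})

test_that("broken stick finds a constructed breakpoint exactly", {
  rows <- segmented_rows(n_fish = 2, flat = 95, knee = 25, slope = 5)
  fit <- broken_stick_search(rows)
  expect_equal(fit$split_do, 27.5)  # tie toward the higher-DO split
  expect_equal(fit$threshold, 25, tolerance = 1e-6)
  expect_lt(fit$rss_total, 1e-10)
})

test_that("search equals exhaustive enumeration on random datasets", {
  set.seed(7)
  for (rep in 1:12) {
    n_lv <- sample(6:12, 1)
    lv <- sort(sample(5:100, n_lv))
    knee <- lv[sample(3:(n_lv - 2), 1)]
    rows <- segmented_rows(n_fish = 6, levels = lv, knee = knee,
                           slope = runif(1, 1, 6), noise_sd = 6,
                           fish_sd = 4, seed = rep)
    fit <- broken_stick_search(rows)
    # independent plain-loop enumeration of every admissible split
    best <- Inf; best_mid <- NA
    for (i in 3:(n_lv - 3)) {
      mid <- (lv[i] + lv[i + 1]) / 2
      rss <- fit_random_intercept_lmm(rows[rows$do > mid, ])$rss +
        fit_random_intercept_lmm(rows[rows$do <= mid, ])$rss
      if (rss < best - 1e-9 || (rss <= best + 1e-9 && mid > best_mid)) {
        best <- rss; best_mid <- mid
      }
    }
    expect_equal(fit$split_do, best_mid)
    expect_equal(fit$rss_total, best, tolerance = 1e-8)
  }
  expect_error(broken_stick_search(segmented_rows(levels = c(10, 20, 30, 40))),
               "insufficient")
})

test_that("Nakagawa R2 agrees with a direct variance decomposition", {
  rows <- linear_rows(n_fish = 10, fish_sd = 5, noise_sd = 6, seed = 11)
  fit <- fit_random_intercept_lmm(rows)
  ref <- lme4::lmer(residence ~ do + (1 | fish_id), data = rows, REML = FALSE)
  vf <- var(model.matrix(ref) %*% lme4::fixef(ref))[1]
  vr <- as.numeric(lme4::VarCorr(ref)$fish_id[1])
  ve <- sigma(ref)^2
  r2 <- nakagawa_r2(fit)
  expect_equal(unname(r2["marginal"]), vf / (vf + vr + ve), tolerance = 1e-6)
  expect_equal(unname(r2["conditional"]), (vf + vr) / (vf + vr + ve),
               tolerance = 1e-6)
})

test_that("residence rescaling leaves the split alone and scales RSS", {
  rows <- segmented_rows(n_fish = 6, noise_sd = 5, fish_sd = 4, seed = 13)
  fit <- broken_stick_search(rows)
  rows2 <- dplyr::mutate(rows, residence = residence * 3)
  fit2 <- broken_stick_search(rows2)
  expect_equal(fit2$split_do, fit$split_do)
  expect_equal(fit2$rss_total, 9 * fit$rss_total, tolerance = 1e-4)
  expect_equal(fit2$threshold, fit$threshold, tolerance = 1e-4)
})

test_that("OLS mode reproduces the mixed-model threshold without fish effects", {
  rows <- segmented_rows(n_fish = 8, noise_sd = 4, fish_sd = 0, seed = 17)
  lmm <- broken_stick_search(rows, mode = "lmm")
  ols <- broken_stick_search(rows, mode = "ols")
  expect_equal(ols$split_do, lmm$split_do)
  expect_equal(ols$threshold, lmm$threshold, tolerance = 1e-6)
})

test_that("random-slope variant also returns a finite threshold", {
  rows <- segmented_rows(n_fish = 10, noise_sd = 5, fish_sd = 5, seed = 19)
  fit <- broken_stick_search(rows, random = "slope")
  expect_true(is.finite(fit$threshold))
})
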