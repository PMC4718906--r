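test_that("t score matches the pooled-variance reference computation", {
  a <- c(0.60, 0.62, 0.64); b <- c(0.70, 0.74, 0.78)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(t_score(a, b), abs(unname(ref$statistic)), tolerance = 1e-12)
  refw <- stats::t.test(a, b)
  expect_equal(t_score(a, b, welch = TRUE), abs(unname(refw$statistic)),
               tolerance = 1e-12)
  expect_equal(t_score(a, a), 0)
  expect_error(t_score(c(0, 0, 0), c(1, 1, 1)), "zero pooled variance")
  expect_error(t_score(0.5, c(1, 2)), "at least 2")
})

test_that("nNUF scan prefers the branch that was actually shifted", {
  jit <- c(0, 0.02, 0.04)
  neg <- lapply(jit, function(e)
    fixture_curve(thi = c(0.1, 0.2, 0.3, 0.5, 0.7),
                  nnuf = c(0.2, 0.6 + e, 1, 0.40 + e, 0.10)))
  pos <- lapply(jit, function(e)
    fixture_curve(thi = c(0.1, 0.2, 0.3, 0.5, 0.7),
                  nnuf = c(0.2, 0.6 + e, 1, 0.70 + e, 0.30)))
  sc <- scan_optimal_nnuf(neg, pos, nnuf_grid = c(0.25, 0.5))
  s <- sc$scan
  t_r <- s$t_score[s$side == "right"]
  t_l <- s$t_score[s$side == "left"]
  expect_true(all(t_r > t_l, na.rm = TRUE))
  expect_identical(sc$optimal_side, "right")
})

test_that("identical cohorts give zero t scores with a reported argmax", {
  curves <- list(
    fixture_curve(thi = c(0.1, 0.3, 0.5, 0.7), nnuf = c(0.2, 1, 0.5, 0.1)),
    fixture_curve(thi = c(0.1, 0.3, 0.5, 0.7), nnuf = c(0.1, 1, 0.6, 0.2)))
  sc <- scan_optimal_nnuf(curves, curves, nnuf_grid = c(0.25, 0.45))
  expect_true(all(abs(sc$scan$t_score) < 1e-12, na.rm = TRUE))
  expect_true(sc$optimal_side %in% c("left", "right"))
})

test_that("scan skips levels without crossings and is order-invariant", {
  shallow <- fixture_curve(thi = c(0.1, 0.3, 0.5, 0.7),
                           nnuf = c(0.60, 1, 0.80, 0.55))  # never below 0.5
  deep <- lapply(c(0, 0.01, 0.03), function(e)
    fixture_curve(thi = c(0.1, 0.3, 0.5, 0.7),
                  nnuf = c(0.2, 1, 0.5 + e, 0.1)))
  sc <- scan_optimal_nnuf(c(deep[1:2], list(shallow)), deep,
                          nnuf_grid = c(0.25, 0.7))
  s <- sc$scan
  expect_true(all(is.na(s$t_score[s$level == 0.25])))  # shallow lacks crossing
  expect_true(any(!is.na(s$t_score[s$level == 0.7])))

  sc2 <- scan_optimal_nnuf(c(list(shallow), deep[2:1]), deep,
                           nnuf_grid = c(0.25, 0.7))
  expect_equal(sc2$scan$t_score, s$t_score)
})

test_that("quadratic concentration fit recovers exact and noisy truths", {
  m <- seq(30, 120, length.out = 12)
  thi <- 0.8 - 0.004 * m + 1e-5 * m^2
  fit <- fit_concentration_model(m, thi)
  expect_equal(unname(coef(fit)), c(0.8, -0.004, 1e-5), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  fit_const <- fit_concentration_model(c(40, 60, 80), rep(0.62, 3))
  expect_equal(unname(coef(fit_const)), c(0.62, 0, 0), tolerance = 1e-10)

  set.seed(12)
  m2 <- runif(40, 30, 110)
  y2 <- 0.75 - 0.003 * m2 + 8e-6 * m2^2 + rnorm(40, 0, 0.01)
  fit2 <- fit_concentration_model(m2, y2)
  X <- cbind(1, m2, m2^2)                      # normal-equations oracle
  beta <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(unname(coef(fit2)), as.vector(beta), tolerance = 1e-8)
  r2 <- 1 - sum((y2 - X %*% beta)^2) / sum((y2 - mean(y2))^2)
  expect_equal(fit2$r_squared, r2, tolerance = 1e-10)

  expect_error(fit_concentration_model(c(40, 40, 60), c(0.6, 0.61, 0.62)),
               "rank-deficient")
})

test_that("normalization is the identity at the reference concentration", {
  model <- structure(list(coefficients = c(c0 = 0.70, c1 = -0.001, c2 = 0),
                          m_ref = 60, r_squared = 1, n_fit = 10,
                          m_range = c(30, 120)),
                     class = "conc_model")
  expect_equal(normalize_thi(model, 0.64, 60), 0.64)
  expect_equal(normalize_thi(model, 0.64, 100), 0.68)  # 0.64 - 0.60 + 0.64
  # order preserving in thi at fixed m
  expect_lt(normalize_thi(model, 0.61, 90), normalize_thi(model, 0.65, 90))
  expect_warning(normalize_thi(model, 0.6, 300), "extrapolating")
})

test_that("fitting then normalizing decorrelates nThI from concentration", {
  set.seed(33)
  m <- runif(40, 30, 110)
  thi <- 0.78 - 0.0035 * m + 9e-6 * m^2 + rnorm(40, 0, 0.015)
  fit <- fit_concentration_model(m, thi)
  nthi <- normalize_thi(fit, thi, m)
  expect_lt(abs(cor(m, nthi)), 0.1)
  # the planted decreasing trend was present before correction
  expect_lt(cor(m, thi), -0.5)
})

test_that("model JSON and scan CSV persistence round trip", {
  m <- seq(35, 100, length.out = 8)
  fit <- fit_concentration_model(m, 0.8 - 0.002 * m + 5e-6 * m^2)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  expect_equal(back$m_ref, fit$m_ref)
  expect_equal(back$r_squared, fit$r_squared, tolerance = 1e-12)
  expect_equal(predict(back, 75), predict(fit, 75), tolerance = 1e-12)

  curves <- lapply(c(0, 0.02, 0.01, 0.03), function(e)
    fixture_curve(thi = c(0.1, 0.3, 0.5, 0.7),
                  nnuf = c(0.2, 1, 0.5 + e, 0.1)))
  sc <- scan_optimal_nnuf(curves[1:2], curves[3:4], nnuf_grid = c(0.25))
  fcsv <- withr::local_tempfile(fileext = ".csv")
  write_scan(sc, fcsv)
  tab <- read.csv(fcsv)
  expect_identical(names(tab), c("level", "side", "t_score"))
})
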