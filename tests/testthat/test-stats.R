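test_that("OLS recovers exact and noisy linear relations", {
  d <- data.frame(x = 1:20)
  d$y <- 2 * d$x
  fit <- suppressWarnings(ols_fit(d, "y", "x")) # exact fit: summary warns
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "x"], 2, tolerance = 1e-10)
  g <- suppressWarnings(glance(fit)) # exact fit: summary warns
  expect_equal(g$adj_r_squared, 100, tolerance = 1e-8)

  # independent noise: adjusted R^2 near zero
  set.seed(101)
  d2 <- data.frame(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(glance(ols_fit(d2, "y", "x"))$adj_r_squared), 1)
})

test_that("OLS agrees with a brute-force normal-equations solve", {
  set.seed(7)
  d <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  d$y <- 1.5 * d$a - 2 * d$b + 0.3 * d$c + rnorm(50, sd = 0.1)
  fit <- ols_fit(d, "y", c("a", "b", "c"))
  X <- cbind(1, as.matrix(d[, c("a", "b", "c")]))
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(tidy(fit)$estimate), as.vector(beta), tolerance = 1e-8)
})

test_that("OLS coefficient confidence intervals have nominal coverage", {
  set.seed(2024)
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    d <- data.frame(x = rnorm(40))
    d$y <- 3 + 1.2 * d$x + rnorm(40)
    fit <- ols_fit(d, "y", "x")$fit
    ci <- stats::confint(fit, "x", level = 0.95)
    hits <- hits + (ci[1] <= 1.2 && 1.2 <= ci[2])
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("OLS validates its inputs", {
  d <- data.frame(x = rnorm(10), z = 1, y = rnorm(10))
  expect_error(ols_fit(d, "y", "z"), class = "atheromech_domain_error")
  d$x2 <- d$x
  expect_error(ols_fit(d, "y", c("x", "x2")), class = "atheromech_singular_error")
  expect_error(ols_fit(d[1:2, ], "y", "x"), class = "atheromech_domain_error")
})

test_that("adjusted R^2 formula and boundaries", {
  expect_equal(adjusted_R2(1, 50, 3), 100)
  expect_equal(adjusted_R2(0.9, 100, 2), (1 - 0.1 * 99 / 97) * 100,
               tolerance = 1e-12)
  expect_equal(round(adjusted_R2(0.9, 100, 2), 2), 89.79)
  expect_error(adjusted_R2(0.5, 4, 3), class = "atheromech_domain_error")
})

test_that("VIF: orthogonal, correlated, and collinear designs", {
  # exactly orthogonal predictors
  n <- 64
  X <- data.frame(a = rep(c(-1, 1), each = n / 2),
                  b = rep(c(-1, 1), times = n / 2))
  expect_equal(unname(vif(X)), c(1, 1), tolerance = 1e-10)

  # correlation rho = 0.6 -> VIF = 1/(1 - 0.36) = 1.5625 exactly
  set.seed(9)
  z <- rnorm(4000)
  a <- scale(z)[, 1]
  e <- scale(stats::residuals(lm(rnorm(4000) ~ a)))[, 1]
  b <- 0.6 * a + sqrt(1 - 0.36) * e
  v <- vif(data.frame(a = a, b = b))
  expect_equal(unname(v), rep(1 / (1 - 0.36), 2), tolerance = 1e-6)

  dup <- data.frame(a = rnorm(30))
  dup$b <- dup$a
  expect_true(all(is.infinite(suppressWarnings(vif(dup)))))
})

test_that("VIF never drops below one and matches the car implementation", {
  skip_if_not_installed("car")
  set.seed(12)
  d <- data.frame(a = rnorm(100), b = rnorm(100), cc = rnorm(100))
  d$y <- d$a + rnorm(100)
  v_ours <- vif(d[, c("a", "b", "cc")])
  expect_true(all(v_ours >= 1 - 1e-12))
  v_car <- car::vif(lm(y ~ a + b + cc, data = d))
  expect_equal(unname(v_ours), unname(v_car), tolerance = 1e-8)
})

test_that("stepwise selection recovers a single true predictor among noise", {
  set.seed(31)
  n_rep <- 100
  exact <- 0
  for (r in seq_len(n_rep)) {
    d <- as.data.frame(matrix(rnorm(60 * 6), 60))
    names(d) <- paste0("x", 1:6)
    d$y <- 2 * d$x3 + rnorm(60, sd = 0.5)
    sel <- stepwise_select(d, "y", paste0("x", 1:6))
    exact <- exact + identical(sel$selected, "x3")
  }
  expect_gte(exact / n_rep, 0.95)
})

test_that("stepwise selection returns intercept-only under the null", {
  set.seed(77)
  n_rep <- 100
  nulls <- 0
  for (r in seq_len(n_rep)) {
    d <- as.data.frame(matrix(rnorm(50 * 5), 50))
    names(d) <- paste0("x", 1:5)
    d$y <- rnorm(50)
    sel <- stepwise_select(d, "y", paste0("x", 1:5))
    nulls <- nulls + (length(sel$selected) == 0)
  }
  expect_gte(nulls / n_rep, 0.90)
})

test_that("the VIF audit keeps exactly one of a collinear pair", {
  # a near-duplicate never survives next to the original
  set.seed(5)
  d <- data.frame(x = rnorm(80))
  d$x_dup <- d$x + rnorm(80, sd = 1e-8)
  d$y <- 3 * d$x + rnorm(80, sd = 0.3)
  sel <- stepwise_select(d, "y", c("x", "x_dup"))
  expect_length(sel$selected, 1)
  expect_true(sel$selected %in% c("x", "x_dup"))

  # both members individually significant but heavily collinear:
  # the audit drops exactly one and logs the step
  set.seed(6)
  n <- 3000
  z <- rnorm(n)
  x1 <- z + rnorm(n, sd = 0.15)
  x2 <- z + rnorm(n, sd = 0.15)
  d2 <- data.frame(x1 = x1, x2 = x2)
  d2$y <- x1 + x2 + rnorm(n, sd = 0.5)
  expect_gt(max(vif(d2[, c("x1", "x2")])), 10)
  sel2 <- stepwise_select(d2, "y", c("x1", "x2"))
  expect_length(sel2$selected, 1)
  expect_true(any(sel2$log$action == "vif_drop"))
})

test_that("stepwise output is invariant to row order", {
  set.seed(14)
  d <- as.data.frame(matrix(rnorm(70 * 4), 70))
  names(d) <- paste0("x", 1:4)
  d$y <- d$x1 - 2 * d$x2 + rnorm(70, sd = 0.4)
  s1 <- stepwise_select(d, "y", paste0("x", 1:4))
  s2 <- stepwise_select(d[rev(seq_len(nrow(d))), ], "y", paste0("x", 1:4))
  expect_setequal(s1$selected, s2$selected)
})

test_that("network input selection pins the four inputs and logs the audit", {
  ds <- toy_dataset(n = 200)
  sel <- select_ann_inputs(ds)
  expect_equal(sel$inputs, c("eps_core_sq", "eps_cap_sq", "eps_theta_sq", "SR"))
  expect_s3_class(sel$selection$log, "tbl_df")
  sel2 <- select_ann_inputs(ds)
  expect_identical(sel$selection$selected, sel2$selection$selected)
})
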