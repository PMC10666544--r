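test_that("SCM weights hit the exact-match corner of the simplex", {
  Y0 <- rbind(a = c(10, 12, 9, 11), b = c(20, 18, 22, 21),
              c = c(30, 29, 31, 33))
  g <- fit_scm_weights(Y0, Y0["b", ])
  expect_lt(abs(g[["b"]] - 1), 1e-6)
  expect_equal(sum(g), 1, tolerance = 1e-10)
  expect_true(all(g >= 0))
})

test_that("SCM weights are uniform when the target is the control mean", {
  set.seed(4)
  Y0 <- matrix(rnorm(12, 20, 5), 3, 4,
               dimnames = list(c("a", "b", "c"), NULL))
  g <- fit_scm_weights(Y0, colMeans(Y0))
  expect_equal(unname(g), rep(1 / 3, 3), tolerance = 1e-6)
})

test_that("SCM weights match the exhaustive simplex grid oracle", {
  set.seed(8)
  for (rep in 1:3) {
    Y0 <- matrix(sample(1:9, 12, replace = TRUE), 3, 4,
                 dimnames = list(c("a", "b", "c"), NULL))
    y1 <- as.numeric(0.2 * Y0[1, ] + 0.5 * Y0[2, ] + 0.3 * Y0[3, ] +
                       rnorm(4, 0, 0.5))
    g <- fit_scm_weights(Y0, y1)
    gg <- scm_grid_oracle(Y0, y1, step = 0.001)
    expect_lt(max(abs(g - gg)), 0.002)
  }
})

test_that("simplex feasibility holds across random problems", {
  set.seed(77)
  for (rep in 1:20) {
    m <- sample(2:12, 1); k <- sample(2:20, 1)
    Y0 <- matrix(rnorm(m * k, 50, 10), m, k)
    y1 <- rnorm(k, 50, 10)
    g <- fit_scm_weights(Y0, y1)
    expect_true(all(g >= 0))
    expect_lt(abs(sum(g) - 1), 1e-8)
    # optimality sanity: no worse than uniform weights
    sse <- sum((y1 - as.numeric(t(Y0) %*% g))^2)
    sse_u <- sum((y1 - colMeans(Y0))^2)
    expect_lte(sse, sse_u + 1e-6)
  }
})

test_that("ridge outcome model equals the closed form at fixed lambda", {
  set.seed(15)
  for (rep in 1:3) {
    Y0_pre <- matrix(rnorm(5 * 8, 40, 8), 5, 8)
    Y0_post <- matrix(rnorm(5 * 6, 40, 8), 5, 6)
    lam <- runif(1, 0.5, 20)
    ro <- fit_ridge_outcome(Y0_pre, Y0_post, lambda = lam)
    expect_lt(max(abs(ro$eta - ridge_oracle(Y0_pre, Y0_post, lam))), 1e-8)
  }
})

test_that("ridge limits behave: huge lambda kills eta, self-consistent CV is exact", {
  set.seed(16)
  Y0_pre <- matrix(rnorm(10 * 8, 40, 8), 10, 8)
  ro <- fit_ridge_outcome(Y0_pre, Y0_pre[, 8, drop = FALSE], lambda = 1e12)
  expect_lt(max(abs(ro$eta)), 1e-6)
  # replicated last pre column as the post outcome, lambda = 0:
  # regression reproduces it within numerical precision
  ro0 <- fit_ridge_outcome(Y0_pre, Y0_pre[, 8, drop = FALSE], lambda = 0)
  pred <- sweep(Y0_pre, 2, colMeans(Y0_pre)) %*% ro0$eta
  resid <- Y0_pre[, 8] - mean(Y0_pre[, 8])
  expect_lt(max(abs(pred - resid)), 1e-6)
})

test_that("ASCM reduces to SCM with exact pre-fit or zero correction", {
  set.seed(23)
  Y0_pre <- matrix(rnorm(4 * 10, 50, 5), 4, 10)
  Y0_post <- matrix(rnorm(4 * 5, 50, 5), 4, 5)
  gamma <- c(0.4, 0.3, 0.2, 0.1)
  y1_exact <- as.numeric(t(Y0_pre) %*% gamma)
  eta <- matrix(rnorm(10 * 5), 10, 5)
  f1 <- ascm_estimate(Y0_pre, Y0_post, y1_exact, gamma, eta)
  expect_lt(max(abs(f1$counterfactual - f1$scm_counterfactual)), 1e-6)
  y1_rough <- y1_exact + rnorm(10)
  f2 <- ascm_estimate(Y0_pre, Y0_post, y1_rough, gamma,
                      matrix(0, 10, 5))
  expect_equal(f2$counterfactual, f2$scm_counterfactual)
})

test_that("ASCM matches hand arithmetic on a 3-control fixture", {
  Y0_pre <- rbind(c(1, 2, 3, 4), c(2, 2, 2, 2), c(4, 3, 2, 1))
  Y0_post <- rbind(c(5, 6), c(3, 3), c(1, 0))
  y1_pre <- c(2.5, 2.5, 2.5, 2.4)
  gamma <- c(0.25, 0.5, 0.25)
  eta <- matrix(c(0.1, 0.2, 0.3, 0.4,
                  0.0, 0.1, 0.0, 0.1), 4, 2)
  imb <- y1_pre - as.numeric(t(Y0_pre) %*% gamma)  # c(-0.25,0.25,0.25,0.15)
  by_hand <- as.numeric(t(Y0_post) %*% gamma) + as.numeric(imb %*% eta)
  f <- ascm_estimate(Y0_pre, Y0_post, y1_pre, gamma, eta)
  expect_equal(f$counterfactual, by_hand)
  expect_equal(f$pre_rmse, sqrt(mean(imb^2)))
  u <- y1_pre - colMeans(Y0_pre)
  expect_equal(f$pre_rmse_uniform, sqrt(mean(u^2)))
})

test_that("infinite-penalty ASCM converges to plain SCM", {
  set.seed(29)
  pre <- 1:12; post <- 13:18
  Y0 <- matrix(rnorm(6 * 18, 60, 10), 6, 18)
  y1 <- colMeans(Y0) + rnorm(18, 0, 2)
  f_inf <- ascm(y1, Y0, pre, post, lambda = 1e14)
  expect_lt(max(abs(f_inf$counterfactual - f_inf$scm_counterfactual)), 1e-6)
})

test_that("adding a constant to every series shifts the counterfactual by it", {
  set.seed(33)
  pre <- 1:10; post <- 11:14
  Y0 <- matrix(rnorm(5 * 14, 50, 8), 5, 14)
  y1 <- 0.5 * Y0[1, ] + 0.5 * Y0[3, ] + rnorm(14, 0, 1)
  f0 <- ascm(y1, Y0, pre, post, lambda = 3)
  f1 <- ascm(y1 + 100, Y0 + 100, pre, post, lambda = 3)
  expect_equal(f1$counterfactual, f0$counterfactual + 100, tolerance = 1e-6)
  eff0 <- y1[post] - f0$counterfactual
  eff1 <- (y1 + 100)[post] - f1$counterfactual
  expect_equal(eff0, eff1, tolerance = 1e-6)
})

test_that("ASCM pre-fit never loses to uniform weights", {
  for (s in 1:10) {
    d <- sim_weekly_panel(n_controls = 10, seed = 200 + s)
    f <- ascm(d$y1, d$Y0, d$pre, d$post)
    expect_lte(f$pre_rmse, f$pre_rmse_uniform + 1e-10)
  }
})

test_that("Jackknife+ degenerates to a point with identical controls", {
  pre <- 1:8; post <- 9:12
  base <- c(10, 11, 12, 11, 10, 9, 10, 11, 12, 13, 12, 11)
  Y0 <- matrix(rep(base, each = 6), 6, 12)
  jk <- jackknife_plus(base, Y0, pre, post)
  expect_lt(max(jk$ci_upper - jk$ci_lower), 1e-6)
  expect_equal(jk$ci_lower, base[post], tolerance = 1e-6)
})

test_that("Jackknife+ refuses fewer than five controls and ignores null controls", {
  d <- sim_weekly_panel(n_controls = 8, seed = 301)
  expect_error(jackknife_plus(d$y1, d$Y0[1:4, ], d$pre, d$post), ">= 5")
  # appending a control identical to an existing one (zero marginal
  # influence) barely moves the band endpoints
  jk1 <- jackknife_plus(d$y1, d$Y0, d$pre, d$post, lambda = 5)
  Y0x <- rbind(d$Y0, dup = d$Y0[1, ])
  jk2 <- jackknife_plus(d$y1, Y0x, d$pre, d$post, lambda = 5)
  expect_lt(mean(abs(jk2$ci_upper - jk1$ci_upper)), 1.0)
  expect_lt(mean(abs(jk2$ci_lower - jk1$ci_lower)), 1.0)
})

test_that("placebo scan ranks an injected effect first", {
  d <- sim_weekly_panel(n_controls = 20, effect = 10, noise_sd = 1.5,
                        seed = 401)
  ps <- placebo_scan(d$y1, d$Y0, d$pre, d$post)
  expect_equal(ps$pseudo_p, 1 / 21)
  expect_gt(ps$treated_effect, 8)
  expect_error(placebo_scan(d$y1, d$Y0[1:3, ], d$pre, d$post), ">= 5")
})

test_that("donor matrix preparation drops gappy controls and interpolates small gaps", {
  Y0 <- matrix(rnorm(4 * 20, 50, 5), 4, 20,
               dimnames = list(paste0("c", 1:4), NULL))
  Y0[1, 5:9] <- NA                     # 25% missing -> dropped
  Y0[2, 7:8] <- NA                     # 2-week gap -> interpolated
  prep <- prepare_donor_matrix(Y0)
  expect_equal(prep$dropped, "c1")
  expect_false(anyNA(prep$Y0))
  expect_equal(prep$Y0["c2", 7],
               Y0["c2", 6] + (Y0["c2", 9] - Y0["c2", 6]) / 3,
               tolerance = 1e-10)
  Y0[3, 11:14] <- NA                   # gap of 4 > limit but < 25%... error
  expect_error(prepare_donor_matrix(Y0, max_missing_frac = 0.3), "gap longer")
})
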