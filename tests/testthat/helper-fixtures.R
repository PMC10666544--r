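# Shared fixtures, built once per test run.

# Small synthetic panel reused by several files (6 controls, 3 treated).
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- panel_config(n_control_cities = 6, n_treated_cities = 3,
                          n_alternative_cities = 1, seed = 42)
      cache <<- generate_panel(cfg)
    }
    cache
  }
})

# Weekly-resolution synthetic control panel: controls share a seasonal mean
# with unit-level offsets; the treated unit's level sits inside the control
# convex hull. Used for placebo calibration and Jackknife+ coverage studies
# at scaled-down size.
sim_weekly_panel <- function(n_controls = 20, n_pre = 26, n_post = 24,
                             effect = 0, noise_sd = 2, unit_sd = 3,
                             seed = 1) {
  set.seed(seed)
  t <- seq_len(n_pre + n_post)
  common <- 50 + 8 * sin(2 * pi * t / 52) - 0.05 * t
  u <- rnorm(n_controls, 0, unit_sd)
  Y0 <- t(vapply(u, function(ui) common + ui + rnorm(length(t), 0, noise_sd),
                 numeric(length(t))))
  rownames(Y0) <- sprintf("C%02d", seq_len(n_controls))
  w <- rexp(n_controls); w <- w / sum(w)
  y1_cf <- common + sum(w * u) + rnorm(length(t), 0, noise_sd)
  y1 <- y1_cf
  post <- (n_pre + 1):(n_pre + n_post)
  y1[post] <- y1[post] + effect
  list(y1 = y1, y1_cf = y1_cf, Y0 = Y0, pre = seq_len(n_pre), post = post)
}

# Exhaustive simplex grid search oracle for 3-control SCM weights.
scm_grid_oracle <- function(Y0, y1, step = 0.001) {
  stopifnot(nrow(Y0) == 3)
  g1 <- seq(0, 1, by = step)
  grid <- expand.grid(a = g1, b = g1)
  grid <- grid[grid$a + grid$b <= 1 + 1e-12, ]
  G <- cbind(grid$a, grid$b, 1 - grid$a - grid$b)
  R <- G %*% Y0
  sse <- rowSums((R - matrix(y1, nrow(R), length(y1), byrow = TRUE))^2)
  G[which.min(sse), ]
}

# Closed-form ridge oracle (independent of the package's linear algebra path).
ridge_oracle <- function(Y0_pre, Y0_post, lambda) {
  X <- sweep(Y0_pre, 2, colMeans(Y0_pre))
  MASS_solve <- qr.solve(crossprod(X) + diag(lambda, ncol(X)),
                         crossprod(X, Y0_post))
  MASS_solve
}
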