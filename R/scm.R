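#' Synthetic control weights on the simplex
#'
#' Solves `min || y1_pre - t(Y0_pre) %*% gamma ||^2 + 1e-8 ||gamma||^2`
#' subject to `gamma >= 0`, `sum(gamma) = 1` (the tiny ridge term breaks ties
#' so the solution is unique). A primal active-set method on the simplex with
#' a KKT optimality check; the solver is deterministic.
#'
#' @param Y0_pre Matrix of control outcomes, controls in rows, pre-treatment
#'   weeks in columns. No missing entries (see [prepare_donor_matrix()]).
#' @param y1_pre Treated unit's pre-treatment outcomes (length `ncol(Y0_pre)`).
#' @param kkt_tol Relative KKT tolerance (default 1e-7).
#' @return Named numeric vector of weights summing to 1.
#' @export
#' @examples
#' Y0 <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
#' fit_scm_weights(Y0, c(2, 2, 2)) # balanced blend
fit_scm_weights <- function(Y0_pre, y1_pre, kkt_tol = 1e-7) {
  Y0_pre <- as.matrix(Y0_pre)
  m <- nrow(Y0_pre)
  if (m < 2) stop("need at least 2 control units")
  if (ncol(Y0_pre) < 2) stop("need at least 2 pre-treatment periods")
  if (length(y1_pre) != ncol(Y0_pre)) stop("y1_pre length mismatch")
  if (anyNA(Y0_pre) || anyNA(y1_pre)) stop("missing entries not allowed")
  # precondition: with sum(gamma) = 1 the objective is invariant to removing
  # a common column offset, which removes the dominant shared component and
  # conditions the normal matrix; then normalize to unit scale
  ctr <- colMeans(Y0_pre)
  Yc <- sweep(Y0_pre, 2, ctr)
  yc <- y1_pre - ctr
  ridge <- 1e-8
  H0 <- Yc %*% t(Yc) + diag(ridge, m)
  scale_h <- max(mean(diag(H0)), ridge)
  H <- H0 / scale_h
  f <- -as.numeric(Yc %*% yc) / scale_h

  solve_eq <- function(free) {
    k <- sum(free)
    K <- rbind(cbind(H[free, free, drop = FALSE], rep(1, k)),
               c(rep(1, k), 0))
    rhs <- c(-f[free], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) {
      solve(K + diag(1e-10, k + 1), rhs)
    })
    list(g = sol[seq_len(k)], nu = sol[k + 1])
  }
  tol_kkt <- 10 * kkt_tol
  free <- rep(TRUE, m)
  barred <- rep(FALSE, m)   # anti-cycling: vars that re-hit zero on release
  gamma <- rep(1 / m, m)
  last_released <- 0L
  for (iter in seq_len(100L * m)) {
    sol <- solve_eq(free)
    cand <- numeric(m)
    cand[free] <- sol$g
    if (min(cand[free]) >= -1e-11) {
      gamma <- cand
      gamma[gamma < 0] <- 0
      gamma <- gamma / sum(gamma)
      # multipliers of the active bound constraints, from the exact solve
      grad <- as.numeric(H %*% cand) + f
      mu <- grad - sol$nu
      bound <- which(!free & !barred)
      if (length(bound) == 0 || min(mu[bound]) >= -tol_kkt / 2) break
      last_released <- bound[which.min(mu[bound])]
      free[last_released] <- TRUE
    } else {
      # move toward the candidate until the first free coordinate hits zero
      d <- cand - gamma
      idx <- which(free & d < -1e-14)
      alphas <- -gamma[idx] / d[idx]
      alpha <- max(0, min(1, alphas))
      gamma <- pmax(gamma + alpha * d, 0)
      hit <- idx[which.min(alphas)]
      if (alpha <= 1e-13 && hit == last_released) barred[hit] <- TRUE
      free[hit] <- FALSE
      gamma[hit] <- 0
      s <- sum(gamma)
      if (s <= 0 || sum(free) == 0) {
        stop("active-set solver degenerated (empty free set)")
      }
      gamma <- gamma / s
    }
  }
  gamma[gamma < 0] <- 0
  gamma <- gamma / sum(gamma)
  # final KKT verification on the normalized problem: the projected gradient
  # must vanish on the support, and bound multipliers must be nonnegative
  kkt_stat <- function(g) {
    grad <- as.numeric(H %*% g) + f
    nu <- mean(grad[g > 1e-10])
    max(ifelse(g > 1e-10, abs(grad - nu), pmax(0, -(grad - nu))))
  }
  if (kkt_stat(gamma) > tol_kkt) {
    # deterministic pairwise Frank-Wolfe polish: move mass from the support
    # coordinate with the largest gradient to the coordinate with the
    # smallest, with the exact line-search step. Handles ill-conditioned
    # (near-degenerate) donor ensembles where the equality solves lose
    # precision.
    g <- gamma
    Hg <- as.numeric(H %*% g)
    for (it in seq_len(50000L)) {
      grad <- Hg + f
      s <- which.min(grad)
      sup <- which(g > 1e-12)
      a <- sup[which.max(grad[sup])]
      gap <- grad[a] - grad[s]
      if (gap <= kkt_tol) break
      d_Hd <- H[s, s] + H[a, a] - 2 * H[s, a]
      t_step <- if (d_Hd > 0) min(g[a], gap / d_Hd) else g[a]
      if (t_step <= 0) break
      g[s] <- g[s] + t_step
      g[a] <- g[a] - t_step
      Hg <- Hg + t_step * (H[, s] - H[, a])
    }
    if (kkt_stat(g) <= kkt_stat(gamma)) gamma <- g
  }
  if (kkt_stat(gamma) > tol_kkt) {
    stop(sprintf(
      "SCM weight solver failed KKT check (normalized violation %.3g)",
      kkt_stat(gamma)))
  }
  names(gamma) <- rownames(Y0_pre)
  gamma
}

#' Ridge outcome model over control units
#'
#' For each post-treatment week `s`, ridge regression of control post
#' outcomes on control pre outcomes centered by control means:
#' `eta_s = solve(t(X) %*% X + lambda I, t(X) %*% y_s)` with
#' `X = sweep(Y0_pre, 2, colMeans(Y0_pre))`. The penalty is chosen from a
#' data-scaled grid by leave-one-control-out cross-validation of the
#' ridge-augmented prediction of each held-out control's post outcomes.
#'
#' @param Y0_pre Controls x pre-weeks matrix (>= 3 controls).
#' @param Y0_post Controls x post-weeks matrix.
#' @param lambda_grid Optional penalty grid; default 10 log-spaced values
#'   spanning `1e-3` to `1e3` times the mean diagonal of `t(X) %*% X`.
#' @param lambda Optional fixed penalty (skips cross-validation).
#' @return list of class `ridge_outcome`: `eta` (pre-weeks x post-weeks
#'   coefficient matrix), `lambda`, `lambda_grid`, `cv_error` (per grid
#'   value; `NA` if fixed), `x_center` (control means of pre weeks).
#' @export
fit_ridge_outcome <- function(Y0_pre, Y0_post, lambda_grid = NULL,
                              lambda = NULL) {
  Y0_pre <- as.matrix(Y0_pre); Y0_post <- as.matrix(Y0_post)
  m <- nrow(Y0_pre)
  if (m < 3) stop("ridge cross-validation needs >= 3 control units")
  if (nrow(Y0_post) != m) stop("Y0_pre / Y0_post row mismatch")
  ctr <- colMeans(Y0_pre)
  X <- sweep(Y0_pre, 2, ctr)
  G <- crossprod(X)
  scale_g <- mean(diag(G))
  if (is.null(lambda_grid)) {
    # data-scaled grid; fixed fallback when the design is degenerate
    # (identical controls give a zero centered matrix)
    lambda_grid <- if (scale_g > 0) {
      scale_g * 10^seq(-3, 3, length.out = 10)
    } else 10^seq(-3, 3, length.out = 10)
  }
  ridge_eta <- function(Xm, Ym, lam) {
    p <- ncol(Xm)
    A <- crossprod(Xm) + diag(lam, p)
    sol <- tryCatch(solve(A, crossprod(Xm, Ym)), error = function(e) NULL)
    if (is.null(sol)) {
      if (lam <= 0) {
        warning("singular ridge system at lambda = 0; using smallest positive grid value")
        lam2 <- min(lambda_grid[lambda_grid > 0])
        sol <- solve(crossprod(Xm) + diag(lam2, p), crossprod(Xm, Ym))
      } else stop("singular ridge system")
    }
    sol
  }
  cv_error <- rep(NA_real_, length(lambda_grid))
  if (is.null(lambda)) {
    # leave-one-control-out: held-out control becomes the pseudo-treated unit
    loo <- vector("list", m)
    for (i in seq_len(m)) {
      g_i <- fit_scm_weights(Y0_pre[-i, , drop = FALSE], Y0_pre[i, ])
      loo[[i]] <- list(
        gamma = g_i,
        imb = Y0_pre[i, ] - as.numeric(t(Y0_pre[-i, , drop = FALSE]) %*% g_i),
        scm_post = as.numeric(t(Y0_post[-i, , drop = FALSE]) %*% g_i))
    }
    for (k in seq_along(lambda_grid)) {
      err <- 0
      for (i in seq_len(m)) {
        Xi <- sweep(Y0_pre[-i, , drop = FALSE],
                    2, colMeans(Y0_pre[-i, , drop = FALSE]))
        eta_i <- ridge_eta(Xi, Y0_post[-i, , drop = FALSE], lambda_grid[k])
        pred <- loo[[i]]$scm_post + as.numeric(loo[[i]]$imb %*% eta_i)
        err <- err + mean((Y0_post[i, ] - pred)^2)
      }
      cv_error[k] <- err / m
    }
    lambda <- lambda_grid[which.min(cv_error)]
  }
  eta <- ridge_eta(X, Y0_post, lambda)
  structure(list(eta = eta, lambda = lambda, lambda_grid = lambda_grid,
                 cv_error = cv_error, x_center = ctr),
            class = "ridge_outcome")
}

#' Ridge-augmented synthetic control estimate
#'
#' Combines simplex weights and the ridge outcome model:
#' `counterfactual(s) = gamma' Y0_post[, s] + (y1_pre - Y0_pre' gamma)' eta_s`,
#' i.e. the SCM weighted average directly corrected by the outcome model
#' applied to the residual pre-treatment imbalance. With an exact pre fit or
#' `eta = 0` the estimate reduces to plain SCM.
#'
#' @param Y0_pre,Y0_post Control matrices (controls x weeks).
#' @param y1_pre Treated pre-treatment outcomes.
#' @param gamma Simplex weights from [fit_scm_weights()].
#' @param eta Coefficient matrix (pre-weeks x post-weeks) from
#'   [fit_ridge_outcome()], or `NULL`/0 for plain SCM.
#' @param lambda Ridge penalty used (stored in the fit).
#' @return Object of class `ascm_fit`: `gamma`, `lambda`, `eta`,
#'   `counterfactual` (post weeks), `scm_counterfactual`,
#'   `counterfactual_pre` (SCM fit on pre weeks), `pre_rmse`,
#'   `pre_rmse_uniform`, `imbalance`.
#' @export
ascm_estimate <- function(Y0_pre, Y0_post, y1_pre, gamma, eta = NULL,
                          lambda = NA_real_) {
  Y0_pre <- as.matrix(Y0_pre); Y0_post <- as.matrix(Y0_post)
  m <- nrow(Y0_pre)
  stopifnot(length(gamma) == m, nrow(Y0_post) == m,
            length(y1_pre) == ncol(Y0_pre))
  if (any(gamma < -1e-8) || abs(sum(gamma) - 1) > 1e-8) {
    stop("gamma must lie on the unit simplex")
  }
  fit_pre <- as.numeric(t(Y0_pre) %*% gamma)
  imb <- y1_pre - fit_pre
  scm_post <- as.numeric(t(Y0_post) %*% gamma)
  corr <- if (is.null(eta)) rep(0, ncol(Y0_post)) else {
    eta <- as.matrix(eta)
    stopifnot(nrow(eta) == ncol(Y0_pre), ncol(eta) == ncol(Y0_post))
    as.numeric(imb %*% eta)
  }
  unif <- rep(1 / m, m)
  pre_rmse <- sqrt(mean(imb^2))
  pre_rmse_uniform <- sqrt(mean((y1_pre - as.numeric(t(Y0_pre) %*% unif))^2))
  structure(list(gamma = gamma, lambda = lambda, eta = eta,
                 counterfactual = scm_post + corr,
                 scm_counterfactual = scm_post,
                 counterfactual_pre = fit_pre,
                 pre_rmse = pre_rmse,
                 pre_rmse_uniform = pre_rmse_uniform,
                 imbalance = imb,
                 y1_pre = y1_pre),
            class = "ascm_fit")
}

#' @export
print.ascm_fit <- function(x, ...) {
  cat("ridge-augmented synthetic control fit\n")
  cat(sprintf("  %d controls, %d pre weeks, %d post weeks\n",
              length(x$gamma), length(x$y1_pre), length(x$counterfactual)))
  cat(sprintf("  pre RMSE %.4g (uniform weights %.4g), lambda %.4g\n",
              x$pre_rmse, x$pre_rmse_uniform, x$lambda))
  nz <- sort(x$gamma[x$gamma > 0.01], decreasing = TRUE)
  if (length(nz)) {
    cat("  weights > 0.01:",
        paste(sprintf("%s=%.2f", names(nz), nz), collapse = ", "), "\n")
  }
  if (!is.null(x$ci_lower)) cat("  Jackknife+ 95% bands attached\n")
  invisible(x)
}

#' Fit the full ridge ASCM for one treated unit
#'
#' Convenience wrapper: simplex weights on the pre period, cross-validated
#' ridge outcome model, augmented counterfactual, and (optionally) Jackknife+
#' bands.
#'
#' @param y1 Treated series over pre + post weeks.
#' @param Y0 Control matrix (controls x weeks) over the same weeks.
#' @param pre_idx,post_idx Column indices of pre and post weeks.
#' @param lambda_grid Optional ridge grid (see [fit_ridge_outcome()]).
#' @param lambda Optional fixed penalty.
#' @param jackknife Attach Jackknife+ 95% bands (default `FALSE`).
#' @return An `ascm_fit` (with `ci_lower`/`ci_upper` if requested).
#' @export
ascm <- function(y1, Y0, pre_idx, post_idx, lambda_grid = NULL,
                 lambda = NULL, jackknife = FALSE) {
  Y0 <- as.matrix(Y0)
  stopifnot(length(y1) == ncol(Y0))
  Y0_pre <- Y0[, pre_idx, drop = FALSE]
  Y0_post <- Y0[, post_idx, drop = FALSE]
  y1_pre <- y1[pre_idx]
  gamma <- fit_scm_weights(Y0_pre, y1_pre)
  ro <- fit_ridge_outcome(Y0_pre, Y0_post, lambda_grid = lambda_grid,
                          lambda = lambda)
  fit <- ascm_estimate(Y0_pre, Y0_post, y1_pre, gamma, ro$eta,
                       lambda = ro$lambda)
  fit$y1_post <- y1[post_idx]
  if (jackknife) {
    jk <- jackknife_plus(y1, Y0, pre_idx, post_idx, lambda = ro$lambda)
    fit$ci_lower <- jk$ci_lower
    fit$ci_upper <- jk$ci_upper
  }
  fit
}

#' Jackknife+ pointwise prediction bands for the ASCM counterfactual
#'
#' For each control `i`, the ASCM is refitted without `i`, giving a
#' counterfactual `yhat_minus_i(s)` and a pre-period residual scale `R_i`.
#' `R_i` is a conformal quantile of the leave-`i`-out fit's cross-validated
#' pre residuals: each pre week is predicted from weights refitted on the
#' remaining pre weeks (out-of-sample residuals; the in-sample pre RMSE is
#' optimistic, since the weights are fitted on those very weeks), and `R_i`
#' is the `ceiling((1 - alpha)(n_pre + 1))`-th order statistic of their
#' absolute values. The pointwise 95% band at post week `s` is
#' `[q_lo{yhat_minus_i(s) - R_i}, q_hi{yhat_minus_i(s) + R_i}]` with the
#' Jackknife+ finite-sample order statistics `floor(alpha (n+1))` and
#' `ceiling((1 - alpha)(n+1))` (clamped to `[1, n]`, which keeps bands
#' finite at small `n`).
#'
#' @param y1 Treated series over pre + post weeks.
#' @param Y0 Control matrix (controls x weeks); >= 5 controls.
#' @param pre_idx,post_idx Pre and post column indices.
#' @param alpha Miscoverage level (default 0.05).
#' @param lambda Fixed ridge penalty for the refits (cross-validating inside
#'   every leave-one-out refit would be slow and is unnecessary; pass the
#'   full-fit penalty).
#' @return list with `ci_lower`, `ci_upper` (length `length(post_idx)`),
#'   `loo_counterfactuals` (controls x post weeks), `loo_rmse` (the per-refit
#'   conformal residual scales `R_i`).
#' @export
jackknife_plus <- function(y1, Y0, pre_idx, post_idx, alpha = 0.05,
                           lambda = NULL) {
  Y0 <- as.matrix(Y0)
  n <- nrow(Y0)
  if (n < 5) stop("Jackknife+ bands need >= 5 control units")
  n_post <- length(post_idx)
  loo_cf <- matrix(NA_real_, n, n_post)
  loo_rmse <- numeric(n)
  for (i in seq_len(n)) {
    Yi <- Y0[-i, , drop = FALSE]
    Yi_pre <- Yi[, pre_idx, drop = FALSE]
    g <- fit_scm_weights(Yi_pre, y1[pre_idx])
    ro <- fit_ridge_outcome(Yi_pre, Yi[, post_idx, drop = FALSE],
                            lambda = lambda)
    f <- ascm_estimate(Yi_pre, Yi[, post_idx, drop = FALSE],
                       y1[pre_idx], g, ro$eta, lambda = ro$lambda)
    loo_cf[i, ] <- f$counterfactual
    # out-of-sample pre residuals: each pre week predicted from weights
    # refitted without it; the residual scale is the conformal
    # ceiling((1-alpha)(n_pre+1)) order statistic of their absolute values
    # (an RMSE would miss the tail factor and under-cover)
    n_pre <- length(pre_idx)
    res_abs <- numeric(n_pre)
    for (j in seq_len(n_pre)) {
      gj <- fit_scm_weights(Yi_pre[, -j, drop = FALSE], y1[pre_idx][-j])
      res_abs[j] <- abs(y1[pre_idx][j] - sum(gj * Yi_pre[, j]))
    }
    k_r <- min(n_pre, as.integer(ceiling((1 - alpha) * (n_pre + 1))))
    loo_rmse[i] <- sort(res_abs, partial = k_r)[k_r]
  }
  k_lo <- max(1L, min(n, as.integer(floor(alpha * (n + 1)))))
  k_hi <- max(1L, min(n, as.integer(ceiling((1 - alpha) * (n + 1)))))
  ci_lower <- apply(loo_cf - loo_rmse, 2,
                    function(v) sort(v, partial = k_lo)[k_lo])
  ci_upper <- apply(loo_cf + loo_rmse, 2,
                    function(v) sort(v, partial = k_hi)[k_hi])
  list(ci_lower = ci_lower, ci_upper = ci_upper,
       loo_counterfactuals = loo_cf, loo_rmse = loo_rmse)
}

#' In-place placebo scan over control units
#'
#' Each control city in turn is pretended to be treated (with the treated
#' unit's calendar already baked into the pre/post indices) and fitted
#' against the remaining controls. The treated unit's heating-period mean
#' effect is ranked against the placebo distribution:
#' `pseudo_p = (1 + #{placebos with |mean effect| >= |treated|}) /
#' (n_placebos + 1)`.
#'
#' @param y1 Treated series over pre + post weeks.
#' @param Y0 Control matrix (controls x weeks); >= 5 controls.
#' @param pre_idx,post_idx Pre and post column indices.
#' @param lambda_grid Optional ridge grid shared by all fits.
#' @return list of class `placebo_result`: `treated_effect` (heating-period
#'   mean), `placebo_effects` (named per control), `pseudo_p`,
#'   `placebo_series` (controls x post weeks effect matrix).
#' @export
placebo_scan <- function(y1, Y0, pre_idx, post_idx, lambda_grid = NULL) {
  Y0 <- as.matrix(Y0)
  n <- nrow(Y0)
  if (n < 5) stop("placebo scan needs >= 5 control units")
  fit1 <- ascm(y1, Y0, pre_idx, post_idx, lambda_grid = lambda_grid)
  treated_effect <- mean(y1[post_idx] - fit1$counterfactual)
  eff <- matrix(NA_real_, n, length(post_idx),
                dimnames = list(rownames(Y0), NULL))
  for (i in seq_len(n)) {
    fit_i <- ascm(Y0[i, ], Y0[-i, , drop = FALSE], pre_idx, post_idx,
                  lambda_grid = lambda_grid)
    eff[i, ] <- Y0[i, post_idx] - fit_i$counterfactual
  }
  placebo_effects <- rowMeans(eff)
  pseudo_p <- (1 + sum(abs(placebo_effects) >= abs(treated_effect))) / (n + 1)
  structure(list(treated_effect = treated_effect,
                 placebo_effects = placebo_effects,
                 pseudo_p = pseudo_p,
                 placebo_series = eff,
                 treated_fit = fit1),
            class = "placebo_result")
}

#' @export
print.placebo_result <- function(x, ...) {
  cat(sprintf(
    "in-place placebo scan: treated mean effect %.3f, %d placebos, pseudo-p %.4f\n",
    x$treated_effect, length(x$placebo_effects), x$pseudo_p))
  invisible(x)
}

#' Prepare the control (donor) matrix from weekly series
#'
#' Drops control cities missing more than `max_missing_frac` of weeks in the
#' window and linearly interpolates interior gaps of at most
#' `max_gap` consecutive weeks in the rest.
#'
#' @param Y0 Controls x weeks matrix, `NA` allowed.
#' @param max_missing_frac Drop threshold (default 0.10).
#' @param max_gap Longest interpolatable run of consecutive missing weeks
#'   (default 2).
#' @return list: `Y0` (complete matrix), `dropped` (city ids removed).
#' @export
prepare_donor_matrix <- function(Y0, max_missing_frac = 0.10, max_gap = 2L) {
  Y0 <- as.matrix(Y0)
  frac <- rowMeans(is.na(Y0))
  dropped <- rownames(Y0)[frac > max_missing_frac]
  Y0 <- Y0[frac <= max_missing_frac, , drop = FALSE]
  for (i in seq_len(nrow(Y0))) {
    v <- Y0[i, ]
    if (!anyNA(v)) next
    r <- rle(is.na(v))
    if (any(r$values & r$lengths > max_gap)) {
      stop("control ", rownames(Y0)[i], " has a gap longer than ", max_gap,
           " weeks")
    }
    idx <- which(!is.na(v))
    if (length(idx) < 2) stop("control ", rownames(Y0)[i],
                              " has too few observed weeks")
    Y0[i, ] <- stats::approx(idx, v[idx], xout = seq_along(v),
                             rule = 2)$y
  }
  list(Y0 = Y0, dropped = dropped)
}
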