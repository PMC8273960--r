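# generate a logistic-normal sample and censor MVPA below a detection limit
censored_sample <- function(n = 150, seed = 21, dl = 30) {
  set.seed(seed)
  z <- cbind(rnorm(n, 1.5, 0.35), rnorm(n, 0.6, 0.55))
  comp <- ilr_pivot_inverse(z, "sb_first", total = 960)
  zero <- comp[, "mvpa"] < dl
  obs <- comp
  obs[zero, "mvpa"] <- 0
  obs[zero, ] <- obs[zero, ] * 960 / rowSums(obs[zero, , drop = FALSE])
  obs[zero, "mvpa"] <- 0
  list(raw = obs, true = comp, zero = zero, dl = dl)
}

test_that("matrices without zeros pass through untouched", {
  m <- random_compositions(40, seed = 20)
  out <- impute_zeros_lrem(m)
  expect_identical(out[, ], m[, ])
  expect_identical(attr(out, "n_imputed"), 0L)
})

test_that("imputed cells fall below the detection limit and rows re-close", {
  m <- rbind(c(950, 10, 0), random_compositions(30, seed = 22))
  out <- impute_zeros_lrem(m, detection_limit = 1)
  expect_identical(attr(out, "n_imputed"), 1L)
  expect_gt(out[1, "mvpa"], 0)
  expect_lt(out[1, "mvpa"], 1)
  # donor parts rescaled, zero-free rows untouched
  expect_lt(max(abs(rowSums(out) - rowSums(m))), 1e-9)
  expect_identical(out[-1, ], m[-1, ])
  expect_true(all(out > 0))
  # deterministic
  expect_identical(out[, ], impute_zeros_lrem(m, detection_limit = 1)[, ])
})

test_that("EM increases the observed-data log-likelihood monotonically", {
  s <- censored_sample(n = 200, seed = 23, dl = 30)
  out <- impute_zeros_lrem(s$raw, detection_limit = s$dl)
  ll <- attr(out, "loglik")
  expect_gt(length(ll), 2)
  expect_true(all(diff(ll) > -1e-8))
})

test_that("EM solution matches direct maximisation of the censored likelihood", {
  s <- censored_sample(n = 150, seed = 24, dl = 30)
  expect_gt(sum(s$raw[, "mvpa"] == 0), 5)
  out <- impute_zeros_lrem(s$raw, detection_limit = s$dl)

  # independent oracle: maximise the observed-data likelihood numerically.
  # alr coordinates anchored on the reported denominator part.
  d <- attr(out, "alr_denominator")
  oth <- setdiff(behaviours(), d)
  y <- log(s$raw[, oth] / s$raw[, d])
  cens <- s$raw[, oth] == 0
  ci <- which(rowSums(cens) > 0)
  cj <- apply(cens[ci, , drop = FALSE], 1, which)
  psi <- log(s$dl / s$raw[ci, d])
  negll <- function(par) {
    mu <- par[1:2]
    s1 <- exp(par[3]); s2 <- exp(par[4]); rho <- tanh(par[5])
    S <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)
    if (S[1, 1] * S[2, 2] - S[1, 2]^2 < 1e-10) return(1e10)
    ll <- 0
    for (i in seq_len(nrow(y))) {
      if (i %in% ci) {
        j <- cj[match(i, ci)]; o <- 3 - j
        mc <- mu[j] + S[j, o] / S[o, o] * (y[i, o] - mu[o])
        vc <- S[j, j] - S[j, o]^2 / S[o, o]
        ll <- ll + dnorm(y[i, o], mu[o], sqrt(S[o, o]), log = TRUE) +
          pnorm(psi[match(i, ci)], mc, sqrt(vc), log.p = TRUE)
      } else {
        r <- y[i, ] - mu
        det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
        q <- drop(r %*% solve(S, r))
        ll <- ll - log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
      }
    }
    -ll
  }
  start <- c(colMeans(y[-ci, ]), log(apply(y[-ci, ], 2, sd)), 0)
  opt <- optim(start, negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-13))
  opt <- optim(opt$par, negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-13))
  mu_hat <- opt$par[1:2]
  s1 <- exp(opt$par[3]); s2 <- exp(opt$par[4]); rho <- tanh(opt$par[5])
  S_hat <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)

  expect_equal(unname(attr(out, "alr_mean")), unname(mu_hat), tolerance = 1e-4)
  expect_equal(unname(attr(out, "alr_cov")), unname(S_hat), tolerance = 1e-3)

  # imputed log-ratios equal the truncated conditional means at the optimum
  for (k in seq_along(ci)) {
    i <- ci[k]; j <- cj[k]; o <- 3 - j
    mc <- mu_hat[j] + S_hat[j, o] / S_hat[o, o] * (y[i, o] - mu_hat[o])
    vc <- S_hat[j, j] - S_hat[j, o]^2 / S_hat[o, o]
    a <- (psi[k] - mc) / sqrt(vc)
    ey <- mc - sqrt(vc) * dnorm(a) / pnorm(a)
    # the imputed cell is exp(ey) times the raw alr denominator; the donor
    # parts (not the imputed cell) absorb the re-closure
    expect_equal(log(out[i, oth[j]] / s$raw[i, d]), ey, tolerance = 5e-3)
  }
})

test_that("degenerate rows are rejected", {
  expect_error(impute_zeros_lrem(rbind(c(960, 0, 0), c(700, 200, 60))),
               "2 positive parts")
  expect_error(impute_zeros_lrem(rbind(c(700, 200, 60)), detection_limit = -1),
               "positive")
})
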