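test_that("the three rotations are one model in different coordinates", {
  co <- lean_cohort(n = 800, seed = 31)
  fits <- lapply(names(rotations()), function(r)
    fit_compositional_cox(co, rotation = r, covariates = lean_covariates))
  lpl <- vapply(fits, function(f) f$loglik, numeric(1))
  expect_lt(max(lpl) - min(lpl), 1e-6)
  # coordinate coefficients rotate but the fitted risk ordering is shared
  ref <- build_reference_mvpa(21)
  hrs <- vapply(fits, function(f)
    reallocation_hr(f, ref, "sb", "mvpa", 10)$hr, numeric(1))
  expect_lt(max(hrs) - min(hrs), 1e-6)
})

test_that("Wald intervals bracket the estimate and the covariance is PSD", {
  co <- lean_cohort(n = 800, seed = 32)
  f <- fit_compositional_cox(co, covariates = lean_covariates)
  tab <- coord_hr_table(f)
  expect_true(all(tab$ci_low <= tab$hr & tab$hr <= tab$ci_high))
  expect_gte(min(eigen(f$vcov, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_equal(sum(co$event), f$n_events)
})

test_that("a null composition effect is recovered without bias", {
  est <- t(vapply(1:30, function(i) {
    co <- simulate_cohort(lean_config(n = 700, seed = 600 + i,
                                      beta_z = c(0, 0)))
    fit_compositional_cox(co, covariates = lean_covariates)$beta_z
  }, numeric(2)))
  # Monte-Carlo error bound: se of the mean of 30 estimates, ~0.2 each
  expect_lt(abs(mean(est[, 1])), 4 * stats::sd(est[, 1]) / sqrt(30))
  expect_lt(abs(mean(est[, 2])), 4 * stats::sd(est[, 2]) / sqrt(30))
})

test_that("collinear covariates are reported by name", {
  co <- lean_cohort(n = 400, seed = 33)
  co$age_copy <- co$age
  expect_error(
    fit_compositional_cox(co, covariates = c("age", "age_copy")),
    "age_copy")
})

test_that("the proportional hazards check behaves as a diagnostic", {
  co <- lean_cohort(n = 800, seed = 34)
  f <- fit_compositional_cox(co, covariates = lean_covariates)
  tab <- ph_check(f)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_identical(tab$term[nrow(tab)], "GLOBAL")

  # a strong step-change in a hazard ratio is detected
  set.seed(35)
  n <- 3000
  x <- rnorm(n)
  u <- runif(n)
  lam <- 0.4
  beta <- 1.2
  # hazard lam before t = 1, lam * exp(beta x) afterwards
  e <- -log(u)
  t_ev <- ifelse(e < lam, e / lam, 1 + (e - lam) / (lam * exp(beta * x)))
  cens <- runif(n, 2, 4)
  d <- data.frame(followup_years = pmin(t_ev, cens),
                  event = as.integer(t_ev <= cens), x = x)
  comp <- random_compositions(n, seed = 36)
  d$sb_min <- comp[, 1]; d$lipa_min <- comp[, 2]; d$mvpa_min <- comp[, 3]
  f2 <- fit_compositional_cox(d, covariates = "x")
  tab2 <- ph_check(f2)
  expect_lt(tab2$p[tab2$term == "x"], 0.01)
})

test_that("single-covariate model: per-term and global PH tests coincide", {
  co <- lean_cohort(n = 500, seed = 37)
  comp <- close_composition(co[, c("sb_min", "lipa_min", "mvpa_min")])
  d <- data.frame(followup_years = co$followup_years, event = co$event,
                  x = drop(ilr_pivot(comp))[, 1])
  fit <- survival::coxph(survival::Surv(followup_years, event) ~ x, data = d)
  zp <- survival::cox.zph(fit)$table
  expect_equal(zp["x", "p"], zp["GLOBAL", "p"], tolerance = 1e-10)
})

test_that("the effect-modification test is well-defined and catches a shift", {
  co <- lean_cohort(n = 800, seed = 38)
  it <- interaction_test(co, "hypertension", covariates = lean_covariates)
  expect_true(it$p >= 0 && it$p <= 1)
  expect_identical(it$df, 2L)
  expect_equal(nrow(it$per_term), 2)

  co$flat <- 1
  expect_error(interaction_test(co, "flat", covariates = lean_covariates),
               "constant")

  # inject a large coordinate-effect shift in one stratum
  set.seed(39)
  cfg <- lean_config(n = 4000, beta_z = c(0, 0))
  comp <- simulate_compositions(cfg$n_subjects, cfg)
  z <- attr(comp, "ilr_true")
  mod <- rbinom(cfg$n_subjects, 1, 0.5)
  lp <- (1.2 * mod) * (z[, 1] - cfg$mean_ilr[1])
  surv <- simulate_survival(lp, cfg)
  d <- data.frame(sb_min = comp[, 1], lipa_min = comp[, 2],
                  mvpa_min = comp[, 3], modifier = mod, surv)
  it2 <- interaction_test(d, "modifier", covariates = character(0))
  expect_lt(it2$p, 0.05)
})
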