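# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# strictly positive random compositions on the 960-min simplex
random_compositions <- function(n, seed = 1, total = 960) {
  set.seed(seed)
  close_composition(matrix(stats::rlnorm(3 * n, c(6.5, 5.3, 4.0), 0.5),
                           n, 3, byrow = TRUE), total = total)
}

# lean simulation setup: few covariates, fast fits, still a valid Cox DGP
lean_spec <- function() {
  list(
    age = list(type = "normal", mean = 68.9, sd = 5.6),
    sex = list(type = "factor", levels = c("man", "woman"),
               probs = c(0.733, 0.267)),
    hypertension = list(type = "binary", p = 0.461),
    diabetes = list(type = "binary", p = 0.111)
  )
}

lean_gamma <- function() {
  list(age = 0.06, sex = c(woman = -0.35), hypertension = 0.35,
       diabetes = 0.45)
}

lean_config <- function(n = 800, seed = NULL, beta_z = c(0.30, 0.15), ...) {
  sim_config(n_subjects = n, beta_z = beta_z, covariate_spec = lean_spec(),
             gamma = lean_gamma(), zero_rate_mvpa = 0, seed = seed, ...)
}

lean_covariates <- c("age", "sex", "hypertension", "diabetes")

# one lean cohort shared by fitting tests
lean_cohort <- function(n = 800, seed = 42, ...) {
  simulate_cohort(lean_config(n = n, seed = seed, ...))
}
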