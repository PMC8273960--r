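test_that("MVPA-anchored references split the remainder by the SB share", {
  ra <- build_reference_mvpa(10, sb_share = 0.77, total = 960)
  expect_equal(unname(ra$composition), c(731.5, 218.5, 10))
  rb <- build_reference_mvpa(21)
  expect_equal(unname(rb$composition), c(723.03, 215.97, 21), tolerance = 1e-12)
  expect_equal(sum(rb$composition), 960)
  expect_error(build_reference_mvpa(0), "strictly between")
  expect_error(build_reference_mvpa(10, sb_share = 1.2), "strictly between")
})

test_that("SB-anchored references assign LIPA the remaining waking time", {
  r1 <- build_reference_sb(540, 10)
  expect_equal(r1$composition[["lipa"]], 410)   # 6 h 50 min
  r2 <- build_reference_sb(840, 10)
  expect_equal(r2$composition[["lipa"]], 110)   # 1 h 50 min
  expect_error(build_reference_sb(955, 10), "no waking time")
})

test_that("reallocation moves minutes between two behaviours only", {
  rb <- build_reference_mvpa(21)
  out <- reallocate(rb, "sb", "mvpa", 10)
  expect_equal(unname(out), c(713.03, 215.97, 31), tolerance = 1e-12)
  expect_equal(sum(out), 960)
  expect_equal(reallocate(rb, "sb", "mvpa", 0), rb$composition)
  # removing 10 min of MVPA from a 10-min reference is infeasible
  expect_error(reallocate(build_reference_mvpa(10), "mvpa", "sb", 10),
               class = "ilrsurv_infeasible_reallocation")
})

test_that("reallocation HRs follow the closed-form log-linear contrast", {
  # frozen oracle: exp(log(2) * dz1) evaluated directly from the ilr formula
  m <- as_comp_cox(c(log(2), 0), rotation = "sb_first")
  est <- reallocation_hr(m, close_composition(c(1, 1, 1)), "sb", "mvpa", 10)
  expect_equal(est$hr, 0.9736767644, tolerance = 1e-9)

  # null coefficients: HR exactly 1 everywhere
  null <- as_comp_cox(c(0, 0))
  tab <- reallocation_table(null, build_reference_mvpa(21), deltas = c(10, 20))
  expect_true(all(tab$hr[tab$feasible] == 1))

  # zero displacement: HR 1 with a zero-width interval
  est0 <- reallocation_hr(m, build_reference_mvpa(21), "sb", "mvpa", 0)
  expect_equal(est0$hr, 1)
  expect_equal(est0$ci_low, 1)
  expect_equal(est0$ci_high, 1)

  # infeasible cells are flagged, not errors
  bad <- reallocation_hr(m, build_reference_mvpa(10), "mvpa", "sb", 10)
  expect_false(bad$feasible)
  expect_true(is.na(bad$hr))
})

test_that("reallocation estimates are invariant to the fitted rotation", {
  co <- lean_cohort(n = 700, seed = 41)
  refs <- list(build_reference_mvpa(21), build_reference_sb(540, 10))
  tabs <- lapply(names(rotations()), function(r) {
    f <- fit_compositional_cox(co, rotation = r, covariates = lean_covariates)
    reallocation_table(f, refs, deltas = c(10, 30))
  })
  for (k in 2:3) {
    expect_equal(tabs[[1]]$hr, tabs[[k]]$hr, tolerance = 1e-6)
    expect_equal(tabs[[1]]$log_hr_se, tabs[[k]]$log_hr_se, tolerance = 1e-6)
  }
})

test_that("log HRs are antisymmetric to first order in the displacement", {
  m <- as_comp_cox(c(0.30, 0.15))
  ref <- build_reference_mvpa(21)
  for (pair in list(c("sb", "mvpa"), c("lipa", "mvpa"), c("sb", "lipa"))) {
    fwd <- log(reallocation_hr(m, ref, pair[1], pair[2], 0.01)$hr)
    bwd <- log(reallocation_hr(m, ref, pair[2], pair[1], 0.01)$hr)
    expect_equal(fwd, -bwd, tolerance = 1e-3)
  }
})

test_that("protective effects give monotone HR along a displacement path", {
  # with both coordinate effects positive (SB-first), moving SB into MVPA
  # lowers both coordinates, so the HR decreases monotonically in the delta
  m <- as_comp_cox(c(0.30, 0.15))
  for (ref in list(build_reference_mvpa(30), build_reference_sb(540, 10))) {
    hrs <- vapply(c(5, 10, 20, 30), function(d)
      reallocation_hr(m, ref, "sb", "mvpa", d)$hr, numeric(1))
    expect_true(all(diff(hrs) < 0))
    expect_true(all(hrs < 1))
  }
})

test_that("the HR surface is anchored at the reference and range-restricted", {
  m <- as_comp_cox(c(0.30, 0.15))
  ref <- build_reference_mvpa(21)
  ranges <- list(sb = c(400, 900), lipa = c(50, 450), mvpa = c(5, 240))
  s <- hr_surface(m, ref, ranges, grid_step = 10)
  expect_equal(s$hr[s$is_reference], 1)
  g <- s[!s$is_reference, ]
  expect_true(all(g$sb_min >= 400 & g$sb_min <= 900))
  expect_true(all(g$mvpa_min >= 5 & g$mvpa_min <= 240))
  expect_equal(unique(g$sb_min + g$lipa_min + g$mvpa_min), 960)
  # more MVPA at fixed LIPA lowers the hazard under a protective fit
  path <- g[g$lipa_min == 250, ]
  path <- path[order(path$mvpa_min), ]
  expect_true(all(diff(path$hr) < 0))
  expect_error(hr_surface(m, ref, list(sb = c(0, 1), lipa = c(0, 1),
                                       mvpa = c(0, 1))), "no grid point")
  p <- plot_hr_ternary(s)
  expect_s3_class(p, "ggplot")
})
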