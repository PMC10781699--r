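cd_spec <- function() fit_distribution(0.04, 0.03, 0.002, 0.19, metal = "Cd")

test_that("lognormal moment matching reproduces the closed-form parameters", {
  spec <- cd_spec()
  # sigma^2 = ln(1 + (sd/mean)^2), mu = ln(mean) - sigma^2/2, by hand:
  expect_equal(spec$par$sdlog, sqrt(log(1 + (0.03 / 0.04)^2)),
               tolerance = 1e-12)
  expect_equal(spec$par$sdlog, 0.6680472, tolerance = 1e-6)
  expect_equal(spec$par$meanlog, log(0.04) - log(1 + (0.03 / 0.04)^2) / 2,
               tolerance = 1e-12)
  expect_equal(spec$par$meanlog, -3.4420194, tolerance = 1e-6)
  expect_error(fit_distribution(0, 1, -1, 1, family = "truncated_lognormal"),
               "truncated_normal or uniform")
  expect_error(fit_distribution(5, 1, 0, 1), "within")
  expect_error(fit_distribution(1, -1, 0, 2), "non-negative")
})

test_that("an untruncated fit recovers the target mean at large n", {
  spec <- fit_distribution(0.04, 0.03, 0, 1e9)  # bounds far beyond the mass
  set.seed(101)
  x <- spec_sample(spec, 1e6)
  expect_lt(abs(mean(x) - 0.04), 3 * 0.03 / sqrt(1e6))
})

test_that("zero spread collapses to a point mass", {
  spec <- fit_distribution(0.04, 0, 0.002, 0.19)
  expect_equal(spec$family, "point_mass")
  set.seed(1)
  expect_equal(spec_sample(spec, 50), rep(0.04, 50))
})

test_that("a point-mass concentration makes every draw the deterministic risk", {
  spec <- fit_distribution(0.04, 0, 0.002, 0.19, metal = "Cd")
  res <- simulate_risk(list(spec), receptor = "adult", route = "oral",
                       endpoint = "CR", n_iter = 1000, seed = 5,
                       keep_draws = TRUE)
  det <- 0.04 * oracle_unit_risk("Cd", "adult", "oral", "CR")
  expect_equal(res$mean, det, tolerance = 1e-12)
  expect_equal(res$p5, det); expect_equal(res$p95, det)
  expect_equal(unique(as.vector(attr(res, "risk_draws"))), det)
})

test_that("simulated percentiles are ordered and draws respect truncation", {
  for (seed in 1:5) {
    res <- simulate_risk(list(cd_spec()), receptor = "child",
                         route = "dermal", endpoint = "CR",
                         n_iter = 400, seed = seed, keep_draws = TRUE)
    expect_true(res$p5 <= res$p50 && res$p50 <= res$p95)
    d <- attr(res, "draws")
    expect_true(all(d >= 0.002 & d <= 0.19))
    expect_true(res$frac_exceed >= 0 && res$frac_exceed <= 1)
  }
})

test_that("identical seeds give bit-identical summaries", {
  a <- simulate_risk(list(cd_spec()), receptor = "adult", route = "oral",
                     endpoint = "HQ", n_iter = 2000, seed = 77)
  b <- simulate_risk(list(cd_spec()), receptor = "adult", route = "oral",
                     endpoint = "HQ", n_iter = 2000, seed = 77)
  expect_identical(a, b)
  c2 <- simulate_risk(list(cd_spec()), receptor = "adult", route = "oral",
                      endpoint = "HQ", n_iter = 2000, seed = 78)
  expect_false(identical(a$mean, c2$mean))
})

test_that("risk percentiles are the concentration percentiles scaled by the unit risk", {
  res <- simulate_risk(list(cd_spec()), receptor = "adult", route = "oral",
                       endpoint = "CR", n_iter = 5000, seed = 12,
                       keep_draws = TRUE)
  k <- oracle_unit_risk("Cd", "adult", "oral", "CR")
  d <- attr(res, "draws")[, "Cd"]
  qs <- quantile(d, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  expect_equal(c(res$p5, res$p50, res$p95), qs * k, tolerance = 1e-12)
})

test_that("Monte Carlo mean matches the truncated-distribution mean by quadrature", {
  spec <- cd_spec()
  # independent numerical-integration oracle for the truncated mean
  dens <- function(x) dlnorm(x, spec$par$meanlog, spec$par$sdlog)
  mass <- integrate(dens, 0.002, 0.19, rel.tol = 1e-10)$value
  num <- integrate(function(x) x * dens(x), 0.002, 0.19,
                   rel.tol = 1e-10)$value
  mu_trunc <- num / mass
  expect_equal(spec_mean(spec), mu_trunc, tolerance = 1e-7)
  k <- oracle_unit_risk("Cd", "adult", "oral", "CR")
  res <- simulate_risk(list(spec), receptor = "adult", route = "oral",
                       endpoint = "CR", n_iter = 10000, seed = 3,
                       keep_draws = TRUE)
  se <- sd(attr(res, "risk_draws")) / sqrt(10000)
  expect_lt(abs(res$mean - mu_trunc * k), 3 * se)
})

test_that("carcinogenic endpoint refuses metals without a slope factor", {
  spec <- fit_distribution(0.03, 0.024, 0.0002, 0.1, metal = "Zn")
  expect_error(simulate_risk(list(spec), receptor = "adult", route = "oral",
                             endpoint = "CR", n_iter = 10, seed = 1),
               "not applicable")
})

test_that("convergence report is deterministic and tightens with n", {
  spec <- cd_spec()
  cv <- convergence_report(list(spec), receptor = "adult", route = "oral",
                           endpoint = "HQ", n_grid = c(100, 100, 4000),
                           seeds = 1:5)
  # same seed and n -> identical rows
  r100 <- cv[cv$n_iter == 100 & cv$seed == 2, ]
  expect_identical(`rownames<-`(r100[1, ], NULL),
                   `rownames<-`(r100[2, ], NULL))
  # across-seed dispersion of the upper percentile shrinks as n grows
  disp <- tapply(cv$p95, cv$n_iter, sd)
  expect_lt(disp[["4000"]], disp[["100"]])
  # a single draw is its own percentile summary
  one <- simulate_risk(list(spec), receptor = "adult", route = "oral",
                       endpoint = "HQ", n_iter = 1, seed = 9)
  expect_equal(one$p5, one$p50)
  expect_equal(one$p50, one$p95)
  expect_error(convergence_report(list(spec), n_grid = 100), "at least 2")
})
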