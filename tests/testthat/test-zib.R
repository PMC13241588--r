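test_that("the zero-inflated beta density is a proper mixture", {
  expect_equal(zibDensity(0, omega = 0.3, mu = 0.4, phi = 5), 0.3)
  # mu = 0.5, phi = 2 is Uniform(0, 1) on the interior
  expect_equal(zibDensity(c(0.1, 0.5, 0.9), 0.25, 0.5, 2), rep(0.75, 3))
  expect_error(zibDensity(1, 0.2, 0.5, 2), "must lie")
  expect_error(zibDensity(-0.1, 0.2, 0.5, 2), "must lie")

  # normalization by quadrature for random parameter draws: the point mass
  # at zero plus the integrated interior density must be 1
  set.seed(11)
  for (k in 1:20) {
    om <- runif(1); mu <- runif(1, 0.05, 0.95); phi <- runif(1, 0.5, 40)
    interior <- stats::integrate(function(x) zibDensity(x, om, mu, phi),
                                 0, 1, rel.tol = 1e-10)$value
    expect_equal(om + interior, 1, tolerance = 1e-8)
  }
})

zib_cov <- function(R = 8, S = 3, seed = 21) {
  set.seed(seed)
  cov <- expand.grid(pop_id = sprintf("P%02d", 1:R),
                     section = LETTERS[1:S], stringsAsFactors = FALSE)
  cov$z_distance <- rnorm(nrow(cov))
  cov$z_area <- rnorm(R)[match(cov$pop_id, unique(cov$pop_id))]
  cov$z_groundwater <- rnorm(R)[match(cov$pop_id, unique(cov$pop_id))]
  cov$connectivity <- sample(c("connected", "waterfall"), R, TRUE,
                             c(0.8, 0.2))[match(cov$pop_id,
                                                unique(cov$pop_id))]
  cov
}

test_that("linear predictors obey the link functions", {
  cov <- zib_cov()
  zero <- zibCoefficients(alpha_mu = 0, beta_distance = 0, beta_area = 0,
                          beta_groundwater = 0,
                          beta_connectivity = c(culvert_diversion = 0,
                                                low_flow = 0, waterfall = 0),
                          alpha_omega = 0, beta_omega_distance = 0,
                          beta_omega_area = 0, beta_omega_groundwater = 0,
                          beta_omega_connectivity = c(culvert_diversion = 0,
                                                      low_flow = 0,
                                                      waterfall = 0),
                          alpha_phi = 0, beta_phi_distance = 0,
                          beta_phi_area = 0, beta_phi_groundwater = 0,
                          beta_phi_connectivity = c(culvert_diversion = 0,
                                                    low_flow = 0,
                                                    waterfall = 0))
  pr <- linearPredictors(cov, zero)
  expect_true(all(pr$omega == 0.5 & pr$mu == 0.5 & pr$phi == 1))

  # mu strictly decreasing in distance when beta_distance < 0
  cov2 <- cov[order(cov$z_distance), ]
  pr2 <- linearPredictors(cov2, zibCoefficients())
  same_unit_sec <- cov2$pop_id == cov2$pop_id[1]
  expect_true(all(diff(pr2$mu[cov2$pop_id == cov2$pop_id[1] &
                              cov2$section == "A"]) <= 0))

  # opposite-sign per-section groundwater slopes reverse the effect
  co3 <- zibCoefficients(beta_groundwater = c(1, -1, 0))
  cov3 <- cov[cov$pop_id %in% c("P01", "P02"), ]
  pr3 <- linearPredictors(cov3, co3)
  gdiff <- function(sec) {
    i <- cov3$section == sec
    o <- order(cov3$z_groundwater[i])
    diff(qlogis(pr3$mu[i][o]))
  }
  expect_true(all(gdiff("A") >= 0))
  expect_true(all(gdiff("B") <= 0))

  cov_bad <- cov; cov_bad$connectivity[1] <- "ferry"
  expect_error(linearPredictors(cov_bad, zibCoefficients()), "connectivity")
})

test_that("the contribution model fit behaves on small self-simulated data", {
  cov <- zib_cov(R = 10, S = 3, seed = 31)
  dat <- simulateZibData(cov, zibCoefficients(), n_years = 3, seed = 32)
  expect_error(fitZib(dat[dat$p > 0, ], chains = 1, warmup = 100, iter = 100),
               "zero and nonzero")
  dat2 <- dat
  dat2$p[which(dat2$p > 0)[1]] <- 1
  expect_warning(
    fit <- fitZib(dat2, chains = 2, warmup = 500, iter = 500, seed = 33),
    "squeezed")
  expect_s4_class(fit, "ZibFit")
  expect_true(all(is.finite(posteriorDraws(fit))))
  expect_equal(nrow(posteriorDraws(fit)), 1000)
  expect_true(all(c("rhat", "ess") %in% names(convergenceDiagnostics(fit))))
  # pointwise log-likelihood covers every observation
  expect_equal(ncol(pointwiseLoglik(fit)), nrow(dat2))

  # posterior median distance slope is negative under the default truth
  expect_lt(median(posteriorDraws(fit)[, "beta_distance"]), 0)
})

test_that("posterior predictive checks report per-stratum statistics", {
  cov <- zib_cov(R = 8, S = 2, seed = 41)
  dat <- simulateZibData(cov, zibCoefficients(), n_years = 2, seed = 42)
  fit <- suppressWarnings(fitZib(dat, chains = 2, warmup = 400, iter = 400,
                                 seed = 43))
  ppc <- posteriorPredictiveCheck(fit, n_rep = 150, seed = 44)
  # one row per statistic per stratum plus the overall block
  n_strata <- length(unique(paste(dat$section, dat$year)))
  expect_equal(nrow(ppc), 3 * (n_strata + 1))
  overall <- ppc[ppc$stratum == "all", ]
  expect_true(all(overall$bayes_p > 0.02 & overall$bayes_p < 0.98))

  # constructed misfit: forcing the zero model high makes the zero-proportion
  # p-value extreme
  broken <- fit
  broken@draws[, "alpha_omega"] <- 4
  ppc2 <- posteriorPredictiveCheck(broken, n_rep = 100, seed = 45)
  pz <- ppc2[ppc2$stratum == "all" & ppc2$statistic == "prop_zero", ]
  expect_gte(pz$bayes_p, 0.99)
})

test_that("effect curves respect the fitted coefficients", {
  cov <- zib_cov(R = 8, S = 2, seed = 51)
  dat <- simulateZibData(cov, zibCoefficients(), n_years = 2, seed = 52)
  fit <- suppressWarnings(fitZib(dat, chains = 1, warmup = 400, iter = 600,
                                 seed = 53))
  cd <- effectCurves(fit, "distance")
  # monotone coefficient -> monotone median curve
  expect_true(all(diff(cd$mu_med) < 0))
  # flat when all distance draws are zeroed
  flat <- fit
  flat@draws[, "beta_distance"] <- 0
  cf <- effectCurves(flat, "distance")
  expect_lt(diff(range(cf$mu_med)), 1e-10)
  # groundwater curves come per section
  cg <- effectCurves(fit, "groundwater")
  expect_setequal(unique(cg$section), unique(dat$section))
  # connectivity marginal effects include every level
  cc <- effectCurves(fit, "connectivity")
  expect_setequal(cc$connectivity, c("connected", "waterfall"))
})
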