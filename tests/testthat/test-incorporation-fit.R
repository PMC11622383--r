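test_that("two-state fit recovers constructed mixtures", {
  pats <- state_patterns("EEDPIHLR",
                         enumerate_states("EEDPIHLR", vil_scheme()))
  rng <- c(1006, 1016)
  u <- render_profile(pats[[1]], 1, 0.0126, 1000, rng)
  l <- render_profile(pats[[3]], 1, 0.0126, 1000, rng)
  mk <- function(bu, bl) {
    observed_spectrum(profile_mz(u), bu * u$intensity + bl * l$intensity)
  }
  f <- fit_two_state(mk(0.30, 0.70), u, l)
  expect_equal(f$states$weight, c(30, 70), tolerance = 1e-6)
  expect_equal(sum(f$states$weight), 100, tolerance = 1e-6)
  # pure endpoints
  expect_equal(fit_two_state(mk(1, 0), u, l)$states$weight[2], 0)
  expect_equal(fit_two_state(mk(0, 1), u, l)$states$weight[2], 100)
  # noisy mixture at true B = 40: within 2 points
  mix <- 0.6 * u$intensity + 0.4 * l$intensity
  noisy <- withr::with_seed(42, pmax(
    mix + rnorm(length(mix), 0, 0.01 * max(mix)), 0))
  fn <- fit_two_state(observed_spectrum(profile_mz(u), noisy), u, l)
  expect_lt(abs(fn$states$weight[2] - 40), 2)
  expect_error(fit_two_state(mk(0, 0), u, l), "no intensity")
})

test_that("multi-state greedy fit recovers noiseless mixtures", {
  g <- make_mixture("EEDPIHLR", vil_scheme(), c(40, 42, 18))
  fit <- fit_multi_state(g$spectrum, g$truth$states, g$patterns,
                         charge = 1, fwhm = g$truth$fwhm)
  expect_equal(fit$states$weight, c(40, 42, 18), tolerance = 0.5 / 40)
  expect_equal(sum(fit$states$weight), 100, tolerance = 1e-6)
  expect_true(all(fit$states$weight >= 0))
  # only the fully labeled state present
  g2 <- make_mixture("EEDPIHLR", vil_scheme(), c(0, 0, 100))
  fit2 <- fit_multi_state(g2$spectrum, g2$truth$states, g2$patterns,
                          charge = 1, fwhm = g2$truth$fwhm)
  expect_equal(fit2$states$weight, c(0, 0, 100), tolerance = 1e-6)
  # combined model fits no worse than any single scaled state
  y <- fit$model$intensity
  grid <- profile_mz(fit$model)
  obs <- approx(g$spectrum$mz, g$spectrum$intensity, grid,
                yleft = 0, yright = 0)$y
  for (p in state_patterns("EEDPIHLR", g$truth$states)) {
    prof <- render_profile(p, 1, g$truth$fwhm, 1000,
                           range(grid))$intensity[seq_along(grid)]
    alpha <- sum(obs * prof) / sum(prof^2)
    expect_gte(sqrt(mean((obs - alpha * prof)^2)) + 1e-12, fit$rmse)
  }
})

test_that("multi-state agrees with the two-state route", {
  # two-state subset: unlabeled + fully labeled SAMPEGYVQER at 65/35
  pep <- "SAMPEGYVQER"
  scheme <- label_scheme(list(V = list(n15N = 1, n13C = 5,
                                       units = list(c(n15N = 1, n13C = 5)))))
  g <- make_mixture(pep, scheme, c(65, 35))
  expect_identical(nrow(g$truth$states), 2L)
  fitm <- fit_multi_state(g$spectrum, g$truth$states, g$patterns,
                          charge = 1, fwhm = g$truth$fwhm)
  rng <- range(profile_mz(fitm$model))
  u <- render_profile(g$patterns[[1]], 1, g$truth$fwhm, 1000, rng)
  l <- render_profile(g$patterns[[2]], 1, g$truth$fwhm, 1000, rng)
  fit2 <- fit_two_state(g$spectrum, u, l, step = 0.1)
  expect_lt(abs(fitm$states$weight[2] - fit2$states$weight[2]), 0.1)
})

test_that("fine-structure mixtures are recovered at high resolving power", {
  g <- make_mixture("YFHHNSDFYIPK", kgs_scheme(lys_n15 = 2),
                    c(25, 30, 25, 12, 8), mode = "fine",
                    resolving_power = 1400000,
                    extras = list(c(n15N = 1, n13C = 2)))
  # fine structure resolves the isobaric N = 3 pair, so every state is
  # fitted at its own monoisotopic position (tie = "all")
  fit <- fit_multi_state(g$spectrum, g$truth$states, g$patterns,
                         charge = 1, fwhm = g$truth$fwhm,
                         points_per_Da = 10000, tie = "all")
  expect_lt(max(abs(fit$states$weight - g$truth$weights)), 0.5)
})

test_that("recovered weights never decrease when the true weight grows", {
  ws <- list(c(50, 30, 20), c(40, 40, 20), c(30, 50, 20))
  rec <- vapply(ws, function(w) {
    g <- make_mixture("EEDPIHLR", vil_scheme(), w)
    fit_multi_state(g$spectrum, g$truth$states, g$patterns,
                    charge = 1, fwhm = g$truth$fwhm)$states$weight[2]
  }, 0)
  expect_false(is.unsorted(rec, strictly = TRUE))
})

test_that("isobaric states follow the first-occurrence rule", {
  pep <- "YFHHNSDFYIPK"
  states <- enumerate_states(pep, kgs_scheme(lys_n15 = 2),
                             list(c(n15N = 1, n13C = 2)))
  # truth places weight on [15N3]; the extra [15N,13C2] at N = 3 is skipped
  g <- make_mixture(pep, kgs_scheme(lys_n15 = 2), c(40, 30, 20, 10, 0),
                    extras = list(c(n15N = 1, n13C = 2)))
  fit <- fit_multi_state(g$spectrum, g$truth$states, g$patterns,
                         charge = 1, fwhm = g$truth$fwhm)
  expect_equal(fit$states$weight, c(40, 30, 20, 10, 0), tolerance = 0.02)
  expect_match(fit$diagnostics, "first-occurrence", all = FALSE)
})

test_that("fwhm measurement matches the closed form", {
  sigma <- 0.004
  grid <- seq(999.8, 1000.2, by = 1e-4)
  obs <- observed_spectrum(grid, dnorm(grid, 1000, sigma))
  expect_equal(measure_fwhm(obs, 1000), 2.3548 * sigma, tolerance = 0.01)
  # rendered profile at R = 80000, m/z ~1000 has fwhm = m/R
  pat <- structure(data.frame(mass = 1000 - 1.00727646, nshift = 0L,
                              abundance = 1),
                   mode = "nominal",
                   class = c("isotope_pattern", "data.frame"))
  prof <- render_profile(pat, 1, fwhm = 1000 / 80000, points_per_Da = 10000)
  expect_equal(measure_fwhm(as_observed(prof), 1000), 0.0125,
               tolerance = 1e-3)
  flat <- observed_spectrum(grid, rep(1, length(grid)))
  expect_error(measure_fwhm(flat, 1000), "unresolved")
})

test_that("single-point calibration corrects multiplicative m/z error", {
  pat <- simulate_pattern(peptide_composition("YFHHNSDFYIPK"))
  prof <- render_profile(pat, 1, 0.015, 2000)
  obs <- as_observed(prof)
  ref <- mz(min(pat$mass), 1)
  # already exact: identity
  cal0 <- calibrate_single_point(obs, ref)
  expect_equal(attr(cal0, "calibration"), 1, tolerance = 5e-7)
  # +5 ppm global shift removed to < 0.01 ppm on the reference peak
  shifted <- observed_spectrum(obs$mz * (1 + 5e-6), obs$intensity)
  cal <- calibrate_single_point(shifted, ref)
  apex <- cal$mz[which.max(cal$intensity)]
  expect_lt(abs(apex - ref) / ref * 1e6, 0.01)
  expect_equal(attr(cal, "calibration"), 1 / (1 + 5e-6), tolerance = 5e-7)
  expect_error(calibrate_single_point(obs, ref * 1.1), "no peak")
})

test_that("mass defect separates 15N from 13C label compositions", {
  # theoretical separation: [15N3] vs [15N,13C2] additions
  expect_equal(2 * iso_constants[["shift_13C"]] - 2 * iso_constants[["shift_15N"]],
               0.0126399, tolerance = 1e-6)
  pep <- "YFHHNSDFYIPK"
  sch <- kgs_scheme()   # K + S: states (0,0), (1,0), (2,0)
  base <- enumerate_states(pep, sch)
  cands <- list(labeling_state(3, 0), labeling_state(1, 2))
  # data generated from the [15N,13C2] candidate
  g <- make_mixture(pep, sch, c(35, 30, 20, 15), resolving_power = 100000,
                    points_per_Da = 10000,
                    extras = list(c(n15N = 1, n13C = 2)))
  res <- mass_defect_discriminate(g$spectrum, pep, base, cands,
                                  isotope_index = 3, charge = 1,
                                  fwhm = g$truth$fwhm)
  expect_lt(abs(res$error_ppm[2]), abs(res$error_ppm[1]))
  expect_true(res$preferred[2])
  # identical candidates score identically
  res2 <- mass_defect_discriminate(g$spectrum, pep, base,
                                   list(labeling_state(1, 2),
                                        labeling_state(1, 2)),
                                   isotope_index = 3, charge = 1,
                                   fwhm = g$truth$fwhm)
  expect_equal(res2$error_ppm[1], res2$error_ppm[2], tolerance = 1e-9)
  expect_error(mass_defect_discriminate(g$spectrum, pep, base,
                                        list(labeling_state(1, 0),
                                             labeling_state(1, 2)),
                                        isotope_index = 3, charge = 1,
                                        fwhm = g$truth$fwhm),
               "share a neutron count")
})
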