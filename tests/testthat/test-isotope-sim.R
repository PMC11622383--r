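test_that("single- and two-carbon patterns match the closed form", {
  p <- simulate_pattern(parse_formula("C"), prune_threshold = 0)
  expect_equal(p$mass, c(12, 13.0033548378), tolerance = 1e-10)
  expect_equal(p$abundance, c(0.9893, 0.0107), tolerance = 1e-12)
  # binomial expansion (0.9893 + 0.0107)^2
  p2 <- simulate_pattern(parse_formula("C2"), prune_threshold = 1e-6)
  expect_equal(p2$abundance, c(0.97871449, 0.02117102, 0.00011449),
               tolerance = 1e-8)
})

test_that("label pseudo-elements shift every centroid rigidly", {
  base <- simulate_pattern(parse_formula("C2"), prune_threshold = 1e-6)
  lab <- simulate_pattern(parse_formula("C2[C13label]"),
                          prune_threshold = 1e-6)
  # {C2} convolved with a single-isotope distribution is a pure shift
  expect_equal(lab$abundance, base$abundance, tolerance = 1e-12)
  expect_equal(lab$mass, base$mass + 13.0033548378, tolerance = 1e-10)

  comp <- peptide_composition("EEDPIHLR")
  u <- simulate_pattern(comp, prune_threshold = 1e-6)
  l <- simulate_pattern(apply_labels(comp, n15N = 2),
                        prune_threshold = 1e-6)
  expect_equal(min(l$mass) - min(u$mass), 2 * 0.9970348932,
               tolerance = 1e-9)
  expect_equal(min(simulate_pattern(apply_labels(comp, n13C = 1))$mass) -
                 min(u$mass), 1.0033548378, tolerance = 1e-9)
})

test_that("abundances normalize to 1 regardless of pruning", {
  for (f in c("C2", "H2O", "C34H53N7O15")) {
    for (pr in c(1e-5, 1e-8)) {
      p <- simulate_pattern(parse_formula(f), mode = "fine",
                            prune_threshold = pr)
      expect_equal(sum(p$abundance), 1, tolerance = 1e-9,
                   label = paste(f, pr))
      expect_false(is.unsorted(p$mass))
      expect_true(all(p$abundance >= 0))
    }
  }
})

test_that("convolution, FFT and brute-force paths agree", {
  panel <- list(
    parse_formula("H2O"),
    parse_formula("C2"),
    parse_formula("C10H20S2"),
    peptide_composition("PEPTIDE"),
    apply_labels(peptide_composition("PEPTIDE"), n13C = 2, n15N = 1),
    peptide_composition("EEDPIHLR")
  )
  for (comp in panel) {
    lbl <- format(comp)
    fine <- simulate_pattern(comp, mode = "fine", prune_threshold = 1e-8)
    bf <- brute_force_pattern(comp, prune_threshold = 1e-8)
    expect_equal(nrow(fine), nrow(bf), label = lbl)
    k <- vapply(fine$mass, function(m) which.min(abs(bf$mass - m)), 0L)
    expect_lt(max(abs(fine$mass - bf$mass[k])), 1e-9)
    expect_lt(max(abs(fine$abundance - bf$abundance[k])), 1e-6)
    # nominal aggregation of both paths agrees too (centroid masses are
    # compared only where abundance is appreciable: the weighted mean of a
    # ~1e-8 tail peak is dominated by which sub-threshold isotopologues
    # survived pruning, so it is not a meaningful oracle quantity)
    nom <- simulate_pattern(comp, mode = "nominal", prune_threshold = 1e-8)
    agg <- aggregate_pattern(bf)
    j <- match(nom$nshift, agg$nshift)
    aj <- ifelse(is.na(j), 0, agg$abundance[j])
    expect_lt(max(abs(nom$abundance - aj)), 1e-6)
    big <- which(nom$abundance >= 1e-4 & !is.na(j))
    # 1e-5 Da (~0.01 ppm): the sequential oracle prunes intermediate
    # states, which perturbs weighted-mean tail masses slightly more than
    # the per-element route
    expect_lt(max(abs(nom$mass[big] - agg$mass[j[big]])), 1e-5)
    # FFT path against the convolution reference
    fft <- simulate_pattern(comp, mode = "nominal", prune_threshold = 1e-8,
                            method = "fft")
    j <- match(nom$nshift, fft$nshift)
    expect_lt(max(abs(nom$abundance - fft$abundance[j])), 1e-6)
    big <- which(nom$abundance >= 1e-4)
    expect_lt(max(abs(nom$mass[big] - fft$mass[j[big]])), 1e-6)
  }
  expect_error(brute_force_pattern(peptide_composition(
    strrep("W", 30))), "oracle guard")
})

test_that("profile rendering places and scales Gaussians correctly", {
  single <- structure(data.frame(mass = 1000, nshift = 0L, abundance = 1),
                      mode = "nominal",
                      class = c("isotope_pattern", "data.frame"))
  prof <- render_profile(single, charge = 1, fwhm = 0.0125,
                         points_per_Da = 10000)
  grid <- profile_mz(prof)
  expect_equal(grid[which.max(prof$intensity)], 1001.00727646,
               tolerance = 2e-4)
  # integrated area proportional to abundance
  expect_equal(sum(prof$intensity) * prof$spacing, 1, tolerance = 1e-6)
  # two equal, well-separated centroids: equal maxima
  two <- structure(data.frame(mass = c(1000, 1001), nshift = 0:1,
                              abundance = c(0.5, 0.5)),
                   mode = "nominal",
                   class = c("isotope_pattern", "data.frame"))
  p2 <- render_profile(two, charge = 1, fwhm = 0.01, points_per_Da = 10000)
  g2 <- profile_mz(p2)
  m1 <- max(p2$intensity[g2 < 1001.5])
  m2 <- max(p2$intensity[g2 >= 1001.5])
  expect_equal(m1, m2, tolerance = 1e-9)
  # coarse grid warning
  expect_warning(render_profile(single, charge = 1, fwhm = 0.0125,
                                points_per_Da = 100), "coarse")
})

test_that("profile rendering is linear in the pattern abundances", {
  pat <- simulate_pattern(peptide_composition("PEPTIDE"))
  a <- pat; a$abundance <- pat$abundance * 0.3
  b <- pat; b$abundance <- pat$abundance * 0.7
  rng <- c(799, 806)
  pa <- render_profile(a, 1, 0.01, 1000, rng)
  pb <- render_profile(b, 1, 0.01, 1000, rng)
  pall <- render_profile(pat, 1, 0.01, 1000, rng)
  expect_lt(max(abs(pa$intensity + pb$intensity - pall$intensity)), 1e-12)
})

test_that(".xy and .asc readers/writers round-trip", {
  pat <- simulate_pattern(parse_formula("C2"))
  prof <- render_profile(pat, 1, 0.01, points_per_Da = 500)
  path <- withr::local_tempfile(fileext = ".xy")
  write_xy(prof, path)
  back <- read_xy(path)
  expect_equal(back$mz, profile_mz(prof), tolerance = 1e-8)
  expect_equal(back$intensity, prof$intensity, tolerance = 1e-6)
  asc <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("# masslist", "500.1 10", "; comment", "400.2, 5", "300.5"),
             asc)
  ml <- read_asc(asc)
  expect_equal(ml$mz, c(300.5, 400.2, 500.1))
  expect_equal(ml$intensity, c(NA, 5, 10))
})
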