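# Synthetic FTICR-like spectra with known ground truth.  No raw spectra
# ship with the package; every fitting operation is validated against
# profiles generated here: Gaussian peaks at a stated resolving power,
# known state mixing weights, additive white noise, fixed seed.

#' Specify a synthetic labeled-peptide spectrum
#'
#' @param peptide peptide sequence string.
#' @param scheme `label_scheme`.
#' @param weights percent abundance per labeling state (aligned with
#'   `enumerate_states(peptide, scheme)`; must sum to 100).
#' @param charge spectrum charge.
#' @param resolving_power instrument resolving power at the peptide's
#'   monoisotopic m/z (fwhm = m/z / R); 80000 emulates the unit-resolution
#'   regime, 1400000 the fine-structure regime.
#' @param points_per_Da grid density (default 1000; use 10000 with
#'   `mode = "fine"`).
#' @param noise_sd additive Gaussian noise s.d. as a fraction of the
#'   maximum intensity.
#' @param baseline constant baseline offset (same units).
#' @param seed RNG seed; fixes the output bit-exactly.
#' @param mode pattern mode for the component simulations.
#' @param extras extra states passed to [enumerate_states()].
#' @return `synth_spec` object.
#' @export
synth_spec <- function(peptide, scheme, weights, charge = 1,
                       resolving_power = 80000, points_per_Da = 1000,
                       noise_sd = 0, baseline = 0, seed = 1,
                       mode = c("nominal", "fine"), extras = list()) {
  mode <- match.arg(mode)
  states <- enumerate_states(peptide, scheme, extras)
  if (length(weights) != nrow(states))
    stop("need ", nrow(states), " weights (one per labeling state), got ",
         length(weights))
  if (abs(sum(weights) - 100) > 1e-6)
    stop("weights must sum to 100, got ", sum(weights))
  if (any(weights < 0)) stop("weights must be nonnegative")
  stopifnot(resolving_power > 0, noise_sd >= 0)
  structure(list(peptide = peptide, scheme = scheme, states = states,
                 weights = weights, charge = as.integer(charge),
                 resolving_power = resolving_power,
                 points_per_Da = points_per_Da, noise_sd = noise_sd,
                 baseline = baseline, seed = as.integer(seed),
                 mode = mode),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec>", x$peptide, "|", nrow(x$states), "states | R =",
      x$resolving_power, "| noise", x$noise_sd, "| seed", x$seed, "\n")
  invisible(x)
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic observed spectrum
#'
#' Renders each labeling state's pattern at `fwhm = m/z / R` on a common
#' grid, combines them with the specified weights, then adds the baseline
#' and seeded Gaussian noise (truncated at zero intensity).
#'
#' @param spec `synth_spec`.
#' @param table isotope table.
#' @return list with `spectrum` (`observed_spectrum`), `truth` (state
#'   table with true weights, fwhm, charge, seed) and `components`
#'   (per-state rendered profiles, weight-scaled).
#' @export
generate_spectrum <- function(spec, table = default_isotope_table()) {
  stopifnot(inherits(spec, "synth_spec"))
  states <- spec$states
  patterns <- lapply(seq_len(nrow(states)), function(i)
    simulate_pattern(labeled_composition(spec$peptide, states[i, ]),
                     mode = spec$mode, table = table))
  proton <- iso_constants[["proton"]]
  mono_mz <- (min(patterns[[1]]$mass) + spec$charge * proton) / spec$charge
  fwhm <- mono_mz / spec$resolving_power
  hi <- max(vapply(patterns, function(p) max(p$mass), 0))
  rng <- c(mono_mz - 2, (hi + spec$charge * proton) / spec$charge + 2)
  profs <- lapply(patterns, render_profile, charge = spec$charge,
                  fwhm = fwhm, points_per_Da = spec$points_per_Da,
                  mz_range = rng)
  combined <- Reduce(`+`, Map(function(p, w) w / 100 * p$intensity,
                              profs, as.list(spec$weights)))
  noisy <- .with_seed(spec$seed, {
    combined + spec$baseline +
      stats::rnorm(length(combined), 0, spec$noise_sd * max(combined))
  })
  grid <- profile_mz(profs[[1]])
  list(spectrum = observed_spectrum(grid, pmax(noisy, 0), type = "profile"),
       truth = list(states = states, weights = spec$weights, fwhm = fwhm,
                    charge = spec$charge, seed = spec$seed,
                    mode = spec$mode, mono_mz = mono_mz),
       components = Map(function(p, w) {
         p$intensity <- w / 100 * p$intensity
         p
       }, profs, as.list(spec$weights)))
}

# default peptide/scheme panel: labeled tryptic peptides whose VIL/KGS
# state sets are free of neutron-count collisions
.recovery_panel <- function() {
  list(
    list(peptide = "EEDPIHLR", scheme = vil_scheme()),
    list(peptide = "SAMPEGYVQER", scheme = vil_scheme()),
    list(peptide = "FEGDTLVNR", scheme = kgs_scheme()),
    list(peptide = "YFHHNSDFYIPK", scheme = kgs_scheme(lys_n15 = 2))
  )
}

#' Weight-recovery benchmark over random synthetic mixtures
#'
#' Draws random peptides (from a fixed panel of labeled tryptic peptides
#' under the VIL and KGS schemes) and random state weights, generates a
#' synthetic spectrum per trial at each noise level, refits it with
#' [fit_multi_state()], and summarizes the per-state weight errors.
#'
#' @param n_trials trials per noise level (>= 1).
#' @param seed master seed; per-trial seeds are derived from it.
#' @param noise_levels noise s.d. levels (fraction of max intensity).
#' @param resolving_power instrument resolving power.
#' @param panel optional list of `list(peptide =, scheme =)` entries.
#' @return data frame, one row per noise level: `noise`, `n_trials`,
#'   `median_abs_error`, `max_abs_error`, `bias` (mean signed error), all
#'   in percentage points; per-trial errors in the `"errors"` attribute.
#' @export
recovery_suite <- function(n_trials = 200, seed = 1,
                           noise_levels = c(0, 0.01),
                           resolving_power = 80000, panel = NULL) {
  stopifnot(n_trials >= 1)
  if (is.null(panel)) panel <- .recovery_panel()
  rows <- list()
  all_err <- list()
  for (nl in noise_levels) {
    errs <- .with_seed(seed, {
      unlist(lapply(seq_len(n_trials), function(tr) {
        entry <- panel[[sample.int(length(panel), 1L)]]
        k <- nrow(enumerate_states(entry$peptide, entry$scheme))
        w <- stats::runif(k, 0.02, 1)
        w <- 100 * w / sum(w)
        sp <- synth_spec(entry$peptide, entry$scheme, weights = w,
                         resolving_power = resolving_power,
                         noise_sd = nl,
                         seed = sample.int(2^30, 1L))
        g <- generate_spectrum(sp)
        pats <- lapply(seq_len(k), function(i)
          simulate_pattern(labeled_composition(entry$peptide,
                                               g$truth$states[i, ])))
        fit <- fit_multi_state(g$spectrum, g$truth$states, pats,
                               charge = 1, fwhm = g$truth$fwhm)
        fit$states$weight - w
      }))
    })
    all_err[[as.character(nl)]] <- errs
    rows[[length(rows) + 1L]] <- data.frame(
      noise = nl, n_trials = n_trials,
      median_abs_error = stats::median(abs(errs)),
      max_abs_error = max(abs(errs)),
      bias = mean(errs))
  }
  out <- do.call(rbind, rows)
  attr(out, "errors") <- all_err
  out
}
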