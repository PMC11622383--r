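# Percent-incorporation fitting: linear combinations of simulated isotope
# patterns fit to an observed spectrum.  Two routes:
#   * two-state RMSE grid fit, (1-B)*unlabeled + B*labeled over B = 0..100%;
#   * multi-state greedy nearest-neighbor scaling, walking the labeling
#     states in mass order and raising each coefficient until the combined
#     model matches the observed intensity at that state's monoisotopic
#     position, then normalizing the coefficients to percentages.
# The identical procedure serves unit-resolution and fine-structure data;
# only the patterns and the measured fwhm change.

#' Construct an observed spectrum
#'
#' @param mzv m/z values (ascending, or sortable).
#' @param intensity nonnegative intensities (arbitrary units).
#' @param type `"profile"` (continuous trace) or `"centroid"`.
#' @return `observed_spectrum`: data frame `mz`, `intensity`.
#' @export
observed_spectrum <- function(mzv, intensity, type = c("profile", "centroid")) {
  type <- match.arg(type)
  stopifnot(length(mzv) == length(intensity), all(intensity >= 0))
  o <- order(mzv)
  structure(data.frame(mz = mzv[o], intensity = intensity[o]),
            type = type, class = c("observed_spectrum", "data.frame"))
}

#' Observed spectrum from a rendered or generated profile
#' @param profile `mz_profile`.
#' @export
as_observed <- function(profile) {
  observed_spectrum(profile_mz(profile), pmax(profile$intensity, 0),
                    type = "profile")
}

# resample an observed spectrum onto a uniform grid (zero outside support)
.resample <- function(obs, grid) {
  stats::approx(obs$mz, obs$intensity, xout = grid,
                yleft = 0, yright = 0)$y
}

.profile_grid_of <- function(p) {
  list(start = p$start, spacing = p$spacing, n = length(p$intensity))
}

#' Two-state percent-incorporation fit
#'
#' Grid search over the labeled fraction B in 0..100% at the given step:
#' the combined model `(1 - B/100) * unlabeled + (B/100) * labeled` is
#' amplitude-scaled to the data by least squares and scored by RMSE; the B
#' of the best-fitting combination is the percent incorporation.
#'
#' @param obs `observed_spectrum` (profile).
#' @param unlabeled,labeled `mz_profile` objects on a common grid.
#' @param step grid step in percent (default 0.1; must divide 100).
#' @return `fit_result` with states `unlabeled`/`labeled`, weights
#'   `(100 - B, B)`.
#' @export
fit_two_state <- function(obs, unlabeled, labeled, step = 0.1) {
  g1 <- .profile_grid_of(unlabeled); g2 <- .profile_grid_of(labeled)
  if (abs(g1$start - g2$start) > 1e-9 || abs(g1$spacing - g2$spacing) > 1e-12 ||
      g1$n != g2$n)
    stop("unlabeled and labeled profiles must share a common grid")
  if (abs((100 / step) - round(100 / step)) > 1e-9)
    stop("step must divide 100")
  grid <- profile_mz(unlabeled)
  y <- .resample(obs, grid)
  if (sum(y) <= 0) stop("observed spectrum has no intensity on the fit window")
  U <- unlabeled$intensity; L <- labeled$intensity
  bs <- seq(0, 100, by = step)
  best <- NULL
  for (b in bs) {
    m <- (1 - b / 100) * U + (b / 100) * L
    denom <- sum(m * m)
    if (denom == 0) next
    alpha <- sum(y * m) / denom
    r <- sqrt(mean((y - alpha * m)^2))
    if (is.null(best) || r < best$rmse)       # first occurrence wins ties
      best <- list(b = b, rmse = r, alpha = alpha, model = alpha * m)
  }
  model <- unlabeled
  model$intensity <- best$model
  .new_fit(descriptors = c("unlabeled", "labeled"),
           weights = c(100 - best$b, best$b),
           coefficients = c((1 - best$b / 100), best$b / 100) * best$alpha,
           rmse = best$rmse, model = model, fwhm = unlabeled$fwhm,
           diagnostics = character(0))
}

.new_fit <- function(descriptors, weights, coefficients, rmse, model, fwhm,
                     diagnostics) {
  w <- weights
  if (sum(w) > 0) w <- 100 * w / sum(w)
  structure(list(
    states = data.frame(descriptor = descriptors, weight = w,
                        coefficient = coefficients),
    rmse = rmse, model = model, fwhm = fwhm, diagnostics = diagnostics),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> rmse =", signif(x$rmse, 5), " fwhm =",
      signif(x$fwhm, 5), "\n")
  df <- x$states
  df$weight <- round(df$weight, 2)
  print.data.frame(df, row.names = FALSE)
  if (length(x$diagnostics)) cat("notes:", paste(x$diagnostics, "\n"))
  invisible(x)
}

# nearest-neighbor peak: the local maximum closest to pos within +/- half;
# falls back to the window's most intense point when no interior maximum
# exists (flat or monotone window)
.window_peak <- function(grid, y, pos, half) {
  idx <- which(grid >= pos - half & grid <= pos + half)
  if (!length(idx)) return(NA_integer_)
  n <- length(y)
  interior <- idx[idx > 1L & idx < n]
  lm <- interior[y[interior] > y[interior - 1L] &
                   y[interior] >= y[interior + 1L] & y[interior] > 0]
  if (!length(lm)) return(idx[which.max(y[idx])])
  lm[which.min(abs(grid[lm] - pos))]
}

#' Multi-state greedy incorporation fit
#'
#' Implements the sequential nearest-neighbor scaling procedure: (1) find
#' the lowest-mass state present (observed peak at its monoisotopic
#' position at least `presence_snr` times the local noise floor); (2)
#' scale its pattern to the observed nearest-neighbor peak; (3) for each
#' subsequent state in neutron-count order, raise its coefficient until the
#' combined model at that state's monoisotopic position matches the
#' observed nearest-neighbor intensity (floored at 0 when already matched
#' or exceeded); (4) normalize the coefficients so they sum to 100.  The
#' coefficient raise is solved analytically -- the result is identical to
#' literal iteration but deterministic.
#'
#' States sharing a neutron count are isobaric: under `tie = "first"` the
#' first occurrence in the set is fitted and later ones are skipped with a
#' diagnostic (use [mass_defect_discriminate()] or fine-structure patterns
#' to resolve them).
#'
#' @param obs `observed_spectrum`.
#' @param states `state_set` (ordered by neutron count).
#' @param patterns list of `isotope_pattern`, one per state row.
#' @param charge spectrum charge.
#' @param fwhm peak width (m/z); measure it from the data with
#'   [measure_fwhm()].
#' @param points_per_Da model grid density (10000 recommended for fine
#'   structure).
#' @param tol_mz nearest-neighbor matching half-window; default
#'   `max(0.5 * fwhm, 5 ppm)`.
#' @param presence_snr presence threshold for the lowest-mass state, as a
#'   multiple of the window's median absolute intensity.
#' @param tie `"first"` (first-occurrence rule) or `"all"` (fit every
#'   state, including isobaric ones, in order).
#' @return `fit_result`: per-state weights summing to 100, raw
#'   coefficients, RMSE over the fit window, combined model profile.
#' @export
fit_multi_state <- function(obs, states, patterns, charge = 1, fwhm,
                            points_per_Da = 1000, tol_mz = NULL,
                            presence_snr = 3, tie = c("first", "all")) {
  tie <- match.arg(tie)
  stopifnot(inherits(states, "state_set"), length(patterns) == nrow(states),
            fwhm > 0)
  if (is.unsorted(states$neutrons))
    stop("states must be ordered by neutron count")
  proton <- iso_constants[["proton"]]
  mono_mz <- vapply(patterns, function(p)
    (min(p$mass) + charge * proton) / charge, 0)
  lastc <- max(vapply(patterns, function(p)
    (max(p$mass) + charge * proton) / charge, 0))
  rng <- c(min(mono_mz) - 2 * fwhm, lastc + 2 * fwhm)
  profs <- lapply(patterns, render_profile, charge = charge, fwhm = fwhm,
                  points_per_Da = points_per_Da, mz_range = rng)
  grid <- profile_mz(profs[[1]])
  y <- .resample(obs, grid)
  if (sum(y) <= 0) stop("observed spectrum has no intensity on the fit window")
  floor_noise <- stats::median(abs(y))
  if (is.null(tol_mz)) tol_mz <- pmax(0.5 * fwhm, 5e-6 * mono_mz)
  tol_mz <- rep_len(tol_mz, length(mono_mz))

  n <- nrow(states)
  coef <- numeric(n)
  diag <- character(0)
  combined <- numeric(length(grid))
  seen_n <- integer(0)
  started <- FALSE
  for (i in seq_len(n)) {
    if (tie == "first" && states$neutrons[i] %in% seen_n) {
      diag <- c(diag, paste0("isobaric state ", states$descriptor[i],
                             " (N=", states$neutrons[i],
                             ") skipped: first-occurrence rule"))
      next
    }
    pk <- .window_peak(grid, y, mono_mz[i], tol_mz[i])
    if (is.na(pk)) {
      diag <- c(diag, paste0("no observed peak within tolerance of ",
                             states$descriptor[i]))
      next
    }
    target <- y[pk]
    if (!started) {
      # presence test for the lowest-mass species
      if (target < presence_snr * floor_noise || target <= 0) {
        diag <- c(diag, paste0("state ", states$descriptor[i],
                               " below the noise floor"))
        next
      }
      started <- TRUE
    }
    own <- profs[[i]]$intensity[pk]
    if (own <= 0) next
    ci <- (target - combined[pk]) / own
    if (ci > 0) {
      coef[i] <- ci
      combined <- combined + ci * profs[[i]]$intensity
    }
    seen_n <- c(seen_n, states$neutrons[i])
  }
  if (all(coef == 0)) stop("no labeling state matched the observed spectrum")
  model <- profs[[1]]
  model$intensity <- combined
  .new_fit(descriptors = states$descriptor, weights = coef,
           coefficients = coef,
           rmse = sqrt(mean((y - combined)^2)),
           model = model, fwhm = fwhm, diagnostics = diag)
}

#' Measure a peak's full width at half maximum
#'
#' Finds the local apex nearest `peak_mz` and linearly interpolates the
#' half-height crossings on both sides.
#'
#' @param obs `observed_spectrum` (profile data).
#' @param peak_mz approximate apex position.
#' @param search half-window (m/z) in which to locate the apex.
#' @return fwhm in m/z units.
#' @export
measure_fwhm <- function(obs, peak_mz, search = 0.25) {
  idx <- which(obs$mz >= peak_mz - search & obs$mz <= peak_mz + search)
  if (!length(idx)) stop("no data near m/z ", peak_mz)
  apex <- idx[which.max(obs$intensity[idx])]
  h <- obs$intensity[apex]
  if (h <= 0) stop("no peak found near m/z ", peak_mz)
  half <- h / 2
  cross <- function(dir) {
    i <- apex
    repeat {
      j <- i + dir
      if (j < 1 || j > nrow(obs))
        stop("peak at m/z ", signif(obs$mz[apex], 8),
             " is unresolved: no half-height crossing")
      if (obs$intensity[j] <= half) {
        # linear interpolation between j and i
        f <- (obs$intensity[i] - half) / (obs$intensity[i] - obs$intensity[j])
        return(obs$mz[i] + f * (obs$mz[j] - obs$mz[i]))
      }
      i <- j
    }
  }
  cross(1L) - cross(-1L)
}

#' Single-point internal calibration
#'
#' Multiplies the m/z axis by `reference / observed_apex` so the peak at
#' `reference_mz` lands on the reference value (residual < 0.1 ppm by
#' construction).
#'
#' @param obs `observed_spectrum`.
#' @param reference_mz theoretical m/z of the calibrant peak.
#' @param tol_ppm search window around the reference (default 20 ppm).
#' @return recalibrated `observed_spectrum`; the scale factor is stored in
#'   the `"calibration"` attribute.
#' @export
calibrate_single_point <- function(obs, reference_mz, tol_ppm = 20) {
  half <- reference_mz * tol_ppm * 1e-6
  pk <- .window_peak(obs$mz, obs$intensity, reference_mz, half)
  if (is.na(pk) || obs$intensity[pk] <= 0)
    stop("no peak within ", tol_ppm, " ppm of m/z ", reference_mz)
  fac <- reference_mz / obs$mz[pk]
  out <- observed_spectrum(obs$mz * fac, obs$intensity,
                           type = attr(obs, "type"))
  attr(out, "calibration") <- fac
  out
}

#' Discriminate isobaric labeling states by isotopic mass defect
#'
#' For candidate states sharing a neutron count, refits the spectrum with
#' each candidate in turn and compares the centroid of the specified
#' isotope peak in the scaled combined model against the observed apex.
#' The candidate with the smaller absolute ppm error is preferred: every
#' 15N-for-13C swap moves the peak by 0.0063199 Da.
#'
#' @param obs calibrated `observed_spectrum`.
#' @param peptide peptide sequence string.
#' @param base_states `state_set` of the undisputed states.
#' @param candidates list of `labeling_state` (equal neutron counts).
#' @param isotope_index which isotope peak to test (k = added neutrons of
#'   the candidates, i.e. A + k).
#' @param charge,fwhm,points_per_Da as in [fit_multi_state()].
#' @param mode pattern mode used for the refit.
#' @param table isotope table.
#' @return data frame: candidate descriptor, theoretical model centroid,
#'   observed apex, signed error in ppm (`observed - model`), `preferred`
#'   flag; `NA` ppm marks an indeterminate candidate (isotope peak absent).
#' @export
mass_defect_discriminate <- function(obs, peptide, base_states, candidates,
                                     isotope_index, charge = 1, fwhm,
                                     points_per_Da = 10000,
                                     mode = c("nominal", "fine"),
                                     table = default_isotope_table()) {
  mode <- match.arg(mode)
  ncand <- vapply(candidates, neutron_count, 0L)
  if (length(unique(ncand)) != 1L)
    stop("candidates must share a neutron count")
  base_df <- as.data.frame(base_states)
  rows <- lapply(candidates, function(cand) {
    df <- rbind(base_df,
                data.frame(n15N = cand$n15N, n13C = cand$n13C,
                           descriptor = cand$descriptor, extra = TRUE,
                           neutrons = neutron_count(cand)))
    df <- df[order(df$neutrons), , drop = FALSE]
    rownames(df) <- NULL
    ss <- structure(df, peptide = peptide,
                    class = c("state_set", "data.frame"))
    pats <- lapply(seq_len(nrow(ss)), function(i)
      simulate_pattern(labeled_composition(peptide, ss[i, ]), mode = mode,
                       table = table))
    fit <- fit_multi_state(obs, ss, pats, charge = charge, fwhm = fwhm,
                           points_per_Da = points_per_Da)
    mono <- mz(min(pats[[1]]$mass), charge)
    lo <- mono + (isotope_index - 0.5) / charge
    hi <- mono + (isotope_index + 0.5) / charge
    grid <- profile_mz(fit$model)
    win <- grid >= lo & grid <= hi
    ymod <- fit$model$intensity[win]
    yobs <- .resample(obs, grid)[win]
    if (!any(win) || max(yobs) <= 0 || max(ymod) <= 0)
      return(data.frame(descriptor = cand$descriptor, model_mz = NA_real_,
                        observed_mz = NA_real_, error_ppm = NA_real_))
    # centroid over the top of the model peak; apex of the observation
    top <- ymod >= 0.05 * max(ymod)
    model_mz <- sum(grid[win][top] * ymod[top]) / sum(ymod[top])
    observed_mz <- grid[win][which.max(yobs)]
    data.frame(descriptor = cand$descriptor, model_mz = model_mz,
               observed_mz = observed_mz,
               error_ppm = (observed_mz - model_mz) / model_mz * 1e6)
  })
  out <- do.call(rbind, rows)
  out$preferred <- FALSE
  ok <- which(!is.na(out$error_ppm))
  if (length(ok)) out$preferred[ok[which.min(abs(out$error_ppm[ok]))]] <- TRUE
  out
}

#' Write a fit report
#'
#' @param fit `fit_result`.
#' @param path output file; `.json` extension switches to JSON, anything
#'   else is written as TSV.
#' @param calibration optional calibration factor to record.
#' @export
write_fit_report <- function(fit, path, calibration = NA_real_) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      states = fit$states, rmse = fit$rmse, fwhm = fit$fwhm,
      calibration = calibration, diagnostics = fit$diagnostics),
      path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    df <- fit$states
    df$rmse <- fit$rmse
    df$fwhm <- fit$fwhm
    df$calibration <- calibration
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Overlay plot of an incorporation fit
#'
#' Observed spectrum (solid), combined model (thick) and per-state scaled
#' components (dashed).
#'
#' @param x `fit_result`.
#' @param obs the observed spectrum that was fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fit_result <- function(x, obs = NULL, ...) {
  grid <- profile_mz(x$model)
  graphics::plot(grid, x$model$intensity, type = "l", lwd = 2,
                 col = "darkorange", xlab = "m/z", ylab = "intensity", ...)
  if (!is.null(obs)) {
    win <- obs$mz >= min(grid) & obs$mz <= max(grid)
    graphics::lines(obs$mz[win], obs$intensity[win], col = "steelblue")
  }
  invisible(x)
}
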