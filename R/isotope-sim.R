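# Isotope pattern computation.  The reference path builds per-element
# multinomial distributions over isotopologue compositions and convolves
# them across elements with pruning; an FFT path (probability generating
# function evaluated on the unit circle, the classic FT formulation of
# isotope pattern synthesis) provides a fast nominal-resolution
# alternative.  A per-atom sequential-convolution oracle is kept fully
# independent for testing.

.new_pattern <- function(mass, abundance, nshift, mode) {
  o <- order(mass)
  structure(
    data.frame(mass = mass[o], nshift = as.integer(nshift[o]),
               abundance = abundance[o]),
    mode = mode, class = c("isotope_pattern", "data.frame"))
}

#' @export
print.isotope_pattern <- function(x, n = 10, ...) {
  cat("<isotope_pattern> mode:", attr(x, "mode"),
      "|", nrow(x), "centroids\n")
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more\n")
  invisible(x)
}

# multinomial distribution over isotopologues of n atoms of one element
.element_multinomial <- function(entry, n, prune) {
  m <- nrow(entry)
  if (n == 0L || m == 1L) {
    return(data.frame(mass = n * entry$mass[1],
                      nshift = n * entry$nshift[1], abundance = 1))
  }
  # cap heavy-isotope counts via marginal binomial tails
  caps <- vapply(2:m, function(i)
    min(n, stats::qbinom(1e-12, n, entry$abundance[i],
                         lower.tail = FALSE) + 1L), 0)
  grid <- do.call(expand.grid, lapply(caps, function(k) 0:k))
  heavy <- as.matrix(grid)
  k0 <- n - rowSums(heavy)
  keep <- k0 >= 0
  heavy <- heavy[keep, , drop = FALSE]
  k0 <- k0[keep]
  counts <- cbind(k0, heavy)
  lp <- lgamma(n + 1) - rowSums(lgamma(counts + 1)) +
    counts %*% log(entry$abundance)
  p <- exp(as.vector(lp))
  keep <- p >= prune
  counts <- counts[keep, , drop = FALSE]
  p <- p[keep]
  data.frame(mass = as.vector(counts %*% entry$mass),
             nshift = as.integer(counts %*% entry$nshift),
             abundance = p)
}

# cross-element convolution of two centroid sets with pruning
.convolve_centroids <- function(a, b, prune) {
  ab <- outer(a$abundance, b$abundance)
  keep <- which(ab >= prune)
  i <- (keep - 1L) %% nrow(a) + 1L
  j <- (keep - 1L) %/% nrow(a) + 1L
  data.frame(mass = a$mass[i] + b$mass[j],
             nshift = a$nshift[i] + b$nshift[j],
             abundance = ab[keep])
}

.aggregate_nominal <- function(df) {
  sp <- split(df, df$nshift)
  mass <- vapply(sp, function(g) sum(g$mass * g$abundance) / sum(g$abundance), 0)
  ab <- vapply(sp, function(g) sum(g$abundance), 0)
  ns <- as.integer(names(sp))
  list(mass = mass, abundance = ab, nshift = ns)
}

#' Simulate the isotope pattern of a composition
#'
#' Computes the isotope distribution of an elemental composition (which may
#' contain the `C13label`/`N15label` pseudo-elements) either aggregated per
#' added-neutron number (`mode = "nominal"`, one centroid per nominal
#' isotope peak with abundance-weighted mean mass) or resolved into
#' isotopic fine structure (`mode = "fine"`, one centroid per distinct
#' isotopologue composition above the pruning threshold).
#'
#' @param comp `elemental_composition`.
#' @param mode `"nominal"` or `"fine"`.
#' @param prune_threshold centroids below this abundance fraction are
#'   dropped (then abundances renormalize to 1).  Defaults: 1e-5 nominal,
#'   1e-8 fine.
#' @param method `"convolution"` (reference; both modes) or `"fft"`
#'   (generating-function/FFT path, nominal mode only).
#' @param table isotope table.
#' @return `isotope_pattern`: data frame with columns `mass` (neutral Da,
#'   ascending), `nshift` (added neutrons above monoisotopic) and
#'   `abundance` (fractions summing to 1).
#' @examples
#' simulate_pattern(parse_formula("C2"))
#' @export
simulate_pattern <- function(comp, mode = c("nominal", "fine"),
                             prune_threshold = NULL,
                             method = c("convolution", "fft"),
                             table = default_isotope_table()) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(inherits(comp, "elemental_composition"))
  if (length(comp) == 0L) stop("empty composition")
  missing <- setdiff(names(comp), names(table))
  if (length(missing))
    stop("element(s) not in isotope table: ", paste(missing, collapse = ", "))
  if (is.null(prune_threshold))
    prune_threshold <- if (mode == "fine") 1e-8 else 1e-5
  if (method == "fft") {
    if (mode != "nominal")
      stop("the fft path computes nominal-aggregated patterns only")
    return(.simulate_fft(comp, prune_threshold, table))
  }
  partial <- prune_threshold * 1e-3
  acc <- NULL
  for (sym in names(comp)) {
    ep <- .element_multinomial(table[[sym]], comp[[sym]], partial)
    acc <- if (is.null(acc)) ep else .convolve_centroids(acc, ep, partial)
  }
  if (mode == "nominal") {
    agg <- .aggregate_nominal(acc)
    keep <- agg$abundance >= prune_threshold
    p <- .new_pattern(agg$mass[keep], agg$abundance[keep], agg$nshift[keep],
                      "nominal")
  } else {
    keep <- acc$abundance >= prune_threshold
    p <- .new_pattern(acc$mass[keep], acc$abundance[keep], acc$nshift[keep],
                      "fine")
  }
  p$abundance <- p$abundance / sum(p$abundance)
  p
}

# nominal pattern via the generating function evaluated on the unit circle
.simulate_fft <- function(comp, prune_threshold, table) {
  # upper bound on the neutron-shift support
  kmax <- 0
  for (sym in names(comp)) {
    e <- table[[sym]]
    n <- comp[[sym]]
    if (nrow(e) == 1L) { kmax <- kmax + n * e$nshift[1]; next }
    for (i in 2:nrow(e))
      kmax <- kmax + e$nshift[i] *
        (stats::qbinom(1e-12, n, e$abundance[i], lower.tail = FALSE) + 1L)
  }
  N <- 2^ceiling(log2(kmax + 2))
  w <- exp(-2i * pi * (0:(N - 1)) / N)
  P <- rep(1 + 0i, N)
  Mu <- rep(0 + 0i, N)
  base_shift <- 0L
  mono <- 0
  for (sym in names(comp)) {
    e <- table[[sym]]
    n <- comp[[sym]]
    mono <- mono + n * e$mass[1]
    ch <- rep(0 + 0i, N)
    chm <- rep(0 + 0i, N)
    for (i in seq_len(nrow(e))) {
      zi <- w^e$nshift[i]
      ch <- ch + e$abundance[i] * zi
      chm <- chm + e$abundance[i] * (e$mass[i] - e$mass[1]) * zi
    }
    P <- P * ch^n
    Mu <- Mu + n * chm / ch
  }
  ab <- Re(stats::fft(P, inverse = TRUE)) / N
  dm <- Re(stats::fft(P * Mu, inverse = TRUE)) / N
  k <- 0:(N - 1)
  keep <- ab >= prune_threshold
  mass <- mono + dm[keep] / ab[keep]
  p <- .new_pattern(mass, ab[keep], k[keep], "nominal")
  p$abundance <- p$abundance / sum(p$abundance)
  p
}

#' Brute-force isotope pattern oracle
#'
#' Exact per-atom sequential convolution over isotopologue compositions:
#' every atom is added one at a time and states are merged on their exact
#' isotope-count signature.  Slow but trivially correct; used as the
#' independent oracle for [simulate_pattern()].
#'
#' @inheritParams simulate_pattern
#' @param max_atoms enumeration guard (default 300 atoms).
#' @return fine-structure `isotope_pattern`.
#' @export
brute_force_pattern <- function(comp, prune_threshold = 1e-8,
                                table = default_isotope_table(),
                                max_atoms = 300) {
  stopifnot(inherits(comp, "elemental_composition"))
  if (sum(comp) > max_atoms)
    stop("composition has ", sum(comp), " atoms; oracle guard is ",
         max_atoms)
  partial <- prune_threshold * 1e-3
  acc <- NULL   # running cross-element state list
  for (sym in names(comp)) {
    e <- table[[sym]]
    m <- nrow(e)
    n <- comp[[sym]]
    # sequential atom-by-atom addition, states keyed by isotope counts
    counts <- matrix(0L, 1L, m)
    prob <- 1
    for (atom in seq_len(n)) {
      newc <- do.call(rbind, lapply(seq_len(m), function(i) {
        ci <- counts; ci[, i] <- ci[, i] + 1L; ci
      }))
      newp <- as.vector(vapply(seq_len(m),
                               function(i) prob * e$abundance[i],
                               numeric(length(prob))))
      key <- apply(newc, 1L, paste, collapse = ",")
      agg <- rowsum(newp, key)        # rows ordered by sorted unique key
      prob <- as.vector(agg[, 1])
      counts <- newc[match(rownames(agg), key), , drop = FALSE]
      keep <- prob >= partial
      counts <- counts[keep, , drop = FALSE]
      prob <- prob[keep]
    }
    elem <- data.frame(mass = as.vector(counts %*% e$mass),
                       nshift = as.integer(counts %*% e$nshift),
                       abundance = prob)
    if (is.null(acc)) { acc <- elem; next }
    # cross-element outer product
    i <- rep(seq_len(nrow(acc)), times = nrow(elem))
    j <- rep(seq_len(nrow(elem)), each = nrow(acc))
    acc <- data.frame(mass = acc$mass[i] + elem$mass[j],
                      nshift = acc$nshift[i] + elem$nshift[j],
                      abundance = acc$abundance[i] * elem$abundance[j])
    acc <- acc[acc$abundance >= partial, , drop = FALSE]
  }
  keep <- acc$abundance >= prune_threshold
  p <- .new_pattern(acc$mass[keep], acc$abundance[keep], acc$nshift[keep],
                    "fine")
  p$abundance <- p$abundance / sum(p$abundance)
  p
}

#' Aggregate a fine-structure pattern to nominal resolution
#'
#' @param pattern `isotope_pattern`.
#' @return nominal-mode `isotope_pattern` (abundance-weighted mean mass per
#'   added-neutron number).
#' @export
aggregate_pattern <- function(pattern) {
  agg <- .aggregate_nominal(pattern)
  p <- .new_pattern(agg$mass, agg$abundance, agg$nshift, "nominal")
  p$abundance <- p$abundance / sum(p$abundance)
  p
}

#' Render an isotope pattern as a Gaussian profile
#'
#' Evaluates a sum of Gaussians (area proportional to centroid abundance,
#' width given by `fwhm` on the m/z axis) on a uniform m/z grid, with
#' centroids placed at `(mass + charge * 1.00727646) / charge`.
#'
#' @param pattern `isotope_pattern`.
#' @param charge rendering charge (>= 1).
#' @param fwhm full width at half maximum in m/z units.
#' @param points_per_Da uniform grid density (>= 100); 1000 suffices at
#'   unit resolution, fine structure needs 10000 to avoid triangular peak
#'   artifacts.
#' @param mz_range optional `c(lo, hi)` grid range; defaults to the
#'   centroid span padded by `max(0.3, 5 * fwhm)` m/z.
#' @param table isotope table (for the proton mass convention only).
#' @return `mz_profile`: list with `start`, `spacing`, `intensity`,
#'   `charge`, `fwhm`; a `"coarse_grid"` attribute records a warning when
#'   fewer than 4 grid points span the fwhm.
#' @export
render_profile <- function(pattern, charge = 1, fwhm,
                           points_per_Da = 1000, mz_range = NULL,
                           table = default_isotope_table()) {
  stopifnot(fwhm > 0, points_per_Da >= 100, charge >= 1)
  centers <- (pattern$mass + charge * iso_constants[["proton"]]) / charge
  spacing <- 1 / points_per_Da
  if (is.null(mz_range)) {
    pad <- max(0.3, 5 * fwhm)
    mz_range <- c(min(centers) - pad, max(centers) + pad)
  }
  start <- floor(mz_range[1] / spacing) * spacing
  npts <- ceiling((mz_range[2] - start) / spacing - 1e-9) + 1L
  grid <- start + spacing * (0:(npts - 1L))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  intensity <- numeric(npts)
  for (i in seq_along(centers)) {
    lo <- max(1L, ceiling((centers[i] - 6 * sigma - start) / spacing) + 1L)
    hi <- min(npts, floor((centers[i] + 6 * sigma - start) / spacing) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    intensity[idx] <- intensity[idx] +
      pattern$abundance[i] * stats::dnorm(grid[idx], centers[i], sigma)
  }
  out <- structure(list(start = start, spacing = spacing,
                        intensity = intensity, charge = charge,
                        fwhm = fwhm),
                   class = "mz_profile")
  if (spacing > fwhm / 4) {
    warning("grid too coarse for fwhm = ", signif(fwhm, 4),
            ": fewer than 4 points per peak width")
    attr(out, "coarse_grid") <- TRUE
  }
  out
}

#' m/z axis of a profile
#' @param profile `mz_profile`.
#' @export
profile_mz <- function(profile) {
  profile$start + profile$spacing * (seq_along(profile$intensity) - 1L)
}

#' @export
print.mz_profile <- function(x, ...) {
  cat(sprintf(
    "<mz_profile> %d points, m/z %.4f-%.4f (spacing %.4g), charge %d, fwhm %.4g\n",
    length(x$intensity), x$start,
    x$start + x$spacing * (length(x$intensity) - 1L), x$spacing,
    x$charge, x$fwhm))
  invisible(x)
}

#' Write / read two-column .xy profiles and .asc centroid masslists
#'
#' `.xy` files are plain two-column (m/z, intensity) whitespace-separated
#' profiles; `.asc` masslists are whitespace- or comma-separated m/z lines
#' with an optional intensity column, `#`/`;` comment lines ignored.
#'
#' @param x an `mz_profile` or a two-column data frame.
#' @param path file path.
#' @return `read_xy`/`read_asc` return a data frame with columns `mz` and
#'   `intensity` (`NA` intensity when the masslist omits it).
#' @export
write_xy <- function(x, path) {
  df <- if (inherits(x, "mz_profile"))
    data.frame(mz = profile_mz(x), intensity = x$intensity)
  else data.frame(mz = x[[1]], intensity = x[[2]])
  utils::write.table(format(df, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_xy
#' @export
read_xy <- function(path) {
  df <- utils::read.table(path, col.names = c("mz", "intensity"),
                          colClasses = "numeric")
  df[order(df$mz), , drop = FALSE]
}

#' @rdname write_xy
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#;]", lines)]
  if (!length(lines))
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  parts <- strsplit(lines, "[,[:space:]]+")
  mzv <- vapply(parts, function(p) as.numeric(p[1]), 0)
  inten <- vapply(parts, function(p)
    if (length(p) >= 2) as.numeric(p[2]) else NA_real_, 0)
  df <- data.frame(mz = mzv, intensity = inten)
  df[order(df$mz), , drop = FALSE]
}
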