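# Label-aware peptide mass fingerprinting and b/y fragment matching.
# Standard CID b/y chemistry: b = [sum of residues + z*H+]z+, y = [sum of
# residues + H2O + z*H+]z+, pinned by the complementarity invariant
# mass(b_i) + mass(y_(n-i)) = M_peptide + 2 * proton at charge 1.

# total enforced labels a scheme places on a sequence (or residue window)
.scheme_label_counts <- function(letters, scheme) {
  n15 <- 0L; n13 <- 0L
  for (res in letters) {
    r <- scheme$rules[[res]]
    if (is.null(r)) next
    n15 <- n15 + r$n15N
    n13 <- n13 + r$n13C
  }
  c(n15N = n15, n13C = n13)
}

#' Label-aware peptide mass fingerprint search
#'
#' For each peptide the monoisotopic m/z of the unlabeled and (when the
#' scheme labels any residue) fully labeled forms are searched in a
#' centroid masslist at every requested charge; matches within `tol_ppm`
#' are reported with signed ppm error (`(observed - theoretical) /
#' theoretical * 1e6`).
#'
#' @param masslist data frame with column `mz` (e.g. from [read_asc()]).
#' @param peptides character vector of peptide sequences.
#' @param scheme `label_scheme`.
#' @param tol_ppm matching tolerance (> 0).
#' @param charges charge states to search.
#' @param table isotope table.
#' @return data frame of matches: `peptide`, `state` (`"unlabeled"` /
#'   `"labeled"`), `charge`, `theoretical_mz`, `observed_mz`, `error_ppm`.
#' @export
pmf_search <- function(masslist, peptides, scheme, tol_ppm = 5,
                       charges = 1, table = default_isotope_table()) {
  stopifnot(tol_ppm > 0, inherits(scheme, "label_scheme"))
  empty <- data.frame(peptide = character(0), state = character(0),
                      charge = integer(0), theoretical_mz = numeric(0),
                      observed_mz = numeric(0), error_ppm = numeric(0))
  if (is.null(masslist) || nrow(masslist) == 0L) {
    warning("empty masslist")
    return(empty)
  }
  obs <- sort(masslist$mz)
  rows <- list()
  for (pep in peptides) {
    comp <- peptide_composition(pep)
    lab <- .scheme_label_counts(strsplit(pep, "")[[1]], scheme)
    forms <- list(unlabeled = comp)
    if (sum(lab) > 0)
      forms$labeled <- apply_labels(comp, n13C = lab[["n13C"]],
                                    n15N = lab[["n15N"]])
    for (state in names(forms)) {
      for (z in charges) {
        th <- mz(forms[[state]], z, table)
        k <- which.min(abs(obs - th))
        err <- (obs[k] - th) / th * 1e6
        if (abs(err) <= tol_ppm)
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = pep, state = state, charge = as.integer(z),
            theoretical_mz = th, observed_mz = obs[k], error_ppm = err)
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Generate label-aware b/y fragment ions
#'
#' All N-terminal (b) and C-terminal (y) fragments of length 1..n-1, at
#' every charge 1..`precursor_charge`, in unlabeled and (when the spanned
#' residues carry labels) fully labeled variants.
#'
#' @param peptide peptide sequence string.
#' @param scheme `label_scheme`.
#' @param precursor_charge precursor charge (>= 1); fragment charges run
#'   up to this value.
#' @param table isotope table.
#' @return data frame, one row per fragment ion: `series` (`"B"`/`"Y"`),
#'   `index`, `charge`, `labeled`, `n15N`, `n13C`, `mz`, `formula`.
#' @examples
#' generate_fragments("GA", label_scheme(list(A = list(n15N = 1))), 1)
#' @export
generate_fragments <- function(peptide, scheme, precursor_charge = 1,
                               table = default_isotope_table()) {
  stopifnot(precursor_charge >= 1)
  letters <- .check_sequence(peptide)
  n <- length(letters)
  if (n < 2L) stop("peptide must have at least 2 residues to fragment")
  proton <- iso_constants[["proton"]]
  water <- iso_constants[["water"]]
  rows <- list()
  add <- function(series, index, span) {
    res_counts <- colSums(.residue_formulas[span, , drop = FALSE])
    comp <- .new_composition(res_counts)
    lab <- .scheme_label_counts(span, scheme)
    variants <- list(list(labeled = FALSE, comp = comp,
                          n15N = 0L, n13C = 0L))
    if (sum(lab) > 0)
      variants <- c(variants, list(list(
        labeled = TRUE,
        comp = apply_labels(comp, n13C = lab[["n13C"]], n15N = lab[["n15N"]]),
        n15N = lab[["n15N"]], n13C = lab[["n13C"]])))
    for (v in variants) {
      m0 <- monoisotopic_mass(v$comp, table) +
        if (series == "Y") water else 0
      for (z in seq_len(precursor_charge)) {
        rows[[length(rows) + 1L]] <<- data.frame(
          series = series, index = index, charge = z,
          labeled = v$labeled, n15N = v$n15N, n13C = v$n13C,
          mz = (m0 + z * proton) / z,
          formula = format(v$comp))
      }
    }
  }
  for (i in seq_len(n - 1L)) {
    add("B", i, letters[seq_len(i)])
    add("Y", i, letters[(n - i + 1L):n])
  }
  do.call(rbind, rows)
}

#' Match fragment ions against a centroid masslist
#'
#' Each fragment is matched to the minimum-|ppm| masslist entry within
#' `tol_ppm`; unmatched fragments keep `NA` observed columns.  A per-(series,
#' index, charge) summary flags whether the labeled, unlabeled, both or
#' neither variant matched, with the inferred label counts.
#'
#' @param masslist data frame with column `mz`.
#' @param fragments data frame from [generate_fragments()].
#' @param tol_ppm tolerance (default 5 ppm).
#' @return the `fragments` table with added `observed_mz`, `error_ppm` and
#'   `matched` columns, plus a `"summary"` attribute (per-fragment
#'   `variant_matched` in `"none"`, `"unlabeled"`, `"labeled"`, `"both"`).
#' @export
match_fragments <- function(masslist, fragments, tol_ppm = 5) {
  stopifnot(tol_ppm > 0)
  obs <- if (!is.null(masslist) && nrow(masslist)) sort(masslist$mz)
         else numeric(0)
  fragments$observed_mz <- NA_real_
  fragments$error_ppm <- NA_real_
  fragments$matched <- FALSE
  if (length(obs)) {
    for (i in seq_len(nrow(fragments))) {
      th <- fragments$mz[i]
      k <- which.min(abs(obs - th))
      err <- (obs[k] - th) / th * 1e6
      if (abs(err) <= tol_ppm) {
        fragments$observed_mz[i] <- obs[k]
        fragments$error_ppm[i] <- err
        fragments$matched[i] <- TRUE
      }
    }
  }
  key <- interaction(fragments$series, fragments$index, fragments$charge,
                     drop = TRUE)
  summ <- do.call(rbind, lapply(split(fragments, key), function(g) {
    u <- any(g$matched & !g$labeled)
    l <- any(g$matched & g$labeled)
    data.frame(series = g$series[1], index = g$index[1],
               charge = g$charge[1],
               variant_matched = if (u && l) "both" else if (l) "labeled"
                                 else if (u) "unlabeled" else "none",
               n15N_inferred = if (l) max(g$n15N) else 0L,
               n13C_inferred = if (l) max(g$n13C) else 0L)
  }))
  summ <- summ[order(summ$series, summ$index, summ$charge), ]
  rownames(summ) <- NULL
  attr(fragments, "summary") <- summ
  fragments
}
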