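# Labeling schemes and enumeration of intermediate labeling states.
#
# A scheme assigns each targeted residue a number of enforced 15N and 13C
# labels, partitioned into removal units: label blocks that metabolic
# scrambling can omit independently (e.g. Val = a [1] 15N unit, whose
# alpha-amino nitrogen exchanges, plus a [5] 13C block that is incorporated
# all-or-none).  A labeling state is identified by its total (15N, 13C)
# counts only: positional isomers are isobaric and unresolvable in MS1.

#' Construct a labeling scheme
#'
#' @param rules named list, one entry per residue letter, each a list with
#'   `n15N`, `n13C` and `units`.  `units` is either a numeric vector of
#'   block sizes (assigned to 15N first, in order, then 13C: `c(1, 5)` with
#'   `n15N = 1, n13C = 5` gives one removable 15N and one removable 13C5
#'   block) or a list of explicit `c(n15N =, n13C =)` blocks.
#' @param extras optional list of extra labeling states beyond the
#'   reachable set (metabolic scrambling into off-target residues), each
#'   `c(n15N =, n13C =)`, optionally named with a descriptor.
#' @return `label_scheme` object.
#' @examples
#' vil_scheme()
#' @export
label_scheme <- function(rules, extras = list()) {
  stopifnot(is.list(rules), !is.null(names(rules)))
  norm <- lapply(rules, function(r) {
    n15 <- as.integer(r$n15N %||% 0)
    n13 <- as.integer(r$n13C %||% 0)
    units <- r$units
    if (is.null(units)) {
      units <- list()
      if (n15 > 0) units <- c(units, replicate(n15, c(n15N = 1L, n13C = 0L),
                                               simplify = FALSE))
      if (n13 > 0) units <- c(units, list(c(n15N = 0L, n13C = n13)))
    } else if (is.numeric(units)) {
      sizes <- as.integer(units)
      if (sum(sizes) != n15 + n13)
        stop("unit sizes must sum to n15N + n13C")
      pool15 <- n15
      units <- lapply(sizes, function(s) {
        a <- min(s, pool15)
        pool15 <<- pool15 - a
        c(n15N = a, n13C = s - a)
      })
    } else {
      units <- lapply(units, function(u)
        c(n15N = as.integer(u[["n15N"]]), n13C = as.integer(u[["n13C"]])))
    }
    tot <- Reduce(`+`, units, c(n15N = 0L, n13C = 0L))
    if (tot[["n15N"]] != n15 || tot[["n13C"]] != n13)
      stop("units are inconsistent with n15N/n13C totals")
    if (n15 < 0 || n13 < 0) stop("negative label counts")
    list(n15N = n15, n13C = n13, units = units)
  })
  structure(list(rules = norm, extras = .norm_extras(extras)),
            class = "label_scheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.norm_extras <- function(extras) {
  lapply(extras, function(e) {
    s <- labeling_state(e[["n15N"]], e[["n13C"]])
    s
  })
}

#' @export
print.label_scheme <- function(x, ...) {
  for (res in names(x$rules)) {
    r <- x$rules[[res]]
    cat(sprintf("  %s: %d x 15N, %d x 13C, units %s\n", res, r$n15N, r$n13C,
                paste(vapply(r$units, function(u)
                  paste0("[", u[["n15N"]], "N,", u[["n13C"]], "C]"), ""),
                  collapse = " ")))
  }
  if (length(x$extras))
    cat("  extras:", paste(vapply(x$extras, function(s) s$descriptor, ""),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Built-in labeling schemes
#'
#' `vil_scheme()`: [15N,13C5]-Val (interval `[1, 5]`), 15N-Ile, 15N-Leu.
#' `kgs_scheme()`: 15N-Lys, [15N,13C2]-Gly (interval `[1, 2]`), 15N-Ser.
#' Lys is supplied with both alpha- and epsilon-amino 15N but the epsilon
#' nitrogen exchanges quantitatively with unlabeled glutamate amino groups
#' in HEK293 expression, so the default retains a single 15N;
#' `lys_n15 = 2` restores the fully labeled form.
#'
#' @param lys_n15 number of retained 15N on Lys (1 or 2).
#' @return `label_scheme`.
#' @export
vil_scheme <- function() {
  label_scheme(list(
    V = list(n15N = 1, n13C = 5, units = c(1, 5)),
    I = list(n15N = 1, n13C = 0, units = 1),
    L = list(n15N = 1, n13C = 0, units = 1)
  ))
}

#' @rdname vil_scheme
#' @export
kgs_scheme <- function(lys_n15 = 1) {
  stopifnot(lys_n15 %in% 1:2)
  label_scheme(list(
    K = list(n15N = lys_n15, n13C = 0, units = rep(1, lys_n15)),
    G = list(n15N = 1, n13C = 2, units = c(1, 2)),
    S = list(n15N = 1, n13C = 0, units = 1)
  ))
}

#' Read / write a labeling-scheme JSON config
#'
#' Format: `{"rules": {"V": {"n15N": 1, "n13C": 5, "units": [1, 5]}, ...},
#' "extras": [{"n15N": 1, "n13C": 2}, ...]}`; a top-level object without
#' `"rules"` is treated as the rules map itself.
#'
#' @param path JSON file.
#' @return `label_scheme`.
#' @export
read_scheme <- function(path) {
  j <- jsonlite::read_json(path)
  rules <- j$rules %||% j
  rules$extras <- NULL
  rules <- lapply(rules, function(r) {
    u <- r$units
    if (!is.null(u) && length(u) && is.list(u[[1]]))
      r$units <- lapply(u, function(b)
        c(n15N = b$n15N %||% 0, n13C = b$n13C %||% 0))
    else r$units <- unlist(u)
    r
  })
  extras <- lapply(j$extras %||% list(), function(e)
    c(n15N = e$n15N %||% 0, n13C = e$n13C %||% 0))
  label_scheme(rules, extras)
}

#' @rdname read_scheme
#' @param scheme `label_scheme` to serialize.
#' @export
write_scheme <- function(scheme, path) {
  j <- list(
    rules = lapply(scheme$rules, function(r)
      list(n15N = r$n15N, n13C = r$n13C,
           units = lapply(r$units, as.list))),
    extras = lapply(scheme$extras, function(s)
      list(n15N = s$n15N, n13C = s$n13C)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' A single labeling state
#'
#' @param n15N,n13C total enforced heavy labels.
#' @param extra logical: user-added state beyond the scheme-reachable set.
#' @return `labeling_state`: list with `n15N`, `n13C`, `descriptor` (e.g.
#'   `"[15N2, 13C5]"`), `extra`.
#' @export
labeling_state <- function(n15N, n13C, extra = FALSE) {
  n15N <- as.integer(n15N); n13C <- as.integer(n13C)
  if (n15N < 0 || n13C < 0) stop("label counts must be nonnegative")
  structure(list(n15N = n15N, n13C = n13C,
                 descriptor = state_descriptor(n15N, n13C),
                 extra = extra),
            class = "labeling_state")
}

#' @rdname labeling_state
#' @export
state_descriptor <- function(n15N, n13C) {
  if (n15N == 0 && n13C == 0) return("unlabeled")
  parts <- c(
    if (n15N > 0) paste0("15N", if (n15N > 1) n15N else ""),
    if (n13C > 0) paste0("13C", if (n13C > 1) n13C else ""))
  paste0("[", paste(parts, collapse = ", "), "]")
}

#' @export
print.labeling_state <- function(x, ...) {
  cat("<labeling_state>", x$descriptor,
      if (x$extra) "(extra)" else "", "\n")
  invisible(x)
}

#' Number of added neutrons of a state
#'
#' States with equal neutron count are isobaric at unit resolution but
#' differ in mass defect (15N adds 0.99703 Da per label, 13C 1.00335 Da).
#'
#' @param state `labeling_state`, or a `state_set` (vectorized).
#' @return integer neutron count(s).
#' @export
neutron_count <- function(state) {
  if (inherits(state, "state_set")) return(state$n15N + state$n13C)
  state$n15N + state$n13C
}

#' Enumerate all labeling states of a peptide under a scheme
#'
#' Every removal unit of every labeled residue in `peptide` can be
#' independently included or omitted; the reachable set of distinct
#' (total 15N, total 13C) pairs -- from unlabeled to fully labeled --
#' forms the state set.  User-declared extras (scrambling into off-target
#' residues) are appended with de-duplication.  States are ordered by
#' neutron count ascending, ties by insertion order.
#'
#' @param peptide peptide sequence string.
#' @param scheme `label_scheme`.
#' @param extras list of extra states (`labeling_state` or
#'   `c(n15N =, n13C =)`), in addition to any stored in the scheme.
#' @return `state_set`: data frame with columns `n15N`, `n13C`,
#'   `descriptor`, `extra` and `neutrons`.
#' @examples
#' enumerate_states("EEDPIHLR", vil_scheme())        # 3 states
#' nrow(enumerate_states("AVVFLEPQWYR", vil_scheme()))  # 12
#' @export
enumerate_states <- function(peptide, scheme, extras = list()) {
  stopifnot(inherits(scheme, "label_scheme"))
  letters <- .check_sequence(peptide)
  units <- list()
  for (res in letters)
    if (res %in% names(scheme$rules))
      units <- c(units, scheme$rules[[res]]$units)
  # reachable (15N, 13C) totals over all unit-inclusion subsets
  pairs <- matrix(0L, 1L, 2L)
  for (u in units) {
    pairs <- unique(rbind(pairs,
                          cbind(pairs[, 1] + u[["n15N"]],
                                pairs[, 2] + u[["n13C"]])))
  }
  df <- data.frame(n15N = pairs[, 1], n13C = pairs[, 2], extra = FALSE)
  all_extras <- c(scheme$extras, .norm_extras(extras))
  for (s in all_extras) {
    if (any(df$n15N == s$n15N & df$n13C == s$n13C)) next  # silent merge
    df <- rbind(df, data.frame(n15N = s$n15N, n13C = s$n13C, extra = TRUE))
  }
  df$descriptor <- mapply(state_descriptor, df$n15N, df$n13C)
  df$neutrons <- df$n15N + df$n13C
  df <- df[order(df$neutrons), , drop = FALSE]   # stable: ties keep order
  rownames(df) <- NULL
  structure(df[, c("n15N", "n13C", "descriptor", "extra", "neutrons")],
            peptide = peptide, class = c("state_set", "data.frame"))
}

#' @export
print.state_set <- function(x, ...) {
  cat("<state_set>", attr(x, "peptide"), "-", nrow(x), "states\n")
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Groups of isobaric states (neutron-count collisions)
#'
#' Partitions a state set by neutron count and reports the groups of size
#' >= 2: states that cannot be distinguished at unit resolution.  Within a
#' group, states are ordered by `n15N` descending (more 15N means lower
#' mass defect).
#'
#' @param states `state_set`.
#' @return named list of data frames, one per colliding neutron count.
#' @export
find_collisions <- function(states) {
  stopifnot(inherits(states, "state_set"))
  sp <- split(as.data.frame(states), states$neutrons)
  sp <- sp[vapply(sp, nrow, 0L) >= 2L]
  lapply(sp, function(g) {
    g <- g[order(-g$n15N), , drop = FALSE]
    rownames(g) <- NULL
    g
  })
}

#' Labeled composition of a peptide in a given state
#'
#' @param peptide peptide sequence string.
#' @param state `labeling_state` or a single row of a `state_set`.
#' @param fixed_mods passed to [peptide_composition()].
#' @return `elemental_composition` with label pseudo-elements.
#' @export
labeled_composition <- function(peptide, state, fixed_mods = NULL) {
  apply_labels(peptide_composition(peptide, fixed_mods),
               n13C = state$n13C, n15N = state$n15N)
}
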