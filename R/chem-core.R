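# Peptide chemistry: sequences -> elemental compositions, sparse-label
# injection, tryptic digestion, monoisotopic mass and m/z arithmetic.

# Monoisotopic residue formulas for the 20 standard amino acids,
# element order C H N O S.
.residue_formulas <- local({
  m <- rbind(
    A = c(3, 5, 1, 1, 0),  R = c(6, 12, 4, 1, 0), N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),  C = c(3, 5, 1, 1, 1),  E = c(5, 7, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),  G = c(2, 3, 1, 1, 0),  H = c(6, 7, 3, 1, 0),
    I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
    M = c(5, 9, 1, 1, 1),  F = c(9, 9, 1, 1, 0),  P = c(5, 7, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  W = c(11, 10, 2, 1, 0),
    Y = c(9, 9, 1, 2, 0),  V = c(5, 9, 1, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  storage.mode(m) <- "integer"
  m
})

#' Amino acid residue formulas
#'
#' @return Integer matrix (20 residues x elements C, H, N, O, S) of
#'   monoisotopic residue (dehydrated) formulas.
#' @export
residue_formulas <- function() .residue_formulas

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single nonempty string")
  letters <- strsplit(sequence, "")[[1]]
  bad <- which(!letters %in% rownames(.residue_formulas))
  if (length(bad))
    stop("unknown residue '", letters[bad[1]], "' at position ", bad[1],
         " in sequence '", sequence, "'")
  letters
}

.new_composition <- function(counts) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("negative atom count in composition")
  structure(as.integer(round(counts)), names = names(counts),
            class = "elemental_composition")
}

#' Elemental composition of a peptide
#'
#' Sums the residue formulas of `sequence` and adds one water for the fixed
#' H-/-OH termini.  Optional fixed modifications are supplied as a named
#' list mapping residue letter to an elemental-delta vector, e.g.
#' `list(C = c(C = 2, H = 3, N = 1, O = 1))` for carbamidomethyl-Cys; no
#' modification is applied by default.
#'
#' @param sequence peptide string over the 20 one-letter codes.
#' @param fixed_mods optional named list of per-residue elemental deltas.
#' @return `elemental_composition`: a named integer vector of atom counts.
#' @examples
#' peptide_composition("PEPTIDE")   # C34 H53 N7 O15
#' @export
peptide_composition <- function(sequence, fixed_mods = NULL) {
  letters <- .check_sequence(sequence)
  counts <- colSums(.residue_formulas[letters, , drop = FALSE])
  counts["H"] <- counts["H"] + 2L
  counts["O"] <- counts["O"] + 1L
  if (!is.null(fixed_mods)) {
    for (res in names(fixed_mods)) {
      n <- sum(letters == res)
      if (n == 0) next
      delta <- fixed_mods[[res]]
      for (elsym in names(delta)) {
        cur <- if (elsym %in% names(counts)) counts[[elsym]] else 0L
        counts[elsym] <- cur + n * delta[[elsym]]
      }
    }
  }
  .new_composition(counts)
}

#' Parse a molecular formula string
#'
#' @param formula e.g. `"C34H53N7O15"`; multi-letter symbols and the
#'   pseudo-elements `C13label`/`N15label` are written in brackets, e.g.
#'   `"C5[C13label]2"`.
#' @return `elemental_composition`.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  rx <- gregexpr("\\[[A-Za-z0-9]+\\][0-9]*|[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(rx))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula '", formula, "'")
  counts <- integer(0)
  for (tok in toks) {
    if (startsWith(tok, "[")) {
      sym <- sub("^\\[([A-Za-z0-9]+)\\].*$", "\\1", tok)
      num <- sub("^\\[[A-Za-z0-9]+\\]", "", tok)
    } else {
      sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
      num <- substring(tok, nchar(sym) + 1L)
    }
    n <- if (num == "") 1L else as.integer(num)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  .new_composition(counts)
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<composition>",
      paste0(names(x), unclass(x), collapse = " "),
      sprintf(" (monoisotopic %.5f Da)\n", monoisotopic_mass(x)))
  invisible(x)
}

#' @export
format.elemental_composition <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' Sum of two compositions
#' @param e1,e2 `elemental_composition` objects.
#' @export
"+.elemental_composition" <- function(e1, e2) {
  syms <- union(names(e1), names(e2))
  v <- stats::setNames(integer(length(syms)), syms)
  v[names(e1)] <- v[names(e1)] + unclass(e1)
  v[names(e2)] <- v[names(e2)] + unclass(e2)
  .new_composition(v)
}

#' Monoisotopic mass of a composition
#'
#' @param comp `elemental_composition`.
#' @param table isotope table (default [default_isotope_table()]).
#' @return neutral monoisotopic mass in Da (lightest isotope per element).
#' @export
monoisotopic_mass <- function(comp, table = default_isotope_table()) {
  syms <- names(comp)
  missing <- setdiff(syms, names(table))
  if (length(missing))
    stop("element(s) not in isotope table: ", paste(missing, collapse = ", "))
  sum(vapply(syms, function(s) table[[s]]$mass[1], 0) * unclass(comp))
}

#' Inject selective heavy labels into a composition
#'
#' Moves `n13C` carbons to the single-isotope pseudo-element `C13label` and
#' `n15N` nitrogens to `N15label`.  Total atom counts per element family are
#' conserved; the monoisotopic mass increases by exactly
#' `n13C * 1.0033548 + n15N * 0.9970349` Da.
#'
#' @param comp `elemental_composition`.
#' @param n13C,n15N numbers of enforced 13C and 15N labels.
#' @return labeled `elemental_composition`.
#' @examples
#' apply_labels(peptide_composition("SAMPEGYVQER"), n13C = 5, n15N = 1)
#' @export
apply_labels <- function(comp, n13C = 0, n15N = 0) {
  stopifnot(inherits(comp, "elemental_composition"),
            n13C >= 0, n15N >= 0)
  v <- stats::setNames(as.integer(comp), names(comp))
  take <- function(v, sym, label, n) {
    have <- if (sym %in% names(v)) v[[sym]] else 0L
    if (n > have)
      stop("cannot label ", n, " ", sym, " atoms: composition has only ",
           have)
    if (n > 0) {
      v[sym] <- have - as.integer(n)
      v[label] <- (if (label %in% names(v)) v[[label]] else 0L) +
        as.integer(n)
    }
    v
  }
  v <- take(v, "C", "C13label", n13C)
  v <- take(v, "N", "N15label", n15N)
  .new_composition(v)
}

#' Tryptic digestion
#'
#' Cleaves C-terminal of K/R, except before proline, and returns peptides in
#' order of appearance, including forms with up to `missed_cleavages`
#' internal sites.
#'
#' @param protein protein sequence string.
#' @param enzyme only `"trypsin"` is implemented.
#' @param missed_cleavages maximum internal missed cleavage sites
#'   (default 1: selectively labeled digests routinely retain peptides such
#'   as TISFKDDGTYK with an internal Lys).
#' @return character vector of peptide sequences.
#' @examples
#' digest("AAAKBBBR", missed_cleavages = 0)  # "AAAK" "BBBR"
#' @export
digest <- function(protein, enzyme = "trypsin", missed_cleavages = 1) {
  if (!identical(enzyme, "trypsin"))
    stop("unsupported enzyme: ", enzyme)
  if (!is.character(protein) || length(protein) != 1L || !nchar(protein))
    stop("protein must be a single nonempty string")
  letters <- strsplit(protein, "")[[1]]
  # any A-Z accepted here: digestion is a string operation; composition
  # lookups downstream enforce the 20-letter alphabet
  bad <- which(!grepl("^[A-Z]$", letters))
  if (length(bad))
    stop("invalid character '", letters[bad[1]], "' at position ", bad[1])
  n <- length(letters)
  sites <- which(letters %in% c("K", "R"))
  sites <- sites[sites < n]             # terminal residue is not a cut
  sites <- sites[letters[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)             # fragment i: (bounds[i]+1):bounds[i+1]
  frags <- substring(protein, bounds[-length(bounds)] + 1L, bounds[-1L])
  out <- character(0)
  nf <- length(frags)
  for (i in seq_len(nf))
    for (m in 0:min(missed_cleavages, nf - i))
      out <- c(out, paste(frags[i:(i + m)], collapse = ""))
  out
}

#' m/z of a composition or neutral mass
#'
#' Protonation convention: `(M + z * 1.00727646) / z`.
#'
#' @param x `elemental_composition` or numeric neutral mass in Da.
#' @param charge positive integer charge.
#' @param table isotope table, used when `x` is a composition.
#' @export
mz <- function(x, charge = 1, table = default_isotope_table()) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  m <- if (inherits(x, "elemental_composition"))
    monoisotopic_mass(x, table) else as.numeric(x)
  (m + charge * iso_constants[["proton"]]) / charge
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()`.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("read_fasta requires the Biostrings package")
  s <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' The GFP-CD16a fusion protein sequence
#'
#' Sequence of the GFP-CD16a fusion construct (TEV site included) whose
#' tryptic peptides are the package's worked examples.
#'
#' @return a single protein sequence string.
#' @export
gfp_cd16a_sequence <- function() {
  paste0(
    "MHHHHHHHHMSGLNDIFEAQKIEWHEMSKGEELFTGVVPILVELDGDVNGHKFSVRGEGEGDATNGK",
    "LTLKFICTTGKLPVPWPTLVTTLTYGVQCFSRYPDHMKRHDFFKSAMPEGYVQERTISFKDDGTYKT",
    "RAEVKFEGDTLVNRIELKGIDFKEDGNILGHKLEYNFNSHNVYITADKQKNGIKANFKIRHNVEDGS",
    "VQLADHYQQNTPIGDGPVLLPDNHYLSTQSVLSKDPNEKRDHMVLLEFVTAAGITHGEFSSENLYFQ",
    "GRTEDLPKAVVFLEPQWYRVLEKDSVTLKCQGAYSPEDNSTQWFHNESLISSQASSYFIDAATVDDS",
    "GEYRCQTNLSTLSDPVQLEVHIGWLLLQAPRWVFKEEDPIHLRCHSWKNTALHKVTYLQNGKGRKYF",
    "HHNSDFYIPKATLKDSGSYFCRGLVGSKNVSSETVNITITQG"
  )
}
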