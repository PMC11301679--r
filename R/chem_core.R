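# Elemental compositions, protein species, adduct deltas and isotope-pattern
# computation. Compositions are named integer vectors (element symbol ->
# count); all arithmetic keeps counts non-negative.

# Monoisotopic residue compositions of the 20 canonical amino acids
# (residue = amino acid minus water).
.RESIDUE_COMPOSITIONS <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

#' Create an elemental composition
#'
#' An elemental composition is a named integer vector of element counts,
#' e.g. \code{composition(C = 6, H = 7, N = 1, O = 2)} for the NEM adduct.
#' All counts must be non-negative integers and all symbols must be in the
#' vendored isotope table.
#'
#' @param ... element counts, named by element symbol
#' @return a named numeric vector of class \code{elemental_composition}
#' @export
composition <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- numeric(0)
  as_composition(x)
}

#' @rdname composition
#' @param x a named numeric vector of element counts
#' @export
as_composition <- function(x) {
  if (length(x) > 0) {
    if (is.null(names(x)) || any(names(x) == ""))
      stop("composition entries must be named by element symbol")
    .check_elements(names(x))
    if (any(x < 0)) stop("element counts must be >= 0")
    if (any(x != round(x))) stop("element counts must be integers")
    x <- x[x > 0]
    # canonical Hill-ish ordering for stable printing/keys
    ord <- order(match(names(x), .known_elements()))
    x <- x[ord]
  }
  structure(as.numeric(x), names = names(x), class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat(format_composition(x), "\n")
  invisible(x)
}

#' @export
format_composition <- function(x) {
  if (length(x) == 0) return("(empty)")
  paste0(names(x), ifelse(unclass(x) == 1, "", unclass(x)), collapse = "")
}

#' Add two compositions (or a signed delta)
#'
#' @param a,b compositions; \code{b} may carry negative counts when used as
#'   a delta, but the result must be non-negative
#' @return an \code{elemental_composition}
#' @export
comp_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] + unclass(b)
  if (any(out < 0))
    stop("composition arithmetic drove a count below zero: ",
         paste(els[out < 0], collapse = ", "))
  as_composition(out[out != 0])
}

#' @rdname comp_add
#' @param n a non-negative integer multiplier
#' @export
comp_scale <- function(a, n) {
  stopifnot(n >= 0, n == round(n))
  if (n == 0 || length(a) == 0) return(composition())
  as_composition(setNames(unclass(a) * n, names(a)))
}

comp_subtract <- function(a, b) {
  comp_add(a, setNames(-unclass(b), names(b)))
}

#' Parse a molecular formula string
#'
#' Accepts simple formulas such as \code{"C6H7NO2"} (no parentheses, no
#' isotope specifiers).
#' @param formula a formula string
#' @return an \code{elemental_composition}
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (formula == "" ) return(composition())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: ", formula)
  els <- sub("[0-9]*$", "", parts)
  cnt <- as.numeric(ifelse(grepl("[0-9]", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(cnt, els, sum)
  as_composition(setNames(as.numeric(out), names(out)))
}

# ---------------------------------------------------------------------------
# Protein species

#' Define a protein species
#'
#' A protein species is a one-letter amino-acid sequence plus its terminal
#' state and fixed modifications. Residue numbering is 1-based counting the
#' first residue of the supplied sequence (the initiator Met is counted when
#' present; for human MT3 this puts the first labeled cysteines at Cys6 and
#' Cys8).
#'
#' @param id identifier string
#' @param sequence one-letter amino-acid sequence (20 canonical letters)
#' @param n_terminal_acetyl logical; is the N-terminus acetylated?
#' @param fixed_mods optional list of fixed modifications, each a list with
#'   \code{name}, \code{formula} (delta composition or formula string) and
#'   \code{positions} (1-based residue indices)
#' @return an object of class \code{protein_species}
#' @export
protein_species <- function(id, sequence, n_terminal_acetyl = FALSE,
                            fixed_mods = list()) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- which(!letters1 %in% names(.RESIDUE_COMPOSITIONS))
  if (length(bad) > 0)
    stop("non-canonical residue '", letters1[bad[1]], "' at position ", bad[1])
  fixed_mods <- lapply(fixed_mods, function(m) {
    if (is.character(m$formula)) m$formula <- parse_formula(m$formula)
    m
  })
  structure(list(id = id, sequence = sequence,
                 n_terminal_acetyl = isTRUE(n_terminal_acetyl),
                 fixed_mods = fixed_mods),
            class = "protein_species")
}

#' @export
print.protein_species <- function(x, ...) {
  cat(sprintf("protein_species %s: %d residues, %d Cys%s\n", x$id,
              nchar(x$sequence), n_cysteines(x),
              if (x$n_terminal_acetyl) ", N-terminal acetyl" else ""))
  invisible(x)
}

#' @export
n_residues <- function(protein) nchar(protein$sequence)

#' Cysteine count and positions
#'
#' @param protein a \code{protein_species}
#' @return \code{n_cysteines}: integer count; \code{cys_positions}: 1-based
#'   positions of cysteines in the sequence
#' @export
n_cysteines <- function(protein) length(cys_positions(protein))

#' @rdname n_cysteines
#' @export
cys_positions <- function(protein) {
  which(strsplit(protein$sequence, "")[[1]] == "C")
}

#' Elemental composition of a protein (or residue span)
#'
#' Sums residue compositions plus one water; includes the N-terminal acetyl
#' delta when flagged and any fixed modifications falling inside the span.
#'
#' @param protein a \code{protein_species}
#' @param span optional integer range \code{c(from, to)} of residues; the
#'   water and terminal deltas are only added for the spans that include the
#'   respective terminus (used by fragment arithmetic)
#' @return an \code{elemental_composition}
#' @export
composition_from_sequence <- function(protein, span = NULL) {
  n <- n_residues(protein)
  if (is.null(span)) span <- c(1L, n)
  stopifnot(span[1] >= 1, span[2] <= n, span[1] <= span[2])
  letters1 <- strsplit(protein$sequence, "")[[1]][span[1]:span[2]]
  comp <- composition()
  tab <- table(letters1)
  for (aa in names(tab))
    comp <- comp_add(comp, comp_scale(as_composition(.RESIDUE_COMPOSITIONS[[aa]]),
                                      tab[[aa]]))
  full <- span[1] == 1 && span[2] == n
  if (full) comp <- comp_add(comp, composition(H = 2, O = 1))
  if (protein$n_terminal_acetyl && span[1] == 1)
    comp <- comp_add(comp, adduct_delta("NtermAcetyl")$formula)
  for (m in protein$fixed_mods) {
    k <- sum(m$positions >= span[1] & m$positions <= span[2])
    if (k > 0) comp <- comp_add(comp, comp_scale(m$formula, k))
  }
  comp
}

# ---------------------------------------------------------------------------
# Masses

#' Monoisotopic and average mass of a composition
#'
#' @param comp an \code{elemental_composition}
#' @param convention for \code{monoisotopic_mass}: \code{"most_abundant"}
#'   (default) uses each element's most abundant isotope; \code{"lightest"}
#'   uses the lightest. The two agree for C/H/N/O/S; they differ for Cd,
#'   whose lightest isotope is rare. Pattern fitting always uses the full
#'   isotope distribution, so the convention only affects reported single
#'   masses.
#' @return mass in Da
#' @export
monoisotopic_mass <- function(comp, convention = c("most_abundant", "lightest")) {
  convention <- match.arg(convention)
  if (length(comp) == 0) return(0)
  .check_elements(names(comp))
  m <- vapply(names(comp), function(el) {
    iso <- .ISOTOPES[[el]]
    if (convention == "most_abundant") iso$mass[which.max(iso$abundance)]
    else min(iso$mass)
  }, numeric(1))
  sum(m * unclass(comp))
}

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(comp) {
  if (length(comp) == 0) return(0)
  .check_elements(names(comp))
  sum(.ATOMIC_WEIGHTS[names(comp)] * unclass(comp))
}

# ---------------------------------------------------------------------------
# Isotope patterns

# Merge pattern entries closer than merge_tol (Da) into abundance-weighted
# means; this aggregates isotopologue fine structure (spacings of a few mDa)
# while keeping the ~1 Da isotopologue peaks separate.
.merge_pattern <- function(mass, abundance, merge_tol) {
  ord <- order(mass)
  mass <- mass[ord]; abundance <- abundance[ord]
  grp <- cumsum(c(1, diff(mass) > merge_tol))
  ab <- as.numeric(tapply(abundance, grp, sum))
  mz <- as.numeric(tapply(mass * abundance, grp, sum)) / ab
  list(mass = mz, abundance = ab)
}

.convolve_patterns <- function(p1, p2, prune, merge_tol) {
  mass <- outer(p1$mass, p2$mass, `+`)
  ab <- outer(p1$abundance, p2$abundance, `*`)
  keep <- ab > max(ab) * prune * 1e-3  # loose pre-prune to bound growth
  p <- .merge_pattern(mass[keep], ab[keep], merge_tol)
  keep2 <- p$abundance > max(p$abundance) * prune * 1e-3
  list(mass = p$mass[keep2], abundance = p$abundance[keep2])
}

# Pattern of element^n by exponentiation-by-squaring convolution.
.element_pattern <- function(el, n, prune, merge_tol) {
  iso <- .ISOTOPES[[el]]
  base <- list(mass = iso$mass, abundance = iso$abundance)
  result <- NULL
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base
                else .convolve_patterns(result, base, prune, merge_tol)
    }
    n <- n %/% 2
    if (n > 0) base <- .convolve_patterns(base, base, prune, merge_tol)
  }
  result
}

#' Aggregated isotope pattern of a composition
#'
#' Computes the isotopologue distribution by iterative per-element
#' convolution with pruning, aggregating fine structure within
#' \code{merge_tol} Da (native-MS peak widths dominate such splittings).
#' The result is normalized to total abundance 1 and sorted by mass.
#'
#' @param comp an \code{elemental_composition}
#' @param prune relative-abundance pruning threshold in (0, 1); entries
#'   below \code{prune} times the most abundant isotopologue are dropped
#' @param merge_tol fine-structure aggregation width in Da
#' @return an object of class \code{isotope_pattern}: a list with numeric
#'   vectors \code{mass} (neutral Da, strictly increasing) and
#'   \code{abundance} (sums to 1)
#' @export
isotope_pattern <- function(comp, prune = 1e-6, merge_tol = 0.2) {
  stopifnot(prune > 0, prune < 1)
  if (length(comp) == 0)
    return(structure(list(mass = 0, abundance = 1), class = "isotope_pattern"))
  .check_elements(names(comp))
  pat <- NULL
  for (el in names(comp)) {
    pe <- .element_pattern(el, unclass(comp)[[el]], prune, merge_tol)
    pat <- if (is.null(pat)) pe else .convolve_patterns(pat, pe, prune, merge_tol)
  }
  keep <- pat$abundance > max(pat$abundance) * prune
  m <- pat$mass[keep]; a <- pat$abundance[keep]
  ord <- order(m)
  a <- a[ord] / sum(a[ord])
  structure(list(mass = m[ord], abundance = a), class = "isotope_pattern")
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat(sprintf("isotope_pattern: %d isotopologues, %.4f-%.4f Da\n",
              length(x$mass), min(x$mass), max(x$mass)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Adduct deltas

# name -> list(formula added, h_displaced (H atoms removed), cys_consumed)
.ADDUCTS <- list(
  Cu_I  = list(formula = c(Cu = 1), h_displaced = 1L, cys_consumed = 1L),
  Zn_II = list(formula = c(Zn = 1), h_displaced = 2L, cys_consumed = 1L),
  Cd_II = list(formula = c(Cd = 1), h_displaced = 2L, cys_consumed = 1L),
  NEM   = list(formula = c(C = 6, H = 7, N = 1, O = 2),
               h_displaced = 0L, cys_consumed = 1L),
  CAM   = list(formula = c(C = 2, H = 3, N = 1, O = 1),
               h_displaced = 0L, cys_consumed = 1L),
  SS    = list(formula = c(), h_displaced = 2L, cys_consumed = 2L),
  NtermAcetyl = list(formula = c(C = 2, H = 2, O = 1),
                     h_displaced = 0L, cys_consumed = 0L)
)

#' Adduct deltas
#'
#' Mass-bookkeeping rules for the supported adducts: Cu(I) displaces one
#' proton from a thiol, Zn(II) and Cd(II) displace two; NEM (Michael
#' addition) adds C6H7NO2 to one cysteine; CAM, the carbamidomethyl adduct
#' left by iodoacetamide, adds C2H3NO to one cysteine; a disulfide (SS)
#' removes two hydrogens and consumes two cysteines; N-terminal acetylation
#' adds C2H2O.
#'
#' @param name one of \code{"Cu_I"}, \code{"Zn_II"}, \code{"Cd_II"},
#'   \code{"NEM"}, \code{"CAM"}, \code{"SS"}, \code{"NtermAcetyl"}
#' @return a list with \code{name}, \code{formula}
#'   (\code{elemental_composition} added), \code{h_displaced} (hydrogens
#'   removed) and \code{cys_consumed}
#' @export
adduct_delta <- function(name) {
  if (!name %in% names(.ADDUCTS)) stop("unknown adduct: ", name)
  a <- .ADDUCTS[[name]]
  list(name = name, formula = as_composition(a$formula),
       h_displaced = a$h_displaced, cys_consumed = a$cys_consumed)
}

#' Apply (or remove) adducts to a composition
#'
#' @param comp an \code{elemental_composition}
#' @param name adduct name (see \code{\link{adduct_delta}})
#' @param n signed count; negative removes previously applied adducts
#' @return the modified composition
#' @export
apply_adduct <- function(comp, name, n = 1) {
  a <- adduct_delta(name)
  stopifnot(n == round(n))
  delta <- comp_scale(a$formula, abs(n))
  hdel <- composition(H = 1)
  if (n >= 0) {
    out <- comp_add(comp, delta)
    if (a$h_displaced > 0)
      out <- comp_subtract(out, comp_scale(hdel, a$h_displaced * n))
  } else {
    out <- comp_subtract(comp, delta)
    if (a$h_displaced > 0)
      out <- comp_add(out, comp_scale(hdel, a$h_displaced * abs(n)))
  }
  out
}

# ---------------------------------------------------------------------------
# FASTA and chemistry-model configuration

#' Read protein sequences from a FASTA file
#'
#' @param path path to a single- or multi-record amino-acid FASTA file
#' @param n_terminal_acetyl logical, applied to every record
#' @return a named list of \code{protein_species}
#' @export
read_fasta <- function(path, n_terminal_acetyl = FALSE) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- lapply(names(recs), function(nm) {
    protein_species(nm, as.character(recs[[nm]]),
                    n_terminal_acetyl = n_terminal_acetyl)
  })
  names(out) <- names(recs)
  out
}

#' Chemistry-model configuration
#'
#' The chemistry model lists the metals and labels in play, the disulfide
#' count range, the charge states and the minimum number of cysteines a
#' bound metal consumes from the budget. \code{default_chem_config()}
#' returns the defaults used throughout (Cu/Zn metals, NEM/CAM labels,
#' 1-2 disulfides for oxidized species, charges 4-5, one cysteine per
#' metal); \code{read_chem_config()} reads a YAML file with the same
#' fields, filling unspecified fields from the defaults.
#'
#' @param path path to a YAML configuration file
#' @return a list with fields \code{metals}, \code{labels}, \code{ss_range},
#'   \code{charges}, \code{min_cys_per_metal}, \code{resolving_power},
#'   \code{ppm_tol}, \code{mz_window}, \code{min_score}
#' @export
default_chem_config <- function() {
  list(metals = c("Cu_I", "Zn_II"),
       labels = c("NEM", "CAM"),
       ss_range = c(1L, 2L),
       charges = c(4L, 5L),
       min_cys_per_metal = 1L,
       resolving_power = 10000,
       ppm_tol = 20,
       mz_window = 3,
       min_score = 0.7)
}

#' @rdname default_chem_config
#' @export
read_chem_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(default_chem_config(), cfg)
  stopifnot(out$min_cys_per_metal >= 0, out$resolving_power > 0,
            out$ppm_tol > 0, out$mz_window > 0)
  out
}
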