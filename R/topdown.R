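# Top-down CID b/y fragment ions with metal and label adducts: candidate
# generation, peak matching, complementary-pair parent reconstruction,
# label localization and fragmentation maps.
#
# Conventions: b_i = sum of residues 1..i (plus the N-terminal acetyl when
# the protein carries one); y_j = sum of residues n-j+1..n plus water.
# Metals displace protons on fragments exactly as on the parent.
# Disulfides are bookkept at parent level by default (connectivity is
# unknown), so complementary neutral masses satisfy
#   b_i + y_{n-i} = parent_neutral + 2 * n_ss * m_H .

.fragment_neutral_comp <- function(protein, type, index) {
  n <- n_residues(protein)
  stopifnot(index >= 1, index < n)
  if (type == "b") {
    composition_from_sequence(protein, span = c(1L, as.integer(index)))
  } else {
    comp <- composition_from_sequence(protein,
                                      span = c(n - as.integer(index) + 1L, n))
    comp_add(comp, composition(H = 2, O = 1))
  }
}

.fragment_cys_count <- function(protein, type, index) {
  n <- n_residues(protein)
  cys <- cys_positions(protein)
  if (type == "b") sum(cys <= index) else sum(cys > n - index)
}

#' Generate b/y fragment candidates for a metalloform parent
#'
#' Enumerates, for every cleavage site and fragment type, the adduct
#' partitions consistent with the cysteine budgets on both sides of the
#' cleavage: labels on a fragment cannot exceed its cysteine count, labels
#' left on the complementary fragment cannot exceed the complementary
#' cysteine count, and metals may sit on either side (no domain assumption).
#' Disulfides stay at parent level by default.
#'
#' @param protein a \code{protein_species}
#' @param parent a \code{metalloform} (the precursor composition)
#' @param types fragment types, subset of \code{c("b", "y")}
#' @param charges fragment charge states
#' @param partition_cap maximum number of adduct partitions kept per
#'   (type, index, z), in lexicographic (parsimony-first) order;
#'   default unlimited
#' @param min_cys_per_metal budget consumed per metal on a fragment
#' @return data frame of fragment candidates: \code{type}, \code{index},
#'   adduct counts, \code{z}, \code{neutral_mono}, \code{mz_mono},
#'   \code{cys_in_fragment}
#' @export
generate_fragments <- function(protein, parent, types = c("b", "y"),
                               charges = 1L, partition_cap = Inf,
                               min_cys_per_metal = 1) {
  if (!cys_budget_ok(protein, parent, min_cys_per_metal))
    stop("parent adducts exceed the protein cysteine budget")
  n <- n_residues(protein)
  ncys <- n_cysteines(protein)
  out <- list()
  for (type in types) {
    for (index in seq_len(n - 1L)) {
      cys_f <- .fragment_cys_count(protein, type, index)
      cys_c <- ncys - cys_f
      base <- .fragment_neutral_comp(protein, type, index)
      # feasible label partitions: frag side fits, complement side fits
      nem_lo <- max(0L, parent$n_nem - cys_c); nem_hi <- min(parent$n_nem, cys_f)
      iam_lo <- max(0L, parent$n_iam - cys_c); iam_hi <- min(parent$n_iam, cys_f)
      if (nem_lo > nem_hi || iam_lo > iam_hi) next
      nem_rng <- nem_lo:nem_hi
      iam_rng <- iam_lo:iam_hi
      parts <- expand.grid(n_cu = 0:parent$n_cu, n_zn = 0:parent$n_zn,
                           n_cd = 0:parent$n_cd, n_nem = nem_rng,
                           n_iam = iam_rng)
      parts <- parts[parts$n_nem + parts$n_iam <= cys_f, , drop = FALSE]
      if (nrow(parts) == 0) next
      parts <- parts[order(parts$n_cu + parts$n_zn + parts$n_cd +
                           parts$n_nem + parts$n_iam,
                           parts$n_cu, parts$n_zn, parts$n_cd,
                           parts$n_nem, parts$n_iam), , drop = FALSE]
      if (is.finite(partition_cap))
        parts <- utils::head(parts, partition_cap)
      for (p in seq_len(nrow(parts))) {
        comp <- base
        for (ad in c("Cu_I", "Zn_II", "Cd_II", "NEM", "CAM")) {
          cnt <- switch(ad, Cu_I = parts$n_cu[p], Zn_II = parts$n_zn[p],
                        Cd_II = parts$n_cd[p], NEM = parts$n_nem[p],
                        CAM = parts$n_iam[p])
          if (cnt > 0) comp <- apply_adduct(comp, ad, cnt)
        }
        m0 <- monoisotopic_mass(comp)
        for (zf in charges) {
          out[[length(out) + 1L]] <- data.frame(
            type = type, index = index,
            n_cu = parts$n_cu[p], n_zn = parts$n_zn[p],
            n_cd = parts$n_cd[p], n_nem = parts$n_nem[p],
            n_iam = parts$n_iam[p], z = as.integer(zf),
            neutral_mono = m0,
            mz_mono = (m0 + zf * PROTON_MASS) / zf,
            cys_in_fragment = cys_f)
        }
      }
    }
  }
  if (length(out) == 0) return(.empty_fragment_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_fragment_table <- function() {
  data.frame(type = character(0), index = integer(0), n_cu = integer(0),
             n_zn = integer(0), n_cd = integer(0), n_nem = integer(0),
             n_iam = integer(0), z = integer(0), neutral_mono = numeric(0),
             mz_mono = numeric(0), cys_in_fragment = integer(0))
}

#' Match fragment candidates to an observed spectrum
#'
#' Nearest-candidate matching within a mass tolerance; each observed peak
#' receives at most one candidate, ties broken by smaller absolute error,
#' then by parsimony (fewer total adducts).
#'
#' @param observed a centroided \code{mass_spectrum}
#' @param candidates fragment table from \code{\link{generate_fragments}}
#' @param tol tolerance value (default 20)
#' @param tol_type \code{"ppm"} (default, as used for fragment searches)
#'   or \code{"mz"} for absolute m/z tolerance
#' @return data frame of annotations: candidate columns plus
#'   \code{obs_mz}, \code{ppm}, \code{intensity}
#' @export
match_fragments <- function(observed, candidates, tol = 20,
                            tol_type = c("ppm", "mz")) {
  tol_type <- match.arg(tol_type)
  if (observed$mode != "centroid")
    stop("match_fragments() expects a centroided spectrum")
  empty <- cbind(.empty_fragment_table(),
                 data.frame(obs_mz = numeric(0), ppm = numeric(0),
                            intensity = numeric(0)))
  if (length(observed$mz) == 0 || nrow(candidates) == 0) return(empty)
  out <- list()
  adducts <- with(candidates, n_cu + n_zn + n_cd + n_nem + n_iam)
  for (i in seq_along(observed$mz)) {
    omz <- observed$mz[i]
    err <- omz - candidates$mz_mono
    lim <- if (tol_type == "ppm") tol * 1e-6 * candidates$mz_mono else tol
    ok <- which(abs(err) <= lim)
    if (length(ok) == 0) next
    best <- ok[order(abs(err[ok]), adducts[ok])][1]
    row <- candidates[best, , drop = FALSE]
    row$obs_mz <- omz
    row$ppm <- err[best] / candidates$mz_mono[best] * 1e6
    row$intensity <- observed$intensity[i]
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reconstruct the parent stoichiometry from a complementary b/y pair
#'
#' For a b_i / y_{n-i} pair, sums the two adduct partitions and residue
#' spans into the implied parent composition. Disulfide counts are not
#' inferable from parent-level bookkeeping and must be supplied.
#'
#' @param b_ann,y_ann one-row fragment annotations (or candidates) with
#'   \code{type}, \code{index} and adduct counts
#' @param protein a \code{protein_species}
#' @param n_ss disulfide count to assign to the reconstructed parent
#' @param z charge to assign to the reconstructed parent
#' @return a \code{metalloform}, or an error when indices are not
#'   complementary
#' @export
complementary_reconstruction <- function(b_ann, y_ann, protein, n_ss = 0,
                                         z = 1) {
  stopifnot(b_ann$type == "b", y_ann$type == "y")
  n <- n_residues(protein)
  if (b_ann$index + y_ann$index != n)
    stop(sprintf("fragments are not complementary: b%d + y%d covers %d of %d residues",
                 b_ann$index, y_ann$index, b_ann$index + y_ann$index, n))
  metalloform(n_cu = b_ann$n_cu + y_ann$n_cu,
              n_zn = b_ann$n_zn + y_ann$n_zn,
              n_cd = b_ann$n_cd + y_ann$n_cd,
              n_nem = b_ann$n_nem + y_ann$n_nem,
              n_iam = b_ann$n_iam + y_ann$n_iam,
              n_ss = n_ss, acetyl = protein$n_terminal_acetyl, z = z)
}

# Walk one fragment ladder (b ascending, or y mirrored) for one label type
# and return per-Cys states. informative: data.frame(index, count) with one
# consistent count per index; conflicting counts drop the index.
.walk_ladder <- function(protein, type, frags, label_col) {
  n <- n_residues(protein)
  cys <- cys_positions(protein)
  states <- setNames(rep("undetermined", length(cys)), cys)
  conflict <- FALSE
  if (nrow(frags) == 0)
    return(list(states = states, conflict = conflict))
  counts <- tapply(frags[[label_col]], frags$index,
                   function(v) if (length(unique(v)) == 1) v[1] else NA_real_)
  idx <- as.integer(names(counts))
  ok <- !is.na(counts)
  idx <- idx[ok]; counts <- as.numeric(counts[ok])
  ord <- order(idx)
  idx <- idx[ord]; counts <- counts[ord]
  prev_i <- 0L; prev_c <- 0
  for (k in seq_along(idx)) {
    # residue positions bracketed by the previous and current fragment
    pos <- if (type == "b") {
      cys[cys > prev_i & cys <= idx[k]]
    } else {
      cys[cys > n - idx[k] & cys <= n - prev_i]
    }
    delta <- counts[k] - prev_c
    key <- as.character(pos)
    if (delta < 0) {
      conflict <- TRUE
      states[key] <- "undetermined"
    } else if (length(pos) > 0) {
      if (delta == 0) states[key] <- "unmodified"
      else if (delta == length(pos)) states[key] <- "labeled"
      else states[key] <- "undetermined"
    }
    prev_i <- idx[k]; prev_c <- counts[k]
  }
  list(states = states, conflict = conflict)
}

.combine_states <- function(a, b) {
  mapply(function(x, y) {
    if (x == y) return(x)
    if (x == "undetermined") return(y)
    if (y == "undetermined") return(x)
    "conflict"
  }, a, b)
}

#' Localize cysteine labels from fragment-ion ladders
#'
#' Walks the b ladder (and the y ladder, mirrored) of matched fragments
#' from a single parent: a label-count increment between consecutive
#' informative fragments places those labels on the cysteines in the
#' bracketed residue interval when their number matches the increment
#' exactly; otherwise the bracketed cysteines stay undetermined. Zero
#' increments mark bracketed cysteines unmodified. NEM and IAM ladders are
#' walked independently; disagreeing ladders flag a conflict.
#'
#' @param annotations fragment annotations (from
#'   \code{\link{match_fragments}}) of a single parent
#' @param protein a \code{protein_species}
#' @return an object of class \code{localization_result}: a data frame with
#'   \code{position} (Cys residue number, initiator-Met-inclusive
#'   numbering), \code{position_noMet} (the alternate numbering without
#'   the initiator Met, reported because both conventions circulate),
#'   \code{state} in \{labeled-NEM, labeled-IAM, unmodified,
#'   undetermined\}, and attribute \code{"conflict"}
#' @export
localize_labels <- function(annotations, protein) {
  cys <- cys_positions(protein)
  per_label <- lapply(c(nem = "n_nem", iam = "n_iam"), function(col) {
    ladders <- lapply(c("b", "y"), function(ty) {
      .walk_ladder(protein, ty,
                   annotations[annotations$type == ty, , drop = FALSE], col)
    })
    states <- .combine_states(ladders[[1]]$states, ladders[[2]]$states)
    list(states = states,
         conflict = ladders[[1]]$conflict || ladders[[2]]$conflict ||
           any(states == "conflict"))
  })
  nem <- per_label$nem$states
  iam <- per_label$iam$states
  state <- mapply(function(s_nem, s_iam) {
    if (s_nem == "conflict" || s_iam == "conflict") return("undetermined")
    if (s_nem == "labeled" && s_iam == "labeled") return("undetermined")
    if (s_nem == "labeled") return("labeled-NEM")
    if (s_iam == "labeled") return("labeled-IAM")
    if (s_nem == "unmodified" && s_iam == "unmodified") return("unmodified")
    "undetermined"
  }, nem, iam)
  res <- data.frame(position = cys, position_noMet = cys - 1L,
                    state = unname(state))
  attr(res, "conflict") <- per_label$nem$conflict || per_label$iam$conflict
  class(res) <- c("localization_result", "data.frame")
  res
}

#' Fragmentation map and sequence coverage
#'
#' Per cleavage site (1..n-1): the supporting b and y annotations with
#' their adduct counts. Sequence coverage is the fraction of cleavage
#' sites bracketed by at least one informative ion.
#'
#' @param annotations fragment annotations
#' @param protein a \code{protein_species}
#' @return a list with \code{map} (data frame: \code{site}, \code{b_ions},
#'   \code{y_ions}, \code{b_max_nem}, \code{y_max_nem}, \code{b_max_iam},
#'   \code{y_max_iam}, \code{covered}) and \code{coverage} (percent)
#' @export
fragmentation_map <- function(annotations, protein) {
  n <- n_residues(protein)
  sites <- seq_len(n - 1L)
  b_idx <- annotations$index[annotations$type == "b"]
  y_idx <- annotations$index[annotations$type == "y"]
  cnt <- function(v, s) sum(v == s)
  mx <- function(col, ty, s) {
    sel <- annotations$type == ty &
      annotations$index == (if (ty == "b") s else n - s)
    if (!any(sel)) NA_integer_ else max(annotations[[col]][sel])
  }
  map <- data.frame(
    site = sites,
    b_ions = vapply(sites, function(s) cnt(b_idx, s), numeric(1)),
    y_ions = vapply(sites, function(s) cnt(y_idx, n - s), numeric(1)),
    b_max_nem = vapply(sites, function(s) mx("n_nem", "b", s), integer(1)),
    y_max_nem = vapply(sites, function(s) mx("n_nem", "y", s), integer(1)),
    b_max_iam = vapply(sites, function(s) mx("n_iam", "b", s), integer(1)),
    y_max_iam = vapply(sites, function(s) mx("n_iam", "y", s), integer(1)))
  map$covered <- map$b_ions + map$y_ions > 0
  list(map = map, coverage = 100 * mean(map$covered))
}
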