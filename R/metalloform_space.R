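# Candidate metalloform enumeration under the cysteine-budget constraint,
# neutral masses, m/z and isobaric grouping.

#' Define a metalloform composition
#'
#' A metalloform composition counts the metal ions (Cu(I), Zn(II), Cd(II)),
#' cysteine labels (NEM, IAM/CAM), intramolecular disulfides and the charge
#' of one annotated species.
#'
#' @param n_cu,n_zn,n_cd metal counts
#' @param n_nem,n_iam label counts (IAM refers to the carbamidomethyl
#'   adduct it leaves)
#' @param n_ss intramolecular disulfide count
#' @param acetyl logical, N-terminal acetylation
#' @param z positive charge state
#' @return an object of class \code{metalloform}
#' @export
metalloform <- function(n_cu = 0, n_zn = 0, n_cd = 0, n_nem = 0, n_iam = 0,
                        n_ss = 0, acetyl = FALSE, z = 1) {
  counts <- c(n_cu = n_cu, n_zn = n_zn, n_cd = n_cd, n_nem = n_nem,
              n_iam = n_iam, n_ss = n_ss)
  stopifnot(all(counts >= 0), all(counts == round(counts)), z >= 1,
            z == round(z))
  structure(list(n_cu = as.integer(n_cu), n_zn = as.integer(n_zn),
                 n_cd = as.integer(n_cd), n_nem = as.integer(n_nem),
                 n_iam = as.integer(n_iam), n_ss = as.integer(n_ss),
                 acetyl = isTRUE(acetyl), z = as.integer(z)),
            class = "metalloform")
}

#' @export
print.metalloform <- function(x, ...) {
  cat(metalloform_label(x), sprintf("%d+\n", x$z))
  invisible(x)
}

#' Human-readable species label, e.g. "Cu4Zn4SS2"
#' @param mfc a \code{metalloform}
#' @export
metalloform_label <- function(mfc) {
  parts <- c(
    if (mfc$n_cu > 0) paste0("Cu", mfc$n_cu),
    if (mfc$n_zn > 0) paste0("Zn", mfc$n_zn),
    if (mfc$n_cd > 0) paste0("Cd", mfc$n_cd),
    if (mfc$n_nem > 0) paste0("NEM", mfc$n_nem),
    if (mfc$n_iam > 0) paste0("IAM", mfc$n_iam),
    if (mfc$n_ss > 0) paste0("SS", mfc$n_ss),
    if (mfc$acetyl) "NAc")
  if (length(parts) == 0) "apo" else paste(parts, collapse = "")
}

.mfc_adduct_counts <- function(mfc) {
  c(Cu_I = mfc$n_cu, Zn_II = mfc$n_zn, Cd_II = mfc$n_cd,
    NEM = mfc$n_nem, CAM = mfc$n_iam, SS = mfc$n_ss)
}

#' Cysteine-budget feasibility
#'
#' A composition is feasible when the labels, disulfides (two cysteines
#' each) and metals (at least \code{min_cys_per_metal} cysteines each) fit
#' inside the protein's cysteine count.
#'
#' @param protein a \code{protein_species}
#' @param mfc a \code{metalloform}
#' @param min_cys_per_metal minimum cysteines consumed per bound metal
#'   (default 1; bridging thiolates make lower coordination bookkeeping
#'   safe, and species with four Cu(I) plus up to 13 NEM are observed)
#' @return logical
#' @export
cys_budget_ok <- function(protein, mfc, min_cys_per_metal = 1) {
  used <- mfc$n_nem + mfc$n_iam + 2 * mfc$n_ss +
    min_cys_per_metal * (mfc$n_cu + mfc$n_zn + mfc$n_cd)
  used <= n_cysteines(protein)
}

#' Elemental composition of a metalloform
#'
#' Applies every adduct delta of \code{mfc} (metals displacing protons,
#' labels adding their formulas, disulfides removing 2 H each) to the
#' protein composition. The protein's own acetyl flag and the metalloform's
#' acetyl flag are OR-ed.
#'
#' @inheritParams cys_budget_ok
#' @return an \code{elemental_composition} of the neutral species
#' @export
metalloform_composition <- function(protein, mfc) {
  comp <- composition_from_sequence(protein)
  if (mfc$acetyl && !protein$n_terminal_acetyl)
    comp <- apply_adduct(comp, "NtermAcetyl")
  for (ad in c("Cu_I", "Zn_II", "Cd_II", "NEM", "CAM", "SS")) {
    n <- .mfc_adduct_counts(mfc)[[ad]]
    if (n > 0) comp <- apply_adduct(comp, ad, n)
  }
  comp
}

#' Neutral mass and m/z of a metalloform
#'
#' @inheritParams cys_budget_ok
#' @param scale \code{"average"} or \code{"monoisotopic"}
#' @param z charge (defaults to the metalloform's own charge)
#' @return mass in Da / m/z
#' @export
neutral_mass <- function(protein, mfc, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  comp <- metalloform_composition(protein, mfc)
  if (scale == "average") average_mass(comp) else monoisotopic_mass(comp)
}

#' @rdname neutral_mass
#' @export
mz <- function(protein, mfc, scale = c("average", "monoisotopic"), z = mfc$z) {
  stopifnot(z >= 1)
  (neutral_mass(protein, mfc, scale) + z * PROTON_MASS) / z
}

#' Enumerate candidate metalloforms
#'
#' Cartesian product over the per-adduct count ranges, filtered by the
#' cysteine budget, in deterministic lexicographic order (by n_cu, n_zn,
#' n_cd, n_nem, n_iam, n_ss, z).
#'
#' @param protein a \code{protein_species}
#' @param ranges named list of \code{c(min, max)} count ranges; recognized
#'   names are \code{cu}, \code{zn}, \code{cd}, \code{nem}, \code{iam},
#'   \code{ss}; omitted adducts default to \code{c(0, 0)}
#' @param charges vector of positive charge states
#' @param min_cys_per_metal see \code{\link{cys_budget_ok}}
#' @param acetyl logical, applied to all candidates
#' @return a \code{candidate_set}: a data frame with count columns, neutral
#'   masses (\code{mass_avg}, \code{mass_mono}) and \code{mz_avg},
#'   \code{mz_mono}; the protein is attached as attribute \code{"protein"}
#' @export
enumerate_candidates <- function(protein, ranges = list(), charges = 5L,
                                 min_cys_per_metal = 1, acetyl = FALSE) {
  rng <- function(nm) {
    r <- ranges[[nm]]
    if (is.null(r)) c(0L, 0L) else {
      if (length(r) == 1) r <- c(r, r)
      stopifnot(all(is.finite(r)), r[1] >= 0, r[1] <= r[2])
      as.integer(r)
    }
  }
  cu <- rng("cu"); zn <- rng("zn"); cd <- rng("cd")
  nem <- rng("nem"); iam <- rng("iam"); ss <- rng("ss")
  stopifnot(all(charges >= 1), min_cys_per_metal >= 0)
  grid <- expand.grid(z = sort(as.integer(charges)),
                      n_ss = ss[1]:ss[2], n_iam = iam[1]:iam[2],
                      n_nem = nem[1]:nem[2], n_cd = cd[1]:cd[2],
                      n_zn = zn[1]:zn[2], n_cu = cu[1]:cu[2])
  grid <- grid[, c("n_cu", "n_zn", "n_cd", "n_nem", "n_iam", "n_ss", "z")]
  grid <- grid[order(grid$n_cu, grid$n_zn, grid$n_cd, grid$n_nem,
                     grid$n_iam, grid$n_ss, grid$z), , drop = FALSE]
  budget <- grid$n_nem + grid$n_iam + 2 * grid$n_ss +
    min_cys_per_metal * (grid$n_cu + grid$n_zn + grid$n_cd)
  keep <- budget <= n_cysteines(protein)
  if (!any(keep)) {
    warning("no candidate satisfies the cysteine budget; returning empty set")
    grid <- grid[0, , drop = FALSE]
  } else grid <- grid[keep, , drop = FALSE]
  rownames(grid) <- NULL
  grid$acetyl <- rep(acetyl | protein$n_terminal_acetyl, nrow(grid))
  # masses: compute each distinct neutral composition once
  if (nrow(grid) > 0) {
    neutral_key <- do.call(paste, c(grid[c("n_cu", "n_zn", "n_cd", "n_nem",
                                           "n_iam", "n_ss", "acetyl")],
                                    sep = "/"))
    uk <- !duplicated(neutral_key)
    mm <- setNames(numeric(sum(uk)), neutral_key[uk])
    ma <- mm
    for (i in which(uk)) {
      mfc <- .row_to_metalloform(grid[i, ])
      mm[[neutral_key[i]]] <- neutral_mass(protein, mfc, "monoisotopic")
      ma[[neutral_key[i]]] <- neutral_mass(protein, mfc, "average")
    }
    grid$mass_mono <- as.numeric(mm[neutral_key])
    grid$mass_avg <- as.numeric(ma[neutral_key])
    grid$mz_mono <- (grid$mass_mono + grid$z * PROTON_MASS) / grid$z
    grid$mz_avg <- (grid$mass_avg + grid$z * PROTON_MASS) / grid$z
    grid$species <- vapply(seq_len(nrow(grid)), function(i)
      metalloform_label(.row_to_metalloform(grid[i, ])), character(1))
  } else {
    grid$mass_mono <- grid$mass_avg <- grid$mz_mono <- grid$mz_avg <- numeric(0)
    grid$species <- character(0)
  }
  structure(grid, protein = protein,
            class = c("candidate_set", "data.frame"))
}

.row_to_metalloform <- function(row) {
  metalloform(n_cu = row$n_cu, n_zn = row$n_zn, n_cd = row$n_cd,
              n_nem = row$n_nem, n_iam = row$n_iam, n_ss = row$n_ss,
              acetyl = row$acetyl, z = row$z)
}

#' Group near-isobaric candidates
#'
#' Partitions the candidates of one charge state into groups whose
#' neighboring m/z values fall within \code{window}; such groups cannot be
#' distinguished by mass alone in a native spectrum (e.g. the NEM(x)IAM(y) /
#' NEM(x+1)IAM(y-2) / NEM(x+2)IAM(y-4) triads, which are 11.0045/z apart,
#' or Cu4Zn4 vs Cu4NEM2 oxidized species near 1486 m/z at 5+).
#'
#' @param cands a \code{candidate_set}
#' @param z charge state to group
#' @param window m/z linkage width (default 3, suited to 5+ ions)
#' @param scale mass scale for the grouping m/z
#' @return the candidate rows of charge \code{z} with a \code{group_id}
#'   column, sorted by m/z within groups
#' @export
isobaric_groups <- function(cands, z, window = 3,
                            scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  stopifnot(window > 0)
  mzcol <- if (scale == "average") "mz_avg" else "mz_mono"
  sub <- cands[cands$z == z, , drop = FALSE]
  if (nrow(sub) == 0) {
    sub$group_id <- integer(0)
    return(sub)
  }
  ord <- order(sub[[mzcol]])
  sub <- sub[ord, , drop = FALSE]
  sub$group_id <- cumsum(c(1, diff(sub[[mzcol]]) > window))
  rownames(sub) <- NULL
  sub
}

#' Export a candidate table to CSV
#'
#' @param cands a \code{candidate_set}
#' @param path output CSV path
#' @export
write_candidates <- function(cands, path) {
  utils::write.csv(as.data.frame(cands), path, row.names = FALSE)
  invisible(path)
}
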