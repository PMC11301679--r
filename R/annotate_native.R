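# Native-MS annotation: theoretical isotope profiles at a given resolving
# power, cosine fit scoring, and joint non-negative least-squares
# deconvolution of overlapping candidates.

# Package-level cache for isotope patterns: enumerating a candidate set and
# scoring many spectra against it reuses the same neutral compositions.
.pattern_cache <- new.env(parent = emptyenv())

.cached_pattern <- function(comp, prune = 1e-6) {
  key <- paste0(format_composition(comp), "@", format(prune))
  if (!is.null(.pattern_cache[[key]])) return(.pattern_cache[[key]])
  pat <- isotope_pattern(comp, prune = prune)
  .pattern_cache[[key]] <- pat
  pat
}

#' Theoretical isotope profile of a metalloform
#'
#' Charges the neutral isotope pattern to \code{z} (adding \code{z} proton
#' masses and dividing by \code{z}) and renders each isotopologue as a
#' Gaussian of FWHM = m/z / resolving_power, summed on a regular grid and
#' normalized to maximum 1.
#'
#' @param protein a \code{protein_species}
#' @param mfc a \code{metalloform}
#' @param z charge (defaults to the metalloform's)
#' @param resolving_power instrument resolving power (FWHM definition);
#'   default 10000, typical of Q-TOF native MS
#' @param grid optional m/z grid to render on; default spans the pattern
#'   plus 2 FWHM at FWHM/8 spacing
#' @param prune isotope-pattern pruning threshold
#' @return a profile-mode \code{mass_spectrum}; the theoretical apex m/z is
#'   attached as attribute \code{"apex_mz"}
#' @export
theoretical_profile <- function(protein, mfc, z = mfc$z,
                                resolving_power = 10000, grid = NULL,
                                prune = 1e-6) {
  stopifnot(resolving_power > 0, z >= 1)
  pat <- .cached_pattern(metalloform_composition(protein, mfc), prune)
  mzs <- (pat$mass + z * PROTON_MASS) / z
  fwhm <- mzs / resolving_power
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (is.null(grid)) {
    pad <- 2 * max(fwhm)
    grid <- seq(min(mzs) - pad, max(mzs) + pad, by = min(fwhm) / 8)
  }
  y <- numeric(length(grid))
  for (k in seq_along(mzs))
    y <- y + pat$abundance[k] * exp(-(grid - mzs[k])^2 / (2 * sigma[k]^2))
  if (max(y) > 0) y <- y / max(y)
  out <- mass_spectrum(grid, y, "profile",
                       metadata = list(label = metalloform_label(mfc)))
  attr(out, "apex_mz") <- grid[which.max(y)]
  out
}

# Render a centroid spectrum as Gaussian sticks on a grid (used when
# scoring centroided observations against theoretical profiles).
.render_on_grid <- function(s, grid, resolving_power) {
  y <- numeric(length(grid))
  if (length(s$mz) == 0) return(y)
  if (s$mode == "profile") {
    if (length(s$mz) == 1) {
      j <- which.min(abs(grid - s$mz))
      y[j] <- s$intensity
      return(y)
    }
    return(stats::approx(s$mz, s$intensity, xout = grid, yleft = 0,
                         yright = 0, ties = "ordered")$y)
  }
  sigma <- (s$mz / resolving_power) / (2 * sqrt(2 * log(2)))
  for (k in seq_along(s$mz))
    y <- y + s$intensity[k] * exp(-(grid - s$mz[k])^2 / (2 * sigma[k]^2))
  y
}

#' Cosine fit score between observed and theoretical profiles
#'
#' Normalized cosine similarity between the observed spectrum, interpolated
#' onto the theoretical grid, and the theoretical profile, restricted to an
#' m/z window. Scale-invariant: uniform intensity scaling of the observed
#' spectrum leaves the score unchanged.
#'
#' @param observed a \code{mass_spectrum} (profile or centroid; centroids
#'   are rendered at \code{resolving_power})
#' @param theo a theoretical profile from \code{\link{theoretical_profile}}
#' @param window optional \code{c(lo, hi)} m/z window; default is the
#'   theoretical profile's support
#' @param resolving_power used to render centroided observations
#' @return a score in [0, 1]
#' @export
score_fit <- function(observed, theo, window = NULL,
                      resolving_power = 10000) {
  grid <- theo$mz
  if (!is.null(window)) {
    keep <- grid >= window[1] & grid <= window[2]
    if (!any(keep)) {
      warning("empty score window")
      return(0)
    }
    grid <- grid[keep]
    ty <- theo$intensity[keep]
  } else ty <- theo$intensity
  oy <- .render_on_grid(observed, grid, resolving_power)
  no <- sqrt(sum(oy^2)); nt <- sqrt(sum(ty^2))
  if (no == 0 || nt == 0) return(0)
  max(0, min(1, sum(oy * ty) / (no * nt)))
}

#' Annotate a native spectrum with metalloform assignments
#'
#' Implements isotope-pattern fitting: candidates whose theoretical apex
#' falls inside the observed range are scored by cosine similarity within
#' \code{mz_window} of their apex; candidates overlapping within a window
#' are deconvolved jointly by non-negative least squares on the profile,
#' giving fitted abundances. Assignments scoring below \code{min_score}
#' are dropped, and surviving near-isobaric sets share an ambiguity group
#' id. Ties are broken by parsimony: fewer total adducts, then lower metal
#' count.
#'
#' @param observed a \code{mass_spectrum}
#' @param cands a \code{candidate_set} from \code{\link{enumerate_candidates}}
#' @param config list of options: \code{resolving_power} (default 10000),
#'   \code{mz_window} (default 3), \code{min_score} (default 0.7),
#'   \code{scale} ("monoisotopic" grids; average-mass quick mode via
#'   \code{quick = TRUE} scores nothing and assigns by apex proximity)
#' @return a data frame of assignments: species label, counts, z,
#'   \code{theo_mz}, \code{score}, \code{abundance}, \code{group_id}
#'   (NA when unambiguous)
#' @export
annotate <- function(observed, cands, config = list()) {
  cfg <- utils::modifyList(list(resolving_power = 10000, mz_window = 3,
                                min_score = 0.7, prune = 1e-6), config)
  protein <- attr(cands, "protein")
  empty <- data.frame(species = character(0), n_cu = integer(0),
                      n_zn = integer(0), n_cd = integer(0),
                      n_nem = integer(0), n_iam = integer(0),
                      n_ss = integer(0), z = integer(0),
                      theo_mz = numeric(0), score = numeric(0),
                      abundance = numeric(0), group_id = integer(0))
  if (nrow(cands) == 0 || length(observed$mz) == 0) return(empty)
  obs_rng <- range(observed$mz)
  out <- list()
  gid_base <- 0L
  for (zc in sort(unique(cands$z))) {
    grp <- isobaric_groups(cands, z = zc, window = cfg$mz_window,
                           scale = "monoisotopic")
    grp <- grp[grp$mz_mono >= obs_rng[1] - cfg$mz_window &
               grp$mz_mono <= obs_rng[2] + cfg$mz_window, , drop = FALSE]
    if (nrow(grp) == 0) next
    for (g in unique(grp$group_id)) {
      rows <- grp[grp$group_id == g, , drop = FALSE]
      res <- .annotate_group(observed, protein, rows, cfg)
      if (is.null(res)) next
      res$group_id <- if (nrow(res) >= 2) gid_base + 1L else NA_integer_
      if (nrow(res) >= 2) gid_base <- gid_base + 1L
      out[[length(out) + 1L]] <- res
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.annotate_group <- function(observed, protein, rows, cfg) {
  profs <- lapply(seq_len(nrow(rows)), function(i) {
    theoretical_profile(protein, .row_to_metalloform(rows[i, ]),
                        resolving_power = cfg$resolving_power,
                        prune = cfg$prune)
  })
  lo <- min(vapply(profs, function(p) min(p$mz), numeric(1)))
  hi <- max(vapply(profs, function(p) max(p$mz), numeric(1)))
  step <- min(vapply(profs, function(p) p$mz[2] - p$mz[1], numeric(1)))
  grid <- seq(lo, hi, by = step)
  A <- vapply(profs, function(p)
    stats::approx(p$mz, p$intensity, xout = grid, yleft = 0, yright = 0,
                  ties = "ordered")$y, numeric(length(grid)))
  A <- matrix(A, nrow = length(grid))
  yobs <- .render_on_grid(observed, grid, cfg$resolving_power)
  if (sum(yobs) == 0) return(NULL)
  fit <- pracma::lsqnonneg(A, yobs)
  abund <- fit$x
  scores <- vapply(seq_len(nrow(rows)), function(i) {
    apex <- attr(profs[[i]], "apex_mz")
    score_fit(observed, profs[[i]],
              window = c(apex - cfg$mz_window, apex + cfg$mz_window),
              resolving_power = cfg$resolving_power)
  }, numeric(1))
  keep <- scores >= cfg$min_score & abund > 0
  if (!any(keep)) return(NULL)
  res <- data.frame(
    species = rows$species[keep], n_cu = rows$n_cu[keep],
    n_zn = rows$n_zn[keep], n_cd = rows$n_cd[keep],
    n_nem = rows$n_nem[keep], n_iam = rows$n_iam[keep],
    n_ss = rows$n_ss[keep], z = rows$z[keep],
    theo_mz = vapply(profs[keep], function(p) attr(p, "apex_mz"),
                     numeric(1)),
    score = scores[keep], abundance = abund[keep])
  # parsimony ordering after score: fewer adducts, then fewer metals
  adducts <- with(res, n_cu + n_zn + n_cd + n_nem + n_iam + n_ss)
  metals <- with(res, n_cu + n_zn + n_cd)
  res[order(-res$score, adducts, metals), , drop = FALSE]
}
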