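# Survival-yield analysis on a center-of-mass collision-energy axis,
# logistic E50 fitting, and fragmentation-spectrum comparison (intensity
# correlation and shared-ion / UpSet-style intersections).

#' Center-of-mass collision energy
#'
#' Converts a laboratory-frame collision voltage into the center-of-mass
#' energy for a singly-to-multiply charged ion colliding with a neutral
#' gas: E_com = z * V * m_gas / (m_gas + M_ion). Argon (39.948 Da) is the
#' default collision gas.
#'
#' @param V collision voltage in volts (>= 0)
#' @param z charge state
#' @param ion_mass ion mass in Da
#' @param gas_mass collision-gas mass in Da (argon by default)
#' @return energy in eV; linear in both V and z
#' @export
e_com <- function(V, z, ion_mass, gas_mass = 39.948) {
  stopifnot(all(V >= 0), z >= 1, ion_mass > 0, gas_mass > 0)
  z * V * gas_mass / (gas_mass + ion_mass)
}

#' Survival-yield curve over a collision-voltage series
#'
#' For each spectrum (tagged with its collision voltage), the survival
#' yield is the intensity inside the precursor m/z window divided by the
#' total ion intensity of the spectrum (precursor plus all fragments).
#' With \code{denominator = "reference"} the denominator is instead the
#' precursor intensity of the lowest-voltage spectrum, for instruments
#' where fragment transmission is unreliable.
#'
#' @param spectra list of \code{mass_spectrum}, each with
#'   \code{metadata$voltage} set
#' @param precursor_window \code{c(lo, hi)} m/z window containing the
#'   precursor (and its metal-loss ladder if desired)
#' @param z precursor charge state
#' @param ion_mass precursor neutral-plus-protons ion mass in Da, used for
#'   the E_com axis
#' @param gas_mass collision-gas mass (argon default)
#' @param denominator \code{"total"} (default) or \code{"reference"}
#' @return an object of class \code{sy_curve}: data frame with
#'   \code{voltage}, \code{e_com}, \code{sy}, sorted by voltage; spectra
#'   with zero total intensity are dropped with a warning
#' @export
survival_yield <- function(spectra, precursor_window, z, ion_mass,
                           gas_mass = 39.948,
                           denominator = c("total", "reference")) {
  denominator <- match.arg(denominator)
  stopifnot(length(precursor_window) == 2,
            precursor_window[1] < precursor_window[2])
  volts <- vapply(spectra, function(s) {
    v <- s$metadata$voltage
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  if (any(is.na(volts)))
    stop("every spectrum must carry metadata$voltage")
  prec <- vapply(spectra, function(s) {
    sel <- s$mz >= precursor_window[1] & s$mz <= precursor_window[2]
    sum(s$intensity[sel])
  }, numeric(1))
  tot <- vapply(spectra, function(s) sum(s$intensity), numeric(1))
  if (denominator == "reference") {
    ref <- prec[which.min(volts)]
    if (ref <= 0) stop("reference precursor intensity is zero")
    sy <- prec / ref
  } else {
    sy <- ifelse(tot > 0, prec / tot, NA_real_)
  }
  drop <- is.na(sy)
  if (any(drop)) {
    warning(sum(drop), " spectra with zero total intensity dropped")
    volts <- volts[!drop]; sy <- sy[!drop]
  }
  sy <- pmin(1, pmax(0, sy))
  ord <- order(volts)
  out <- data.frame(voltage = volts[ord],
                    e_com = e_com(volts[ord], z, ion_mass, gas_mass),
                    sy = sy[ord])
  attr(out, "precursor_window") <- precursor_window
  attr(out, "z") <- z
  attr(out, "ion_mass") <- ion_mass
  class(out) <- c("sy_curve", "data.frame")
  out
}

#' Fit a logistic survival-yield curve and extract E50
#'
#' Least-squares fit of SY(E) = 1 / (1 + exp((E - E50) / k)) on the
#' center-of-mass energy axis, initialized from the empirical 50%
#' crossing. E50 is the relative gas-phase stability measure; k is the
#' transition width.
#'
#' @param curve an \code{sy_curve} (>= 4 points spanning the SY decline)
#' @return an object of class \code{sy_fit}: list with \code{e50} (eV),
#'   \code{k} (eV), \code{resid_norm}, \code{extrapolated} (TRUE when E50
#'   falls outside the scanned E_com range) and the \code{nls} fit object
#' @export
fit_sy <- function(curve) {
  stopifnot(inherits(curve, "data.frame"), nrow(curve) >= 4)
  E <- curve$e_com; sy <- curve$sy
  if (max(sy) - min(sy) < 0.2 || min(sy) > 0.5 || max(sy) < 0.5)
    stop("SY curve does not span its decline; cannot locate the 50% crossing")
  # empirical 50% crossing for initialization
  below <- which(sy <= 0.5)[1]
  if (is.na(below) || below == 1) {
    e50_0 <- stats::median(E)
  } else {
    i <- below - 1
    e50_0 <- E[i] + (0.5 - sy[i]) * (E[below] - E[i]) / (sy[below] - sy[i])
  }
  k0 <- max(diff(range(E)) / 10, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(sy ~ 1 / (1 + exp((E - e50) / k)),
                      data = data.frame(E = E, sy = sy),
                      start = list(e50 = e50_0, k = k0),
                      lower = c(e50 = min(E) - diff(range(E)),
                                k = 1e-9),
                      upper = c(e50 = max(E) + diff(range(E)), k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("survival-yield fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  cf <- stats::coef(fit)
  out <- list(e50 = unname(cf["e50"]), k = unname(cf["k"]),
              resid_norm = sqrt(sum(stats::resid(fit)^2)),
              extrapolated = cf["e50"] < min(E) || cf["e50"] > max(E),
              fit = fit)
  class(out) <- "sy_fit"
  out
}

#' @export
print.sy_fit <- function(x, ...) {
  cat(sprintf("sy_fit: E50 = %.4f eV, k = %.4f eV, ||resid|| = %.3g%s\n",
              x$e50, x$k, x$resid_norm,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

# Align centroided peaks across spectra into a union peak table by
# single-linkage gap clustering of the pooled m/z values; absent peaks are
# zero intensity.
.union_peak_table <- function(spectra, match_tol) {
  stopifnot(length(spectra) >= 2, match_tol > 0)
  pool <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    if (length(s$mz) == 0) return(NULL)
    data.frame(spec = i, mz = s$mz, intensity = s$intensity)
  }))
  if (is.null(pool) || nrow(pool) == 0)
    return(matrix(0, nrow = 0, ncol = length(spectra)))
  ord <- order(pool$mz)
  pool <- pool[ord, ]
  grp <- cumsum(c(1, diff(pool$mz) > match_tol))
  tab <- matrix(0, nrow = max(grp), ncol = length(spectra))
  for (r in seq_len(nrow(pool)))
    tab[grp[r], pool$spec[r]] <- tab[grp[r], pool$spec[r]] +
      pool$intensity[r]
  rownames(tab) <- vapply(seq_len(max(grp)), function(g)
    sprintf("%.4f", stats::weighted.mean(pool$mz[grp == g],
                                         pool$intensity[grp == g] + 1e-12)),
    character(1))
  tab
}

#' Pairwise intensity correlation of fragmentation spectra
#'
#' Aligns peaks across centroided spectra (within \code{match_tol}) into a
#' union peak table, imputing absent peaks as zero, then computes the
#' Pearson correlation of intensities for every pair. The matrix is
#' symmetric with unit diagonal; spectra with fewer than two peaks give
#' NA rows/columns (flagged by attribute \code{"undefined"}).
#'
#' @param spectra list of centroided \code{mass_spectrum} (>= 2)
#' @param match_tol m/z alignment tolerance (default 0.05)
#' @return correlation matrix, one row/column per spectrum; spectrum
#'   labels (metadata \code{label}) are used as dimnames when present
#' @export
spectral_correlation <- function(spectra, match_tol = 0.05) {
  stopifnot(length(spectra) >= 2)
  tab <- .union_peak_table(spectra, match_tol)
  n <- length(spectra)
  labs <- vapply(seq_len(n), function(i) {
    l <- spectra[[i]]$metadata$label
    if (is.null(l)) paste0("S", i) else as.character(l)
  }, character(1))
  undef <- vapply(spectra, function(s) length(s$mz) < 2, logical(1))
  M <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  diag(M) <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (undef[i] || undef[j]) next
    M[i, j] <- M[j, i] <- stats::cor(tab[, i], tab[, j])
  }
  attr(M, "undefined") <- labs[undef]
  M
}

#' Shared-ion (UpSet-style) analysis of fragmentation spectra
#'
#' Aligns detected peaks across spectra and tabulates which spectra share
#' which ions: per-spectrum detected-peak counts, pairwise shared counts
#' and percentages (of the pair's union), the fraction common to all
#' spectra, and the full membership-pattern (UpSet) table.
#'
#' @param spectra list of centroided \code{mass_spectrum} (>= 2)
#' @param match_tol m/z alignment tolerance (default 0.05)
#' @return a list with \code{per_spectrum} (label, n_peaks),
#'   \code{pairwise} (i, j, shared, union, pct_shared),
#'   \code{all_shared} (count and pct of ions present in every spectrum),
#'   and \code{patterns} (membership pattern string -> ion count)
#' @export
shared_ion_analysis <- function(spectra, match_tol = 0.05) {
  stopifnot(length(spectra) >= 2)
  tab <- .union_peak_table(spectra, match_tol)
  present <- tab > 0
  n <- length(spectra)
  labs <- vapply(seq_len(n), function(i) {
    l <- spectra[[i]]$metadata$label
    if (is.null(l)) paste0("S", i) else as.character(l)
  }, character(1))
  per <- data.frame(label = labs, n_peaks = colSums(present))
  pairs <- utils::combn(n, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    shared <- sum(present[, i] & present[, j])
    uni <- sum(present[, i] | present[, j])
    data.frame(spectrum_a = labs[i], spectrum_b = labs[j],
               shared = shared, union = uni,
               pct_shared = if (uni > 0) 100 * shared / uni else NA_real_)
  }))
  all_n <- sum(rowSums(present) == n)
  total <- sum(rowSums(present) > 0)
  pat <- apply(present, 1, function(r) paste(as.integer(r), collapse = ""))
  patterns <- as.data.frame(table(pattern = pat), stringsAsFactors = FALSE)
  names(patterns) <- c("pattern", "n_ions")
  list(per_spectrum = per, pairwise = pw,
       all_shared = list(count = all_n,
                         pct = if (total > 0) 100 * all_n / total
                               else NA_real_),
       patterns = patterns)
}
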