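# Deterministic simulators of native and fragment spectra with known
# ground truth, plus the vendored sequence fixtures. These stand in for
# the instrument in every recovery test: a 68-residue, 20-cysteine
# protein carrying 0-7 metals, 0-20 labels and 0-2 disulfides at charge
# states 4+/5+, rendered at configurable resolving power and noise.

#' Sequence fixtures
#'
#' \code{mt3_sequence()} returns the vendored human metallothionein-3
#' sequence (UniProt P25713; 68 residues, 20 cysteines, initiator Met
#' included, so the first two labelable cysteines are Cys6 and Cys8).
#' \code{mt2_like_sequence()} returns a synthetic 61-residue, 20-cysteine
#' protein laid out like a mammalian metallothionein-2 (the real rabbit
#' MT2a/b/c sequences are not bundled; supply them as FASTA for real
#' reanalysis).
#'
#' @param n_terminal_acetyl logical; mammalian MT2 isoforms are
#'   N-acetylated, so \code{mt2_like_sequence} defaults to TRUE
#' @return a \code{protein_species}
#' @export
mt3_sequence <- function() {
  protein_species(
    "MT3_HUMAN_P25713",
    "MDPETCPCPSGGSCTCADSCKCEGCKCTSCKKSCCSCCPAECEKCAKDCVCKGGEAAEAEAEKCSCCQ")
}

#' @rdname mt3_sequence
#' @export
mt2_like_sequence <- function(n_terminal_acetyl = TRUE) {
  protein_species(
    "MT2_LIKE_SYNTHETIC",
    "MDPNCSCAAGDSCTCAGSCKCKECKCTSCKKSCCSCCPVGCAKCAQGCICKGASDKCSCCA",
    n_terminal_acetyl = n_terminal_acetyl)
}

#' Simulation specification for native spectra
#'
#' @param protein a \code{protein_species}
#' @param species list of \code{list(mfc = metalloform, abundance = x)}
#'   with abundances > 0
#' @param resolving_power instrument resolving power (default 10000)
#' @param snr signal-to-noise ratio: Gaussian noise sigma = max intensity
#'   / snr (Inf disables noise)
#' @param baseline constant baseline as a fraction of max intensity
#' @param mass_error_ppm uniform m/z jitter half-width applied per species
#' @param seed random seed fixing all randomness (default 1234)
#' @param grid_step optional m/z grid spacing; default FWHM/8 at the
#'   lowest rendered m/z
#' @return a \code{simulation_spec} list
#' @export
simulation_spec <- function(protein, species, resolving_power = 10000,
                            snr = Inf, baseline = 0, mass_error_ppm = 0,
                            seed = 1234, grid_step = NULL) {
  stopifnot(length(species) >= 1)
  for (sp in species) {
    stopifnot(inherits(sp$mfc, "metalloform"), sp$abundance > 0)
    if (!cys_budget_ok(protein, sp$mfc))
      stop("species ", metalloform_label(sp$mfc),
           " exceeds the protein cysteine budget")
  }
  structure(list(protein = protein, species = species,
                 resolving_power = resolving_power, snr = snr,
                 baseline = baseline, mass_error_ppm = mass_error_ppm,
                 seed = seed, grid_step = grid_step),
            class = "simulation_spec")
}

#' Simulate a native electrospray spectrum
#'
#' Sums the theoretical isotope profiles of the specified species scaled
#' by their abundances, applies a per-species uniform ppm mass error, then
#' adds the baseline and seeded Gaussian intensity noise. Deterministic
#' for a fixed seed. The ground truth (species labels, charges, apex m/z,
#' abundances) is attached as attribute \code{"ground_truth"}.
#'
#' @param spec a \code{simulation_spec}
#' @return a profile-mode \code{mass_spectrum}
#' @export
simulate_native <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  profs <- lapply(spec$species, function(sp) {
    p <- theoretical_profile(spec$protein, sp$mfc,
                             resolving_power = spec$resolving_power)
    if (spec$mass_error_ppm > 0) {
      shift <- stats::runif(1, -spec$mass_error_ppm, spec$mass_error_ppm)
      p$mz <- p$mz * (1 + shift * 1e-6)
    }
    p
  })
  lo <- min(vapply(profs, function(p) min(p$mz), numeric(1)))
  hi <- max(vapply(profs, function(p) max(p$mz), numeric(1)))
  step <- spec$grid_step
  if (is.null(step))
    step <- (lo / spec$resolving_power) / 8
  grid <- seq(lo - 1, hi + 1, by = step)
  y <- numeric(length(grid))
  for (k in seq_along(profs)) {
    yk <- stats::approx(profs[[k]]$mz, profs[[k]]$intensity, xout = grid,
                        yleft = 0, yright = 0, ties = "ordered")$y
    y <- y + spec$species[[k]]$abundance * yk
  }
  ymax <- max(y)
  if (spec$baseline > 0) y <- y + spec$baseline * ymax
  if (is.finite(spec$snr) && spec$snr > 0)
    y <- pmax(0, y + stats::rnorm(length(y), sd = ymax / spec$snr))
  out <- mass_spectrum(grid, y, "profile",
                       metadata = list(label = "simulated native"))
  attr(out, "ground_truth") <- data.frame(
    species = vapply(spec$species, function(sp)
      metalloform_label(sp$mfc), character(1)),
    z = vapply(spec$species, function(sp) sp$mfc$z, integer(1)),
    apex_mz = vapply(profs, function(p) attr(p, "apex_mz"), numeric(1)),
    abundance = vapply(spec$species, function(sp) sp$abundance,
                       numeric(1)))
  out
}

#' Simulate a centroided fragment spectrum with planted label placement
#'
#' Generates the b/y ladder of a parent whose labels sit at the planted
#' cysteine positions: each fragment carries exactly the labels of the
#' placement falling inside its residue span. Peaks get a uniform ppm
#' jitter and intensities from an exponential decay in fragment length.
#' The ground-truth candidate table is attached as attribute
#' \code{"ground_truth"}.
#'
#' @param protein a \code{protein_species}
#' @param parent a \code{metalloform}; its label counts must equal the
#'   planted placement sizes
#' @param nem_at,iam_at integer vectors of cysteine positions carrying
#'   NEM / IAM
#' @param types fragment types to emit
#' @param charges fragment charge states
#' @param indices optional restriction of fragment indices (per type,
#'   list with elements \code{b} and \code{y}); default all 1..n-1
#' @param ppm_jitter uniform m/z error half-width in ppm
#' @param decay exponential intensity decay rate per residue of fragment
#'   length
#' @param seed random seed
#' @return a centroid-mode \code{mass_spectrum}
#' @export
simulate_fragments <- function(protein, parent, nem_at = integer(0),
                               iam_at = integer(0), types = c("b", "y"),
                               charges = 1L, indices = NULL,
                               ppm_jitter = 1, decay = 0.02, seed = 1234) {
  cys <- cys_positions(protein)
  stopifnot(all(nem_at %in% cys), all(iam_at %in% cys),
            length(intersect(nem_at, iam_at)) == 0)
  if (length(nem_at) != parent$n_nem || length(iam_at) != parent$n_iam)
    stop("planted placement sizes must match the parent label counts")
  if (!cys_budget_ok(protein, parent))
    stop("parent exceeds the protein cysteine budget")
  set.seed(seed)
  n <- n_residues(protein)
  rows <- list()
  for (type in types) {
    idx <- if (!is.null(indices)) indices[[type]] else seq_len(n - 1L)
    for (i in idx) {
      span <- if (type == "b") c(1L, i) else c(n - i + 1L, n)
      nem_f <- sum(nem_at >= span[1] & nem_at <= span[2])
      iam_f <- sum(iam_at >= span[1] & iam_at <= span[2])
      comp <- .fragment_neutral_comp(protein, type, i)
      if (nem_f > 0) comp <- apply_adduct(comp, "NEM", nem_f)
      if (iam_f > 0) comp <- apply_adduct(comp, "CAM", iam_f)
      m0 <- monoisotopic_mass(comp)
      for (zf in charges) {
        mzv <- (m0 + zf * PROTON_MASS) / zf
        if (ppm_jitter > 0)
          mzv <- mzv * (1 + stats::runif(1, -ppm_jitter, ppm_jitter) * 1e-6)
        rows[[length(rows) + 1L]] <- data.frame(
          type = type, index = i, n_cu = 0L, n_zn = 0L, n_cd = 0L,
          n_nem = nem_f, n_iam = iam_f, z = as.integer(zf),
          mz = mzv, intensity = 1000 * exp(-decay * i))
      }
    }
  }
  if (length(rows) == 0)
    return(mass_spectrum(numeric(0), numeric(0), "centroid",
                         metadata = list(label = "simulated fragments")))
  truth <- do.call(rbind, rows)
  ord <- order(truth$mz)
  truth <- truth[ord, ]
  keep <- c(TRUE, diff(truth$mz) > 1e-9)
  truth <- truth[keep, ]
  out <- mass_spectrum(truth$mz, truth$intensity, "centroid",
                       metadata = list(label = "simulated fragments"))
  attr(out, "ground_truth") <- truth
  out
}

#' Simulate a collision-voltage series for survival-yield analysis
#'
#' At each voltage, the precursor/fragment intensity split follows the
#' logistic survival yield at that voltage's center-of-mass energy, with
#' optional Gaussian noise on the SY value. Returns centroided two-peak
#' spectra (precursor plus one aggregate fragment peak) and the voltage
#' table.
#'
#' @param e50 true E50 in eV
#' @param slope logistic width k in eV
#' @param voltages collision voltages in V
#' @param z precursor charge
#' @param ion_mass precursor ion mass in Da
#' @param precursor_mz precursor m/z (default computed from mass and z)
#' @param noise_sigma Gaussian noise s.d. on SY (0 = noiseless)
#' @param gas_mass collision-gas mass
#' @param seed random seed
#' @return list with \code{spectra} (list of \code{mass_spectrum}, each
#'   tagged with its voltage), \code{table} (voltage, e_com, true_sy) and
#'   \code{precursor_window}
#' @export
simulate_sy_series <- function(e50, slope, voltages, z, ion_mass,
                               precursor_mz = (ion_mass + z * PROTON_MASS) / z,
                               noise_sigma = 0, gas_mass = 39.948,
                               seed = 1234) {
  stopifnot(length(voltages) >= 1, slope > 0)
  set.seed(seed)
  E <- e_com(voltages, z, ion_mass, gas_mass)
  sy_true <- 1 / (1 + exp((E - e50) / slope))
  sy_obs <- sy_true
  if (noise_sigma > 0)
    sy_obs <- pmin(1, pmax(0, sy_true + stats::rnorm(length(E),
                                                     sd = noise_sigma)))
  frag_mz <- precursor_mz / 2
  spectra <- lapply(seq_along(voltages), function(i) {
    mass_spectrum(c(frag_mz, precursor_mz),
                  c(1000 * (1 - sy_obs[i]), 1000 * sy_obs[i]),
                  "centroid",
                  metadata = list(voltage = voltages[i],
                                  label = sprintf("V=%g", voltages[i])))
  })
  list(spectra = spectra,
       table = data.frame(voltage = voltages, e_com = E, true_sy = sy_true),
       precursor_window = c(precursor_mz - 2, precursor_mz + 2))
}

#' Write a simulated spectrum with its ground-truth sidecar
#'
#' Writes the spectrum as a TSV peak list (and mzML when \code{mzml =
#' TRUE}) plus a JSON sidecar holding the ground-truth table, so recovery
#' harnesses can reload both.
#'
#' @param s a \code{mass_spectrum} carrying a \code{"ground_truth"}
#'   attribute
#' @param stem output path stem (extensions are appended)
#' @param mzml also write mzML (requires mzR)
#' @return invisibly, the paths written
#' @export
write_simulation <- function(s, stem, mzml = FALSE) {
  paths <- character(0)
  pk <- paste0(stem, ".tsv")
  write_peaklist(s, pk)
  paths <- c(paths, pk)
  if (mzml) {
    mz_path <- paste0(stem, ".mzML")
    write_mzml(s, mz_path)
    paths <- c(paths, mz_path)
  }
  gt <- attr(s, "ground_truth")
  if (!is.null(gt)) {
    gt_path <- paste0(stem, "_truth.json")
    jsonlite::write_json(gt, gt_path, digits = NA)
    paths <- c(paths, gt_path)
  }
  invisible(paths)
}
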