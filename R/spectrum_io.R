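# Spectrum container, mzML / peak-list I/O and centroiding.

#' Create a mass spectrum
#'
#' @param mz numeric vector of m/z values, strictly increasing
#' @param intensity numeric vector of intensities, same length, >= 0
#' @param mode \code{"profile"} or \code{"centroid"}
#' @param metadata named list; recognized fields include \code{label},
#'   \code{voltage} (collision voltage, V, >= 0), \code{charge_window},
#'   \code{polarity}
#' @return an object of class \code{mass_spectrum}
#' @export
mass_spectrum <- function(mz, intensity, mode = c("centroid", "profile"),
                          metadata = list()) {
  mode <- match.arg(mode)
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("m/z values must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (!is.null(metadata$voltage) && metadata$voltage < 0)
    stop("collision voltage must be >= 0")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 mode = mode, metadata = metadata),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  rng <- if (length(x$mz)) sprintf("%.2f-%.2f m/z", min(x$mz), max(x$mz))
         else "empty"
  cat(sprintf("mass_spectrum (%s): %d points, %s\n", x$mode,
              length(x$mz), rng))
  invisible(x)
}

#' Read spectra from an mzML file
#'
#' @param path path to an mzML file
#' @param scans optional integer vector of scan (acquisition) numbers to
#'   keep; \code{NULL} keeps all. A selector matching nothing returns an
#'   empty list with a warning.
#' @return a list of \code{mass_spectrum}, in scan order; centroid/profile
#'   mode and collision energy are taken from the scan headers when present
#' @export
read_mzml <- function(path, scans = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  idx <- seq_len(nrow(hdr))
  if (!is.null(scans)) {
    idx <- idx[hdr$acquisitionNum %in% scans]
    if (length(idx) == 0) {
      warning("no scans matched the selector")
      return(list())
    }
  }
  lapply(idx, function(i) {
    pk <- mzR::peaks(fh, i)
    ord <- order(pk[, 1])
    md <- list(scan = hdr$acquisitionNum[i])
    if (!is.null(hdr$collisionEnergy) && !is.na(hdr$collisionEnergy[i]))
      md$voltage <- hdr$collisionEnergy[i]
    mode <- if (!is.null(hdr$centroided) && isTRUE(hdr$centroided[i]))
      "centroid" else "profile"
    mass_spectrum(pk[ord, 1], pmax(pk[ord, 2], 0), mode = mode,
                  metadata = md)
  })
}

#' Write spectra to an mzML file
#'
#' @param spectra a \code{mass_spectrum} or list of them
#' @param path output path
#' @export
write_mzml <- function(spectra, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the mzR package")
  if (inherits(spectra, "mass_spectrum")) spectra <- list(spectra)
  n <- length(spectra)
  # scans carrying a collision voltage are written as MS2 so that the
  # mzML schema has a slot for the collision energy
  has_v <- vapply(spectra, function(s) !is.null(s$metadata$voltage),
                  logical(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = ifelse(has_v, 2L, 1L),
    polarity = 1L, peaksCount = vapply(spectra, function(s)
      length(s$mz), integer(1)),
    totIonCurrent = vapply(spectra, function(s) sum(s$intensity), numeric(1)),
    retentionTime = as.numeric(seq_len(n)),
    basePeakMZ = vapply(spectra, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(spectra, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = vapply(spectra, function(s)
      if (is.null(s$metadata$voltage)) NA_real_ else s$metadata$voltage,
      numeric(1)),
    ionisationEnergy = 0, lowMZ = vapply(spectra, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(spectra, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L,
    # a precursor record is required for the collision energy to land in
    # the mzML activation element
    precursorMZ = vapply(spectra, function(s) {
      if (is.null(s$metadata$voltage)) NA_real_
      else if (!is.null(s$metadata$precursor_mz)) s$metadata$precursor_mz
      else if (length(s$mz)) s$mz[which.max(s$intensity)] else 0
    }, numeric(1)),
    precursorCharge = vapply(spectra, function(s) {
      if (is.null(s$metadata$voltage)) 0L
      else if (!is.null(s$metadata$z)) as.integer(s$metadata$z) else 1L
    }, integer(1)),
    precursorIntensity = ifelse(has_v, 100, 0),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = vapply(spectra, function(s) s$mode == "centroid",
                        logical(1)),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  data <- lapply(spectra, function(s) cbind(mz = s$mz,
                                            intensity = s$intensity))
  mzR::writeMSData(data, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a two-column tab-separated peak list
#'
#' Dialect: tab-separated m/z and intensity columns, lines starting with
#' \code{#} are comments, no header required (a header line is skipped if
#' its first field is not numeric).
#'
#' @param path path to the TSV peak list
#' @param mode spectrum mode to assign
#' @param metadata metadata list passed to \code{\link{mass_spectrum}}
#' @return a \code{mass_spectrum}
#' @export
read_peaklist <- function(path, mode = "centroid", metadata = list()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) > 0) {
    first <- strsplit(trimws(lines[1]), "[\t ]+")[[1]][1]
    if (is.na(suppressWarnings(as.numeric(first)))) lines <- lines[-1]
  }
  if (length(lines) == 0)
    return(mass_spectrum(numeric(0), numeric(0), mode = mode,
                         metadata = metadata))
  fields <- do.call(rbind, strsplit(trimws(lines), "[\t ]+"))
  mzv <- as.numeric(fields[, 1]); iv <- as.numeric(fields[, 2])
  ord <- order(mzv)
  mass_spectrum(mzv[ord], iv[ord], mode = mode, metadata = metadata)
}

#' Write a spectrum as a tab-separated peak list
#' @param s a \code{mass_spectrum}
#' @param path output path
#' @export
write_peaklist <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# m/z\tintensity", con)
  if (length(s$mz) > 0)
    writeLines(sprintf("%.*f\t%.*f", 6, s$mz, 6, s$intensity), con)
  invisible(path)
}

#' Robust noise level of a profile spectrum
#'
#' 1.4826 times the median absolute deviation of the intensities below
#' their 50th percentile; robust for sparse native spectra where most of
#' the trace is baseline.
#' @param s a \code{mass_spectrum}
#' @export
noise_level <- function(s) {
  low <- s$intensity[s$intensity <= stats::quantile(s$intensity, 0.5)]
  stats::mad(low, constant = 1.4826)
}

#' Centroid a profile spectrum
#'
#' Local maxima above \code{snr_min} times the robust noise estimate are
#' reduced to intensity-weighted centroids over \code{window} profile
#' points on each side.
#'
#' @param s a profile-mode \code{mass_spectrum}
#' @param snr_min minimum signal-to-noise ratio (default 3)
#' @param window half-width of the centroiding window, in profile points
#' @return a centroid-mode \code{mass_spectrum}
#' @export
centroid <- function(s, snr_min = 3, window = 3L) {
  if (s$mode != "profile")
    stop("centroid() expects a profile-mode spectrum")
  n <- length(s$mz)
  if (n == 0)
    return(mass_spectrum(numeric(0), numeric(0), "centroid", s$metadata))
  noise <- noise_level(s)
  thr <- max(snr_min * noise, .Machine$double.eps)
  y <- s$intensity
  is_max <- rep(FALSE, n)
  if (n >= 3) {
    mid <- 2:(n - 1)
    is_max[mid] <- y[mid] >= y[mid - 1] & y[mid] > y[mid + 1] & y[mid] >= thr
  }
  peaks <- which(is_max)
  if (length(peaks) == 0)
    return(mass_spectrum(numeric(0), numeric(0), "centroid", s$metadata))
  cm <- vapply(peaks, function(i) {
    lo <- max(1, i - window); hi <- min(n, i + window)
    w <- y[lo:hi]
    sum(s$mz[lo:hi] * w) / sum(w)
  }, numeric(1))
  ci <- y[peaks]
  ord <- order(cm)
  cm <- cm[ord]; ci <- ci[ord]
  keep <- c(TRUE, diff(cm) > 0)
  mass_spectrum(cm[keep], ci[keep], "centroid", s$metadata)
}

#' Write / read annotation and fragment-map tables
#'
#' CSV writers with a stable column schema; \code{read} counterparts give
#' bit-exact round trips for numeric columns via full-precision formatting.
#'
#' @param table a data frame
#' @param path output CSV path
#' @export
write_annotations <- function(table, path) {
  .write_table_csv(table, path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_annotations
#' @param map a fragment-map data frame
#' @export
write_fragmap <- function(map, path) {
  .write_table_csv(map, path)
}

#' @rdname write_annotations
#' @export
read_fragmap <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.write_table_csv <- function(table, path) {
  df <- as.data.frame(table)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  old <- options(digits = 17)
  on.exit(options(old), add = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
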