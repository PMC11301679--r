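# Elemental isotope table (masses in Da, abundances as mole fractions) and
# conventional standard atomic weights. Snapshot of the IUPAC/NIST 2018
# compilation, vendored so that no network access is ever needed.
#
# Only elements occurring in proteins and in the supported adducts (metals,
# alkylation labels) are included; unknown symbols are rejected explicitly.

.ISOTOPES <- list(
  H = list(mass = c(1.00782503207, 2.01410177785),
           abundance = c(0.999885, 0.000115)),
  C = list(mass = c(12.0, 13.00335483507),
           abundance = c(0.9893, 0.0107)),
  N = list(mass = c(14.00307400443, 15.00010889888),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = list(mass = 30.97376199842, abundance = 1.0),
  Se = list(mass = c(73.922475934, 75.919213704, 76.919914154,
                     77.91730928, 79.9165218, 81.9166995),
            abundance = c(0.0089, 0.0937, 0.0763, 0.2377, 0.4961, 0.0873)),
  Cu = list(mass = c(62.92959772, 64.92778970),
            abundance = c(0.6915, 0.3085)),
  Zn = list(mass = c(63.92914201, 65.92603381, 66.92712775,
                     67.92484455, 69.9253192),
            abundance = c(0.4917, 0.2773, 0.0404, 0.1845, 0.0061)),
  Cd = list(mass = c(105.9064599, 107.9041834, 109.90300661, 110.90418287,
                     111.90276287, 112.90440813, 113.90336509, 115.90476315),
            abundance = c(0.0125, 0.0089, 0.1249, 0.1280,
                          0.2413, 0.1222, 0.2873, 0.0749)),
  Na = list(mass = 22.9897692820, abundance = 1.0),
  K = list(mass = c(38.9637064864, 39.963998166, 40.9618252579),
           abundance = c(0.932581, 0.000117, 0.067302))
)

# Conventional standard atomic weights (abridged IUPAC values), used for
# average masses as printed on native-MS annotations.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  Se = 78.971, Cu = 63.546, Zn = 65.38, Cd = 112.414, Na = 22.990, K = 39.098
)

#' Mass of a proton, in Da
#'
#' Used for all charge arithmetic (m/z = (M + z * proton) / z). Distinct from
#' the hydrogen atom mass (1.007825 Da) because electrospray charging adds
#' bare protons.
#' @export
PROTON_MASS <- 1.007276

.known_elements <- function() names(.ISOTOPES)

.check_elements <- function(symbols) {
  bad <- setdiff(symbols, .known_elements())
  if (length(bad) > 0L)
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
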