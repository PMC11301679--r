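# Shared fixtures and small independent oracles used across test files.

mt3 <- mt3_sequence()

# Independent brute-force isotope-pattern oracle: enumerate every
# isotopologue combination of a small composition explicitly, then apply
# the same fine-structure aggregation the package uses. Exponential in
# atom count, so only usable for a handful of atoms.
brute_force_pattern <- function(comp, merge_tol = 0.2) {
  iso <- metalloMS:::.ISOTOPES
  atoms <- rep(names(comp), times = unclass(comp))
  states <- lapply(atoms, function(el) seq_along(iso[[el]]$mass))
  grid <- expand.grid(states)
  mass <- apply(grid, 1, function(idx)
    sum(mapply(function(el, k) iso[[el]]$mass[k], atoms, idx)))
  ab <- apply(grid, 1, function(idx)
    prod(mapply(function(el, k) iso[[el]]$abundance[k], atoms, idx)))
  m <- metalloMS:::.merge_pattern(mass, ab, merge_tol)
  ord <- order(m$mass)
  list(mass = m$mass[ord], abundance = m$abundance[ord] / sum(m$abundance))
}

# Gaussian profile peak generator for centroiding tests.
gaussian_profile <- function(centers, heights, fwhm, span = 2,
                             step = fwhm / 20) {
  grid <- seq(min(centers) - span, max(centers) + span, by = step)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  y <- numeric(length(grid))
  for (k in seq_along(centers))
    y <- y + heights[k] * exp(-(grid - centers[k])^2 / (2 * sigma^2))
  mass_spectrum(grid, y, "profile")
}
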