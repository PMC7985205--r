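#' Optical properties of a homogeneous turbid medium
#'
#' Bundles the four physical parameters of one slab realization: refractive
#' index `n`, scattering anisotropy `g` (the mean cosine of the
#' single-scattering deflection angle), scattering coefficient `mu_s` and
#' absorption coefficient `mu_a`. The reduced scattering coefficient
#' `mu_s_prime = (1 - g) * mu_s` is derived and stored alongside; diffusive
#' transport depends on the latter rather than on `g` and `mu_s` separately.
#'
#' @param n Refractive index (dimensionless, >= 1).
#' @param g Scattering anisotropy, mean cosine of the deflection angle
#'   (dimensionless, strictly between -1 and 1). Around 0.9 in soft tissue.
#' @param mu_s Scattering coefficient (mm^-1, > 0); the mean free path
#'   between scattering events is `1 / mu_s`.
#' @param mu_a Absorption coefficient (mm^-1, >= 0).
#'
#' @return An object of class `optical_properties`: a list with fields
#'   `n`, `g`, `mu_s`, `mu_a` and the derived `mu_s_prime`.
#' @examples
#' optical_properties(n = 1.4, g = 0.85, mu_s = 1 / 0.15, mu_a = 0.1)
#' @export
optical_properties <- function(n, g, mu_s, mu_a) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(mu_s), length(mu_s) == 1L, is.finite(mu_s),
            is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a))
  if (n < 1) stop("refractive index `n` must be >= 1")
  if (abs(g) >= 1) stop("anisotropy `g` must satisfy -1 < g < 1")
  if (mu_s <= 0) stop("scattering coefficient `mu_s` must be > 0")
  if (mu_a < 0) stop("absorption coefficient `mu_a` must be >= 0")
  structure(
    list(n = n, g = g, mu_s = mu_s, mu_a = mu_a,
         mu_s_prime = (1 - g) * mu_s),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties> n = %.4g, g = %.4g, mu_s = %.4g mm^-1, mu_a = %.4g mm^-1 (mu_s' = %.4g mm^-1)\n",
    x$n, x$g, x$mu_s, x$mu_a, x$mu_s_prime))
  invisible(x)
}

#' Slab geometry
#'
#' A single homogeneous layer of finite thickness along the optical axis and
#' unbounded transverse extent, bounded above and below by non-scattering
#' ambient media (air by default). The illuminated face sits at `z = 0` and
#' `z` increases into the slab.
#'
#' @param thickness Slab thickness (mm, > 0). Default 10 mm.
#' @param n_ambient_top Refractive index of the medium above the illuminated
#'   face (>= 1). Default 1 (air).
#' @param n_ambient_bottom Refractive index below the slab (>= 1). Default 1.
#'
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(thickness = 10, n_ambient_top = 1,
                          n_ambient_bottom = 1) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L,
            is.finite(thickness))
  if (thickness <= 0) stop("`thickness` must be > 0")
  if (n_ambient_top < 1 || n_ambient_bottom < 1)
    stop("ambient refractive indices must be >= 1")
  structure(
    list(thickness = thickness, n_ambient_top = n_ambient_top,
         n_ambient_bottom = n_ambient_bottom),
    class = "slab_geometry"
  )
}

#' Simulation configuration
#'
#' Run-level knobs of the photon transport simulation: launch count, Russian
#' roulette settings, RNG seed and the per-photon scattering-event cap.
#'
#' @param n_photons Number of photons launched at `t = 0` (>= 1).
#' @param roulette_threshold Weight below which a photon enters Russian
#'   roulette (default `1e-6`). Set to `0` to disable roulette entirely.
#' @param roulette_m Roulette survival divisor: a sub-threshold photon
#'   survives with probability `1 / roulette_m` and has its weight multiplied
#'   by `roulette_m`, which keeps the expected weight unbiased. Default 10.
#' @param seed Master RNG seed (non-negative integer). Each photon draws its
#'   deviates from a substream derived from `(seed, photon index)`, so a run
#'   is reproducible and independent of batching.
#' @param max_events Per-photon cap on scattering events; photons reaching it
#'   are terminated and their weight tallied as lost, never silently dropped.
#' @param tally_absorption Whether to accumulate the absorbed-weight tally.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_photons, roulette_threshold = 1e-6, roulette_m = 10,
                       seed = 1, max_events = 1e6, tally_absorption = TRUE) {
  stopifnot(is.numeric(n_photons), length(n_photons) == 1L,
            n_photons >= 1, n_photons == floor(n_photons))
  if (roulette_threshold < 0 || roulette_threshold >= 1)
    stop("`roulette_threshold` must lie in [0, 1); 0 disables roulette")
  if (roulette_m < 2 || roulette_m != floor(roulette_m))
    stop("`roulette_m` must be an integer >= 2")
  if (max_events < 1) stop("`max_events` must be >= 1")
  if (seed < 0) stop("`seed` must be non-negative")
  structure(
    list(n_photons = as.double(n_photons),
         roulette_threshold = roulette_threshold,
         roulette_m = as.integer(roulette_m),
         seed = as.double(seed),
         c_vacuum = 0.299792458,
         max_events = as.double(max_events),
         tally_absorption = isTRUE(tally_absorption)),
    class = "sim_config"
  )
}
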