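#' Sample a scattering free path
#'
#' Inverts the exponential free-path distribution
#' \eqn{\rho(d) = \mu_s e^{-\mu_s d}}: a uniform deviate `u` maps to
#' \eqn{d = -\ln(u)/\mu_s}. The mean of many draws converges to the mean
#' free path `1 / mu_s`. Step lengths in the transport kernel are sampled
#' from the scattering coefficient alone; absorption is handled separately
#' by continuous Beer-Lambert attenuation along each traversed segment.
#'
#' @param mu_s Scattering coefficient (mm^-1, > 0).
#' @param u Uniform deviate(s) in (0, 1).
#' @return Free path length(s) in mm.
#' @examples
#' sample_free_path(2, 0.5)        # log(2)/2 ~ 0.3466 mm
#' mean(sample_free_path(2, runif(1e4)))  # ~ 0.5 mm
#' @export
sample_free_path <- function(mu_s, u) {
  if (!is.numeric(mu_s) || length(mu_s) != 1L || !is.finite(mu_s) || mu_s <= 0)
    stop("`mu_s` must be a single positive number")
  if (any(u <= 0 | u >= 1)) stop("`u` must lie strictly inside (0, 1)")
  cpp_sample_free_path(mu_s, as.numeric(u))
}

#' Sample a Henyey-Greenstein scattering cosine
#'
#' Draws \eqn{\cos\theta} from the Henyey-Greenstein phase function
#' \eqn{\rho(\cos\theta) = (1-g^2) / (2[1+g^2-2g\cos\theta]^{3/2})}
#' by closed-form inversion of its CDF:
#' \eqn{\cos\theta = [1+g^2 - ((1-g^2)/(1-g+2gu))^2]/(2g)} for \eqn{g \ne 0},
#' and \eqn{2u - 1} (isotropic) at \eqn{g = 0}. The empirical mean of many
#' draws converges to the anisotropy `g`.
#'
#' @param g Anisotropy, with `|g| < 1`.
#' @param u Uniform deviate(s) in `[0, 1]`.
#' @return Scattering cosine(s) in `[-1, 1]`.
#' @examples
#' sample_scatter_cosine(0.85, c(0, 0.5, 1))
#' @export
sample_scatter_cosine <- function(g, u) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || abs(g) >= 1)
    stop("`g` must satisfy |g| < 1")
  if (any(u < 0 | u > 1)) stop("`u` must lie in [0, 1]")
  cpp_sample_scatter_cosine(g, as.numeric(u))
}

#' Deflect a unit direction vector
#'
#' Rotates `direction` by polar angle `acos(cos_theta)` about itself with
#' azimuth `phi`, the standard local-frame rotation of Monte Carlo photon
#' transport. Near-axial directions (`|uz| > 1 - 1e-6`) use a dedicated
#' formula that avoids the singular transverse frame.
#'
#' @param direction Unit 3-vector (checked to 1e-6).
#' @param cos_theta Cosine of the deflection angle, in `[-1, 1]`.
#' @param phi Azimuthal angle in radians.
#' @return A unit 3-vector whose dot product with `direction` is `cos_theta`.
#' @export
new_direction <- function(direction, cos_theta, phi) {
  if (length(direction) != 3L || abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    stop("`direction` must be a unit 3-vector")
  if (abs(cos_theta) > 1) stop("`cos_theta` must lie in [-1, 1]")
  cpp_new_direction(as.numeric(direction), cos_theta, phi)
}

#' Beer-Lambert weight attenuation
#'
#' Attenuates a photon's statistical weight over a traversed path:
#' `w * exp(-mu_a * d)`.
#'
#' @param w Weight(s), > 0.
#' @param mu_a Absorption coefficient (mm^-1, >= 0).
#' @param d Path length (mm, >= 0).
#' @return Attenuated weight(s).
#' @export
attenuate_weight <- function(w, mu_a, d) {
  if (any(w <= 0)) stop("`w` must be > 0")
  if (any(mu_a < 0)) stop("`mu_a` must be >= 0")
  if (any(d < 0)) stop("`d` must be >= 0")
  w * exp(-mu_a * d)
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized Fresnel power reflectances at a planar
#' interface, with the transmitted angle from Snell's law. Returns exactly 1
#' beyond the critical angle (total internal reflection) and 0 at a matched
#' boundary.
#'
#' @param n_i Refractive index on the incident side (>= 1).
#' @param n_t Refractive index on the transmitted side (>= 1).
#' @param cos_theta_i Cosine(s) of the angle of incidence, in (0, 1].
#' @return Reflectance(s) in `[0, 1]`.
#' @examples
#' fresnel_reflectance(1, 1.4, 1)  # normal incidence: ((0.4)/(2.4))^2 = 1/36
#' @export
fresnel_reflectance <- function(n_i, n_t, cos_theta_i) {
  if (n_i < 1 || n_t < 1) stop("refractive indices must be >= 1")
  if (any(cos_theta_i <= 0 | cos_theta_i > 1))
    stop("`cos_theta_i` must lie in (0, 1]")
  cpp_fresnel_reflectance(n_i, n_t, as.numeric(cos_theta_i))
}

#' Russian roulette weight termination
#'
#' Unbiased termination of low-weight photons: a weight below `threshold`
#' survives with probability `1/m` and is multiplied by `m`, otherwise it is
#' set to zero. The expected returned weight equals the input weight. Weights
#' at or above the threshold pass through untouched.
#'
#' @param w Photon weight (> 0).
#' @param threshold Roulette threshold.
#' @param m Survival divisor (integer >= 2).
#' @param u Uniform deviate in `[0, 1)` deciding survival.
#' @return Either `w` (above threshold), `m * w` (survived) or `0` (killed).
#' @export
russian_roulette <- function(w, threshold, m, u) {
  if (w <= 0) stop("`w` must be > 0")
  if (m < 2) stop("`m` must be >= 2")
  if (w >= threshold) return(w)
  if (u < 1 / m) m * w else 0
}

#' Run a time-resolved Monte Carlo transport simulation
#'
#' Launches `config$n_photons` photons at the origin at `t = 0`, directed
#' normally into the slab, and propagates each through cycles of exponential
#' free-path steps, continuous Beer-Lambert attenuation, Henyey-Greenstein
#' scattering and stochastic Fresnel boundary interactions until it exits,
#' dies in Russian roulette, or reaches the scattering-event cap. Every
#' exiting photon is logged with its exit position, outgoing direction,
#' weight and arrival time (elapsed at the phase velocity `c/n`).
#'
#' The specular reflection of the incident beam at the entry face is deducted
#' deterministically (`R_sp = ((n_amb - n)/(n_amb + n))^2` at normal
#' incidence): each photon launches with weight `1 - R_sp` and the deducted
#' weight appears as a single specular reflection record at `r = 0, t = 0`.
#'
#' @param properties An [optical_properties()] object.
#' @param geometry A [slab_geometry()] object.
#' @param config A [sim_config()] object. The same `(properties, geometry,
#'   config)` triple, seed included, reproduces a bit-identical result.
#' @return An object of class `simulation_result`: a list with
#'   `exit_records` (data frame with columns `side`, `x`, `y`, `r`, `ux`,
#'   `uy`, `uz`, `weight`, `time`), `specular_record` (one-row data frame or
#'   `NULL` at a matched entry face), the `absorbed_weight`, `lost_weight`
#'   and `roulette_boost` tallies, `launch_weight`, `n_cap_terminations`,
#'   and the input `properties`, `geometry` and `config`.
#' @examples
#' res <- run_simulation(
#'   optical_properties(1.4, 0.85, 1 / 0.15, 0.1),
#'   slab_geometry(), sim_config(n_photons = 1000, seed = 7))
#' sum(res$exit_records$weight[res$exit_records$side == "reflection"])
#' @export
run_simulation <- function(properties, geometry = slab_geometry(),
                           config = sim_config(n_photons = 1e4)) {
  stopifnot(inherits(properties, "optical_properties"),
            inherits(geometry, "slab_geometry"),
            inherits(config, "sim_config"))
  raw <- cpp_run_simulation(
    properties$n, properties$g, properties$mu_s, properties$mu_a,
    geometry$thickness, geometry$n_ambient_top, geometry$n_ambient_bottom,
    as.integer(config$n_photons), config$roulette_threshold,
    config$roulette_m, config$seed, config$c_vacuum, config$max_events,
    0)
  build_simulation_result(raw, properties, geometry, config)
}

#' Propagate a single photon
#'
#' Runs the transport loop for the photon with absolute index `photon_index`
#' of the run described by `config`, using exactly the RNG substream that
#' [run_simulation()] would assign it, so single-photon trajectories can be
#' inspected (or a run re-assembled in arbitrary batches) without changing
#' any result.
#'
#' @inheritParams run_simulation
#' @param photon_index Zero-based absolute photon index within the run.
#' @return A `simulation_result` for this one launch.
#' @export
propagate_photon <- function(properties, geometry, config, photon_index = 0) {
  stopifnot(photon_index >= 0)
  raw <- cpp_run_simulation(
    properties$n, properties$g, properties$mu_s, properties$mu_a,
    geometry$thickness, geometry$n_ambient_top, geometry$n_ambient_bottom,
    1L, config$roulette_threshold, config$roulette_m, config$seed,
    config$c_vacuum, config$max_events, as.double(photon_index))
  build_simulation_result(raw, properties, geometry, config,
                          n_launched = 1)
}

build_simulation_result <- function(raw, properties, geometry, config,
                                    n_launched = config$n_photons) {
  records <- data.frame(
    side = c("reflection", "transmission")[raw$side],
    x = raw$x, y = raw$y, r = sqrt(raw$x^2 + raw$y^2),
    ux = raw$ux, uy = raw$uy, uz = raw$uz,
    weight = raw$weight, time = raw$time,
    stringsAsFactors = FALSE)
  specular <- NULL
  if (raw$specular_weight > 0) {
    specular <- data.frame(
      side = "reflection", x = 0, y = 0, r = 0,
      ux = 0, uy = 0, uz = -1,
      weight = raw$specular_weight,
      time = 0, stringsAsFactors = FALSE)
  }
  lost_frac <- raw$lost_weight / max(n_launched, 1)
  if (lost_frac > 1e-3)
    warning(sprintf(
      "lost weight (roulette kills + event-cap terminations) is %.3g of the launched weight",
      lost_frac))
  structure(
    list(exit_records = records, specular_record = specular,
         absorbed_weight = if (config$tally_absorption) raw$absorbed_weight else NA_real_,
         lost_weight = raw$lost_weight,
         roulette_boost = raw$roulette_boost,
         launch_weight = raw$launch_weight,
         n_cap_terminations = raw$n_cap_terminations,
         properties = properties, geometry = geometry, config = config),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  refl <- sum(x$exit_records$weight[x$exit_records$side == "reflection"])
  trans <- sum(x$exit_records$weight[x$exit_records$side == "transmission"])
  cat("<simulation_result>\n")
  cat(sprintf("  photons launched : %g (launch weight %.6g)\n",
              x$config$n_photons, x$launch_weight))
  cat(sprintf("  exit records     : %d\n", nrow(x$exit_records)))
  cat(sprintf("  diffuse reflected / transmitted weight: %.6g / %.6g\n",
              refl, trans))
  if (!is.null(x$specular_record))
    cat(sprintf("  specular weight  : %.6g\n", x$specular_record$weight))
  cat(sprintf("  absorbed / lost  : %.6g / %.6g\n",
              x$absorbed_weight, x$lost_weight))
  invisible(x)
}

#' Histogram the time-resolved and radial diffuse reflectance
#'
#' Bins the reflected exit records of a simulation into time-resolved and
#' radial reflectance curves (diffuse impulse response of the slab), the
#' standard summary views of a transport run. The specular record, when
#' present, lands in the first time/radius bin.
#'
#' @param result A `simulation_result`.
#' @param time_breaks,r_breaks Bin edges (ps, mm); defaults cover the logged
#'   range with 50 bins.
#' @param include_specular Include the specular record. Default `TRUE`.
#' @return A list of two data frames, `temporal` (`time_mid`, `weight`) and
#'   `radial` (`r_mid`, `weight`), weights normalized per launched photon.
#' @export
reflectance_histograms <- function(result, time_breaks = NULL, r_breaks = NULL,
                                   include_specular = TRUE) {
  rec <- result$exit_records
  rec <- rec[rec$side == "reflection", , drop = FALSE]
  if (include_specular && !is.null(result$specular_record))
    rec <- rbind(result$specular_record, rec)
  if (nrow(rec) == 0) stop("no reflected photons to histogram")
  if (is.null(time_breaks))
    time_breaks <- seq(0, max(rec$time) + 1e-9, length.out = 51L)
  if (is.null(r_breaks))
    r_breaks <- seq(0, max(rec$r) + 1e-9, length.out = 51L)
  n <- result$config$n_photons
  tbin <- cut(rec$time, time_breaks, include.lowest = TRUE)
  rbin <- cut(rec$r, r_breaks, include.lowest = TRUE)
  list(
    temporal = data.frame(
      time_mid = (head(time_breaks, -1) + tail(time_breaks, -1)) / 2,
      weight = as.numeric(tapply(rec$weight, tbin, sum, default = 0)) / n),
    radial = data.frame(
      r_mid = (head(r_breaks, -1) + tail(r_breaks, -1)) / 2,
      weight = as.numeric(tapply(rec$weight, rbin, sum, default = 0)) / n))
}
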