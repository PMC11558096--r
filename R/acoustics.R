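# Acoustic enrichment: standing-wave field, primary radiation force, and an
# overdamped particle-migration simulator.
#
# Coordinate convention: x = 0 at a rigid cavity wall, which is a pressure
# antinode; the acoustic pressure mode is p(x) ~ cos(kx). For a resonant
# cavity of length L = m * lambda/2 the interior pressure nodes sit at
# x = (2n + 1) * lambda/4, n = 0 .. m-1 (the fundamental has exactly one, at
# L/2). The textbook node-referenced force -C * Phi * sin(2 k x'), with x' the
# signed distance to the nearest pressure node, becomes
# F(x) = +C * Phi * sin(2 k x) in these absolute coordinates, so positive
# acoustic-contrast particles are driven toward the nodes.

#' Particle specification
#'
#' Physical description of a (spherical) particle subject to the acoustic
#' radiation force. For aggregates, `effective_cluster_radius` replaces the
#' single-particle radius in both the force (via the particle volume) and the
#' Stokes drag; a single 40 nm nanoparticle experiences a radiation force far
#' too weak to migrate on experimental timescales, so cluster-scale migration
#' is what the simulator is meant for.
#'
#' @param radius Particle radius (m).
#' @param density Particle mass density \eqn{\rho_p} (kg/m^3).
#' @param compressibility Particle compressibility \eqn{\beta_p} (1/Pa);
#'   0 for a rigid particle.
#' @param effective_cluster_radius Optional aggregate radius (m) used for
#'   force/drag scaling instead of `radius`.
#' @return An object of class `uelfa_particle`.
#' @seealso [gold_nanoparticle()] for the standard colloidal-gold tracer.
#' @export
particle_spec <- function(radius, density, compressibility,
                          effective_cluster_radius = NULL) {
  assert_that(is_scalar_number(radius) && radius > 0, "`radius` must be > 0")
  assert_that(is_scalar_number(density) && density > 0, "`density` must be > 0")
  assert_that(is_scalar_number(compressibility) && compressibility >= 0,
              "`compressibility` must be >= 0")
  if (!is.null(effective_cluster_radius)) {
    assert_that(is_scalar_number(effective_cluster_radius) &&
                  effective_cluster_radius > 0,
                "`effective_cluster_radius` must be > 0")
  }
  structure(
    list(radius = radius, density = density,
         compressibility = compressibility,
         effective_cluster_radius = effective_cluster_radius),
    class = "uelfa_particle"
  )
}

#' @rdname particle_spec
#' @param diameter Particle diameter (m); default 40 nm, the tracer size with
#'   the strongest colorimetric response.
#' @export
gold_nanoparticle <- function(diameter = 40e-9, effective_cluster_radius = NULL) {
  particle_spec(radius = diameter / 2, density = 19320, compressibility = 0,
                effective_cluster_radius = effective_cluster_radius)
}

# Radius used for V_p and Stokes drag: aggregate if given.
effective_radius <- function(particle) {
  if (!is.null(particle$effective_cluster_radius)) {
    particle$effective_cluster_radius
  } else {
    particle$radius
  }
}

particle_volume <- function(particle) {
  (4 / 3) * pi * effective_radius(particle)^3
}

#' Medium specification
#'
#' Acoustic and viscous properties of the suspending fluid. If
#' `compressibility` is omitted it is derived from the sound speed as
#' \eqn{\beta_m = 1/(\rho_m c^2)}; if supplied it must be consistent with the
#' sound speed to within 0.1% relative.
#'
#' @param density Medium density \eqn{\rho_m} (kg/m^3).
#' @param sound_speed Speed of sound \eqn{c} (m/s).
#' @param dynamic_viscosity Dynamic viscosity \eqn{\eta} (Pa s).
#' @param temperature Absolute temperature (K), used for the Brownian term.
#' @param compressibility Optional \eqn{\beta_m} (1/Pa).
#' @return An object of class `uelfa_medium`.
#' @export
medium_spec <- function(density, sound_speed, dynamic_viscosity, temperature,
                        compressibility = NULL) {
  for (nm in c("density", "sound_speed", "dynamic_viscosity", "temperature")) {
    v <- get(nm)
    assert_that(is_scalar_number(v) && v > 0, paste0("`", nm, "` must be > 0"))
  }
  if (is.null(compressibility)) {
    compressibility <- 1 / (density * sound_speed^2)
  } else {
    assert_that(is_scalar_number(compressibility) && compressibility > 0,
                "`compressibility` must be > 0")
    c_implied <- 1 / sqrt(density * compressibility)
    assert_that(abs(sound_speed - c_implied) / sound_speed < 1e-3,
                "`compressibility` inconsistent with `sound_speed` (>0.1% off)")
  }
  structure(
    list(density = density, compressibility = compressibility,
         sound_speed = sound_speed, dynamic_viscosity = dynamic_viscosity,
         temperature = temperature),
    class = "uelfa_medium"
  )
}

#' @rdname medium_spec
#' @export
water_medium <- function(temperature = 298) {
  medium_spec(density = 997, sound_speed = 1497,
              dynamic_viscosity = 8.9e-4, temperature = temperature)
}

#' One-dimensional standing-wave field
#'
#' @param pressure_amplitude Acoustic pressure amplitude \eqn{P_a} (Pa).
#' @param cavity_length Cavity length along the wave axis (m).
#' @param frequency Drive frequency (Hz); default 700 kHz, the resonant drive
#'   of the enrichment cavity.
#' @param sound_speed Speed of sound in the medium (m/s) used to derive the
#'   wavelength; pass `medium$sound_speed` for consistency.
#' @return An object of class `uelfa_field` with derived `wavelength` and
#'   `wavenumber`.
#' @export
standing_wave_field <- function(pressure_amplitude, cavity_length,
                                frequency = 700e3, sound_speed = 1497) {
  assert_that(is_scalar_number(pressure_amplitude) && pressure_amplitude >= 0,
              "`pressure_amplitude` must be >= 0")
  assert_that(is_scalar_number(frequency) && frequency > 0,
              "`frequency` must be > 0")
  assert_that(is_scalar_number(cavity_length) && cavity_length > 0,
              "`cavity_length` must be > 0")
  wavelength <- sound_speed / frequency
  structure(
    list(pressure_amplitude = pressure_amplitude, frequency = frequency,
         cavity_length = cavity_length, sound_speed = sound_speed,
         wavelength = wavelength, wavenumber = 2 * pi / wavelength),
    class = "uelfa_field"
  )
}

#' Resonance predicate and mode number
#'
#' A field is resonant when the cavity length is an integer multiple of half
#' a wavelength; the mode number m is that integer (the fundamental has
#' m = 1 and a single interior pressure node).
#'
#' @param field A [standing_wave_field()].
#' @param rel_tol Relative tolerance on `cavity_length` for the integer match.
#' @return `is_resonant()`: logical. `mode_number()`: integer m, or `NA` if
#'   non-resonant.
#' @export
is_resonant <- function(field, rel_tol = 1e-6) {
  !is.na(mode_number(field, rel_tol))
}

#' @rdname is_resonant
#' @export
mode_number <- function(field, rel_tol = 1e-6) {
  m <- round(2 * field$cavity_length / field$wavelength)
  if (m >= 1 &&
      abs(field$cavity_length - m * field$wavelength / 2) <
        rel_tol * field$cavity_length) {
    as.integer(m)
  } else {
    NA_integer_
  }
}

#' Acoustic contrast factor
#'
#' \deqn{\Phi = 1 + \frac{3(\rho_p - \rho_m)}{2\rho_p + \rho_m} -
#'   \frac{\beta_p}{\beta_m}}
#'
#' The sign of \eqn{\Phi} decides whether particles collect at pressure nodes
#' (\eqn{\Phi > 0}, e.g. dense rigid gold particles in water) or at antinodes
#' (\eqn{\Phi < 0}, e.g. bubbles or lipid droplets).
#'
#' @param particle A [particle_spec()].
#' @param medium A [medium_spec()].
#' @return Dimensionless contrast factor.
#' @export
acoustic_contrast_factor <- function(particle, medium) {
  rp <- particle$density
  rm <- medium$density
  1 + 3 * (rp - rm) / (2 * rp + rm) -
    particle$compressibility / medium$compressibility
}

# Force amplitude C = pi * Pa^2 * V_p * beta_m / (2 * lambda); F = C*Phi*sin(2kx).
prf_amplitude <- function(particle, medium, field) {
  pi * field$pressure_amplitude^2 * particle_volume(particle) *
    medium$compressibility / (2 * field$wavelength)
}

#' Primary acoustic radiation force
#'
#' Time-averaged radiation force on a small particle at absolute position `x`
#' in the cavity (x = 0 at a wall/pressure antinode):
#' \deqn{F(x) = \frac{\pi P_a^2 V_p \beta_m}{2\lambda}\,\Phi\,\sin(2kx)}
#' which is the node-referenced form \eqn{-C\,\Phi\,\sin(2kx')} (with
#' \eqn{x'} the signed distance to the nearest pressure node) rewritten in
#' absolute coordinates. For \eqn{\Phi > 0} the force is restoring about each
#' pressure node; it vanishes exactly at nodes and antinodes.
#'
#' @param x Position(s) in `[0, cavity_length]` (m); vectorised.
#' @inheritParams acoustic_contrast_factor
#' @param field A [standing_wave_field()].
#' @return Force (N), same length as `x`; positive toward larger `x`.
#' @export
primary_radiation_force <- function(x, particle, medium, field) {
  assert_that(is.numeric(x) && all(is.finite(x)), "`x` must be numeric")
  assert_that(all(x >= 0 & x <= field$cavity_length),
              "`x` must lie within [0, cavity_length]")
  phi <- acoustic_contrast_factor(particle, medium)
  prf_amplitude(particle, medium, field) * phi * sin(2 * field$wavenumber * x)
}

#' Stable equilibrium positions in a resonant cavity
#'
#' Positions in (0, L) where the radiation force vanishes with negative slope
#' (stable trapping). For positive acoustic contrast these are the interior
#' pressure nodes, one per half-wavelength (mode m has m of them; the
#' fundamental exactly one, at L/2). For negative contrast they are the
#' interior pressure antinodes (m - 1 of them; none for the fundamental).
#'
#' @param field A resonant [standing_wave_field()].
#' @param contrast_sign +1 or -1, the sign of the acoustic contrast factor.
#' @return Numeric vector of stable positions (m), increasing.
#' @export
pressure_nodes <- function(field, contrast_sign = 1) {
  m <- mode_number(field)
  if (is.na(m)) {
    stop("field is not resonant: cavity_length is not an integer multiple of ",
         "lambda/2, so the mode structure is undefined", call. = FALSE)
  }
  assert_that(contrast_sign %in% c(-1, 1), "`contrast_sign` must be +1 or -1")
  lam <- field$wavelength
  if (contrast_sign > 0) {
    (2 * seq_len(m) - 1) * lam / 4      # interior pressure nodes
  } else if (m > 1) {
    seq_len(m - 1) * lam / 2            # interior pressure antinodes
  } else {
    numeric(0)
  }
}

#' Overdamped particle migration in the standing wave
#'
#' Integrates inertialess Stokes-drag dynamics
#' \eqn{x \leftarrow x + F(x)\,\Delta t/(6\pi\eta r)} by Euler(-Maruyama)
#' stepping, optionally with the fluctuation-dissipation Brownian increment
#' \eqn{\sqrt{2 k_B T \Delta t/(6\pi\eta r)}\,\xi}. Positions are clamped to
#' the cavity. With Brownian motion off and positive contrast, every
#' particle's distance to its nearest stable node is non-increasing (the step
#' bound enforced below guarantees this Lyapunov property).
#'
#' @param initial_positions Numeric vector of starting positions (m) within
#'   the cavity.
#' @inheritParams primary_radiation_force
#' @param duration Total simulated time (s).
#' @param dt Time step (s). An error is raised if the maximal advective step
#'   \eqn{C|\Phi|\mu\,\Delta t} exceeds \eqn{\lambda/(2\pi)}, beyond which a
#'   particle can overshoot past an antinode in one step.
#' @param brownian Add thermal noise?
#' @param seed Integer seed for the Brownian increments (bit-reproducible).
#' @param convergence_tol Distance defining "arrived at a node"; default 1% of
#'   the wavelength (dimensionless of any grid).
#' @return An object of class `uelfa_trajectory`: `times` (s), `positions`
#'   (n_particles x n_times matrix, m), `converged_fraction`,
#'   `enrichment_factor` (window half-width \eqn{\lambda/20}; see
#'   [enrichment_factor()] to recompute), plus the field and contrast sign.
#' @export
simulate_migration <- function(initial_positions, particle, medium, field,
                               duration, dt, brownian = FALSE, seed = NULL,
                               convergence_tol = 0.01 * field$wavelength) {
  assert_that(is.numeric(initial_positions) && length(initial_positions) >= 1,
              "`initial_positions` must be a non-empty numeric vector")
  assert_that(all(initial_positions >= 0 &
                    initial_positions <= field$cavity_length),
              "initial positions must lie within the cavity")
  assert_that(is_scalar_number(dt) && dt > 0, "`dt` must be > 0")
  assert_that(is_scalar_number(duration) && duration >= dt,
              "`duration` must be >= dt")

  phi <- acoustic_contrast_factor(particle, medium)
  amp <- prf_amplitude(particle, medium, field)
  mobility <- 1 / (6 * pi * medium$dynamic_viscosity * effective_radius(particle))
  max_step <- amp * abs(phi) * mobility * dt
  if (max_step > field$wavelength / (2 * pi)) {
    stop("`dt` too large for stable integration: maximal advective step ",
         format(max_step, digits = 3), " m exceeds lambda/(2*pi) = ",
         format(field$wavelength / (2 * pi), digits = 3),
         " m (overshoot past an antinode possible); reduce dt", call. = FALSE)
  }

  n_steps <- ceiling(duration / dt)
  assert_that(n_steps <= 5e5, "too many steps (> 5e5); increase dt")
  n <- length(initial_positions)
  pos <- matrix(NA_real_, nrow = n, ncol = n_steps + 1L)
  pos[, 1L] <- initial_positions
  k2 <- 2 * field$wavenumber
  noise_sd <- if (brownian) {
    sqrt(2 * .kB * medium$temperature * mobility * dt)
  } else 0

  with_seed(seed, {
    x <- initial_positions
    for (s in seq_len(n_steps)) {
      f <- amp * phi * sin(k2 * x)
      x <- x + f * mobility * dt
      if (brownian) x <- x + rnorm(n, 0, noise_sd)
      x <- pmin(pmax(x, 0), field$cavity_length)
      pos[, s + 1L] <- x
    }
  })

  csign <- if (phi < 0) -1 else 1
  nodes <- pressure_nodes(field, contrast_sign = csign)
  final <- pos[, n_steps + 1L]
  conv <- if (length(nodes) == 0) 0 else {
    mean(apply(abs(outer(final, nodes, "-")), 1, min) <= convergence_tol)
  }
  traj <- structure(
    list(times = seq(0, by = dt, length.out = n_steps + 1L),
         positions = pos, converged_fraction = conv,
         enrichment_factor = NA_real_, field = field, contrast_sign = csign),
    class = "uelfa_trajectory"
  )
  traj$enrichment_factor <-
    suppressWarnings(enrichment_factor(traj, field$wavelength / 20))
  traj
}

#' Enrichment factor of a migration run
#'
#' Ratio of the final to the initial number of particles inside windows of
#' half-width `window_half_width` centred on the stable trapping positions.
#' Equals 1 when positions are unchanged; for an initially uniform cloud that
#' fully converges into a window covering 1/10 of the cavity it approaches 10.
#'
#' @param traj A `uelfa_trajectory` from [simulate_migration()].
#' @param window_half_width Half-width of the counting window (m).
#' @param field Standing-wave field; defaults to the one stored in `traj`.
#' @return Dimensionless enrichment factor (>= 0; `Inf` if the window starts
#'   empty and ends occupied).
#' @export
enrichment_factor <- function(traj, window_half_width, field = traj$field) {
  assert_that(inherits(traj, "uelfa_trajectory"), "`traj` must be a trajectory")
  if (is.null(traj$positions) || ncol(traj$positions) == 0) {
    stop("empty trajectory", call. = FALSE)
  }
  assert_that(is_scalar_number(window_half_width) && window_half_width > 0,
              "`window_half_width` must be > 0")
  nodes <- pressure_nodes(field, contrast_sign = traj$contrast_sign)
  assert_that(all(nodes - window_half_width >= 0) &&
                all(nodes + window_half_width <= field$cavity_length),
              "window extends outside the cavity")
  in_window <- function(x) {
    if (length(nodes) == 0) return(0L)
    sum(apply(abs(outer(x, nodes, "-")), 1, min) <= window_half_width)
  }
  n0 <- in_window(traj$positions[, 1L])
  n1 <- in_window(traj$positions[, ncol(traj$positions)])
  if (n0 == 0L) {
    if (n1 == 0L) return(1)
    warning("window initially empty; enrichment factor is infinite")
    return(Inf)
  }
  n1 / n0
}

#' @export
print.uelfa_trajectory <- function(x, ...) {
  cat("Overdamped migration trajectory\n")
  cat("  particles:          ", nrow(x$positions), "\n")
  cat("  time span:          ", max(x$times), "s in", ncol(x$positions) - 1,
      "steps\n")
  cat("  converged fraction: ", format(x$converged_fraction, digits = 4), "\n")
  cat("  enrichment factor:  ", format(x$enrichment_factor, digits = 4), "\n")
  invisible(x)
}

#' Export a trajectory to CSV / JSON summary
#'
#' Writes the long-format trajectory table (`time_s`, `particle_id`, `x_m`)
#' and, optionally, a JSON summary with the convergence and enrichment
#' figures.
#'
#' @param traj A `uelfa_trajectory`.
#' @param csv_path Path for the CSV table.
#' @param json_path Optional path for the JSON summary.
#' @return Invisibly, the summary list.
#' @export
export_trajectory <- function(traj, csv_path, json_path = NULL) {
  n <- nrow(traj$positions)
  tab <- data.frame(
    time_s = rep(traj$times, each = n),
    particle_id = rep(seq_len(n), times = length(traj$times)),
    x_m = as.vector(traj$positions)
  )
  utils::write.csv(tab, csv_path, row.names = FALSE)
  summ <- list(converged_fraction = traj$converged_fraction,
               enrichment_factor = traj$enrichment_factor)
  if (!is.null(json_path)) {
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summ)
}
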