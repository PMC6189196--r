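#' Component reference spectrum
#'
#' Ground-truth emission model of one chemical component: a set of
#' pseudo-Voigt bands (50\% Lorentzian) plus a scattering strength per unit
#' particle volume. Band amplitudes are relative; the rendered contribution
#' of a component scales with its weight fraction, the particle volume and
#' the scattering strength.
#'
#' @param name component name.
#' @param bands data frame with columns `center` (cm^-1), `width` (HWHM,
#'   cm^-1) and `amplitude` (> 0, relative).
#' @param scatter scattering strength per unit volume (arbitrary units).
#' @return a `component_spectrum`.
#' @export
component_spectrum <- function(name, bands, scatter = 1) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "width", "amplitude") %in% names(bands)),
            nrow(bands) >= 1L,
            all(bands$width > 0), all(bands$amplitude > 0), scatter > 0)
  structure(list(name = name, bands = bands, scatter = scatter),
            class = "component_spectrum")
}

pseudo_voigt <- function(nu, center, hwhm, amplitude) {
  x2 <- (nu - center)^2
  g2 <- hwhm^2
  amplitude * (0.5 * g2 / (x2 + g2) + 0.5 * exp(-log(2) * x2 / g2))
}

eval_component <- function(comp, nu) {
  out <- numeric(length(nu))
  for (i in seq_len(nrow(comp$bands))) {
    b <- comp$bands[i, ]
    out <- out + pseudo_voigt(nu, b$center, b$width, b$amplitude)
  }
  out * comp$scatter
}

#' Built-in component library
#'
#' Reference bands of the particle systems exercised by the simulation
#' presets: DPPC and deuterated DPPC lipids (C-D stretch 2105 cm^-1, CH2
#' deformation 1450 cm^-1), PDMS and heparin blocks of the polymersome
#' formulations (PDMS 490/709 cm^-1, heparin saccharide 930/1070 cm^-1),
#' polystyrene, the perchlorate solution marker (938 cm^-1), the serial
#' functionalisation reporters (S-H 936, S-S 452/512, tyrosine 840/860
#' cm^-1) and the click-reaction trio (alkyne 2129, azide 2116, triazole
#' 1331 cm^-1).
#'
#' Band amplitudes within each component are rescaled so every component
#' integrates to the same total scattering cross-section per unit mass
#' (before the `scatter` multiplier). Under that convention, area
#' normalisation maps component weight fractions directly onto band-area
#' fractions, which is the premise of comparing measured band-area ratios
#' with theoretical weight-fraction ratios.
#'
#' @return named list of `component_spectrum` objects.
#' @export
component_library <- function() {
  # integral of a unit-amplitude 50/50 pseudo-Voigt of HWHM w is
  # (pi/2 + sqrt(pi/log 2)/2) * w
  pv_area <- pi / 2 + sqrt(pi / log(2)) / 2
  cs <- function(name, m, scatter = 1) {
    total <- pv_area * sum(m[, 2] * m[, 3])
    component_spectrum(name,
                       data.frame(center = m[, 1], width = m[, 2],
                                  amplitude = m[, 3] * 30 / total), scatter)
  }
  list(
    dppc = cs("dppc", rbind(c(1095, 10, 0.5), c(1296, 9, 0.8),
                            c(1450, 10, 1.0), c(2850, 12, 0.9))),
    d_dppc = cs("d_dppc", rbind(c(1095, 10, 0.5), c(1296, 9, 0.6),
                                c(1450, 10, 0.7), c(2105, 14, 1.2)),
                scatter = 1.6),  # C-D is a strong Raman scatterer
    pdms = cs("pdms", rbind(c(490, 12, 1.0), c(709, 10, 0.8),
                            c(1262, 9, 0.5), c(1410, 12, 0.3))),
    pmoxa = cs("pmoxa", rbind(c(1240, 14, 0.35), c(1430, 14, 0.45))),
    heparin = cs("heparin", rbind(c(930, 12, 0.6), c(1070, 12, 0.5))),
    polystyrene = cs("polystyrene", rbind(c(621, 8, 0.4), c(1001, 6, 1.0),
                                          c(1031, 7, 0.5), c(1602, 8, 0.6))),
    perchlorate = cs("perchlorate", rbind(c(938, 8, 1.0))),
    sulfhydryl = cs("sulfhydryl", rbind(c(936, 9, 0.7))),
    disulfide_tnb = cs("disulfide_tnb", rbind(c(452, 9, 0.5), c(512, 9, 0.6),
                                              c(1331, 10, 0.8))),
    tyrosine = cs("tyrosine", rbind(c(840, 8, 0.5), c(860, 8, 0.5))),
    alkyne = cs("alkyne", rbind(c(2129, 9, 1.0))),
    azide = cs("azide", rbind(c(2116, 9, 0.8))),
    triazole = cs("triazole", rbind(c(1331, 10, 0.9))),
    buffer = cs("buffer", rbind(c(1640, 60, 0.15)))
  )
}

#' Particle specification
#'
#' @param diameter particle diameter in nm (> 0).
#' @param composition named numeric of component weight fractions summing to
#'   one (names must exist in the component library in use).
#' @param id integer identity tag (fresh tag per arrival in simulations).
#' @return a `particle_spec`.
#' @export
particle_spec <- function(diameter, composition, id = 1L) {
  stopifnot(diameter > 0, length(composition) >= 1L,
            !is.null(names(composition)))
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition weight fractions must sum to 1")
  structure(list(diameter = diameter, composition = composition,
                 id = as.integer(id)), class = "particle_spec")
}

particle_volume_um3 <- function(diameter_nm) (pi / 6) * (diameter_nm / 1000)^3

#' Trap physics parameters
#'
#' Phenomenological trap model: Stokes-Einstein diffusion, a capture radius
#' within which a released particle is considered re-trappable, a confocal
#' volume for the displacement law, and a Smoluchowski arrival rate
#' `k_a = 4 pi D a c` when a number concentration is given.
#'
#' @param temperature kelvin.
#' @param viscosity dynamic viscosity in Pa s.
#' @param capture_radius capture radius in micrometres.
#' @param confocal_volume confocal volume in cubic micrometres.
#' @param concentration particle number concentration per ml (used for the
#'   arrival rate); `NULL` disables arrivals unless `arrival_rate` is set.
#' @param arrival_rate explicit arrival rate in 1/s, overriding the
#'   Smoluchowski value.
#' @return a `trap_physics` list.
#' @export
trap_physics <- function(temperature = 298, viscosity = 0.89e-3,
                         capture_radius = 0.5, confocal_volume = 1,
                         concentration = 1e11, arrival_rate = NULL) {
  stopifnot(temperature > 0, viscosity > 0, capture_radius > 0,
            confocal_volume > 0)
  structure(list(temperature = temperature, viscosity = viscosity,
                 capture_radius = capture_radius,
                 confocal_volume = confocal_volume,
                 concentration = concentration,
                 arrival_rate = arrival_rate),
            class = "trap_physics")
}

k_boltzmann <- 1.380649e-23

#' Stokes-Einstein diffusion coefficient
#' @param diameter particle diameter in nm.
#' @param physics a [trap_physics()].
#' @return diffusivity in m^2/s.
#' @export
diffusivity <- function(diameter, physics = trap_physics()) {
  k_boltzmann * physics$temperature /
    (3 * pi * physics$viscosity * diameter * 1e-9)
}

arrival_rate <- function(diameter, physics) {
  if (!is.null(physics$arrival_rate)) return(physics$arrival_rate)
  if (is.null(physics$concentration)) return(0)
  D <- diffusivity(diameter, physics)
  4 * pi * D * (physics$capture_radius * 1e-6) * (physics$concentration * 1e6)
}

#' Probability that a released particle is still within the capture radius
#'
#' After the laser is disabled for `t_off`, a particle starting at the trap
#' centre has undergone isotropic Brownian displacement with variance `2 D
#' t_off` per axis, so the squared radial displacement over `2 D t_off` is
#' chi-squared with 3 degrees of freedom. The returned value is the
#' probability of still being inside the capture radius (the escape
#' probability is its complement).
#'
#' @param t_off laser-off time in seconds (>= 0).
#' @param diameter particle diameter in nm.
#' @param physics a [trap_physics()].
#' @return retention probability in [0, 1]; 1 at `t_off = 0`.
#' @export
escape_probability <- function(t_off, diameter, physics = trap_physics()) {
  stopifnot(t_off >= 0)
  if (t_off == 0) return(1)
  D <- diffusivity(diameter, physics)
  a <- physics$capture_radius * 1e-6
  stats::pchisq(a^2 / (2 * D * t_off), df = 3)
}

#' Stream configuration for the virtual instrument
#'
#' @param axis_lo,axis_hi,axis_step wavenumber axis definition in cm^-1
#'   (defaults give the extended 606-2254 cm^-1 range at the instrument's
#'   3 cm^-1 spectral resolution).
#' @param shot_noise logical; apply Poisson shot noise to the expected
#'   counts.
#' @param read_noise Gaussian read noise s.d. in counts (per channel).
#' @param particle_response counts/s per unit band amplitude per um^3 of
#'   particle volume (detector response; sets the particle signal scale).
#' @param baseline_amplitude peak counts/s of the slowly varying fluorescence
#'   baseline (rendered as a broad squared-cosine hump).
#' @param solution_amplitude counts/s scale of the perchlorate marker band at
#'   an empty trap (0 = no marker in solution).
#' @param spike_prob probability of a cosmic spike per spectrum.
#' @param seed mandatory RNG seed; every draw of the stream flows from it.
#' @return a `stream_config` list.
#' @export
stream_config <- function(axis_lo = 606, axis_hi = 2254, axis_step = 3,
                          shot_noise = TRUE, read_noise = 2,
                          particle_response = 2e4,
                          baseline_amplitude = 50, solution_amplitude = 0,
                          spike_prob = 0.01, seed = 1L) {
  stopifnot(axis_step > 0, axis_lo < axis_hi, particle_response > 0,
            spike_prob >= 0, spike_prob <= 1, !is.null(seed))
  structure(list(axis_lo = axis_lo, axis_hi = axis_hi, axis_step = axis_step,
                 shot_noise = isTRUE(shot_noise), read_noise = read_noise,
                 particle_response = particle_response,
                 baseline_amplitude = baseline_amplitude,
                 solution_amplitude = solution_amplitude,
                 spike_prob = spike_prob, seed = as.integer(seed)),
            class = "stream_config")
}

stream_axis <- function(cfg) seq(cfg$axis_lo, cfg$axis_hi, by = cfg$axis_step)

#' Render one spectrum of the trap volume
#'
#' Deterministic model intensity per second:
#' baseline + buffer background + `fill * sum_c w_c S_c(nu) * V_p * 1e3`
#' + `perchlorate(nu) * (1 - fill * V_p / V_c)` -- a particle displaces its
#' own volume of marker solution out of the confocal volume, so the marker
#' band shrinks in proportion to `V_p / V_c`. The expectation is scaled by
#' the integration time, then Poisson shot noise, Gaussian read noise and
#' (with probability `spike_prob`) a cosmic spike are applied.
#'
#' @param particle a [particle_spec()] or `NULL` for an empty trap.
#' @param fill fraction of the integration time the particle was present
#'   (in [0, 1]; mid-iteration arrivals give partial fills).
#' @param t_int integration time in seconds.
#' @param config a [stream_config()]; `config$seed` makes the render
#'   reproducible unless `deterministic = TRUE`.
#' @param physics a [trap_physics()].
#' @param library component library (named list of [component_spectrum()]).
#' @param deterministic if `TRUE`, return the noise-free expectation.
#' @return a `raman_spectrum`.
#' @export
render_spectrum <- function(particle = NULL, fill = 1, t_int = 1,
                            config = stream_config(),
                            physics = trap_physics(),
                            library = component_library(),
                            deterministic = FALSE) {
  stopifnot(fill >= 0, fill <= 1, t_int > 0)
  nu <- stream_axis(config)
  # slowly varying fluorescence tail: exponential decay across the range
  base <- config$baseline_amplitude *
    exp(-(nu - config$axis_lo) / (config$axis_hi - config$axis_lo))
  model <- base + eval_component(library$buffer, nu) * 20
  vp <- 0
  if (!is.null(particle)) {
    vp <- particle_volume_um3(particle$diameter)
    if (vp > physics$confocal_volume)
      stop("particle exceeds confocal volume")
    sig <- numeric(length(nu))
    for (nm in names(particle$composition)) {
      comp <- library[[nm]]
      if (is.null(comp)) stop(sprintf("unknown component '%s'", nm))
      sig <- sig + particle$composition[[nm]] * eval_component(comp, nu)
    }
    model <- model + fill * sig * vp * config$particle_response
  }
  if (config$solution_amplitude > 0) {
    depletion <- 1 - fill * vp / physics$confocal_volume
    model <- model + config$solution_amplitude *
      eval_component(library$perchlorate, nu) * depletion
  }
  expected <- t_int * model
  if (deterministic)
    return(spectrum(nu, expected, integration_time = t_int))
  counts <- expected
  if (config$shot_noise)
    counts <- stats::rpois(length(nu), expected)
  counts <- counts + stats::rnorm(length(nu), 0, config$read_noise)
  if (config$spike_prob > 0 && stats::runif(1) < config$spike_prob) {
    ch <- sample.int(length(nu), 1)
    counts[ch] <- counts[ch] + 50 * max(counts)
  }
  counts <- pmax(counts, 0)
  spectrum(nu, counts, integration_time = t_int)
}

#' Advance the trap occupancy state
#'
#' One step of the occupancy dynamics behind the acquisition controller's
#' view. With the laser off and the trap occupied, the particle is retained
#' with [escape_probability()]'s return value, else it vacates. With the
#' laser on and the trap empty, a new particle arrives within `dt` with
#' probability `1 - exp(-k_a dt)`; the arrival instant is uniform in the
#' interval, so the fill fraction for that spectrum is < 1. An occupied trap
#' with the laser on holds its particle. Each arrival receives a fresh
#' identity tag.
#'
#' @param state list with `occupied`, `particle`, `fill`, `next_id`.
#' @param laser_on logical.
#' @param dt step duration in seconds (> 0).
#' @param physics a [trap_physics()].
#' @param sampler function() returning a new `particle_spec` (without id).
#' @return the new state.
#' @export
step_stream <- function(state, laser_on, dt, physics = trap_physics(),
                        sampler = NULL) {
  stopifnot(dt > 0)
  state$fill <- if (state$occupied) 1 else 0
  if (!laser_on) {
    if (state$occupied) {
      p_keep <- escape_probability(dt, state$particle$diameter, physics)
      if (stats::runif(1) >= p_keep) {
        state$occupied <- FALSE
        state$particle <- NULL
        state$fill <- 0
      }
    }
    return(state)
  }
  if (!state$occupied && !is.null(sampler)) {
    dia <- if (!is.null(state$diameter_hint)) state$diameter_hint else 200
    ka <- arrival_rate(dia, physics)
    if (ka > 0 && stats::runif(1) < 1 - exp(-ka * dt)) {
      p <- sampler()
      p$id <- state$next_id
      state$next_id <- state$next_id + 1L
      state$particle <- p
      state$occupied <- TRUE
      state$fill <- stats::runif(1)  # arrival uniform in the interval
    }
  }
  state
}

new_stream_state <- function() {
  list(occupied = FALSE, particle = NULL, fill = 0, next_id = 1L,
       diameter_hint = NULL)
}

#' Component weight fractions from block masses
#'
#' Exact mass-fraction arithmetic over possibly nested mixtures. A leaf is a
#' named mass; a nested mixture is `list(mass = <total mass>, parts =
#' <spec>)`, whose leaf masses are rescaled to the stated total. Fractions of
#' identically named leaves are aggregated.
#'
#' For example the PMOXA-b-PDMS-b-PMOXA triblock with block masses
#' 0.5/4.8/0.5 kDa is 83 wt.\% PDMS; blending it 75:25 by weight with a
#' PDMS-b-heparin copolymer (5 kDa PDMS of 16 kDa total) gives 70 wt.\%.
#'
#' @param x named numeric vector of masses, or a named list mixing bare
#'   masses and `list(mass=, parts=)` sub-mixtures.
#' @return named numeric of weight fractions summing to 1.
#' @export
component_weight_fractions <- function(x) {
  masses <- flatten_masses(x)
  total <- sum(masses)
  if (total <= 0) stop("zero total mass")
  out <- tapply(masses, names(masses), sum) / total
  stats::setNames(as.numeric(out), names(out))
}

flatten_masses <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("masses must be named")
    if (any(x < 0)) stop("masses must be positive")
    return(x)
  }
  if (!is.list(x)) stop("unsupported mass specification")
  out <- numeric(0)
  for (nm in names(x)) {
    el <- x[[nm]]
    if (is.numeric(el) && length(el) == 1L) {
      v <- stats::setNames(el, nm)
    } else if (is.list(el) && !is.null(el$mass) && !is.null(el$parts)) {
      sub <- flatten_masses(el$parts)
      v <- sub / sum(sub) * el$mass
    } else stop(sprintf("element '%s' is neither a mass nor a sub-mixture", nm))
    out <- c(out, v)
  }
  out
}
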