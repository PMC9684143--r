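#' Simulation scene: ground-truth emitters plus photophysics
#'
#' Bundles the true emitter geometry with the kinetic and photophysical
#' parameters shared by the DNA-PAINT and dSTORM generators: mean blinks per
#' emitter, mean photons per event (exponential), PSF size (localization
#' precision is sigma_PSF/sqrt(photons)), acquisition length, optional
#' per-emitter linear drift vectors, and the dSTORM three-state rates.
#'
#' @param positions Two-column matrix of true emitter (x, y) in nm.
#' @param geometry Free-text tag.
#' @param lambda Mean blinking/binding events per emitter (> 0).
#' @param mean_photons Mean detected photons per event (default 1800).
#' @param sigma_psf PSF sigma in nm (default 120).
#' @param n_frames Acquisition length in frames.
#' @param drift Optional K x 2 matrix of per-emitter total drifts over the
#'   acquisition (nm); see [apply_drift].
#' @param k_on,k_off,k_b dSTORM per-frame rates: off->on, on->off, on->bleach.
#' @return List of class `"sim_scene"`.
#' @export
sim_scene <- function(positions, geometry = "custom", lambda = 50,
                      mean_photons = 1800, sigma_psf = 120,
                      n_frames = 1000L, drift = NULL,
                      k_on = 2e-4, k_off = 5e-2, k_b = 5e-2) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, lambda > 0, mean_photons > 0, sigma_psf > 0,
            n_frames >= 1, k_on >= 0, k_off >= 0, k_b >= 0)
  if (!is.null(drift)) {
    drift <- as.matrix(drift)
    stopifnot(nrow(drift) == nrow(positions), ncol(drift) == 2)
  }
  structure(list(positions = positions, geometry = geometry, lambda = lambda,
                 mean_photons = mean_photons, sigma_psf = sigma_psf,
                 n_frames = as.integer(n_frames), drift = drift,
                 k_on = k_on, k_off = k_off, k_b = k_b),
            class = "sim_scene")
}

#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf("<sim_scene> %s: %d emitters, lambda=%.1f, %d frames\n",
              x$geometry, nrow(x$positions), x$lambda, x$n_frames))
  invisible(x)
}

#' Regular n-mer ring (8-mer by default)
#'
#' Emitters equally spaced on a circle of radius R; the neighbor spacing of an
#' 8-mer is 2 R sin(pi/8) ~ 0.76 R.
#'
#' @param R Ring radius in nm.
#' @param n_sites Number of emitters on the ring.
#' @param center Ring center (nm).
#' @param ... Passed to [sim_scene].
#' @export
sim_8mer <- function(R, n_sites = 8, center = c(0, 0), ...) {
  ang <- 2 * pi * (seq_len(n_sites) - 1) / n_sites
  sim_scene(cbind(center[1] + R * cos(ang), center[2] + R * sin(ang)),
            geometry = sprintf("%d-mer R=%g", n_sites, R), ...)
}

#' Two emitters separated by d nm
#' @param d Separation in nm.
#' @param center Midpoint (nm).
#' @param ... Passed to [sim_scene].
#' @export
sim_dimer <- function(d, center = c(0, 0), ...) {
  sim_scene(rbind(center + c(-d / 2, 0), center + c(d / 2, 0)),
            geometry = sprintf("dimer d=%g", d), ...)
}

#' Uniform random emitter field at a given density
#'
#' Emitter count is `round(rho * area)`; positions uniform over the area. The
#' expected nearest-neighbor separation of such a field is 1/(2 sqrt(rho)).
#'
#' @param rho Density in emitters per square micrometre.
#' @param area Extent `c(xmin, xmax, ymin, ymax)` in nm
#'   (default 500 x 500 nm^2).
#' @param ... Passed to [sim_scene].
#' @export
sim_density_field <- function(rho, area = c(0, 500, 0, 500), ...) {
  stopifnot(rho > 0, length(area) == 4)
  a_um2 <- (area[2] - area[1]) * (area[4] - area[3]) / 1e6
  n <- max(1L, as.integer(round(rho * a_um2)))
  sim_scene(cbind(stats::runif(n, area[1], area[2]),
                  stats::runif(n, area[3], area[4])),
            geometry = sprintf("field rho=%g/um2", rho), ...)
}

#' Pair of parallel lines with randomly placed emitters
#'
#' @param separation Distance between the two lines (nm).
#' @param length Line length (nm).
#' @param n_per_line Emitters placed uniformly at random along each line.
#' @param angle Rotation of the pair (radians).
#' @param center Midpoint (nm).
#' @param ... Passed to [sim_scene].
#' @export
sim_line_pair <- function(separation, length = 100, n_per_line = 70,
                          angle = 0, center = c(0, 0), ...) {
  u <- c(cos(angle), sin(angle)); v <- c(-sin(angle), cos(angle))
  p <- NULL
  for (s in c(-separation / 2, separation / 2)) {
    tpos <- stats::runif(n_per_line, -length / 2, length / 2)
    p <- rbind(p, cbind(center[1] + tpos * u[1] + s * v[1],
                        center[2] + tpos * u[2] + s * v[2]))
  }
  sim_scene(p, geometry = sprintf("line pair sep=%g", separation), ...)
}

#' Cross of two perpendicular lines with equally spaced emitters
#'
#' Two arms of the given length at 90 degrees through a common center;
#' emitters sit at +-(separation/2 + j separation) along each arm, so no two
#' emitters coincide at the center.
#'
#' @param separation Spacing between adjacent emitters on an arm (nm).
#' @param arm_length Full arm length (nm, default 100).
#' @param center Cross center (nm).
#' @param ... Passed to [sim_scene].
#' @export
sim_cross <- function(separation, arm_length = 100, center = c(0, 0), ...) {
  half <- arm_length / 2
  offs <- seq(separation / 2, half, by = separation)
  offs <- c(-rev(offs), offs)
  p <- rbind(cbind(center[1] + offs, center[2]),
             cbind(center[1], center[2] + offs))
  sim_scene(p, geometry = sprintf("cross sep=%g", separation), ...)
}

#' Attach per-emitter linear drift to a scene
#'
#' Each emitter receives a linear drift over the acquisition, either of fixed
#' magnitude in a random direction, or a common fixed vector. Observed blink
#' positions are offset by drift * t with t = frame/n_frames in \[0, 1\].
#'
#' @param scene A [sim_scene].
#' @param velocity Drift magnitude in nm per acquisition (used with random
#'   directions). Default 2 nm.
#' @param vector Optional fixed drift vector `c(dx, dy)` applied to every
#'   emitter (overrides `velocity`).
#' @return The scene with its `drift` matrix set.
#' @export
apply_drift <- function(scene, velocity = 2, vector = NULL) {
  stopifnot(inherits(scene, "sim_scene"))
  K <- nrow(scene$positions)
  if (!is.null(vector)) {
    scene$drift <- matrix(rep(as.numeric(vector), each = K), K, 2)
  } else {
    th <- stats::runif(K, 0, 2 * pi)
    scene$drift <- velocity * cbind(cos(th), sin(th))
  }
  scene
}

#' dSTORM three-state blinking kinetics (Gillespie)
#'
#' Every fluorophore starts in the off state; off->on waiting times are
#' exponential with rate `k_on` per frame; each on period ends after an
#' exponential time with rate `k_off + k_b`, branching to the bleached state
#' with probability `k_b/(k_off+k_b)` and back to off otherwise. Events are
#' truncated at `n_frames`. The number of blinks of a fluorophore that
#' bleaches before truncation is geometric with mean `(k_off+k_b)/k_b`.
#'
#' @param scene A [sim_scene] with positive rates.
#' @return List per fluorophore of blink onset times (frames, fractional);
#'   fluorophores that never turn on contribute `numeric(0)`.
#' @export
sim_dstorm_kinetics <- function(scene) {
  stopifnot(inherits(scene, "sim_scene"), scene$k_on > 0,
            scene$k_off + scene$k_b > 0)
  K <- nrow(scene$positions)
  p_b <- scene$k_b / (scene$k_off + scene$k_b)
  lapply(seq_len(K), function(k) {
    t <- 0; on <- numeric(0)
    repeat {
      t <- t + stats::rexp(1, scene$k_on)
      if (t >= scene$n_frames) break
      on <- c(on, t)
      t <- t + stats::rexp(1, scene$k_off + scene$k_b)
      if (stats::runif(1) < p_b || t >= scene$n_frames) break
    }
    on
  })
}

#' Generate a localization list from a scene
#'
#' DNA-PAINT mode draws a Poisson(lambda) number of binding events per emitter
#' at uniformly random frames; dSTORM mode takes blink times from the
#' three-state Gillespie kinetics. Every event detects
#' I ~ Exponential(mean_photons) photons, has per-axis precision
#' sigma = sigma_PSF/sqrt(I), and is observed at the true position (plus
#' drift * t if the scene has drift) with Gaussian noise of that precision.
#'
#' @param scene A [sim_scene].
#' @param mode `"paint"` or `"dstorm"`.
#' @return List with `set` (a [localizations] object), `emitter` (ground-truth
#'   generating emitter index per localization), and `scene`.
#' @export
simulate_blinks <- function(scene, mode = c("paint", "dstorm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scene, "sim_scene"))
  K <- nrow(scene$positions)
  if (mode == "paint") {
    counts <- stats::rpois(K, scene$lambda)
    emitter <- rep(seq_len(K), counts)
    frames <- sample.int(scene$n_frames, length(emitter), replace = TRUE) - 1L
  } else {
    ev <- sim_dstorm_kinetics(scene)
    counts <- lengths(ev)
    emitter <- rep(seq_len(K), counts)
    frames <- as.integer(floor(unlist(ev)))
  }
  n <- length(emitter)
  if (n == 0)
    return(list(set = localizations(numeric(0), numeric(0), numeric(0)),
                emitter = integer(0), scene = scene))
  I <- stats::rexp(n, rate = 1 / scene$mean_photons)
  I <- pmax(I, 1)  # at least one photon detected
  sig <- scene$sigma_psf / sqrt(I)
  tt <- frames / scene$n_frames
  px <- scene$positions[emitter, 1]
  py <- scene$positions[emitter, 2]
  if (!is.null(scene$drift)) {
    px <- px + scene$drift[emitter, 1] * tt
    py <- py + scene$drift[emitter, 2] * tt
  }
  x <- stats::rnorm(n, px, sig)
  y <- stats::rnorm(n, py, sig)
  list(set = localizations(x, y, sig, sig, frame = frames, photons = I),
       emitter = emitter, scene = scene)
}
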