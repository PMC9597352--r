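#' Motion model for trajectory simulation
#'
#' Describes one particle's motion regime. Five kinds are supported:
#' \describe{
#'   \item{stationary}{no motion (localization noise only);}
#'   \item{ballistic}{constant-velocity directed motion, the idealization of
#'     motor-driven processive transport;}
#'   \item{brownian}{free diffusion with independent Gaussian displacements
#'     per axis of variance `2 * diffusion_coeff * dt`;}
#'   \item{confined}{Brownian motion reflected at a circle of
#'     `confinement_radius` around the start point (subdiffusive at lags
#'     beyond the confinement time);}
#'   \item{switching}{a two-state per-frame Markov chain alternating an
#'     active state (ballistic with a persistent heading, redrawn at each
#'     activation) and a passive state (Brownian). This emulates vesicles
#'     alternating motor-driven runs with pauses/diffusion.}
#' }
#'
#' @param kind One of `"stationary"`, `"ballistic"`, `"brownian"`,
#'   `"confined"`, `"switching"`.
#' @param speed Active-state speed in µm/s (ballistic, switching).
#' @param heading Direction of ballistic motion in radians; `NA` draws a
#'   uniform heading at simulation time.
#' @param diffusion_coeff Diffusion coefficient D in µm²/s (brownian,
#'   confined, and the passive state of switching).
#' @param confinement_radius Radius of the reflecting circle in µm (confined).
#' @param p_active_to_passive,p_passive_to_active Per-frame switching
#'   probabilities of the two-state chain, in \[0, 1\].
#' @param localization_noise_sd Additive i.i.d. Gaussian localization error
#'   per coordinate per frame, in µm.
#'
#' @return An object of class `"motion_model"`.
#' @examples
#' motion_model("ballistic", speed = 1)
#' motion_model("switching", speed = 0.8, diffusion_coeff = 0.02,
#'              p_active_to_passive = 0.05, p_passive_to_active = 0.05)
#' @export
motion_model <- function(kind = c("stationary", "ballistic", "brownian",
                                  "confined", "switching"),
                         speed = 0, heading = NA_real_,
                         diffusion_coeff = 0, confinement_radius = NA_real_,
                         p_active_to_passive = 0, p_passive_to_active = 0,
                         localization_noise_sd = 0) {
  kind <- match.arg(kind)
  if (!is_number(speed) || speed < 0) abort_invalid("`speed` must be >= 0")
  if (!is_number(diffusion_coeff) || diffusion_coeff < 0) {
    abort_invalid("`diffusion_coeff` must be >= 0")
  }
  if (kind == "confined" &&
      (!is_number(confinement_radius) || confinement_radius <= 0)) {
    abort_invalid("`confinement_radius` must be > 0 for confined motion")
  }
  for (p in c(p_active_to_passive, p_passive_to_active)) {
    if (!is_number(p) || p < 0 || p > 1) {
      abort_invalid("switch probabilities must lie in [0, 1]")
    }
  }
  if (!is_number(localization_noise_sd) || localization_noise_sd < 0) {
    abort_invalid("`localization_noise_sd` must be >= 0")
  }
  structure(
    list(kind = kind, speed = speed, heading = heading,
         diffusion_coeff = diffusion_coeff,
         confinement_radius = confinement_radius,
         p_active_to_passive = p_active_to_passive,
         p_passive_to_active = p_passive_to_active,
         localization_noise_sd = localization_noise_sd),
    class = "motion_model"
  )
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("<motion_model: %s>\n", x$kind))
  invisible(x)
}

## Noise-free positions + per-frame state for one track; states are "active"
## for frames whose outgoing step is ballistic, "passive" otherwise (the last
## frame inherits the state of the step that reached it).
simulate_core <- function(model, n_frames, dt) {
  n <- n_frames
  x <- numeric(n); y <- numeric(n)
  state <- rep("passive", n)
  step_sd <- sqrt(2 * model$diffusion_coeff * dt)
  switch(model$kind,
    stationary = NULL,
    ballistic = {
      h <- if (is.na(model$heading)) stats::runif(1, 0, 2 * pi) else model$heading
      tt <- (seq_len(n) - 1L) * dt
      x <- model$speed * tt * cos(h)
      y <- model$speed * tt * sin(h)
      state <- rep("active", n)
    },
    brownian = {
      x <- c(0, cumsum(stats::rnorm(n - 1L, 0, step_sd)))
      y <- c(0, cumsum(stats::rnorm(n - 1L, 0, step_sd)))
    },
    confined = {
      R <- model$confinement_radius
      for (i in 2:n) {
        px <- x[i - 1L] + stats::rnorm(1, 0, step_sd)
        py <- y[i - 1L] + stats::rnorm(1, 0, step_sd)
        d <- sqrt(px^2 + py^2)
        while (d > R) {            # radial reflection at the boundary
          scl <- (2 * R - d) / d
          if (scl < -1) scl <- -1  # pathological step longer than 2R
          px <- px * scl; py <- py * scl
          d <- sqrt(px^2 + py^2)
        }
        x[i] <- px; y[i] <- py
      }
    },
    switching = {
      p_ap <- model$p_active_to_passive
      p_pa <- model$p_passive_to_active
      denom <- p_ap + p_pa
      p_start_active <- if (denom > 0) p_pa / denom else 0.5
      active <- stats::runif(1) < p_start_active
      h <- stats::runif(1, 0, 2 * pi)
      for (i in 2:n) {
        state[i - 1L] <- if (active) "active" else "passive"
        if (active) {
          x[i] <- x[i - 1L] + model$speed * dt * cos(h)
          y[i] <- y[i - 1L] + model$speed * dt * sin(h)
        } else {
          x[i] <- x[i - 1L] + stats::rnorm(1, 0, step_sd)
          y[i] <- y[i - 1L] + stats::rnorm(1, 0, step_sd)
        }
        flip <- stats::runif(1)
        if (active && flip < p_ap) {
          active <- FALSE
        } else if (!active && flip < p_pa) {
          active <- TRUE
          h <- stats::runif(1, 0, 2 * pi)  # new run, new direction
        }
      }
      state[n] <- state[n - 1L]
    }
  )
  list(x = x, y = y, state = state)
}

#' Simulate a single trajectory with ground truth
#'
#' Draws one noise-free path from `model`, adds i.i.d. Gaussian localization
#' noise per coordinate, and returns both the observed trajectory and the
#' generating truth. Identical `(model, n_frames, dt, seed)` reproduce the
#' output exactly; the caller's RNG state is left untouched.
#'
#' @param model A [motion_model()].
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame interval in seconds (> 0).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param track_id Identifier for the emitted trajectory.
#'
#' @return A list with elements
#'   \item{trajectory}{a [trajectory()];}
#'   \item{ground_truth}{a list: `kind`, `model`, per-frame `state`
#'     ("active"/"passive"), and the noise-free `x_true`, `y_true`.}
#' @examples
#' sim <- simulate_trajectory(motion_model("ballistic", speed = 1),
#'                            n_frames = 50, dt = 1, seed = 1)
#' tail(as.data.frame(sim$trajectory), 2)
#' @export
simulate_trajectory <- function(model, n_frames, dt, seed = NULL,
                                track_id = "track") {
  if (!inherits(model, "motion_model")) abort_invalid("`model` must be a motion_model")
  if (!is_count(n_frames, min = 2L)) abort_invalid("`n_frames` must be an integer >= 2")
  if (!is_number(dt) || dt <= 0) abort_invalid("`dt` must be a positive number")
  with_seed(seed, {
    core <- simulate_core(model, as.integer(n_frames), dt)
    sd0 <- model$localization_noise_sd
    xo <- core$x + if (sd0 > 0) stats::rnorm(n_frames, 0, sd0) else 0
    yo <- core$y + if (sd0 > 0) stats::rnorm(n_frames, 0, sd0) else 0
    list(
      trajectory = trajectory(xo, yo, dt = dt, track_id = track_id),
      ground_truth = list(kind = model$kind, model = model, state = core$state,
                          x_true = core$x, y_true = core$y)
    )
  })
}

#' Simulate a population of trajectories from a motion-model mixture
#'
#' Each track's model is drawn from the normalized mixture weights
#' (multinomial assignment); all stochastic draws flow from one seeded
#' generator, so identical arguments reproduce identical populations.
#'
#' @param mixture A list of components, each `list(model = motion_model(),
#'   weight = w)` with `w >= 0`; weights must sum to a positive value.
#' @param n_tracks Number of tracks (>= 0).
#' @param n_frames Frames per track (>= 2).
#' @param dt Frame interval in seconds.
#' @param seed Integer seed, or `NULL`.
#'
#' @return A list with `tracks` (list of [trajectory()], ids `"T0001"`, ...)
#'   and `ground_truth` (list, one entry per track as in
#'   [simulate_trajectory()] plus the component index drawn).
#' @examples
#' mix <- list(list(model = motion_model("ballistic", speed = 1), weight = 1),
#'             list(model = motion_model("brownian", diffusion_coeff = 0.1),
#'                  weight = 1))
#' pop <- simulate_population(mix, n_tracks = 4, n_frames = 30, dt = 1, seed = 7)
#' vapply(pop$ground_truth, `[[`, "", "kind")
#' @export
simulate_population <- function(mixture, n_tracks, n_frames, dt, seed = NULL) {
  if (!is.list(mixture) || length(mixture) == 0L) {
    abort_invalid("`mixture` must be a non-empty list of (model, weight) components")
  }
  w <- vapply(mixture, function(m) {
    if (!is.list(m) || !inherits(m$model, "motion_model") || !is_number(m$weight)) {
      abort_invalid("each mixture component must be list(model = motion_model(), weight = number)")
    }
    m$weight
  }, numeric(1))
  if (any(w < 0) || sum(w) <= 0) {
    abort_invalid("mixture weights must be nonnegative with a positive sum")
  }
  if (!is_count(n_tracks)) abort_invalid("`n_tracks` must be a nonnegative integer")
  if (n_tracks == 0L) return(list(tracks = list(), ground_truth = list()))
  with_seed(seed, {
    comp <- sample.int(length(mixture), n_tracks, replace = TRUE, prob = w / sum(w))
    tracks <- vector("list", n_tracks)
    truth <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      sim <- simulate_trajectory(mixture[[comp[i]]]$model, n_frames, dt,
                                 seed = NULL, track_id = sprintf("T%04d", i))
      tracks[[i]] <- sim$trajectory
      truth[[i]] <- c(sim$ground_truth, list(component = comp[i]))
    }
    list(tracks = tracks, ground_truth = truth)
  })
}
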