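#' Advance the melt by velocity-Verlet Langevin dynamics
#'
#' Integrates `n_steps` steps of underdamped Langevin dynamics with the
#' LAMMPS-style impulsive friction/noise thermostat: every monomer feels
#' the conservative forces (WCA + FENE + bending), a friction
#' \eqn{-\gamma m v} and Gaussian white noise whose variance satisfies the
#' fluctuation--dissipation relation at its own label's temperature
#' (`T_h` for hot monomers, `T_c` for cold ones).  Noise streams are
#' counter-based, keyed by (seed, global step, monomer, component), so a
#' run is reproducible and can be continued seamlessly via `step_offset`.
#'
#' If any bond reaches `r_max` the integration aborts with an error of
#' class `"ringmelt_overstretch"` carrying the last valid state in its
#' `state` field.
#'
#' @param state a [melt_state()].
#' @param n_steps number of time steps.
#' @param seed integer noise seed.
#' @param stride if positive, record a frame every `stride` steps and
#'   attach frames as attribute `"frames"` (list with unwrapped positions,
#'   velocities and times).
#' @param clamp_r clamp the WCA force magnitude below this separation
#'   (sigma; builder push-off only, never in production; `0` disables).
#' @param max_disp per-step displacement limit in sigma (push-off only;
#'   `0` disables).
#' @param step_offset global step counter offset for the noise stream.
#' @return The advanced [melt_state()].
#' @export
md_advance <- function(state, n_steps, seed = 1, stride = 0,
                       clamp_r = 0, max_disp = 0, step_offset = 0) {
  p <- state$params
  res <- .cpp_md_run(state$pos, state$img, state$vel, state$box,
                     state$bonds - 1L, state$angles - 1L,
                     as.integer(state$hot), p[c("epsilon", "sigma", "mass",
                                                "r_max", "K", "k_theta",
                                                "gamma", "dt", "T_h", "T_c")],
                     as.integer(n_steps), as.integer(stride),
                     as.numeric(seed), as.numeric(step_offset),
                     clamp_r, max_disp, 0.3 * p$sigma)
  st <- state
  st$pos <- res$pos
  st$img <- res$img
  st$vel <- res$vel
  st$time <- state$time + res$steps_done * p$dt
  if (res$overstretched_bond > 0) {
    cond <- structure(class = c("ringmelt_overstretch", "error", "condition"),
                      list(message = sprintf(
                        "bond %d reached r_max after %d steps; aborting (chain crossing risk)",
                        res$overstretched_bond, res$steps_done),
                        call = sys.call(), state = st))
    stop(cond)
  }
  if (stride > 0 && res$n_frames > 0) {
    n <- nrow(state$pos)
    attr(st, "frames") <- list(
      pos = aperm(array(res$frames_pos, c(3, n, res$n_frames)), c(3, 2, 1)),
      vel = aperm(array(res$frames_vel, c(3, n, res$n_frames)), c(3, 2, 1)),
      times = state$time + seq_len(res$n_frames) * stride * p$dt)
  }
  st
}

#' Kinetic temperatures of the hot and cold channels
#'
#' Computes \eqn{\langle m v^2 \rangle / 3} separately over hot- and
#' cold-labelled monomers, from a single state or averaged over the frames
#' of a trajectory window.  A channel with no monomers is reported as `NA`.
#'
#' @param x a [melt_state()] or [melt_trajectory()].
#' @param frames optional frame indices (trajectory input only).
#' @return Named numeric vector `c(T_hot = ..., T_cold = ...)`.
#' @export
kinetic_temperatures <- function(x, frames = NULL) {
  if (inherits(x, "melt_state")) {
    v2 <- rowSums(x$vel^2)
    m <- x$params$mass
    hotv <- v2[x$hot]; coldv <- v2[!x$hot]
  } else if (inherits(x, "melt_trajectory")) {
    if (is.null(x$vel)) stop("trajectory carries no velocities")
    if (is.null(frames)) frames <- seq_len(dim(x$vel)[1])
    m <- x$params$mass
    v2 <- apply(x$vel[frames, , , drop = FALSE]^2, 2, sum) /
      length(frames) # per-monomer mean of |v|^2 over frames
    hotv <- v2[x$hot]; coldv <- v2[!x$hot]
  } else stop("x must be a melt_state or melt_trajectory")
  c(T_hot = if (length(hotv)) m * mean(hotv) / 3 else NA_real_,
    T_cold = if (length(coldv)) m * mean(coldv) / 3 else NA_real_)
}

#' Run a multi-phase simulation protocol
#'
#' Executes a schedule of phases on a melt state and collects the recorded
#' frames into a [melt_trajectory()].  Supported phases:
#' \describe{
#'   \item{`"equilibrate"`}{all monomers relabelled cold for the duration
#'     (original labels restored afterwards).}
#'   \item{`"active"`}{dynamics with the state's current hot/cold labels.
#'     The first `active` phase tags its start as the activity onset
#'     `t0 = 0`.}
#'   \item{`"cut"`}{applies [cut_bonds()] (zero duration unless given),
#'     resets the time origin to the cutting moment, then continues.}
#' }
#'
#' @param state a [melt_state()].
#' @param schedule a list of phases, each a list with elements
#'   `phase` (character), `duration` (tau) and `stride` (tau between
#'   recorded frames; 0 records none).
#' @param seed integer seed; each phase derives its own noise stream.
#' @return A [melt_trajectory()]; its `state` field holds the final state.
#' @export
run_protocol <- function(state, schedule, seed = 1) {
  p <- state$params
  frames_pos <- list(); frames_vel <- list(); times <- numeric(0)
  onset_tagged <- FALSE
  st <- state
  for (ph in seq_along(schedule)) {
    ent <- schedule[[ph]]
    dur <- ent$duration %||% 0
    if (dur < 0) stop("schedule durations must be non-negative")
    stride_t <- ent$stride %||% 0
    nst <- round(dur / p$dt)
    stride <- if (stride_t > 0) max(1L, round(stride_t / p$dt)) else 0L
    if (identical(ent$phase, "cut")) {
      st <- cut_bonds(st)
      st$time <- 0
      times <- numeric(0); frames_pos <- list(); frames_vel <- list()
    } else if (identical(ent$phase, "equilibrate")) {
      saved_hot <- st$hot
      st$hot <- rep(FALSE, length(st$hot))
      if (nst > 0)
        st <- md_advance(st, nst, seed = derive_seed(seed, 100 + ph),
                         stride = stride)
      st$hot <- saved_hot
    } else if (identical(ent$phase, "active")) {
      if (!onset_tagged) {
        st$time <- 0 # activity onset defines t0 = 0
        onset_tagged <- TRUE
      }
    }
    if (!identical(ent$phase, "equilibrate") && nst > 0) {
      if (stride > 0) {
        # record the phase-start frame (the activity onset / cut moment)
        frames_pos[[length(frames_pos) + 1]] <-
          array(unwrap_abs(st), c(1, nrow(st$pos), 3))
        frames_vel[[length(frames_vel) + 1]] <-
          array(st$vel, c(1, nrow(st$pos), 3))
        times <- c(times, st$time)
      }
      st <- md_advance(st, nst, seed = derive_seed(seed, 100 + ph),
                       stride = stride)
    }
    fr <- attr(st, "frames")
    if (!is.null(fr)) {
      frames_pos[[length(frames_pos) + 1]] <- fr$pos
      frames_vel[[length(frames_vel) + 1]] <- fr$vel
      times <- c(times, fr$times)
      attr(st, "frames") <- NULL
    }
  }
  pos <- if (length(frames_pos)) do.call(abind3, frames_pos) else
    array(unwrap_abs(st), c(1, nrow(st$pos), 3))
  vel <- if (length(frames_vel)) do.call(abind3, frames_vel) else
    array(st$vel, c(1, nrow(st$pos), 3))
  if (!length(times)) times <- st$time
  melt_trajectory(pos = pos, vel = vel, times = times, box = st$box,
                  hot = st$hot, ring = st$ring, cyclic = st$cyclic,
                  params = p, state = st, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bind arrays along the first (frame) dimension
abind3 <- function(...) {
  parts <- list(...)
  n <- dim(parts[[1]])[2]
  total <- sum(vapply(parts, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(total, n, 3))
  at <- 0
  for (a in parts) {
    f <- dim(a)[1]
    out[at + seq_len(f), , ] <- a
    at <- at + f
  }
  out
}

#' Trajectory container
#'
#' Time-ordered frames of unwrapped coordinates (and velocities) produced
#' by [run_protocol()] or assembled from file readers / synthetic
#' generators.  Frame times are in tau relative to the activity onset (or
#' cutting moment).
#'
#' @param pos frames x monomers x 3 array of unwrapped positions.
#' @param vel matching velocity array or `NULL`.
#' @param times frame times (tau), strictly increasing.
#' @param box periodic box edge lengths.
#' @param hot,ring,cyclic per-monomer labels / ring ids / per-ring topology.
#' @param params the [ring_params()] used.
#' @param state final [melt_state()] or `NULL`.
#' @param seed seed used to generate the trajectory (metadata).
#' @return An object of class `"melt_trajectory"`.
#' @export
melt_trajectory <- function(pos, vel = NULL, times, box, hot, ring, cyclic,
                            params = NULL, state = NULL, seed = NULL) {
  stopifnot(length(dim(pos)) == 3, dim(pos)[1] == length(times))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(pos = pos, vel = vel, times = times, box = box,
                 hot = hot, ring = as.integer(ring), cyclic = cyclic,
                 params = params, state = state, seed = seed),
            class = "melt_trajectory")
}

#' @export
print.melt_trajectory <- function(x, ...) {
  cat(sprintf("Melt trajectory: %d frames x %d monomers, t in [%g, %g] tau\n",
              dim(x$pos)[1], dim(x$pos)[2], min(x$times), max(x$times)))
  invisible(x)
}

# per-ring unwrapped contour from one trajectory frame (contour = storage
# order for rings built by build_melt; cut chains carry chain_order in the
# final state, but frame coordinates are already unwrapped absolutely).
traj_frame_state <- function(traj, f) {
  n <- dim(traj$pos)[2]
  pos <- traj$pos[f, , ]
  box <- traj$box
  wrapped <- pos %% rep(box, each = n)
  img <- matrix(as.integer(round((pos - wrapped) / rep(box, each = n))), n, 3)
  melt_state(wrapped, img, matrix(0, n, 3), box, traj$hot, traj$ring,
             traj$cyclic, bonds = matrix(0L, 0, 2),
             angles = matrix(0L, 0, 3), time = traj$times[f],
             params = traj$params,
             chain_order = traj$state$chain_order)
}
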