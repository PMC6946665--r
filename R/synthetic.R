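#' Synthetic centre-of-mass trajectories
#'
#' Generators of idealized ring-COM dynamics with known statistics, used to
#' validate the dynamic observables against closed forms: Brownian motion
#' (Einstein slope \eqn{6D}, EB \eqn{\to (4/3)\Delta/t}, Gaussian
#' displacements), fractional Gaussian motion with a prescribed MSD
#' exponent, and displacement-kick trajectories with arbitrary 1d
#' displacement laws.  Each "ring" is a single point particle; the
#' resulting [melt_trajectory()] works with every COM-based observable.
#'
#' @param M number of rings (point particles).
#' @param n_frames number of recorded frames.
#' @param dt_frame frame spacing (tau).
#' @param D diffusion coefficient (sigma^2/tau).
#' @param box periodic box lengths (analysis metadata only; paths are not
#'   wrapped).
#' @param seed integer seed.
#' @return A [melt_trajectory()].
#' @export
brownian_trajectory <- function(M, n_frames, dt_frame = 1, D = 1,
                                box = c(100, 100, 100), seed = 1) {
  set.seed(derive_seed(seed, 31))
  pos <- array(0, c(n_frames, M, 3))
  start <- matrix(stats::runif(3 * M, 0, box[1]), M, 3)
  for (a in 1:3) {
    inc <- matrix(stats::rnorm((n_frames - 1) * M, 0,
                               sqrt(2 * D * dt_frame)), n_frames - 1, M)
    pos[, , a] <- matrix(start[, a], n_frames, M, byrow = TRUE) +
      rbind(0, apply(inc, 2, cumsum))
  }
  synthetic_com_trajectory(pos, dt_frame, box)
}

#' @param alpha MSD exponent: \eqn{\langle x^2(t)\rangle \propto t^\alpha},
#'   `0 < alpha < 2` (fractional Gaussian motion, Hurst `alpha/2`).
#' @param scale displacement scale per frame spacing.
#' @rdname brownian_trajectory
#' @export
fgn_trajectory <- function(M, n_frames, dt_frame = 1, alpha = 0.5,
                           scale = 1, seed = 1) {
  set.seed(derive_seed(seed, 37))
  t <- seq_len(n_frames - 1)
  # fBm covariance of positions after the first frame
  cov <- 0.5 * (outer(t^alpha, rep(1, n_frames - 1)) +
                  outer(rep(1, n_frames - 1), t^alpha) -
                  abs(outer(t, t, `-`))^alpha) * scale^2
  Lc <- t(chol(cov + diag(1e-10, n_frames - 1)))
  pos <- array(0, c(n_frames, M, 3))
  for (a in 1:3) {
    z <- matrix(stats::rnorm((n_frames - 1) * M), n_frames - 1, M)
    pos[2:n_frames, , a] <- Lc %*% z
  }
  synthetic_com_trajectory(pos, dt_frame, c(1, 1, 1) * 100)
}

#' @param sampler function(n) drawing n i.i.d. 1d displacements; applied
#'   independently per axis and frame step.
#' @rdname brownian_trajectory
#' @export
kick_trajectory <- function(M, n_frames, sampler, dt_frame = 1, seed = 1,
                            box = c(100, 100, 100)) {
  set.seed(derive_seed(seed, 41))
  pos <- array(0, c(n_frames, M, 3))
  for (a in 1:3)
    pos[, , a] <- apply(rbind(0, matrix(sampler((n_frames - 1) * M),
                                        n_frames - 1, M)), 2, cumsum)
  synthetic_com_trajectory(pos, dt_frame, box)
}

#' Wrap an array of COM paths as a trajectory of point rings
#'
#' @param pos frames x M x 3 array of positions.
#' @param dt_frame frame spacing (tau).
#' @param box box lengths.
#' @return A [melt_trajectory()] of M single-monomer rings.
#' @export
synthetic_com_trajectory <- function(pos, dt_frame = 1,
                                     box = c(100, 100, 100)) {
  M <- dim(pos)[2]
  melt_trajectory(pos = pos, vel = NULL,
                  times = (seq_len(dim(pos)[1]) - 1) * dt_frame,
                  box = box, hot = rep(FALSE, M), ring = seq_len(M),
                  cyclic = rep(TRUE, M),
                  params = ring_params(N = 1, M = M, N_h = 0))
}

#' Synthetic two-state Markov threading series
#'
#' Each of `n_pairs` directed pairs is independently threaded/unthreaded
#' as a two-state Markov chain with per-frame switch-on probability
#' `p_on` and switch-off probability `p_off`, started from the stationary
#' distribution.  Closed forms: the threading correlation is
#' \eqn{\Phi(t) = \pi_\infty + (1-\pi_\infty)\lambda^t} with
#' \eqn{\lambda = 1 - p_{on} - p_{off}},
#' \eqn{\pi_\infty = p_{on}/(p_{on}+p_{off})}, and the survival
#' distribution is geometric, \eqn{\pi(t) = p_{off}(1-p_{off})^{t-1}}.
#'
#' @param n_pairs number of directed ring pairs.
#' @param n_frames number of frames.
#' @param p_on,p_off per-frame transition probabilities.
#' @param seed integer seed.
#' @return list of character pair-key sets, one per frame.
#' @export
markov_threading_series <- function(n_pairs, n_frames, p_on, p_off,
                                    seed = 1) {
  set.seed(derive_seed(seed, 43))
  keys <- paste0(seq_len(n_pairs), ">", seq_len(n_pairs) + n_pairs)
  state <- stats::runif(n_pairs) < p_on / (p_on + p_off)
  series <- vector("list", n_frames)
  series[[1]] <- keys[state]
  for (f in 2:n_frames) {
    u <- stats::runif(n_pairs)
    state <- ifelse(state, u >= p_off, u < p_on)
    series[[f]] <- keys[state]
  }
  series
}
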