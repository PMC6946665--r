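#' Interaction potentials of the bead-spring model
#'
#' The three potentials governing the melt: the purely repulsive, cut and
#' shifted Lennard-Jones (WCA) pair potential
#' \deqn{U_{WCA}(r) = \left(4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] +
#'   \epsilon\right)\theta(2^{1/6}\sigma - r),}
#' the finitely extensible nonlinear elastic bond
#' \deqn{U_{FENE}(r) = -\tfrac12 r_{max}^2 K \log[1 - (r/r_{max})^2],}
#' and the cosine bending term
#' \deqn{U_{angle}(\theta) = k_\theta (1 - \cos(\theta - \pi)),}
#' which vanishes for a straight chain (\eqn{\theta = \pi}).
#' `*_force()` returns \eqn{-dU/dr} (for the angle term, \eqn{-dU/d\theta}).
#'
#' @param r distance (sigma); vectorised.
#' @param theta bond angle in radians, in \eqn{[0, \pi]}; vectorised.
#' @param params a [ring_params()] object (any `N`, `M` work; only the
#'   force-field constants are used).
#' @return Energy (epsilon) or force, same length as the input.
#' @examples
#' p <- ring_params(N = 8, M = 1)
#' wca_energy(2^(1/6), p)      # 0 at the cutoff
#' fene_energy(1.0, p)         # ~19.84 for K = 30, r_max = 1.5
#' angle_energy(pi, p)         # 0 for a straight chain
#' @name potentials
NULL

#' @rdname potentials
#' @export
wca_energy <- function(r, params = ring_params(1, 1)) {
  if (any(r <= 0)) stop("invalid geometry: r must be positive")
  s <- params$sigma; e <- params$epsilon
  rc <- 2^(1 / 6) * s
  u <- ifelse(r < rc, 4 * e * ((s / r)^12 - (s / r)^6) + e, 0)
  pmax(u, 0) # clip tiny negative round-off at the cutoff
}

#' @rdname potentials
#' @export
wca_force <- function(r, params = ring_params(1, 1)) {
  if (any(r <= 0)) stop("invalid geometry: r must be positive")
  s <- params$sigma; e <- params$epsilon
  rc <- 2^(1 / 6) * s
  ifelse(r < rc, 24 * e * (2 * (s / r)^12 - (s / r)^6) / r, 0)
}

#' @rdname potentials
#' @export
fene_energy <- function(r, params = ring_params(1, 1)) {
  rm <- params$r_max
  if (any(r < 0)) stop("invalid geometry: r must be non-negative")
  if (any(r >= rm))
    stop("overstretched bond: r >= r_max (chain crossing risk)")
  -0.5 * rm^2 * params$K * log(1 - (r / rm)^2)
}

#' @rdname potentials
#' @export
fene_force <- function(r, params = ring_params(1, 1)) {
  rm <- params$r_max
  if (any(r < 0)) stop("invalid geometry: r must be non-negative")
  if (any(r >= rm))
    stop("overstretched bond: r >= r_max (chain crossing risk)")
  -params$K * r / (1 - (r / rm)^2)
}

#' @rdname potentials
#' @export
angle_energy <- function(theta, params = ring_params(1, 1)) {
  params$k_theta * (1 - cos(theta - pi))
}

#' @rdname potentials
#' @export
angle_force <- function(theta, params = ring_params(1, 1)) {
  -params$k_theta * sin(theta - pi)
}
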