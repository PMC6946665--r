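#' Model parameters for the active ring-polymer melt
#'
#' Collects every force-field, thermostat and composition constant of the
#' bead-spring (Kremer--Grest type) ring melt in reduced Lennard-Jones units:
#' \eqn{\epsilon = \sigma = m = k_B = 1}, with the time unit
#' \eqn{\tau = \sigma\sqrt{m/\epsilon}}.
#'
#' The melt consists of `M` rings of `N` monomers at monomer number density
#' `rho`.  On each of the `M_a` partly active rings one consecutive arc of
#' `N_h` monomers is coupled to a Langevin thermostat at temperature `T_h`
#' ("hot"), while all remaining monomers are thermostatted at `T_c` ("cold").
#' Both thermostats use the same friction `gamma`.
#'
#' @param N monomers per ring.
#' @param M number of rings.
#' @param N_h hot-segment length (monomers); default `N/8` (rounded).
#' @param M_a number of partly active rings, `0 <= M_a <= M`; default `M`.
#' @param rho monomer number density (sigma^-3).
#' @param T_h,T_c hot and cold thermostat temperatures (epsilon/k_B).
#' @param gamma thermostat friction (1/tau).
#' @param dt integration time step (tau).
#' @param K FENE spring constant (epsilon/sigma^2).
#' @param r_max FENE maximum bond extension (sigma).
#' @param k_theta bending stiffness (epsilon).
#' @param epsilon,sigma,mass energy, length and mass units (leave at 1).
#' @return An object of class `"ring_params"` (a named list).
#' @examples
#' p <- ring_params(N = 80, M = 10, N_h = 10)
#' p$T_h
#' @export
ring_params <- function(N, M, N_h = round(N / 8), M_a = M, rho = 0.85,
                        T_h = 3, T_c = 1, gamma = 2 / 3, dt = 0.005,
                        K = 30, r_max = 1.5, k_theta = 1.5,
                        epsilon = 1, sigma = 1, mass = 1) {
  p <- list(N = as.integer(N), M = as.integer(M), N_h = as.integer(N_h),
            M_a = as.integer(M_a), rho = rho, T_h = T_h, T_c = T_c,
            gamma = gamma, dt = dt, K = K, r_max = r_max, k_theta = k_theta,
            epsilon = epsilon, sigma = sigma, mass = mass)
  class(p) <- "ring_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(is.list(p))
  with(p, {
    if (r_max <= 2^(1 / 6) * sigma)
      stop("r_max must exceed the WCA cutoff 2^(1/6) sigma")
    if (N < 1 || M < 1) stop("N and M must be positive")
    if (N_h < 0 || N_h > N) stop("N_h must lie in [0, N]")
    if (M_a < 0 || M_a > M) stop("M_a must lie in [0, M]")
    if (rho <= 0) stop("density rho must be positive")
    if (dt <= 0) stop("time step dt must be positive")
    if (T_c <= 0 || T_h < T_c) stop("temperatures must satisfy T_h >= T_c > 0")
    if (gamma <= 0) stop("friction gamma must be positive")
  })
  invisible(p)
}

#' @export
print.ring_params <- function(x, ...) {
  cat("Ring melt model parameters (reduced LJ units)\n")
  cat(sprintf("  %d rings x %d monomers, rho = %g; hot arc N_h = %d on M_a = %d rings\n",
              x$M, x$N, x$rho, x$N_h, x$M_a))
  cat(sprintf("  T_h = %g, T_c = %g, gamma = %g/tau, dt = %g tau\n",
              x$T_h, x$T_c, x$gamma, x$dt))
  cat(sprintf("  FENE: K = %g, r_max = %g; bending k_theta = %g\n",
              x$K, x$r_max, x$k_theta))
  invisible(x)
}

#' Read / write model parameters as YAML
#'
#' Keys in the file are identical to the argument names of [ring_params()].
#'
#' @param path file path.
#' @return `read_params()` returns a `"ring_params"` object.
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(ring_params, vals)
}

#' @param params a `"ring_params"` object.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

# Cubic periodic box holding M*N monomers at density rho.
melt_box <- function(params) {
  L <- (params$M * params$N / params$rho)^(1 / 3)
  c(L, L, L)
}
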