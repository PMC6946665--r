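#' Melt state container
#'
#' A `"melt_state"` holds one snapshot of the system: wrapped positions with
#' integer periodic image flags, velocities, the periodic box, per-monomer
#' temperature labels (hot/cold), the bonded topology (cyclic rings, or
#' linear chains after [cut_bonds()]) and the simulation time.
#'
#' @param pos n x 3 matrix of wrapped positions (sigma).
#' @param img n x 3 integer matrix of periodic image flags.
#' @param vel n x 3 matrix of velocities (sigma/tau).
#' @param box length-3 box edge lengths (sigma).
#' @param hot logical vector, length n: TRUE for hot monomers.
#' @param ring integer vector, length n: ring id (1..M) of each monomer.
#' @param cyclic logical vector, length M: is each molecule still a ring?
#' @param bonds B x 2 integer matrix of bonded monomer pairs (1-based).
#' @param angles A x 3 integer matrix of bending triplets (1-based).
#' @param time simulation time (tau).
#' @param params the [ring_params()] the state was built with.
#' @return An object of class `"melt_state"`.
#' @export
melt_state <- function(pos, img, vel, box, hot, ring, cyclic, bonds, angles,
                       time = 0, params = NULL, chain_order = NULL) {
  n <- nrow(pos)
  stopifnot(nrow(vel) == n, nrow(img) == n, length(hot) == n,
            length(ring) == n, length(box) == 3)
  if (is.null(chain_order))
    chain_order <- lapply(seq_along(cyclic),
                          function(k) seq_len(sum(ring == k)))
  structure(list(pos = pos, img = img, vel = vel, box = box,
                 hot = as.logical(hot), ring = as.integer(ring),
                 cyclic = as.logical(cyclic),
                 bonds = matrix(as.integer(bonds), ncol = 2),
                 angles = matrix(as.integer(angles), ncol = 3),
                 time = time, params = params, chain_order = chain_order),
            class = "melt_state")
}

#' @export
print.melt_state <- function(x, ...) {
  M <- length(x$cyclic)
  cat(sprintf("Melt state: %d monomers in %d %s at t = %g tau\n",
              nrow(x$pos), M,
              if (all(x$cyclic)) "rings" else "chains", x$time))
  cat(sprintf("  box %.3f x %.3f x %.3f sigma, %d hot / %d cold monomers\n",
              x$box[1], x$box[2], x$box[3], sum(x$hot), sum(!x$hot)))
  invisible(x)
}

# cyclic bonds/angles for M rings of N monomers (1-based, contour order)
ring_topology <- function(M, N) {
  bonds <- NULL
  angles <- NULL
  for (m in seq_len(M)) {
    off <- (m - 1) * N
    i <- seq_len(N)
    bonds <- rbind(bonds, cbind(off + i, off + ifelse(i == N, 1L, i + 1L)))
    if (N >= 3) {
      prev <- ifelse(i == 1L, N, i - 1L)
      nxt <- ifelse(i == N, 1L, i + 1L)
      angles <- rbind(angles, cbind(off + prev, off + i, off + nxt))
    }
  }
  list(bonds = bonds, angles = if (is.null(angles)) matrix(0L, 0, 3) else angles)
}

#' Unwrapped contour of one molecule
#'
#' Reconstructs the continuous-space polyline of ring (or chain) `k` by
#' accumulating minimum-image bond vectors from its first monomer.  For a
#' cyclic molecule the closure defect (distance between the accumulated end
#' point and the start) must be below `tol`, otherwise the frame is rejected
#' as badly unwrapped.
#'
#' @param state a [melt_state()].
#' @param k ring index (1..M).
#' @param tol closure tolerance (sigma).
#' @return N x 3 matrix of unwrapped coordinates in contour order.
#' @export
ring_contour <- function(state, k, tol = 1e-6) {
  idx <- which(state$ring == k)
  if (!is.null(state$chain_order)) idx <- idx[state$chain_order[[k]]]
  p <- state$pos[idx, , drop = FALSE]
  L <- state$box
  n <- nrow(p)
  d <- p[c(2:n, 1), , drop = FALSE] - p
  for (a in 1:3) {
    d[, a] <- d[, a] - L[a] * round(d[, a] / L[a])
  }
  out <- matrix(0, n, 3)
  out[1, ] <- p[1, ]
  if (n > 1)
    out[2:n, ] <- rep(p[1, ], each = n - 1) +
      apply(d[1:(n - 1), , drop = FALSE], 2, cumsum)
  if (state$cyclic[k]) {
    defect <- sqrt(sum(colSums(d)^2))
    if (defect > tol)
      stop(sprintf("ring %d closure defect %.3g sigma exceeds %g", k, defect, tol))
  }
  out
}

# unwrapped absolute coordinates of all monomers (pos + box * image)
unwrap_abs <- function(state) {
  state$pos + sweep(state$img, 2, state$box, `*`)
}

# deterministic child seeds derived from one integer seed (kept < 2^31)
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 11 * stream) %% 2147483647
}
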