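#' Ring centre-of-mass positions for every frame
#'
#' Unwrapped ring COMs, optionally measured relative to the centre of mass
#' of the whole system at each frame.  The system-COM frame is the
#' convention for every displacement observable here, since Langevin
#' dynamics does not conserve momentum.
#'
#' @param traj a [melt_trajectory()].
#' @param com_frame subtract the per-frame system centre of mass.
#' @return frames x M x 3 array.
#' @export
ring_coms <- function(traj, com_frame = TRUE) {
  dm <- dim(traj$pos)
  F <- dm[1]; n <- dm[2]
  M <- max(traj$ring)
  out <- array(0, c(F, M, 3))
  sizes <- tabulate(traj$ring, M)
  for (a in 1:3) {
    pa <- matrix(traj$pos[, , a], nrow = F)
    coms <- sweep(t(rowsum(t(pa), traj$ring)), 2, sizes, `/`) # F x M
    if (com_frame) coms <- coms - rowMeans(pa)
    out[, , a] <- coms
  }
  out
}

#' Radius of gyration
#'
#' Root-mean-square radius of gyration
#' \eqn{R_g = \langle R_g^2 \rangle^{1/2}} over a selection of chains or
#' contour segments.  With `segment = s`, every contiguous `s`-monomer
#' segment (all start positions; cyclic for rings) of every selected ring
#' enters the average; with `hot_only`/`cold_only`, only the hot (cold)
#' blocks are measured.
#'
#' @param state a [melt_state()].
#' @param segment segment length in monomers, or `NULL` for whole chains.
#' @param rings ring indices to include (default all).
#' @param hot_only,cold_only restrict to the hot (cold) block of each ring.
#' @return numeric scalar (sigma).
#' @export
radius_of_gyration <- function(state, segment = NULL, rings = NULL,
                               hot_only = FALSE, cold_only = FALSE) {
  M <- length(state$cyclic)
  if (is.null(rings)) rings <- seq_len(M)
  rg2 <- c()
  for (k in rings) {
    contour <- ring_contour(state, k)
    sel <- rep(TRUE, nrow(contour))
    hot_k <- state$hot[which(state$ring == k)][state$chain_order[[k]]]
    if (hot_only) sel <- hot_k
    if (cold_only) sel <- !hot_k
    if (!any(sel)) next
    pts <- contour[sel, , drop = FALSE]
    if (is.null(segment)) {
      rg2 <- c(rg2, mean(rowSums(sweep(pts, 2, colMeans(pts))^2)))
    } else {
      rg2 <- c(rg2, segment_rg2(pts, segment,
                                cyclic = state$cyclic[k] && all(sel)))
    }
  }
  if (!length(rg2)) stop("empty selection")
  sqrt(mean(rg2))
}

# mean squared radius of gyration over all s-monomer windows of a contour
segment_rg2 <- function(pts, s, cyclic = TRUE) {
  n <- nrow(pts)
  if (s > n) stop("segment longer than selection")
  ext <- if (cyclic) rbind(pts, pts[seq_len(s - 1), , drop = FALSE]) else pts
  nwin <- nrow(ext) - s + 1
  cs <- apply(rbind(0, ext), 2, cumsum)
  cs2 <- cumsum(c(0, rowSums(ext^2)))
  i <- seq_len(nwin)
  sum_r <- cs[i + s, ] - cs[i, ]
  sum_r2 <- cs2[i + s] - cs2[i]
  mean(sum_r2 / s - rowSums(sum_r^2) / s^2)
}

# locate the frame index whose time matches t0
frame_at <- function(traj, t0) {
  f <- which.min(abs(traj$times - t0))
  spacing <- if (length(traj$times) > 1) min(diff(traj$times)) else Inf
  if (abs(traj$times[f] - t0) > spacing / 2 + 1e-9)
    stop(sprintf("t0 = %g is not a frame time", t0))
  f
}

#' Mean squared displacement of ring centres of mass, g3
#'
#' \eqn{g_3(t, t_0) = \langle [R(t_0+t) - R(t_0)]^2 \rangle}, with ring COM
#' positions measured relative to the system centre of mass at each time,
#' averaged over rings only (no multiple time origins: the dynamics is not
#' stationary in general).
#'
#' @param traj a [melt_trajectory()].
#' @param t0 measurement start time (tau); must be a frame time.
#' @return data.frame with columns `t` and `g3`; per-ring squared
#'   displacements attached as attribute `"per_ring"` (frames x M).
#' @export
g3 <- function(traj, t0 = traj$times[1]) {
  coms <- ring_coms(traj)
  f0 <- frame_at(traj, t0)
  F <- dim(coms)[1]
  disp2 <- matrix(0, F - f0 + 1, dim(coms)[2])
  for (a in 1:3)
    disp2 <- disp2 + (coms[f0:F, , a, drop = TRUE] -
                        rep(coms[f0, , a], each = F - f0 + 1))^2
  out <- data.frame(t = traj$times[f0:F] - traj$times[f0],
                    g3 = rowMeans(disp2))
  attr(out, "per_ring") <- disp2
  out
}

# lattice-compatible wavevectors with |q| in a relative shell around target
lattice_qvecs <- function(box, q, shell = 0.02, min_ok = 0.05) {
  dq <- 2 * pi / box[1]
  nmax <- ceiling(q * (1 + min_ok) / dq) + 1
  g <- as.matrix(expand.grid(-nmax:nmax, -nmax:nmax, 0:nmax))
  g <- g[!(g[, 3] == 0 & (g[, 1] < 0 | (g[, 1] == 0 & g[, 2] < 0))), ]
  g <- g[rowSums(g^2) > 0, , drop = FALSE]
  qv <- g * dq
  mag <- sqrt(rowSums(qv^2))
  sel <- abs(mag - q) <= shell * q
  if (!any(sel)) {
    best <- mag[which.min(abs(mag - q))]
    if (abs(best - q) / q > min_ok)
      stop(sprintf("no box-compatible wavevector within %.0f%% of q = %g (nearest |q| = %.4f)",
                   100 * min_ok, q, best))
    sel <- abs(mag - best) <= 1e-9
  }
  qv[sel, , drop = FALSE]
}

#' Self-intermediate scattering function of ring centres of mass
#'
#' \eqn{F_s(q, t, t_0) = \frac1M \sum_m \exp(i q \cdot (R_m(t_0+t) - R_m(t_0)))},
#' averaged over rings and over all box-compatible wavevectors within a
#' narrow shell (default 2% relative width) of the requested magnitude;
#' the real part is reported.  Displacements are in the system-COM frame.
#'
#' @inheritParams g3
#' @param q requested wavevector magnitude (1/sigma).
#' @param shell relative shell width for wavevector averaging.
#' @return data.frame with columns `t` and `Fs`; `Fs[1] == 1`.
#' @export
self_isf <- function(traj, q, t0 = traj$times[1], shell = 0.02) {
  coms <- ring_coms(traj)
  f0 <- frame_at(traj, t0)
  qv <- lattice_qvecs(traj$box, q, shell)
  F <- dim(coms)[1]; M <- dim(coms)[2]
  fs <- vapply(f0:F, function(f) {
    d <- coms[f, , ] - coms[f0, , ]
    if (is.null(dim(d))) d <- matrix(d, nrow = M)
    ph <- d %*% t(qv)
    mean(cos(ph))
  }, numeric(1))
  data.frame(t = traj$times[f0:F] - traj$times[f0], Fs = fs)
}

#' Non-ergodicity parameter
#'
#' \eqn{f(q, t_0) = F_s(q, t_{max}, t_0)}: the self-ISF evaluated at the
#' final available lag, on a grid of wavevector magnitudes.
#'
#' @inheritParams self_isf
#' @param q_grid wavevector magnitudes (1/sigma).
#' @return data.frame with columns `q` and `f`.
#' @export
nonergodicity_parameter <- function(traj, q_grid, t0 = traj$times[1],
                                    shell = 0.02) {
  f <- vapply(q_grid, function(q) {
    s <- self_isf(traj, q, t0, shell)
    s$Fs[nrow(s)]
  }, numeric(1))
  data.frame(q = q_grid, f = f)
}

#' Ergodicity-breaking parameter
#'
#' Relative variance across rings of the per-ring time-averaged squared
#' displacement at lag `Delta`,
#' \deqn{EB(t) = \frac{\langle \bar g_3^2 \rangle - \langle \bar g_3 \rangle^2}
#'   {\langle \bar g_3 \rangle^2},\qquad
#'   \bar g_3(t; \Delta) = \frac{1}{t-\Delta}\int_{t_0}^{t_0+t-\Delta}
#'   [R(t'+\Delta) - R(t')]^2 \, dt',}
#' discretized by the trapezoidal rule at the frame spacing.  Decays as
#' \eqn{(4/3)\Delta/t} for ergodic Brownian motion.
#'
#' @inheritParams g3
#' @param Delta lag time (tau); must be a multiple of the frame spacing.
#' @param t_grid evaluation times (tau); default all frame times > Delta.
#' @return data.frame with columns `t` and `EB`.
#' @export
ergodicity_breaking <- function(traj, Delta, t0 = traj$times[1],
                                t_grid = NULL) {
  coms <- ring_coms(traj)
  f0 <- frame_at(traj, t0)
  times <- traj$times[f0:length(traj$times)] - traj$times[f0]
  M <- dim(coms)[2]
  if (M < 2) warning("EB degenerate with a single ring; returning 0")
  dtf <- times[2] - times[1]
  lag <- round(Delta / dtf)
  if (lag < 1 || abs(lag * dtf - Delta) > 1e-6 * dtf)
    stop("Delta must be a positive multiple of the frame spacing")
  F <- length(times)
  if (is.null(t_grid)) t_grid <- times[times > Delta]
  if (any(t_grid <= Delta))
    stop("all evaluation times t must exceed the lag Delta")
  # squared displacement at lag for every origin frame: (F - lag) x M
  sq <- matrix(0, F - lag, M)
  for (a in 1:3)
    sq <- sq + (coms[(f0 + lag):(f0 + F - 1), , a, drop = TRUE] -
                  coms[f0:(f0 + F - 1 - lag), , a, drop = TRUE])^2
  eb <- vapply(t_grid, function(tt) {
    nf <- round((tt - Delta) / dtf) # origins 0 .. t - Delta
    if (nf < 1) return(NA_real_)
    w <- rep(1, nf + 1); w[1] <- w[nf + 1] <- 0.5 # trapezoid
    gbar <- colSums(sq[seq_len(nf + 1), , drop = FALSE] * w) / nf
    if (M < 2 || mean(gbar) == 0) return(0) # degenerate: no variance
    mean(gbar^2) / mean(gbar)^2 - 1
  }, numeric(1))
  data.frame(t = t_grid, EB = eb)
}

#' Cold-hot vector magnitude and directionality correlation
#'
#' For each partly active ring, the cold-hot vector
#' \eqn{ch = R_{hot} - R_{cold}} connects the centres of mass of the cold
#' and hot blocks.  Reported are the ring-averaged magnitude
#' \eqn{\langle |ch| \rangle}(t) and, for each requested lag `Delta`, the
#' directionality correlation
#' \eqn{\langle e_d(t+\Delta)\cdot e_{ch}(t)\rangle}
#' between the unit displacement \eqn{d(t) = R(t+\Delta) - R(t)} of the
#' ring COM (system-COM frame) and the unit cold-hot vector.
#' Fully passive rings are excluded (with a warning).
#'
#' @inheritParams g3
#' @param Delta lag times (tau), multiples of the frame spacing.
#' @return list with `magnitude` (data.frame `t`, `ch`) and `correlation`
#'   (data.frame `t`, `Delta`, `corr`).
#' @export
cold_hot_vector <- function(traj, Delta = NULL) {
  M <- max(traj$ring)
  active <- vapply(seq_len(M), function(k)
    any(traj$hot[traj$ring == k]) && any(!traj$hot[traj$ring == k]),
    logical(1))
  if (!any(active)) stop("no partly active rings")
  if (!all(active)) warning("fully passive rings excluded from ch average")
  F <- dim(traj$pos)[1]
  ch <- array(0, c(F, sum(active), 3))
  ai <- 0
  for (k in which(active)) {
    idx <- which(traj$ring == k)
    hot <- idx[traj$hot[idx]]
    cold <- idx[!traj$hot[idx]]
    ai <- ai + 1
    for (a in 1:3)
      ch[, ai, a] <- rowMeans(matrix(traj$pos[, hot, a], nrow = F)) -
        rowMeans(matrix(traj$pos[, cold, a], nrow = F))
  }
  mag <- sqrt(ch[, , 1]^2 + ch[, , 2]^2 + ch[, , 3]^2)
  mag <- matrix(mag, nrow = F)
  out_mag <- data.frame(t = traj$times, ch = rowMeans(mag))
  out_corr <- NULL
  if (!is.null(Delta)) {
    coms <- ring_coms(traj)[, active, , drop = FALSE]
    dtf <- traj$times[2] - traj$times[1]
    for (D in Delta) {
      lag <- round(D / dtf)
      if (lag < 1 || lag >= F) next
      d <- coms[(1 + lag):F, , , drop = FALSE] -
        coms[1:(F - lag), , , drop = FALSE]
      dn <- sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
      cn <- mag[1:(F - lag), , drop = FALSE]
      dots <- (d[, , 1] * ch[1:(F - lag), , 1] +
                 d[, , 2] * ch[1:(F - lag), , 2] +
                 d[, , 3] * ch[1:(F - lag), , 3]) / (dn * cn)
      dots[!is.finite(dots)] <- NA # |ch| = 0: correlation undefined
      out_corr <- rbind(out_corr,
                        data.frame(t = traj$times[1:(F - lag)], Delta = D,
                                   corr = rowMeans(dots, na.rm = TRUE)))
    }
  }
  list(magnitude = out_mag, correlation = out_corr)
}

#' Mean squared internal distances and trail exponent
#'
#' \eqn{\langle R^2(s) \rangle}: squared distance between the endpoints of
#' contour subsegments of length `s`, averaged over the segment position
#' within the named block (hot, cold, or the whole ring), over rings and
#' over the supplied frames, together with a least-squares power-law fit
#' \eqn{R^2(s) \sim s^{2\nu}} on log-log axes over `fit_window`.
#'
#' @param states a [melt_state()] or list of them (frames).
#' @param block `"hot"`, `"cold"` or `"all"`.
#' @param s segment lengths (monomers, bonds as unit).
#' @param fit_window range of `s` used for the exponent fit.
#' @return data.frame (`s`, `R2`) with attributes `"nu"` and `"nu_se"`.
#' @export
internal_distances <- function(states, block = c("all", "hot", "cold"),
                               s = NULL, fit_window = c(10, 100)) {
  block <- match.arg(block)
  if (inherits(states, "melt_state")) states <- list(states)
  N <- states[[1]]$params$N
  if (is.null(s)) s <- unique(round(exp(seq(0, log(N / 2), length.out = 20))))
  acc <- matrix(0, length(s), 2) # sum, count
  for (st in states) {
    M <- length(st$cyclic)
    for (k in seq_len(M)) {
      contour <- ring_contour(st, k)
      hot_k <- st$hot[which(st$ring == k)][st$chain_order[[k]]]
      if (block == "all") {
        pts <- contour
        cyc <- st$cyclic[k]
      } else {
        sel <- if (block == "hot") hot_k else !hot_k
        if (!any(sel)) next
        if (max(s) >= sum(sel))
          stop(sprintf("segment length s = %d exceeds the %s block (%d monomers)",
                       max(s), block, sum(sel)))
        # rotate so the block is contiguous in index order
        ord <- block_order(sel, st$cyclic[k])
        pts <- contour[ord, , drop = FALSE]
        cyc <- FALSE
      }
      n <- nrow(pts)
      for (si in seq_along(s)) {
        ss <- s[si]
        if (ss >= n) next
        if (cyc) {
          j <- ((seq_len(n) - 1 + ss) %% n) + 1
          d2 <- rowSums((pts[j, , drop = FALSE] - pts)^2)
        } else {
          d2 <- rowSums((pts[(1 + ss):n, , drop = FALSE] -
                           pts[1:(n - ss), , drop = FALSE])^2)
        }
        acc[si, 1] <- acc[si, 1] + sum(d2)
        acc[si, 2] <- acc[si, 2] + length(d2)
      }
    }
  }
  ok <- acc[, 2] > 0
  out <- data.frame(s = s[ok], R2 = acc[ok, 1] / acc[ok, 2])
  fit <- fit_power_law(out$s, out$R2, window = fit_window)
  attr(out, "nu") <- fit$exponent / 2
  attr(out, "nu_se") <- fit$se / 2
  out
}

# indices putting a contiguous (possibly wrapping) block in contour order
block_order <- function(sel, cyclic) {
  n <- length(sel)
  w <- which(sel)
  if (!cyclic || !(sel[1] && sel[n])) return(w)
  # block wraps the origin: start after the gap
  gap_end <- max(which(!sel))
  c(w[w > gap_end], w[w <= gap_end])
}

#' Least-squares power-law fit on log-log axes
#'
#' Fits \eqn{y \sim x^{b}} by ordinary least squares of
#' \eqn{\log y} on \eqn{\log x} over a window of `x`, reporting the
#' exponent with its standard error.  Used for the trail exponent
#' \eqn{\nu_{trail}} (via \eqn{R^2(s) \sim s^{2\nu}}) and for MSD
#' exponents of `g3` series.
#'
#' @param x,y positive numeric vectors.
#' @param window `c(min, max)` range of `x` entering the fit.
#' @return list with `exponent`, `se`, `prefactor`, `n`.
#' @export
fit_power_law <- function(x, y, window = range(x)) {
  sel <- x >= window[1] & x <= window[2] & x > 0 & y > 0
  if (sum(sel) < 3) return(list(exponent = NA_real_, se = NA_real_,
                                prefactor = NA_real_, n = sum(sel)))
  fit <- stats::lm(log(y[sel]) ~ log(x[sel]))
  s <- suppressWarnings(summary(fit))$coefficients
  list(exponent = unname(s[2, 1]), se = unname(s[2, 2]),
       prefactor = exp(unname(s[1, 1])), n = sum(sel))
}

#' Distribution of 1d centre-of-mass displacements and kurtosis
#'
#' Per-ring COM displacement component at lag `Delta` (system-COM frame,
#' all frame pairs at that lag), its normalized histogram and the excess
#' kurtosis \eqn{\kappa = m_4/m_2^2 - 3} (central moments); \eqn{\kappa=0}
#' for Gaussian displacements, 3 for Laplace.
#'
#' @inheritParams g3
#' @param Delta lag time (tau), multiple of the frame spacing.
#' @param axis 1, 2 or 3 (x, y, z).
#' @param breaks passed to [hist()].
#' @return list with `displacements`, `kurtosis`, `hist`.
#' @export
displacement_distribution <- function(traj, Delta, axis = 1, breaks = 30) {
  coms <- ring_coms(traj)
  F <- dim(coms)[1]
  dtf <- traj$times[2] - traj$times[1]
  lag <- round(Delta / dtf)
  if (lag < 1 || lag >= F) stop("need at least two frames at lag Delta")
  d <- as.numeric(coms[(1 + lag):F, , axis] - coms[1:(F - lag), , axis])
  d <- d - mean(d)
  m2 <- mean(d^2); m4 <- mean(d^4)
  list(displacements = d, kurtosis = m4 / m2^2 - 3,
       hist = graphics::hist(d, breaks = breaks, plot = FALSE))
}

#' Mean number of neighbouring hot segments
#'
#' Two hot segments are neighbours when their centres of mass are within
#' `cutoff` (minimum image); reported is the mean neighbour count per hot
#' segment.  The default cutoff is the hot-segment radius of gyration
#' scale, 3.25 sigma.
#'
#' @param state a [melt_state()].
#' @param cutoff neighbour distance (sigma).
#' @return numeric scalar (0 for fewer than two active rings).
#' @export
hot_neighbor_count <- function(state, cutoff = 3.25) {
  M <- length(state$cyclic)
  coms <- NULL
  for (k in seq_len(M)) {
    idx <- which(state$ring == k)
    if (!any(state$hot[idx])) next
    contour <- ring_contour(state, k)
    hot_k <- state$hot[idx][state$chain_order[[k]]]
    coms <- rbind(coms, colMeans(contour[hot_k, , drop = FALSE]))
  }
  if (is.null(coms) || nrow(coms) < 2) return(0)
  uniform_neighbor_count(coms, state$box, cutoff)
}

# neighbour count of a point set under minimum image
uniform_neighbor_count <- function(pts, box, cutoff) {
  n <- nrow(pts)
  cnt <- 0
  for (i in seq_len(n - 1)) {
    d <- sweep(pts[(i + 1):n, , drop = FALSE], 2, pts[i, ])
    for (a in 1:3) d[, a] <- d[, a] - box[a] * round(d[, a] / box[a])
    cnt <- cnt + 2 * sum(rowSums(d^2) < cutoff^2)
  }
  cnt / n
}

#' Expected hot-segment neighbour count for a uniform distribution
#'
#' Closed form \eqn{(4/3)\pi c^3 \, M/V} with \eqn{V = MN/\rho}: the mean
#' number of other segment COMs within distance `c` if segments were
#' distributed uniformly in the box (one hot segment per ring).
#'
#' @param params a [ring_params()].
#' @param cutoff neighbour distance (sigma).
#' @return numeric scalar.
#' @export
uniform_neighbor_expectation <- function(params, cutoff = 3.25) {
  V <- params$M * params$N / params$rho
  (4 / 3) * pi * cutoff^3 * params$M / V
}

#' Static structure factor of a point set
#'
#' \eqn{S(q) = \frac1M \left|\sum_m e^{i q\cdot R_m}\right|^2} over
#' box-compatible wavevectors, binned by magnitude; reports the location
#' `q_star` of the maximum.
#'
#' @param pts M x 3 matrix (e.g. ring COMs).
#' @param box periodic box lengths.
#' @param q_max largest magnitude (1/sigma).
#' @param nbins number of magnitude bins.
#' @return data.frame (`q`, `S`) with attribute `"q_star"`.
#' @export
structure_factor <- function(pts, box, q_max = 4, nbins = 60) {
  if (nrow(pts) < 2) stop("need at least two points")
  dq <- 2 * pi / box[1]
  nmax <- ceiling(q_max / dq)
  g <- as.matrix(expand.grid(-nmax:nmax, -nmax:nmax, 0:nmax))
  g <- g[!(g[, 3] == 0 & (g[, 1] < 0 | (g[, 1] == 0 & g[, 2] < 0))), ]
  g <- g[rowSums(g^2) > 0, , drop = FALSE]
  qv <- g * dq
  mag <- sqrt(rowSums(qv^2))
  keep <- mag <= q_max
  qv <- qv[keep, , drop = FALSE]; mag <- mag[keep]
  ph <- pts %*% t(qv)
  S <- (colSums(cos(ph))^2 + colSums(sin(ph))^2) / nrow(pts)
  bins <- cut(mag, breaks = seq(0, q_max, length.out = nbins + 1))
  out <- data.frame(q = tapply(mag, bins, mean), S = tapply(S, bins, mean))
  out <- out[is.finite(out$q), ]
  rownames(out) <- NULL
  attr(out, "q_star") <- out$q[which.max(out$S)]
  out
}
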