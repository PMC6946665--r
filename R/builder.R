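#' Build a dense melt of unknotted, nonconcatenated rings
#'
#' Constructs `M` rings of `N` monomers in a cubic periodic box at monomer
#' density `rho`.  Each ring is instantiated as a planar double-spiral
#' (a simple closed curve, hence unknotted) confined to its own cell of a
#' grid of parallel planes, so all pairwise Gauss linking numbers are zero
#' by construction.  The configuration is then pushed off to full excluded
#' volume with a clamped WCA force and a per-step displacement limiter, and
#' pre-equilibrated briefly with the production potentials.  Topology is
#' verified (all pairwise linking numbers must be 0) before the state is
#' returned.  Deterministic given `seed`.
#'
#' Full equilibration at production scale is *not* promised here; the
#' returned state is locally relaxed and topologically clean.  Activity
#' labels are all cold; use [assign_activity()] to switch on hot arcs.
#'
#' @param params a [ring_params()] object.
#' @param seed integer seed.
#' @param pushoff_steps steps of clamped-force overlap removal.
#' @param equil_steps steps of plain dynamics at `T_c` after push-off.
#' @param verify check pairwise linking numbers before returning.
#' @return A [melt_state()] with all-cold labels at `time = 0`.
#' @export
build_melt <- function(params, seed = 1, pushoff_steps = 3000,
                       equil_steps = 5000, verify = TRUE) {
  validate_params(params)
  M <- params$M; N <- params$N
  box <- melt_box(params)
  Lt <- box[1]          # target box
  L <- 1.3 * Lt         # enlarged construction box (density / 2.2)
  b0 <- 0.8 * params$sigma

  lay <- spiral_layout(M, N, L, b0)
  if (lay$score < 0.22)
    stop(sprintf(paste0("builder failure: cannot place %d rings of %d monomers ",
                        "at rho = %g (best strand/plane spacing %.2f sigma)"),
                 M, N, params$rho, lay$score))

  set.seed(derive_seed(seed, 1))
  pos <- matrix(0, M * N, 3)
  for (m in seq_len(M)) {
    cell <- lay$cells[m, ] # cx, cy, cz centre of the ring's cell
    rot <- stats::runif(1, 0, 2 * pi)
    xy <- make_double_spiral(N, b0, lay$R_fit)
    R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2)
    xy <- xy %*% t(R)
    idx <- (m - 1) * N + seq_len(N)
    pos[idx, 1] <- (cell[1] + xy[, 1]) %% L
    pos[idx, 2] <- (cell[2] + xy[, 2]) %% L
    pos[idx, 3] <- cell[3] %% L
  }
  vel <- matrix(stats::rnorm(3 * M * N, 0, sqrt(params$T_c / params$mass)),
                ncol = 3)
  topo <- ring_topology(M, N)
  st <- melt_state(pos, matrix(0L, M * N, 3), vel, c(L, L, L),
                   hot = rep(FALSE, M * N), ring = rep(seq_len(M), each = N),
                   cyclic = rep(TRUE, M), bonds = topo$bonds,
                   angles = topo$angles, time = 0, params = params)

  # push-off: clamped WCA + displacement limiter, essentially athermal
  # (pure overlap relaxation: a thermalized push-off would let soft-core
  # strands diffuse through one another and concatenate).  The clamp
  # radius ramps down so early forces stay below the FENE restoring scale.
  st$params$T_h <- st$params$T_c <- 1e-6
  st$vel[] <- 0
  ramp <- c(1.05, 0.95, 0.85, 0.75, 0.65, 0.6) * params$sigma
  nper <- max(200, ceiling(pushoff_steps / length(ramp)))
  off <- 0
  for (round in seq_along(ramp)) {
    st <- md_advance(st, nper, seed = derive_seed(seed, 2),
                     clamp_r = ramp[round], max_disp = 0.02,
                     step_offset = off)
    off <- off + nper
  }
  dmin <- .cpp_min_pair_dist(st$pos, st$box, st$bonds - 1L)
  for (extra in 1:6) {
    if (dmin >= 0.8 * params$sigma) break
    st <- md_advance(st, nper, seed = derive_seed(seed, 2),
                     clamp_r = 0.6 * params$sigma, max_disp = 0.02,
                     step_offset = off)
    off <- off + nper
    dmin <- .cpp_min_pair_dist(st$pos, st$box, st$bonds - 1L)
  }
  if (dmin < 0.8 * params$sigma)
    stop(sprintf("builder failure: overlap resolution stalled (min pair distance %.3f sigma)", dmin))

  # affine compression to the target box under the full (uncrossable)
  # potential, in ~1.5% steps with short relaxations in between
  while (st$box[1] > Lt * (1 + 1e-12)) {
    sc <- max(0.985, Lt / st$box[1])
    st$pos <- st$pos * sc
    st$box <- st$box * sc
    st <- md_advance(st, 400, seed = derive_seed(seed, 2),
                     clamp_r = 0.6 * params$sigma, max_disp = 0.02,
                     step_offset = off)
    off <- off + 400
  }
  st$box <- box # exact target (guards rounding of the scale product)
  dmin <- .cpp_min_pair_dist(st$pos, st$box, st$bonds - 1L)
  if (dmin < 0.75 * params$sigma)
    stop(sprintf("builder failure: compression left overlaps (min pair distance %.3f sigma)", dmin))

  # restore thermostats, re-draw velocities, pre-equilibrate locally
  st$params$T_h <- params$T_h
  st$params$T_c <- params$T_c
  set.seed(derive_seed(seed, 8))
  st$vel <- matrix(stats::rnorm(3 * nrow(st$pos), 0,
                                sqrt(params$T_c / params$mass)), ncol = 3)
  if (equil_steps > 0)
    st <- md_advance(st, equil_steps, seed = derive_seed(seed, 9))
  st$time <- 0

  if (verify) {
    lk <- pairwise_linking(st)
    if (any(lk != 0))
      stop("builder failure: nonzero pairwise linking number after push-off")
  }
  st
}

# Solve ring placement: nz parallel planes, g x g cells per plane.
# Returns cell centres, spiral fit radius and a feasibility score
# (min of strand spacing and plane spacing).
spiral_layout <- function(M, N, L, b0) {
  best <- NULL
  S <- N * b0
  for (nz in seq_len(max(1, min(M, floor(L / 0.55))))) {
    k <- ceiling(M / nz)
    g <- ceiling(sqrt(k))
    cellw <- L / g
    R_fit <- cellw / 2 - 0.35
    if (R_fit <= 0.4) next
    # outer radius c*(phi+pi) <= R_fit with c = S/phi^2
    phi <- (S + sqrt(S^2 + 4 * R_fit * S * pi)) / (2 * R_fit)
    cc <- S / phi^2
    d_arm <- pi * cc
    dz <- L / nz
    score <- min(d_arm, dz)
    if (is.null(best) || score > best$score)
      best <- list(nz = nz, g = g, R_fit = R_fit, score = score)
  }
  if (is.null(best)) return(list(score = 0))
  # assign cells: fill planes bottom-up, row-major within a plane
  cells <- matrix(0, M, 3)
  for (m in seq_len(M)) {
    iz <- (m - 1) %% best$nz
    ixy <- (m - 1) %/% best$nz
    ix <- ixy %% best$g
    iy <- ixy %/% best$g
    cells[m, ] <- c((ix + 0.5) * L / best$g, (iy + 0.5) * L / best$g,
                    (iz + 0.5) * L / best$nz)
  }
  c(best, list(cells = cells))
}

# Planar double-spiral closed polyline with N vertices, total chord length
# ~ N*b, outer radius <= R_fit.  Simple (non-self-intersecting) by
# construction: two interleaved Archimedean arms joined by radial hops.
make_double_spiral <- function(N, b, R_fit) {
  S <- N * b
  phi_max <- (S + sqrt(S^2 + 4 * R_fit * S * pi)) / (2 * R_fit)
  cc <- S / phi_max^2
  phi_min <- min(pi / 2, phi_max / 4)
  ngrid <- 2000
  phis <- seq(phi_min, phi_max, length.out = ngrid)
  arm1 <- cbind(cc * phis * cos(phis), cc * phis * sin(phis))
  arm2 <- cbind(cc * (phis + pi) * cos(phis), cc * (phis + pi) * sin(phis))
  hop_out <- cbind(seq(cc * phi_max, cc * (phi_max + pi), length.out = 8) *
                     cos(phi_max),
                   seq(cc * phi_max, cc * (phi_max + pi), length.out = 8) *
                     sin(phi_max))
  hop_in <- cbind(seq(cc * (phi_min + pi), cc * phi_min, length.out = 8) *
                    cos(phi_min),
                  seq(cc * (phi_min + pi), cc * phi_min, length.out = 8) *
                    sin(phi_min))
  poly <- rbind(arm1, hop_out[2:7, ], arm2[ngrid:1, ], hop_in[2:7, ])
  resample_closed(poly, N)
}

# resample a closed polyline to n equidistant vertices
resample_closed <- function(poly, n) {
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- (seq_len(n) - 1) * total / n
  out <- matrix(0, n, ncol(poly))
  j <- 1
  for (i in seq_len(n)) {
    while (s[j + 1] < targets[i]) j <- j + 1
    w <- (targets[i] - s[j]) / max(s[j + 1] - s[j], 1e-300)
    out[i, ] <- (1 - w) * closed[j, ] + w * closed[j + 1, ]
  }
  out
}

#' Assign a hot arc to partly active rings
#'
#' Marks one contiguous arc of `N_h` monomers as hot on each of `M_a` rings
#' (sampled uniformly among rings, arc start uniform on the contour, both
#' seeded); all other monomers are cold.
#'
#' @param state a [melt_state()] of cyclic rings.
#' @param N_h hot arc length (monomers); defaults to `params$N_h`.
#' @param M_a number of active rings; defaults to `params$M_a`.
#' @param seed integer seed.
#' @return The relabelled state.
#' @export
assign_activity <- function(state, N_h = state$params$N_h,
                            M_a = state$params$M_a, seed = 1) {
  M <- length(state$cyclic)
  N <- state$params$N
  stopifnot(N_h >= 0, N_h <= N, M_a >= 0, M_a <= M)
  set.seed(derive_seed(seed, 17))
  state$hot <- rep(FALSE, nrow(state$pos))
  if (N_h > 0 && M_a > 0) {
    active <- sort(sample.int(M, M_a))
    for (m in active) {
      start <- sample.int(N, 1) # arc start, uniform on the cycle
      arc <- ((start - 1 + seq_len(N_h) - 1) %% N) + 1
      state$hot[(m - 1) * N + arc] <- TRUE
    }
  }
  state$params$N_h <- as.integer(N_h)
  state$params$M_a <- as.integer(M_a)
  state
}

#' Gauss linking number of two closed polylines
#'
#' Discrete Gauss double sum (exact signed solid angles per segment pair)
#' over two closed, unwrapped, disjoint contours, rounded to the nearest
#' integer.  The pre-rounding residual is available as attribute
#' `"residual"`.
#'
#' @param contour_i,contour_j n x 3 matrices of unwrapped vertices in order.
#' @return Integer linking number (symmetric in its arguments).
#' @export
linking_number <- function(contour_i, contour_j) {
  dmin <- min_vertex_separation(contour_i, contour_j)
  if (dmin < 1e-6)
    stop("ill-conditioned geometry: contours touch within 1e-6 sigma")
  raw <- .cpp_linking_sum(contour_i, contour_j)
  if (is.na(raw))
    stop("ill-conditioned geometry: degenerate segment pair in Gauss sum")
  lk <- round(raw)
  attr(lk, "residual") <- raw - lk
  lk
}

min_vertex_separation <- function(a, b) {
  ## min over vertex pairs; adequate guard for polymer-scale segments
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 +
                (b[, 3] - a[i, 3])^2)
    if (d2 < best) best <- d2
  }
  sqrt(best)
}

# all pairwise linking numbers, in the minimum-image frame of each pair
pairwise_linking <- function(state) {
  M <- length(state$cyclic)
  lk <- matrix(0L, M, M)
  if (M < 2) return(lk)
  contours <- lapply(seq_len(M), function(k) ring_contour(state, k))
  cens <- t(vapply(contours, colMeans, numeric(3)))
  for (i in 1:(M - 1)) for (j in (i + 1):M) {
    if (!state$cyclic[i] || !state$cyclic[j]) next
    shift <- round((cens[i, ] - cens[j, ]) / state$box) * state$box
    ci <- sweep(contours[[i]], 2, shift, `-`)
    lk[i, j] <- lk[j, i] <- as.integer(linking_number(ci, contours[[j]]))
  }
  lk
}

#' Topology report for a melt state
#'
#' Checks the invariants the model relies on: all pairwise Gauss linking
#' numbers zero (nonconcatenation, the hard gate), all bond lengths below
#' `r_max`, and an advisory per-ring unknottedness screen by
#' triangle-elimination contour simplification (reported as
#' `"unknot-consistent"` or `"suspect"`).
#'
#' @param state a [melt_state()].
#' @param knot_screen run the (slower) advisory knot screen.
#' @return A list of class `"topology_report"` with elements
#'   `linking` (M x M integer matrix), `bond_range`, `knots`, and logical
#'   flags `nonconcatenated`, `bonds_ok`, `pass`.
#' @export
verify_topology <- function(state, knot_screen = TRUE) {
  lk <- pairwise_linking(state)
  bl <- bond_lengths(state)
  M <- length(state$cyclic)
  knots <- rep(NA_character_, M)
  if (knot_screen) {
    for (k in seq_len(M)) {
      if (!state$cyclic[k]) { knots[k] <- "open chain"; next }
      n_left <- kmt_reduce(ring_contour(state, k))
      knots[k] <- if (n_left <= 3) "unknot-consistent" else "suspect"
    }
  }
  rep <- list(linking = lk,
              bond_range = range(bl),
              knots = knots,
              nonconcatenated = all(lk == 0),
              bonds_ok = all(bl < state$params$r_max))
  rep$pass <- rep$nonconcatenated && rep$bonds_ok
  class(rep) <- "topology_report"
  rep
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("Topology report: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  nonconcatenated: %s (max |Lk| = %d)\n",
              x$nonconcatenated, max(abs(x$linking))))
  cat(sprintf("  bond lengths in [%.3f, %.3f] sigma (ok: %s)\n",
              x$bond_range[1], x$bond_range[2], x$bonds_ok))
  if (!all(is.na(x$knots)))
    cat(sprintf("  knot screen: %d/%d unknot-consistent\n",
                sum(x$knots == "unknot-consistent"), length(x$knots)))
  invisible(x)
}

bond_lengths <- function(state) {
  d <- state$pos[state$bonds[, 1], , drop = FALSE] -
    state$pos[state$bonds[, 2], , drop = FALSE]
  for (a in 1:3) d[, a] <- d[, a] - state$box[a] * round(d[, a] / state$box[a])
  sqrt(rowSums(d^2))
}

# KMT-style reduction: repeatedly delete vertices whose elimination triangle
# is not crossed by any other segment; returns remaining vertex count.
kmt_reduce <- function(contour, max_pass = 200) {
  v <- contour
  for (pass in seq_len(max_pass)) {
    n <- nrow(v)
    if (n <= 3) return(n)
    removed <- FALSE
    i <- 1
    while (i <= nrow(v) && nrow(v) > 3) {
      n <- nrow(v)
      ip <- if (i == 1) n else i - 1
      inx <- if (i == n) 1 else i + 1
      tri <- v[c(ip, i, inx), , drop = FALSE]
      others <- setdiff(seq_len(n), c(ip, i))
      p <- v[others, , drop = FALSE]
      q <- v[ifelse(others == n, 1, others + 1), , drop = FALSE]
      hit <- segments_cross_triangle(p, q, tri)
      if (!hit) {
        v <- v[-i, , drop = FALSE]
        removed <- TRUE
      } else i <- i + 1
    }
    if (!removed) break
  }
  nrow(v)
}

# does any segment (p_k, q_k) properly cross triangle tri?  Segments sharing
# a triangle vertex are tolerated via the strict barycentric margin.
segments_cross_triangle <- function(p, q, tri, eps = 1e-9) {
  a <- tri[1, ]; b <- tri[2, ]; cc <- tri[3, ]
  e1 <- b - a; e2 <- cc - a
  d <- q - p
  h1 <- d[, 2] * e2[3] - d[, 3] * e2[2]
  h2 <- d[, 3] * e2[1] - d[, 1] * e2[3]
  h3 <- d[, 1] * e2[2] - d[, 2] * e2[1]
  det <- h1 * e1[1] + h2 * e1[2] + h3 * e1[3]
  s1 <- p[, 1] - a[1]; s2 <- p[, 2] - a[2]; s3 <- p[, 3] - a[3]
  u <- (s1 * h1 + s2 * h2 + s3 * h3) / det
  q1 <- s2 * e1[3] - s3 * e1[2]
  q2 <- s3 * e1[1] - s1 * e1[3]
  q3 <- s1 * e1[2] - s2 * e1[1]
  vv <- (d[, 1] * q1 + d[, 2] * q2 + d[, 3] * q3) / det
  tt <- (e2[1] * q1 + e2[2] * q2 + e2[3] * q3) / det
  ok <- is.finite(u) & is.finite(vv) & is.finite(tt) &
    u > eps & vv > eps & (u + vv) < 1 - eps & tt > eps & tt < 1 - eps
  any(ok)
}

#' Cut each ring into a linear cold-hot-cold triblock
#'
#' On every ring, removes the single bond between the two cold monomers
#' most distant along the contour from the midpoint of the hot arc
#' (for fully cold rings, the bond closing the contour).  The two bending
#' terms spanning the removed bond are dropped.  Monomer storage order is
#' unchanged (so trajectories recorded across the cut stay consistent);
#' each chain's contour order is recorded in `state$chain_order`.  The
#' result is `M` linear chains of `N` monomers with cold ends and an
#' interior hot arc.
#'
#' @param state a [melt_state()] of cyclic rings.
#' @return A [melt_state()] of linear chains.
#' @export
cut_bonds <- function(state) {
  M <- length(state$cyclic)
  N <- state$params$N
  if (!all(state$cyclic)) stop("cut_bonds expects cyclic rings")
  if (state$params$N_h > N - 2 && any(state$hot))
    stop("no cold bond available to cut (cold segment shorter than 2)")
  st <- state
  for (m in seq_len(M)) {
    idx <- (m - 1) * N + seq_len(N)
    hot <- state$hot[idx]
    if (any(hot)) {
      loc <- which(hot) - 1L # 0-based contour positions of hot monomers
      if (length(loc) < N) {
        gaps <- setdiff(0:(N - 1), loc)
        # arc start: hot position whose predecessor is cold
        start <- loc[((loc - 1) %% N) %in% gaps][1]
      } else start <- 0L
      mid <- start + (sum(hot) - 1) / 2
      cutpos <- (mid + N / 2) %% N       # contour coordinate of the cut bond
      jl <- (floor(cutpos) %% N) + 1L    # bond between local jl and jl+1 (1-based)
    } else {
      jl <- N                            # cut the closing bond
    }
    j2 <- (jl %% N) + 1L
    if (state$hot[idx[jl]] || state$hot[idx[j2]])
      stop("cut bond is not between two cold monomers")
    u <- idx[jl]; v <- idx[j2]
    drop_b <- (st$bonds[, 1] == u & st$bonds[, 2] == v) |
      (st$bonds[, 1] == v & st$bonds[, 2] == u)
    st$bonds <- st$bonds[!drop_b, , drop = FALSE]
    pair_is <- function(a, b) (a == u & b == v) | (a == v & b == u)
    drop_a <- pair_is(st$angles[, 1], st$angles[, 2]) |
      pair_is(st$angles[, 2], st$angles[, 3])
    st$angles <- st$angles[!drop_a, , drop = FALSE]
    # contour order of the open chain: j2, j2+1, ..., wrap, ..., jl
    st$chain_order[[m]] <- ((j2 - 1 + seq_len(N) - 1) %% N) + 1L
  }
  st$cyclic <- rep(FALSE, M)
  st
}
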