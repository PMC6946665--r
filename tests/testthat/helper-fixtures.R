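# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small equilibrated-ish melt of 4 rings of 32 monomers
small_melt <- function() {
  cached("small_melt", function() {
    p <- ring_params(N = 32, M = 4, N_h = 4)
    st <- build_melt(p, seed = 101)
    md_advance(st, 5000, seed = 102)
  })
}

# melt sized for threading analysis (rings well below the box size)
threading_melt <- function() {
  cached("threading_melt", function() {
    p <- ring_params(N = 16, M = 27, N_h = 4)
    st <- build_melt(p, seed = 103)
    md_advance(st, 15000, seed = 104)
  })
}

# discretized circle in the xy plane
circle3 <- function(n = 64, R = 1, center = c(0, 0, 0), plane = "xy") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  out <- switch(plane,
                xy = cbind(R * cos(th), R * sin(th), 0),
                xz = cbind(R * cos(th), 0, R * sin(th)))
  sweep(out, 2, center, `+`)
}

# single-ring planar state with a hot arc, for label/cut arithmetic tests
labelled_ring_state <- function(N, hot_arc = integer(0), M = 1) {
  th <- seq(0, 2 * pi, length.out = N + 1)[-(N + 1)]
  R0 <- N / (2 * pi)
  pos <- NULL
  ring <- integer(0)
  hot <- logical(0)
  for (m in seq_len(M)) {
    pos <- rbind(pos, cbind(R0 * cos(th), R0 * sin(th), m * 2))
    ring <- c(ring, rep(m, N))
    h <- rep(FALSE, N)
    h[hot_arc] <- TRUE
    hot <- c(hot, h)
  }
  L <- 10 * R0 + 10
  topo <- ringmelt:::ring_topology(M, N)
  melt_state(pos %% L, matrix(0L, M * N, 3), matrix(0, M * N, 3),
             c(L, L, L), hot = hot, ring = ring, cyclic = rep(TRUE, M),
             bonds = topo$bonds, angles = topo$angles,
             params = ring_params(N = N, M = M,
                                  N_h = max(length(hot_arc), 0)))
}

# independent brute-force segment/triangle intersector (plane crossing +
# barycentric point-in-triangle by scalar algebra); used as oracle.
brute_piercings <- function(surface, contour) {
  V <- surface$V; tri <- surface$tri
  n <- nrow(contour)
  out <- NULL
  for (i in seq_len(n)) {
    p <- contour[i, ]
    q <- contour[if (i == n) 1 else i + 1, ]
    for (tt in seq_len(nrow(tri))) {
      a <- V[tri[tt, 1], ]; b <- V[tri[tt, 2], ]; cc <- V[tri[tt, 3], ]
      nrm <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
               (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
               (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
      dp <- sum(nrm * (p - a)); dq <- sum(nrm * (q - a))
      if (dp == 0 || dq == 0 || sign(dp) == sign(dq)) next
      lam <- dp / (dp - dq)
      x <- p + lam * (q - p)
      # barycentric via areas
      w <- rbind(a, b, cc)
      m <- cbind(w[2, ] - w[1, ], w[3, ] - w[1, ])
      rhs <- x - w[1, ]
      uv <- solve(crossprod(m), crossprod(m, rhs))
      if (uv[1] > 1e-9 && uv[2] > 1e-9 && sum(uv) < 1 - 1e-9)
        out <- rbind(out, data.frame(bond = i - 1L,
                                     sign = ifelse(dq > dp, 1L, -1L)))
    }
  }
  out
}

# explicit-walk oracle for the separation length: accumulate the two
# alternating side totals by stepping monomer-by-monomer around the cycle.
brute_L_sep <- function(bonds, N) {
  mids <- sort(bonds) + 0.5
  side <- 0
  tot <- c(0, 0)
  for (m in seq_len(N)) {           # monomer centres 1..N
    crossed <- sum(mids < m)        # piercings passed before this monomer
    side <- crossed %% 2
    tot[side + 1] <- tot[side + 1] + 1
  }
  min(tot)
}
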