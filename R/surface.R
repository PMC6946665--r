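#' Triangulated disc-topology surface spanned on a ring contour
#'
#' Builds the initial surface for threading detection: a fan triangulation
#' from the contour centroid, with the ring's unwrapped monomer positions
#' as fixed boundary vertices.  The mesh has disc topology (Euler
#' characteristic \eqn{V - E + F = 1}) and a consistent orientation
#' inherited from the contour order.  Boundary vertices are rows
#' `1..nb` of `$V` and are never moved by [minimize_area()].
#'
#' @param contour n x 3 matrix of unwrapped ring vertices in contour order
#'   (closed implicitly: last connects to first).
#' @return An object of class `"ring_surface"`: list with `V` (vertices),
#'   `tri` (triangle vertex indices, consistent orientation), `nb`
#'   (number of boundary vertices).
#' @export
triangulate_ring <- function(contour) {
  n <- nrow(contour)
  if (n < 3) stop("contour must have at least 3 vertices")
  cen <- colMeans(contour)
  V <- rbind(contour, cen)
  dimnames(V) <- NULL
  tri <- cbind(seq_len(n), c(2:n, 1L), n + 1L)
  surf <- structure(list(V = V, tri = tri, nb = n), class = "ring_surface")
  stopifnot(euler_characteristic(surf) == 1)
  surf
}

#' @export
print.ring_surface <- function(x, ...) {
  cat(sprintf("Disc surface: %d vertices (%d boundary), %d triangles, area %.4f sigma^2\n",
              nrow(x$V), x$nb, nrow(x$tri), surface_area(x)))
  invisible(x)
}

#' Total area of a triangulated surface
#' @param surface a `"ring_surface"`.
#' @return Sum of triangle areas (sigma^2).
#' @export
surface_area <- function(surface) {
  sum(triangle_areas(surface$V, surface$tri))
}

triangle_areas <- function(V, tri) {
  a <- V[tri[, 1], , drop = FALSE]
  b <- V[tri[, 2], , drop = FALSE]
  cc <- V[tri[, 3], , drop = FALSE]
  n <- cross3(b - a, cc - a)
  0.5 * sqrt(rowSums(n^2))
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

euler_characteristic <- function(surface) {
  tri <- surface$tri
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nE <- nrow(unique(e))
  nrow(surface$V) - nE + nrow(tri)
}

#' Minimize the area of a disc surface with fixed boundary
#'
#' Evolves the interior vertices by steepest descent on the total triangle
#' area (the discrete mean-curvature flow of an overdamped surface under
#' tension), with a backtracking line search per sweep, interleaved with
#' mesh maintenance: Delaunay-style edge flips, refinement of long interior
#' edges toward a target edge length of about one bond length, and collapse
#' of short interior edges.  The boundary polyline is preserved bit-exactly
#' and disc topology (\eqn{\chi = 1}) is maintained throughout.  The area
#' is non-increasing across accepted sweeps; iteration stops when the
#' relative area decrease in one sweep falls below `tol`.
#'
#' @param surface a `"ring_surface"` from [triangulate_ring()].
#' @param tol relative area-decrease convergence threshold per sweep.
#' @param max_iters maximum number of descent sweeps.
#' @param target_edge mesh refinement target edge length (sigma); no
#'   threading bond can skip a triangle when this is at the bond scale.
#' @return The minimized `"ring_surface"` with attribute `"iterations"`.
#' @export
minimize_area <- function(surface, tol = 1e-4, max_iters = 400,
                          target_edge = 1.0) {
  V <- surface$V
  tri <- surface$tri
  nb <- surface$nb
  boundary0 <- V[seq_len(nb), , drop = FALSE]
  lambda <- 0.25
  area <- sum(triangle_areas(V, tri))
  it <- 0
  while (it < max_iters) {
    it <- it + 1
    # maintenance every few sweeps (and once at the start)
    if (it %% 4 == 1) {
      m <- maintain_mesh(V, tri, nb, target_edge)
      V <- m$V; tri <- m$tri
      area <- sum(triangle_areas(V, tri))
    }
    g <- area_gradient(V, tri)
    g[seq_len(nb), ] <- 0 # boundary fixed
    gmax <- sqrt(max(rowSums(g^2)))
    if (gmax < 1e-12) break
    # backtracking line search on the sweep step
    accepted <- FALSE
    lam <- lambda
    for (bt in 1:30) {
      Vn <- V - lam * g
      an <- sum(triangle_areas(Vn, tri))
      if (an < area) { accepted <- TRUE; break }
      lam <- lam / 2
    }
    if (!accepted) {
      if (it > 4) break else next
    }
    rel <- (area - an) / area
    V <- Vn
    area <- an
    lambda <- min(lam * 1.5, 2)
    if (rel < tol && it > 8) break
  }
  if (any(triangle_areas(V, tri) < 1e-10)) {
    m <- maintain_mesh(V, tri, nb, target_edge)
    V <- m$V; tri <- m$tri
    if (any(triangle_areas(V, tri) < 1e-10)) {
      cond <- structure(class = c("ringmelt_degenerate_mesh", "error", "condition"),
                        list(message = "unresolvable degenerate triangle in surface mesh",
                             call = sys.call(),
                             mesh = list(V = V, tri = tri, nb = nb)))
      stop(cond)
    }
  }
  stopifnot(identical(V[seq_len(nb), , drop = FALSE], boundary0))
  out <- structure(list(V = V, tri = tri, nb = nb), class = "ring_surface")
  stopifnot(euler_characteristic(out) == 1)
  attr(out, "iterations") <- it
  out
}

# gradient of total area w.r.t. every vertex
area_gradient <- function(V, tri) {
  a <- V[tri[, 1], , drop = FALSE]
  b <- V[tri[, 2], , drop = FALSE]
  cc <- V[tri[, 3], , drop = FALSE]
  n <- cross3(b - a, cc - a)
  nn <- sqrt(rowSums(n^2))
  nn[nn < 1e-300] <- 1e-300
  nh <- n / nn
  gb <- 0.5 * cross3(cc - a, nh)
  gc <- 0.5 * cross3(nh, b - a)
  ga <- -(gb + gc)
  g <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    g[, k] <- g[, k] + tabulate_sum(tri[, 1], ga[, k], nrow(V)) +
      tabulate_sum(tri[, 2], gb[, k], nrow(V)) +
      tabulate_sum(tri[, 3], gc[, k], nrow(V))
  }
  g
}

tabulate_sum <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# --- mesh maintenance: flips, refine, collapse (chi = 1 preserving) -------
maintain_mesh <- function(V, tri, nb, target_edge) {
  for (r in 1:3) {
    res <- refine_long_edges(V, tri, nb, 1.6 * target_edge)
    V <- res$V; tri <- res$tri
    if (!res$changed) break
  }
  tri <- flip_edges(V, tri, nb)
  res <- collapse_short_edges(V, tri, nb, 0.35 * target_edge)
  V <- res$V; tri <- res$tri
  tri <- flip_edges(V, tri, nb)
  list(V = V, tri = tri)
}

# table of interior edges with their two adjacent triangles
interior_edges <- function(tri) {
  e <- rbind(cbind(tri[, 1], tri[, 2], seq_len(nrow(tri)), 3L),
             cbind(tri[, 2], tri[, 3], seq_len(nrow(tri)), 1L),
             cbind(tri[, 3], tri[, 1], seq_len(nrow(tri)), 2L))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sp <- split(seq_len(nrow(e)), key)
  sp <- sp[lengths(sp) == 2]
  if (!length(sp)) return(NULL)
  do.call(rbind, lapply(sp, function(rows) {
    c(e[rows[1], 1], e[rows[1], 2], # directed as in first triangle
      e[rows[1], 3], e[rows[1], 4], # tri id + opposite-vertex slot
      e[rows[2], 3], e[rows[2], 4])
  }))
}

flip_edges <- function(V, tri, nb, max_flips = 1000) {
  for (pass in 1:4) {
    ie <- interior_edges(tri)
    if (is.null(ie)) return(tri)
    flipped <- FALSE
    touched <- logical(nrow(tri))
    for (r in seq_len(nrow(ie))) {
      u <- ie[r, 1]; v <- ie[r, 2]
      t1 <- ie[r, 3]; t2 <- ie[r, 5]
      if (touched[t1] || touched[t2]) next
      w1 <- tri[t1, ie[r, 4]]
      w2 <- tri[t2, ie[r, 6]]
      # Delaunay criterion: flip if opposite angles sum exceeds pi
      a1 <- angle_at(V[w1, ], V[u, ], V[v, ])
      a2 <- angle_at(V[w2, ], V[u, ], V[v, ])
      if (a1 + a2 <= pi + 1e-9) next
      # do not create an existing edge
      if (share_edge(tri, w1, w2)) next
      nt1 <- c(w1, u, w2)
      nt2 <- c(w2, v, w1)
      A <- triangle_areas(V, rbind(nt1, nt2))
      if (any(A < 1e-12)) next
      tri[t1, ] <- nt1
      tri[t2, ] <- nt2
      touched[t1] <- touched[t2] <- TRUE
      flipped <- TRUE
    }
    if (!flipped) break
  }
  tri
}

angle_at <- function(p, q, r) {
  u <- q - p; v <- r - p
  c0 <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, c0)))
}

share_edge <- function(tri, a, b) {
  hit <- (tri[, 1] == a | tri[, 2] == a | tri[, 3] == a) &
    (tri[, 1] == b | tri[, 2] == b | tri[, 3] == b)
  any(hit)
}

refine_long_edges <- function(V, tri, nb, lmax) {
  ie <- interior_edges(tri)
  if (is.null(ie)) return(list(V = V, tri = tri, changed = FALSE))
  len <- sqrt(rowSums((V[ie[, 1], , drop = FALSE] -
                         V[ie[, 2], , drop = FALSE])^2))
  ord <- order(len, decreasing = TRUE)
  touched <- logical(nrow(tri))
  changed <- FALSE
  newV <- list(); newT <- list()
  kill <- logical(nrow(tri))
  nextv <- nrow(V)
  for (r in ord) {
    if (len[r] <= lmax) break
    t1 <- ie[r, 3]; t2 <- ie[r, 5]
    if (touched[t1] || touched[t2]) next
    u <- ie[r, 1]; v <- ie[r, 2]
    w1 <- tri[t1, ie[r, 4]]
    w2 <- tri[t2, ie[r, 6]]
    nextv <- nextv + 1
    mid <- (V[u, ] + V[v, ]) / 2
    newV[[length(newV) + 1]] <- mid
    # edge runs u -> v in t1's orientation
    newT[[length(newT) + 1]] <- rbind(c(u, nextv, w1), c(nextv, v, w1),
                                      c(v, nextv, w2), c(nextv, u, w2))
    kill[t1] <- kill[t2] <- TRUE
    touched[t1] <- touched[t2] <- TRUE
    changed <- TRUE
  }
  if (!changed) return(list(V = V, tri = tri, changed = FALSE))
  V <- rbind(V, do.call(rbind, newV))
  tri <- rbind(tri[!kill, , drop = FALSE], do.call(rbind, newT))
  list(V = V, tri = tri, changed = TRUE)
}

collapse_short_edges <- function(V, tri, nb, lmin) {
  repeat {
    ie <- interior_edges(tri)
    if (is.null(ie)) return(list(V = V, tri = tri))
    both_int <- ie[, 1] > nb & ie[, 2] > nb
    len <- sqrt(rowSums((V[ie[, 1], , drop = FALSE] -
                           V[ie[, 2], , drop = FALSE])^2))
    cand <- which(both_int & len < lmin)
    if (!length(cand)) return(list(V = V, tri = tri))
    r <- cand[which.min(len[cand])]
    u <- ie[r, 1]; v <- ie[r, 2]
    mid <- (V[u, ] + V[v, ]) / 2
    tri2 <- tri
    tri2[tri2 == v] <- u
    degen <- tri2[, 1] == tri2[, 2] | tri2[, 2] == tri2[, 3] |
      tri2[, 3] == tri2[, 1]
    tri2 <- tri2[!degen, , drop = FALSE]
    V2 <- V
    V2[u, ] <- mid
    # validity: no duplicated triangles, no near-zero areas
    key <- apply(tri2, 1, function(z) paste(sort(z), collapse = "-"))
    if (anyDuplicated(key) || any(triangle_areas(V2, tri2) < 1e-12))
      return(list(V = V, tri = tri))
    # drop vertex v, remap indices
    keepv <- setdiff(seq_len(nrow(V2)), v)
    map <- integer(nrow(V2)); map[keepv] <- seq_along(keepv)
    V <- V2[keepv, , drop = FALSE]
    tri <- matrix(map[tri2], ncol = 3)
  }
}
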