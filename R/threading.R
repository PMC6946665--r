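#' Detect piercings of a ring's minimal surface by another ring's contour
#'
#' Finds every transversal intersection of the bonds (segments) of
#' `contour` with the triangles of `surface`, reporting for each piercing
#' the bond index, the intersection point and the crossing sign relative
#' to the surface orientation.  When `box` is given, the contour is first
#' translated by the box vector bringing its centroid into the minimum
#' image of the surface's boundary centroid, and the neighbouring
#' \eqn{\pm 1} box-shift images are also tested (with bounding-box
#' culling) so pairs spanning the periodic boundary are handled.
#'
#' Grazing geometry (a hit within `1e-9` of a triangle edge, or a segment
#' lying in a triangle's plane) triggers a tiny seeded perturbation of the
#' contour and a retry; persistent degeneracy is an error.
#'
#' @param surface a minimized `"ring_surface"` of the threaded ring.
#' @param contour n x 3 unwrapped closed polyline of the threading ring.
#' @param box periodic box lengths, or `NULL` for open space.
#' @return A data.frame with columns `bond` (0-based contour bond index),
#'   `x`, `y`, `z`, `sign` (+1/-1), `t` (position along the bond), ordered
#'   by `bond` then `t`.
#' @export
find_piercings <- function(surface, contour, box = NULL) {
  shifts <- matrix(0, 1, 3)
  cont <- contour
  if (!is.null(box)) {
    cenS <- colMeans(surface$V[seq_len(surface$nb), , drop = FALSE])
    cenC <- colMeans(contour)
    base <- round((cenC - cenS) / box) * box
    cont <- sweep(contour, 2, base, `-`)
    ext <- apply(contour, 2, function(z) diff(range(z)))
    if (any(ext > box - 1e-9))
      stop("contour larger than the box; threading analysis aborted")
    g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
    shifts <- g * rep(box, each = nrow(g))
  }
  lo <- apply(surface$V, 2, min) - 1e-9
  hi <- apply(surface$V, 2, max) + 1e-9
  out <- NULL
  for (s in seq_len(nrow(shifts))) {
    cs <- sweep(cont, 2, shifts[s, ], `-`)
    clo <- apply(cs, 2, min); chi <- apply(cs, 2, max)
    if (any(clo > hi) || any(chi < lo)) next
    hits <- piercings_one_image(surface, cs, seed = s)
    if (!is.null(hits) && nrow(hits)) {
      hits[, c("x", "y", "z")] <- sweep(as.matrix(hits[, c("x", "y", "z")]),
                                        2, shifts[s, ], `+`)
      out <- rbind(out, hits)
    }
  }
  if (is.null(out))
    out <- data.frame(bond = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), sign = integer(0), t = numeric(0))
  out[order(out$bond, out$t), , drop = FALSE]
}

piercings_one_image <- function(surface, cont, seed = 1, max_retry = 3) {
  n <- nrow(cont)
  for (try in 0:max_retry) {
    cs <- cont
    if (try > 0) {
      set.seed(1000003L * seed + try)
      cs <- cont + matrix(stats::runif(3, -1, 1) * 1e-7, n, 3, byrow = TRUE)
    }
    res <- mt_intersections(surface$V, surface$tri, cs)
    if (!res$degenerate) return(res$hits)
  }
  stop("persistent degenerate segment-triangle geometry in piercing detection")
}

# Moeller-Trumbore over all (bond, triangle) pairs; loops over bonds,
# vectorised over triangles.
mt_intersections <- function(V, tri, cont, eps = 1e-9) {
  n <- nrow(cont)
  a <- V[tri[, 1], , drop = FALSE]
  e1 <- V[tri[, 2], , drop = FALSE] - a
  e2 <- V[tri[, 3], , drop = FALSE] - a
  nrm <- cross3(e1, e2)
  hits <- NULL
  degen <- FALSE
  for (i in seq_len(n)) {
    p <- cont[i, ]
    q <- cont[if (i == n) 1 else i + 1, ]
    d <- q - p
    det <- nrm[, 1] * d[1] + nrm[, 2] * d[2] + nrm[, 3] * d[3]
    s1 <- p[1] - a[, 1]; s2 <- p[2] - a[, 2]; s3 <- p[3] - a[, 3]
    num <- -(nrm[, 1] * s1 + nrm[, 2] * s2 + nrm[, 3] * s3)
    nlen <- sqrt(rowSums(nrm^2))
    # segment lying in a triangle's plane: perturb and retry
    if (any(abs(det) < 1e-12 * nlen & abs(num) < 1e-9 * nlen)) {
      degen <- TRUE
      break
    }
    tt <- num / det
    keep <- which(is.finite(tt) & tt >= 0 & tt < 1)
    if (!length(keep)) next
    hx <- s1[keep] + tt[keep] * d[1]
    hy <- s2[keep] + tt[keep] * d[2]
    hz <- s3[keep] + tt[keep] * d[3]
    # barycentric coordinates of hit point in (e1, e2) basis
    d11 <- rowSums(e1[keep, , drop = FALSE]^2)
    d22 <- rowSums(e2[keep, , drop = FALSE]^2)
    d12 <- rowSums(e1[keep, , drop = FALSE] * e2[keep, , drop = FALSE])
    dh1 <- e1[keep, 1] * hx + e1[keep, 2] * hy + e1[keep, 3] * hz
    dh2 <- e2[keep, 1] * hx + e2[keep, 2] * hy + e2[keep, 3] * hz
    den <- d11 * d22 - d12^2
    u <- (d22 * dh1 - d12 * dh2) / den
    v <- (d11 * dh2 - d12 * dh1) / den
    inside <- u > eps & v > eps & (u + v) < 1 - eps
    # grazing: a hit within eps of a triangle edge (either side)
    near <- !inside & u > -eps & v > -eps & (u + v) < 1 + eps
    if (any(near)) {
      degen <- TRUE
      break
    }
    w <- which(inside)
    if (!length(w)) next
    k <- keep[w]
    sgn <- ifelse(det[k] > 0, 1L, -1L)
    hits <- rbind(hits, data.frame(bond = i - 1L,
                                   x = p[1] + tt[k] * d[1],
                                   y = p[2] + tt[k] * d[2],
                                   z = p[3] + tt[k] * d[3],
                                   sign = sgn, t = tt[k]))
  }
  list(hits = hits, degenerate = degen)
}

#' Separation length and threading ratio from an ordered piercing list
#'
#' Splits the threading ring's contour at its surface penetrations and sums
#' the inter-penetration arc lengths of alternating parity:
#' \deqn{L_{sep} = \min\left(\sum_{i\,even} L_{t_i}, \sum_{i\,odd} L_{t_i}\right),}
#' where \eqn{L_{t_i}} is the contour length in monomers between the i-th
#' and (i+1)-th penetration (cyclically; bonds attributed by their
#' midpoint).  The two parity sums total `N`, so which penetration is
#' labelled first is immaterial.  The threading ratio is
#' \eqn{Q = L_{sep}/(N - L_{sep}) \in (0, 1]}.
#'
#' @param bonds integer vector of 0-based piercing bond indices (repeats
#'   allowed), any order.
#' @param N contour length of the threading ring (monomers).
#' @return list with `L_sep` and `Q`.
#' @export
separation_length <- function(bonds, N) {
  k <- length(bonds)
  if (k < 2 || k %% 2 != 0)
    stop("concatenation anomaly: piercing count must be even and >= 2")
  b <- sort(as.numeric(bonds)) + 0.5 # bond midpoints on the contour
  arcs <- diff(c(b, b[1] + N)) # cyclic gaps, sum to N
  s_odd <- sum(arcs[seq(1, k, by = 2)])
  s_even <- sum(arcs[seq(2, k, by = 2)])
  L_sep <- min(s_odd, s_even)
  list(L_sep = L_sep, Q = L_sep / (N - L_sep))
}

#' Threading analysis of one configuration
#'
#' For every ring `j`, spans and minimizes a disc surface on its contour,
#' then tests every other ring `i` for piercings.  A directed pair
#' (`i` threads `j`) enters the table when `i`'s contour pierces `j`'s
#' surface; for nonconcatenated rings the piercing count is even and the
#' signed crossings cancel.  An odd count or nonzero signed sum is flagged
#' in the `anomaly` column rather than silently dropped.
#'
#' Surfaces are recomputed independently per call (no warm start).
#'
#' @param state a [melt_state()] of cyclic rings (or a trajectory frame via
#'   [traj_frame_state]-style states).
#' @param rings rings to analyse as threaded (`j`); default all.
#' @param tol,max_iters,target_edge passed to [minimize_area()].
#' @return A data.frame of class `"threading_table"` with columns
#'   `time`, `i`, `j`, `n_pierce`, `L_sep`, `Q`, `anomaly`; the per-pair
#'   piercing data.frames are attached as attribute `"piercings"`.
#' @export
analyze_threading <- function(state, rings = NULL, tol = 1e-4,
                              max_iters = 200, target_edge = 1.0) {
  M <- length(state$cyclic)
  if (is.null(rings)) rings <- seq_len(M)
  N <- state$params$N
  contours <- lapply(seq_len(M), function(k) ring_contour(state, k))
  rows <- NULL
  plist <- list()
  for (j in rings) {
    if (!state$cyclic[j]) next
    surf <- minimize_area(triangulate_ring(contours[[j]]), tol = tol,
                          max_iters = max_iters, target_edge = target_edge)
    for (i in seq_len(M)) {
      if (i == j || !state$cyclic[i]) next
      pr <- find_piercings(surf, contours[[i]], box = state$box)
      if (!nrow(pr)) next
      anomaly <- (nrow(pr) %% 2 != 0) || (sum(pr$sign) != 0)
      if (!anomaly && nrow(pr) >= 2) {
        sl <- separation_length(pr$bond, N)
        # both piercings on one bond: a graze, not a threading
        if (sl$L_sep < 1) next
      } else sl <- list(L_sep = NA_real_, Q = NA_real_)
      rows <- rbind(rows, data.frame(time = state$time, i = i, j = j,
                                     n_pierce = nrow(pr),
                                     L_sep = sl$L_sep, Q = sl$Q,
                                     anomaly = anomaly))
      plist[[paste(i, j)]] <- pr
    }
  }
  if (is.null(rows))
    rows <- data.frame(time = numeric(0), i = integer(0), j = integer(0),
                       n_pierce = integer(0), L_sep = numeric(0),
                       Q = numeric(0), anomaly = logical(0))
  class(rows) <- c("threading_table", "data.frame")
  attr(rows, "M") <- M
  attr(rows, "piercings") <- plist
  rows
}

#' Threading clusters by separation-length cutoff
#'
#' Two rings belong to the same cluster if at least one of them threads the
#' other with `L_sep > L_cutoff` (union-find over the undirected pair
#' graph).  For mixed active/passive systems the biggest cluster over all
#' rings and the biggest among clusters containing only passive rings are
#' both reported.
#'
#' @param table a `"threading_table"`.
#' @param L_cutoff separation-length cutoff (monomers).
#' @param M total number of rings (default from the table attribute).
#' @param active optional logical vector (length M): is each ring partly
#'   active?
#' @return list with `labels` (cluster id per ring), `sizes`,
#'   `biggest` (M^BC over all rings) and `biggest_passive` (or `NA`).
#' @export
threading_clusters <- function(table, L_cutoff, M = attr(table, "M"),
                               active = NULL) {
  parent <- seq_len(M)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ok <- !table$anomaly & !is.na(table$L_sep) & table$L_sep > L_cutoff
  for (r in which(ok)) {
    a <- find(as.integer(table$i[r]))
    b <- find(as.integer(table$j[r]))
    if (a != b) parent[a] <- b
  }
  labels <- vapply(seq_len(M), find, numeric(1))
  labels <- match(labels, unique(labels))
  sizes <- tabulate(labels)
  biggest_passive <- NA_integer_
  if (!is.null(active)) {
    pure <- vapply(seq_len(max(labels)), function(cl)
      !any(active[labels == cl]), logical(1))
    if (any(pure)) biggest_passive <- max(sizes[pure])
  }
  list(labels = labels, sizes = sizes, biggest = max(sizes),
       biggest_passive = biggest_passive)
}

pair_keys <- function(table) {
  ok <- !table$anomaly & !is.na(table$L_sep)
  paste(table$i[ok], table$j[ok], sep = ">")
}

#' Threading gain and loss between two times
#'
#' Set differences of the directed threaded-pair sets:
#' \eqn{\Delta n^+ = |T(t+\Delta t) \setminus T(t)|},
#' \eqn{\Delta n^- = |T(t) \setminus T(t+\Delta t)|}.
#'
#' @param T_t,T_next threaded pair sets: `"threading_table"`s or character
#'   vectors of directed pair keys (`"i>j"`).
#' @return named vector `c(gain = ..., loss = ...)`.
#' @export
threading_gain_loss <- function(T_t, T_next) {
  a <- if (inherits(T_t, "data.frame")) pair_keys(T_t) else T_t
  b <- if (inherits(T_next, "data.frame")) pair_keys(T_next) else T_next
  c(gain = length(setdiff(b, a)), loss = length(setdiff(a, b)))
}

#' Threading existence correlation
#'
#' \eqn{\Phi(t, t_0)}: the fraction of pairs threaded at `t0` that are also
#' threaded at `t0 + t` (presence-based: a pair that unthreads and
#' re-threads still correlates).  \eqn{\Phi(0, t_0) = 1}.
#'
#' @param series list of pair-key sets (character vectors), one per frame.
#' @param t0 frame index of the time origin.
#' @return data.frame with columns `lag` (frames) and `phi`, or `NULL` when
#'   no pair is threaded at `t0`.
#' @export
threading_correlation <- function(series, t0 = 1) {
  base <- series[[t0]]
  if (!length(base)) return(NULL)
  lags <- 0:(length(series) - t0)
  phi <- vapply(lags, function(l)
    mean(base %in% series[[t0 + l]]), numeric(1))
  data.frame(lag = lags, phi = phi)
}

#' Threading survival-time distribution
#'
#' For every pair threaded at `t0`, the waiting time (in frames) until it
#' first unthreads.  Pairs that never unthread within the analysed window
#' accumulate in the final bin (reported with `censored = TRUE`).
#'
#' @inheritParams threading_correlation
#' @return data.frame with `lag`, `prob`, `censored`, or `NULL`.
#' @export
survival_distribution <- function(series, t0 = 1) {
  base <- series[[t0]]
  if (!length(base)) return(NULL)
  nlag <- as.integer(length(series) - t0)
  if (nlag < 1) stop("need at least one frame after t0")
  wait <- vapply(base, function(p) {
    for (l in seq_len(nlag)) if (!(p %in% series[[t0 + l]])) return(l)
    nlag + 1L # censored: survived the whole window
  }, integer(1))
  counts <- tabulate(wait, nbins = nlag + 1L)
  data.frame(lag = seq_len(nlag + 1L), prob = counts / length(base),
             censored = c(rep(FALSE, nlag), TRUE))
}

#' Mean number of threaded neighbours
#'
#' Total number of directed threadings in the system divided by the number
#' of rings, \eqn{n_{tn} = n_{th}/M}.
#'
#' @param table a `"threading_table"`.
#' @param M number of rings.
#' @return numeric scalar.
#' @export
threaded_neighbor_count <- function(table, M = attr(table, "M")) {
  length(pair_keys(table)) / M
}

#' Write / read a threading table as tab-separated text
#' @param table a `"threading_table"`.
#' @param path file path.
#' @export
write_threading_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param M ring count to restore on the read table.
#' @rdname write_threading_table
#' @export
read_threading_table <- function(path, M = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  class(df) <- c("threading_table", "data.frame")
  attr(df, "M") <- M %||% max(df$i, df$j, 0)
  df
}
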