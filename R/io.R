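#' Write a melt state as a LAMMPS data file
#'
#' Molecular-style data file with `Atoms`, `Velocities`, `Bonds` and
#' `Angles` sections; atom type 1 = cold, 2 = hot; image flags included.
#'
#' @param state a [melt_state()].
#' @param path output file.
#' @export
write_lammps_data <- function(state, path) {
  n <- nrow(state$pos)
  con <- file(path, "w")
  on.exit(close(con))
  L <- state$box
  writeLines(c("ring melt data file",
               "",
               sprintf("%d atoms", n),
               sprintf("%d bonds", nrow(state$bonds)),
               sprintf("%d angles", nrow(state$angles)),
               "",
               "2 atom types", "1 bond types", "1 angle types",
               "",
               sprintf("0.0 %.10g xlo xhi", L[1]),
               sprintf("0.0 %.10g ylo yhi", L[2]),
               sprintf("0.0 %.10g zlo zhi", L[3]),
               "",
               "Masses", "",
               sprintf("1 %.10g", state$params$mass),
               sprintf("2 %.10g", state$params$mass),
               "",
               "Atoms # molecular", ""), con)
  writeLines(sprintf("%d %d %d %.10g %.10g %.10g %d %d %d",
                     seq_len(n), state$ring, ifelse(state$hot, 2L, 1L),
                     state$pos[, 1], state$pos[, 2], state$pos[, 3],
                     state$img[, 1], state$img[, 2], state$img[, 3]), con)
  writeLines(c("", "Velocities", ""), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(n),
                     state$vel[, 1], state$vel[, 2], state$vel[, 3]), con)
  writeLines(c("", "Bonds", ""), con)
  writeLines(sprintf("%d 1 %d %d", seq_len(nrow(state$bonds)),
                     state$bonds[, 1], state$bonds[, 2]), con)
  if (nrow(state$angles)) {
    writeLines(c("", "Angles", ""), con)
    writeLines(sprintf("%d 1 %d %d %d", seq_len(nrow(state$angles)),
                       state$angles[, 1], state$angles[, 2],
                       state$angles[, 3]), con)
  }
  invisible(path)
}

#' Read a melt state from a LAMMPS data file
#'
#' Reads molecular-style data files as written by [write_lammps_data()]
#' (sections `Atoms`, `Velocities`, `Bonds`, `Angles`; image flags
#' optional).
#'
#' @param path input file.
#' @param params the [ring_params()] to attach.
#' @return A [melt_state()].
#' @export
read_lammps_data <- function(path, params) {
  lines <- readLines(path)
  num <- function(pat) as.numeric(sub(paste0("\\s*", pat, ".*"), "",
                                      grep(pat, lines, value = TRUE)[1]))
  n <- num("atoms"); nb <- num("bonds"); na <- num("angles")
  bx <- as.numeric(strsplit(trimws(grep("xlo xhi", lines, value = TRUE)[1]),
                            "\\s+")[[1]][1:2])
  by <- as.numeric(strsplit(trimws(grep("ylo yhi", lines, value = TRUE)[1]),
                            "\\s+")[[1]][1:2])
  bz <- as.numeric(strsplit(trimws(grep("zlo zhi", lines, value = TRUE)[1]),
                            "\\s+")[[1]][1:2])
  box <- c(bx[2] - bx[1], by[2] - by[1], bz[2] - bz[1])
  sec <- function(name, count, ncol_min) {
    i <- grep(paste0("^", name), lines)[1]
    if (is.na(i)) return(NULL)
    block <- lines[(i + 2):(i + 1 + count)]
    do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
  }
  at <- sec("Atoms", n, 6)
  at <- at[order(at[, 1]), , drop = FALSE]
  img <- if (ncol(at) >= 9) at[, 7:9] else matrix(0, n, 3)
  vl <- sec("Velocities", n, 4)
  vel <- if (!is.null(vl)) {
    vl <- vl[order(vl[, 1]), , drop = FALSE]
    vl[, 2:4]
  } else matrix(0, n, 3)
  bd <- sec("Bonds", nb, 4)
  an <- if (na > 0) sec("Angles", na, 5) else NULL
  ring <- as.integer(at[, 2])
  M <- max(ring)
  # cyclic iff each molecule has as many bonds as atoms
  bonds <- matrix(as.integer(bd[, 3:4]), ncol = 2)
  bc <- tabulate(ring[bonds[, 1]], M)
  cyclic <- bc == tabulate(ring, M)
  melt_state(at[, 4:6], matrix(as.integer(img), ncol = 3), vel, box,
             hot = at[, 3] == 2, ring = ring, cyclic = cyclic,
             bonds = bonds,
             angles = if (is.null(an)) matrix(0L, 0, 3) else
               matrix(as.integer(an[, 3:5]), ncol = 3),
             params = params)
}

#' Write a trajectory as LAMMPS dump text
#'
#' One `ITEM: TIMESTEP` block per frame with
#' `ATOMS id mol type x y z ix iy iz` (wrapped coordinates plus image
#' flags).
#'
#' @param traj a [melt_trajectory()].
#' @param path output file.
#' @export
write_lammps_dump <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  F <- dim(traj$pos)[1]; n <- dim(traj$pos)[2]
  L <- traj$box
  dt <- traj$params$dt %||% 1
  for (f in seq_len(F)) {
    pos <- traj$pos[f, , ]
    wrapped <- pos %% rep(L, each = n)
    img <- round((pos - wrapped) / rep(L, each = n))
    writeLines(c("ITEM: TIMESTEP",
                 sprintf("%d", round(traj$times[f] / dt)),
                 "ITEM: NUMBER OF ATOMS",
                 sprintf("%d", n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0.0 %.10g", L[1]),
                 sprintf("0.0 %.10g", L[2]),
                 sprintf("0.0 %.10g", L[3]),
                 "ITEM: ATOMS id mol type x y z ix iy iz"), con)
    writeLines(sprintf("%d %d %d %.8g %.8g %.8g %d %d %d",
                       seq_len(n), traj$ring, ifelse(traj$hot, 2L, 1L),
                       wrapped[, 1], wrapped[, 2], wrapped[, 3],
                       img[, 1], img[, 2], img[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS dump trajectory
#'
#' Accepts `x y z` (+ optional `ix iy iz` image flags) or scaled
#' `xs ys zs` coordinate columns; unwraps using the image flags when
#' present.
#'
#' @param path dump file.
#' @param params [ring_params()] for time reconstruction (`dt`).
#' @return A [melt_trajectory()].
#' @export
read_lammps_dump <- function(path, params) {
  lines <- readLines(path)
  starts <- grep("^ITEM: TIMESTEP", lines)
  frames <- list(); times <- numeric(0)
  hot <- NULL; ring <- NULL; box <- NULL
  for (s in starts) {
    step <- as.numeric(lines[s + 1])
    n <- as.integer(lines[s + 3])
    bb <- do.call(rbind, lapply(strsplit(trimws(lines[s + 5:7]), "\\s+"),
                                as.numeric))
    box <- bb[, 2] - bb[, 1]
    hdr <- strsplit(sub("ITEM: ATOMS ", "", lines[s + 8]), "\\s+")[[1]]
    block <- lines[s + 8 + seq_len(n)]
    d <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    colnames(d) <- hdr
    d <- d[order(d[, "id"]), , drop = FALSE]
    if (all(c("x", "y", "z") %in% hdr)) {
      pos <- d[, c("x", "y", "z")]
    } else if (all(c("xs", "ys", "zs") %in% hdr)) {
      pos <- d[, c("xs", "ys", "zs")] * rep(box, each = n)
    } else stop("dump file lacks x/y/z or xs/ys/zs columns")
    if (all(c("ix", "iy", "iz") %in% hdr))
      pos <- pos + d[, c("ix", "iy", "iz")] * rep(box, each = n)
    frames[[length(frames) + 1]] <- pos
    times <- c(times, step * params$dt)
    if (is.null(hot)) {
      hot <- if ("type" %in% hdr) d[, "type"] == 2 else rep(FALSE, n)
      ring <- if ("mol" %in% hdr) as.integer(d[, "mol"]) else rep(1L, n)
    }
  }
  pos <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) pos[f, , ] <- frames[[f]]
  melt_trajectory(pos = pos, vel = NULL, times = times, box = box,
                  hot = hot, ring = ring,
                  cyclic = rep(TRUE, max(ring)), params = params)
}

#' Write / read XYZ coordinates
#'
#' Plain XYZ: element column encodes the temperature label (`C` cold,
#' `H` hot).  `read_xyz()` returns the coordinate matrix (one frame) or a
#' list of frames.
#'
#' @param state a [melt_state()] (or matrix of coordinates).
#' @param path file path.
#' @export
write_xyz <- function(state, path) {
  pos <- if (inherits(state, "melt_state")) unwrap_abs(state) else state
  lab <- if (inherits(state, "melt_state"))
    ifelse(state$hot, "H", "C") else rep("C", nrow(pos))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%d", nrow(pos)), "ring melt frame"), con)
  writeLines(sprintf("%s %.8g %.8g %.8g", lab, pos[, 1], pos[, 2], pos[, 3]),
             con)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- as.integer(trimws(lines[i]))
    block <- lines[i + 2 + 0:(n - 1)]
    d <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                               function(z) as.numeric(z[2:4])))
    out[[length(out) + 1]] <- d
    i <- i + 2 + n
  }
  if (length(out) == 1) out[[1]] else out
}

#' Export / import a triangulated surface (OFF and PLY)
#'
#' ASCII OFF / PLY meshes for external inspection of minimal surfaces.
#'
#' @param surface a `"ring_surface"`.
#' @param path file path (`.off` or `.ply` chosen by `format`).
#' @param format `"off"` or `"ply"`.
#' @export
write_surface <- function(surface, path, format = c("off", "ply")) {
  format <- match.arg(format)
  V <- surface$V; tri <- surface$tri
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "off") {
    writeLines(c("OFF", sprintf("%d %d 0", nrow(V), nrow(tri))), con)
    writeLines(sprintf("%.8g %.8g %.8g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", tri[, 1] - 1L, tri[, 2] - 1L,
                       tri[, 3] - 1L), con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(tri)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.8g %.8g %.8g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", tri[, 1] - 1L, tri[, 2] - 1L,
                       tri[, 3] - 1L), con)
  }
  invisible(path)
}

#' @param nb boundary vertex count to restore (surfaces written by
#'   [write_surface()] store boundary vertices first).
#' @rdname write_surface
#' @export
read_surface <- function(path, nb) {
  lines <- readLines(path)
  if (identical(lines[1], "OFF")) {
    counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- counts[1]; nf <- counts[2]
    V <- do.call(rbind, lapply(strsplit(trimws(lines[2 + 1:nv]), "\\s+"),
                               as.numeric))
    Tm <- do.call(rbind, lapply(strsplit(trimws(lines[2 + nv + 1:nf]), "\\s+"),
                                as.integer))
  } else {
    nv <- as.integer(sub("element vertex ", "",
                         grep("element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("element face", lines, value = TRUE)))
    h <- grep("end_header", lines)
    V <- do.call(rbind, lapply(strsplit(trimws(lines[h + 1:nv]), "\\s+"),
                               as.numeric))
    Tm <- do.call(rbind, lapply(strsplit(trimws(lines[h + nv + 1:nf]), "\\s+"),
                                as.integer))
  }
  structure(list(V = V[, 1:3, drop = FALSE],
                 tri = Tm[, 2:4, drop = FALSE] + 1L, nb = nb),
            class = "ring_surface")
}
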