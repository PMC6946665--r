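test_that("radius of gyration matches hand-computable configurations", {
  # 4 monomers at unit-square corners: R_g = sqrt(1/2)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)) + 3
  topo <- ringmelt:::ring_topology(1, 4)
  st <- melt_state(sq, matrix(0L, 4, 3), matrix(0, 4, 3), c(10, 10, 10),
                   hot = rep(FALSE, 4), ring = rep(1L, 4), cyclic = TRUE,
                   bonds = topo$bonds, angles = topo$angles,
                   params = ring_params(N = 4, M = 1))
  expect_equal(radius_of_gyration(st), sqrt(0.5), tolerance = 1e-12)
  # coincident monomers: zero
  st0 <- st
  st0$pos[] <- 3
  expect_equal(radius_of_gyration(st0), 0)
  # segment R_g of a straight rod: closed form s^2 l^2 variance
  rod <- labelled_ring_state(64)
  # whole-ring value positive and finite
  expect_gt(radius_of_gyration(rod, segment = 8), 0)
})

test_that("g3 vanishes at t = 0 and for rigid co-moving systems", {
  tr <- brownian_trajectory(M = 20, n_frames = 30, seed = 7)
  g <- g3(tr)
  expect_equal(g$g3[1], 0)
  # rigid uniform translation: system-COM frame removes all displacement
  pos <- array(0, c(10, 15, 3))
  set.seed(8)
  base <- matrix(runif(45, 0, 10), 15, 3)
  for (f in 1:10) pos[f, , ] <- base + (f - 1) * 0.7
  g2 <- g3(synthetic_com_trajectory(pos))
  expect_lt(max(g2$g3), 1e-20)
})

test_that("g3 of independent Brownian rings has the Einstein slope", {
  D <- 0.8
  tr <- brownian_trajectory(M = 300, n_frames = 300, dt_frame = 1, D = D,
                            seed = 9)
  g <- g3(tr)
  slope <- mean((g$g3 / g$t)[g$t >= 100])
  expect_equal(slope, 6 * D * (1 - 1 / 300), tolerance = 0.08)
  fit <- fit_power_law(g$t, g$g3, window = c(3, 299))
  expect_equal(fit$exponent, 1, tolerance = 0.05)
})

test_that("self-ISF equals 1 at t = 0, for frozen systems, and the Gaussian form", {
  M <- 500; s <- 1.1
  pos <- array(0, c(3, M, 3))
  set.seed(10)
  pos[1, , ] <- matrix(runif(3 * M, 0, 60), M, 3)
  pos[2, , ] <- pos[1, , ] # frozen
  pos[3, , ] <- pos[1, , ] + matrix(rnorm(3 * M, 0, s), M, 3)
  tr <- synthetic_com_trajectory(pos, box = c(60, 60, 60))
  for (q in c(0.4, 0.8, 1.3)) {
    isf <- self_isf(tr, q)
    expect_equal(isf$Fs[1], 1)
    expect_equal(isf$Fs[2], 1, tolerance = 1e-12)
    expect_equal(isf$Fs[3], exp(-q^2 * s^2 / 2), tolerance = 0.08)
  }
  expect_error(self_isf(tr, 2 * pi / 60 * 0.4), "wavevector")
})

test_that("small-q ISF expansion matches g3: 1 - F_s ~ q^2 g3 / 6", {
  tr <- brownian_trajectory(M = 600, n_frames = 12, dt_frame = 1, D = 0.05,
                            box = c(150, 150, 150), seed = 11)
  g <- g3(tr)
  q <- 0.15 # q * typical displacement stays below 0.3
  isf <- self_isf(tr, q, shell = 0.05)
  late <- nrow(g)
  expect_equal(1 - isf$Fs[late], q^2 * g$g3[late] / 6, tolerance = 0.05)
})

test_that("non-ergodicity parameter: frozen, diffusive and q -> 0 limits", {
  M <- 300
  pos <- array(0, c(6, M, 3))
  set.seed(12)
  pos[1, , ] <- matrix(runif(3 * M, 0, 40), M, 3)
  for (f in 2:6) pos[f, , ] <- pos[1, , ]
  frozen <- synthetic_com_trajectory(pos, box = c(40, 40, 40))
  fq <- nonergodicity_parameter(frozen, q_grid = c(0.5, 1, 2))
  expect_true(all(abs(fq$f - 1) < 1e-12))
  diffusive <- brownian_trajectory(M = 300, n_frames = 80, D = 2, seed = 13,
                                   box = c(40, 40, 40))
  fq2 <- nonergodicity_parameter(diffusive, q_grid = c(1, 2))
  expect_true(all(abs(fq2$f) < 0.1))
  # bounded displacements: f(q -> 0) -> 1
  wig <- pos
  set.seed(14)
  for (f in 2:6) wig[f, , ] <- pos[1, , ] + matrix(rnorm(3 * M, 0, 0.3), M, 3)
  fq3 <- nonergodicity_parameter(synthetic_com_trajectory(wig,
                                                          box = c(40, 40, 40)),
                                 q_grid = 0.16)
  expect_gt(fq3$f, 0.95)
})

test_that("EB vanishes for identical trajectories and follows the Brownian law", {
  # identical rings: zero variance
  pos <- array(0, c(20, 5, 3))
  set.seed(15)
  path <- apply(matrix(rnorm(60), 20, 3), 2, cumsum)
  for (m in 1:5) pos[, m, ] <- path
  tr0 <- synthetic_com_trajectory(pos)
  eb0 <- ergodicity_breaking(tr0, Delta = 2, t_grid = c(10, 19))
  expect_true(all(eb0$EB == 0))
  # Brownian: EB = (4/3)(Delta/t)/3 for 3d displacements
  tr <- brownian_trajectory(M = 400, n_frames = 400, D = 1, seed = 16)
  eb <- ergodicity_breaking(tr, Delta = 4, t_grid = c(40, 100, 200, 399))
  theory <- (4 / 9) * 4 / eb$t
  expect_true(all(eb$EB / theory > 1 / 1.5 & eb$EB / theory < 1.5))
  # monotone decay ~ t^-1
  fit <- fit_power_law(eb$t, eb$EB)
  expect_equal(fit$exponent, -1, tolerance = 0.25)
  # rotation invariance
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  posR <- tr$pos
  for (f in seq_len(dim(posR)[1])) posR[f, , ] <- tr$pos[f, , ] %*% t(R)
  ebR <- ergodicity_breaking(synthetic_com_trajectory(posR), Delta = 4,
                             t_grid = c(100, 399))
  expect_equal(ebR$EB, eb$EB[c(2, 4)], tolerance = 1e-9)
  expect_error(ergodicity_breaking(tr, Delta = 4, t_grid = 3),
               "exceed the lag")
})

test_that("cold-hot vector magnitude and directionality behave as defined", {
  # two-monomer rings: one hot, one cold monomer each
  M <- 40; F <- 6
  set.seed(17)
  posm <- array(0, c(F, 2 * M, 3))
  base <- matrix(runif(3 * M, 0, 20), M, 3)
  ch_dir <- matrix(rnorm(3 * M), M, 3)
  ch_dir <- ch_dir / sqrt(rowSums(ch_dir^2))
  for (f in 1:F) {
    com <- base + (f - 1) * 0.5 * ch_dir # displacement along ch
    posm[f, seq(1, 2 * M, 2), ] <- com + 0.8 * ch_dir # hot
    posm[f, seq(2, 2 * M, 2), ] <- com - 0.8 * ch_dir # cold
  }
  tr <- melt_trajectory(pos = posm, vel = NULL, times = 0:(F - 1),
                        box = c(100, 100, 100),
                        hot = rep(c(TRUE, FALSE), M),
                        ring = rep(seq_len(M), each = 2),
                        cyclic = rep(TRUE, M),
                        params = ring_params(N = 2, M = M, N_h = 1))
  ch <- cold_hot_vector(tr, Delta = 1)
  expect_equal(ch$magnitude$ch, rep(1.6, F), tolerance = 1e-9)
  # COM subtraction leaves displacements d = 0.5*ch_dir - drift; with random
  # directions the drift is small: correlation near 1
  expect_gt(min(ch$correlation$corr), 0.9)
  # isotropic displacements: correlation ~ 0 within 3/sqrt(n)
  pos2 <- posm
  set.seed(18)
  for (f in 2:F) {
    kick <- matrix(rnorm(3 * M, 0, 0.5), M, 3)
    pos2[f, seq(1, 2 * M, 2), ] <- pos2[f - 1, seq(1, 2 * M, 2), ] + kick
    pos2[f, seq(2, 2 * M, 2), ] <- pos2[f - 1, seq(2, 2 * M, 2), ] + kick
  }
  tr2 <- tr
  tr2$pos <- pos2
  ch2 <- cold_hot_vector(tr2, Delta = 1)
  expect_lt(abs(mean(ch2$correlation$corr)), 3 / sqrt(M * (F - 1)))
  # fully passive ring: excluded with a warning
  tr3 <- tr
  tr3$hot[1:2] <- FALSE
  expect_warning(cold_hot_vector(tr3), "excluded")
})

test_that("internal distances recover rod and random-walk scaling", {
  # straight rod: R^2(s) = (s l)^2, exponent 2 (nu = 1)
  rod <- matrix(0, 64, 3)
  rod[, 1] <- 0.97 * (0:63)
  st <- melt_state(rod + 100, matrix(0L, 64, 3), matrix(0, 64, 3),
                   c(400, 400, 400), hot = rep(FALSE, 64),
                   ring = rep(1L, 64), cyclic = FALSE,
                   bonds = cbind(1:63, 2:64), angles = matrix(0L, 0, 3),
                   params = ring_params(N = 64, M = 1))
  id <- internal_distances(st, "all", s = c(2, 4, 8, 16, 32),
                           fit_window = c(2, 32))
  expect_equal(attr(id, "nu"), 1, tolerance = 1e-6)
  expect_equal(id$R2, (0.97 * id$s)^2, tolerance = 1e-9)
  # freely-jointed closed rings: nu = 1/2 at intermediate s
  set.seed(19)
  Nfj <- 256; Mfj <- 30
  pos <- NULL
  for (m in seq_len(Mfj)) {
    steps <- matrix(rnorm(3 * Nfj), Nfj, 3)
    steps <- steps / sqrt(rowSums(steps^2))
    steps <- sweep(steps, 2, colMeans(steps)) # close the loop
    pos <- rbind(pos, apply(steps, 2, cumsum) + 1000)
  }
  topo <- ringmelt:::ring_topology(Mfj, Nfj)
  stf <- melt_state(pos, matrix(0L, Mfj * Nfj, 3), matrix(0, Mfj * Nfj, 3),
                    c(4000, 4000, 4000), hot = rep(FALSE, Mfj * Nfj),
                    ring = rep(seq_len(Mfj), each = Nfj),
                    cyclic = rep(TRUE, Mfj), bonds = topo$bonds,
                    angles = topo$angles,
                    params = ring_params(N = Nfj, M = Mfj, r_max = 1e6))
  idf <- internal_distances(stf, "all", s = c(4, 6, 9, 13, 18),
                            fit_window = c(4, 18))
  # random-walk ring: R^2(s) = s (1 - s/N) per unit bond
  expect_equal(idf$R2, idf$s * (1 - idf$s / Nfj), tolerance = 0.05)
  expect_lt(abs(attr(idf, "nu") - 0.5), 0.07)
  # hot-block selection errors when s exceeds the block
  sth <- labelled_ring_state(64, hot_arc = 1:8)
  expect_silent(internal_distances(sth, "hot", s = c(2, 4), fit_window = c(2, 4)))
  expect_error(internal_distances(sth, "hot", s = c(2, 20),
                                  fit_window = c(2, 20)), "block")
})

test_that("displacement kurtosis separates Gaussian from Laplace dynamics", {
  trG <- kick_trajectory(300, 120, function(n) rnorm(n), seed = 20)
  dG <- displacement_distribution(trG, Delta = 1)
  expect_lt(abs(dG$kurtosis), 0.2)
  rlap <- function(n) {
    u <- runif(n) - 0.5
    -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
  }
  trL <- kick_trajectory(300, 120, rlap, seed = 21)
  dL <- displacement_distribution(trL, Delta = 1)
  expect_equal(dL$kurtosis, 3, tolerance = 0.5)
  # isotropy: same statistics on each axis
  k3 <- vapply(1:3, function(a)
    displacement_distribution(trG, Delta = 1, axis = a)$kurtosis, numeric(1))
  expect_lt(max(abs(k3)), 0.25)
})

test_that("hot segment neighbour counting matches closed form and MC", {
  # hand geometry: two hot COMs at distance 3 < 3.25
  st <- labelled_ring_state(16, hot_arc = 1:4, M = 2) # hot COMs 2 sigma apart
  expect_equal(hot_neighbor_count(st), 1)
  # single active ring: zero
  st1 <- labelled_ring_state(16, hot_arc = 1:4, M = 1)
  expect_equal(hot_neighbor_count(st1), 0)
  # uniform expectation at production geometry ~ 0.3
  pp <- ring_params(N = 400, M = 1600, N_h = 50)
  expect_equal(uniform_neighbor_expectation(pp, 3.25), 0.3, tolerance = 0.02)
  # Monte-Carlo cross-check of the closed form
  set.seed(22)
  L <- (1600 * 400 / 0.85)^(1 / 3)
  reps <- vapply(1:5, function(i) {
    pts <- matrix(runif(3 * 1600, 0, L), 1600, 3)
    ringmelt:::uniform_neighbor_count(pts, c(L, L, L), 3.25)
  }, numeric(1))
  expect_equal(mean(reps), uniform_neighbor_expectation(pp, 3.25),
               tolerance = 0.05)
})

test_that("structure factor shows ideal-gas and Bragg limits", {
  set.seed(23)
  L <- 20
  pts <- matrix(runif(3 * 600, 0, L), 600, 3)
  sq <- structure_factor(pts, c(L, L, L), q_max = 6)
  expect_true(all(sq$S >= 0))
  expect_equal(mean(sq$S[sq$q > 3]), 1, tolerance = 0.15)
  # simple cubic lattice, spacing a = 2: Bragg peak at 2 pi / a
  a <- 2
  g <- as.matrix(expand.grid(0:9, 0:9, 0:9)) * a
  sqb <- structure_factor(g, c(20, 20, 20), q_max = 4, nbins = 80)
  expect_equal(attr(sqb, "q_star"), pi, tolerance = 0.05)
})

test_that("fractional Gaussian trajectories recover their MSD exponent", {
  for (alpha in c(0.5, 1.3)) {
    tr <- fgn_trajectory(M = 600, n_frames = 120, alpha = alpha, seed = 24)
    g <- g3(tr)
    fit <- fit_power_law(g$t, g$g3, window = c(2, 80))
    expect_lt(abs(fit$exponent - alpha), 0.03)
  }
})

test_that("observables are invariant under global translation", {
  tr <- brownian_trajectory(M = 50, n_frames = 40, seed = 25)
  tr2 <- tr
  tr2$pos <- tr$pos + 13.7
  expect_equal(g3(tr2)$g3, g3(tr)$g3, tolerance = 1e-9)
  expect_equal(ergodicity_breaking(tr2, 2, t_grid = c(20, 39))$EB,
               ergodicity_breaking(tr, 2, t_grid = c(20, 39))$EB,
               tolerance = 1e-9)
  expect_equal(displacement_distribution(tr2, 1)$kurtosis,
               displacement_distribution(tr, 1)$kurtosis, tolerance = 1e-9)
})
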