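free_gas <- function(M, hot_frac = 0, L = 200) {
  p <- ring_params(N = 1, M = M, N_h = 0, rho = 1e-6)
  set.seed(1)
  pos <- matrix(runif(3 * M, 0, L), M, 3)
  melt_state(pos, matrix(0L, M, 3), matrix(0, M, 3), c(L, L, L),
             hot = seq_len(M) <= hot_frac * M, ring = seq_len(M),
             cyclic = rep(TRUE, M), bonds = matrix(0L, 0, 2),
             angles = matrix(0L, 0, 3), params = p)
}

test_that("each thermostat channel is Maxwell-Boltzmann at its own temperature", {
  st <- free_gas(500, hot_frac = 0.5)
  st <- md_advance(st, 3000, seed = 21)
  # sample every 4.5 tau = 3 friction times so velocities decorrelate
  st <- md_advance(st, 81000, seed = 21, stride = 900, step_offset = 3000)
  fr <- attr(st, "frames")
  vh <- as.numeric(fr$vel[, st$hot, ])
  vc <- as.numeric(fr$vel[, !st$hot, ])
  expect_equal(mean(vh^2), 3, tolerance = 0.03)
  expect_equal(mean(vc^2), 1, tolerance = 0.03)
  # KS against the exact Gaussian, ~50k samples per channel
  expect_gt(suppressWarnings(ks.test(vh, "pnorm", sd = sqrt(3)))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(vc, "pnorm", sd = 1))$p.value, 0.01)
})

test_that("a free monomer diffuses with the Einstein slope 6T/(m gamma)", {
  st <- free_gas(400)
  st <- md_advance(st, 2000, seed = 22) # velocity equilibration
  st <- md_advance(st, 40000, seed = 22, stride = 400, step_offset = 2000)
  fr <- attr(st, "frames")
  traj <- synthetic_com_trajectory(fr$pos, dt_frame = 400 * st$params$dt)
  g <- g3(traj)
  slope <- mean((g$g3 / g$t)[g$t > 20])
  # system-COM subtraction rescales by (1 - 1/M)
  expect_equal(slope, 9 * (1 - 1 / 400), tolerance = 0.1)
})

test_that("T = 0 dynamics is purely dissipative", {
  st <- free_gas(100)
  st$params$T_c <- 1e-12 # zero-noise limit (T_c > 0 required by validation)
  set.seed(3)
  st$vel <- matrix(rnorm(300), 100, 3)
  ke <- numeric(6)
  ke[1] <- sum(st$vel^2)
  for (i in 2:6) {
    st <- md_advance(st, 200, seed = 23, step_offset = 200 * i)
    ke[i] <- sum(st$vel^2)
  }
  expect_true(all(diff(ke) < 0))
})

test_that("identical (state, n_steps, seed) reproduce bitwise-identical output", {
  st <- small_melt()
  a <- md_advance(st, 500, seed = 77)
  b <- md_advance(st, 500, seed = 77)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  c2 <- md_advance(st, 500, seed = 78)
  expect_false(identical(a$pos, c2$pos))
})

test_that("equilibrium melt at T_h = T_c = 1 satisfies equipartition", {
  st <- small_melt() # all cold
  st <- md_advance(st, 3000, seed = 24)
  st <- md_advance(st, 9000, seed = 24, stride = 150, step_offset = 3000)
  fr <- attr(st, "frames")
  Tkin <- mean(fr$vel^2)
  expect_equal(Tkin, 1, tolerance = 0.03)
})

test_that("bonds never approach crossing length in production dynamics", {
  st <- small_melt()
  st <- assign_activity(st, N_h = 8, M_a = 4, seed = 3)
  worst <- 0
  for (i in 1:10) {
    st <- md_advance(st, 2000, seed = 25, step_offset = 2000 * i)
    worst <- max(worst, max(ringmelt:::bond_lengths(st)))
  }
  expect_lt(worst, 1.4)
})

test_that("overstretched bonds abort with the last valid state attached", {
  N <- 4
  pos <- cbind(c(0, 1.49, 3.5, 4.5), 0.5, 0.5) + 5
  topo <- list(bonds = cbind(1:3, 2:4), angles = matrix(0L, 0, 3))
  st <- melt_state(pos, matrix(0L, N, 3), matrix(0, N, 3), c(20, 20, 20),
                   hot = rep(FALSE, N), ring = rep(1L, N), cyclic = FALSE,
                   bonds = topo$bonds, angles = topo$angles,
                   params = ring_params(N = N, M = 1, T_h = 50, T_c = 50))
  st$vel[1, 1] <- -30 # rip the first bond
  err <- tryCatch(md_advance(st, 100, seed = 26), condition = function(e) e)
  expect_s3_class(err, "ringmelt_overstretch")
  expect_s3_class(err$state, "melt_state")
})

test_that("run_protocol bookkeeping: strides, cut phase, zero-duration runs", {
  st <- small_melt()
  st <- assign_activity(st, N_h = 4, M_a = 4, seed = 4)
  traj <- run_protocol(st, list(
    list(phase = "equilibrate", duration = 5),
    list(phase = "active", duration = 20, stride = 2)), seed = 31)
  expect_equal(dim(traj$pos)[1], 11) # duration / stride + 1 frames
  expect_equal(diff(traj$times)[1], 2)
  expect_equal(traj$times[1], 0) # the activity-onset frame is t0 = 0
  # cut phase: topology becomes linear and the run continues
  traj2 <- run_protocol(st, list(
    list(phase = "active", duration = 5, stride = 2.5),
    list(phase = "cut", duration = 10, stride = 2.5)), seed = 32)
  expect_false(any(traj2$state$cyclic))
  expect_equal(nrow(traj2$state$bonds), 4 * 31)
  expect_gt(dim(traj2$pos)[1], 1)
  # zero-duration schedule: single-frame trajectory
  traj3 <- run_protocol(st, list(list(phase = "active", duration = 0)),
                        seed = 33)
  expect_equal(dim(traj3$pos)[1], 1)
})

test_that("kinetic_temperatures reports channels and degenerate cases", {
  st <- small_melt()
  st$vel[] <- 0
  expect_equal(unname(kinetic_temperatures(st)),
               c(NA_real_, 0)) # no hot monomers; cold channel zero
  st$hot[1:10] <- TRUE
  set.seed(5)
  st$vel <- matrix(rnorm(length(st$vel)), ncol = 3) # T = 1 draw
  tt <- kinetic_temperatures(st)
  expect_equal(unname(tt["T_cold"]), 1, tolerance = 0.15)
})
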