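test_that("builder hits the target density and box volume exactly", {
  p <- ring_params(N = 16, M = 2)
  expect_equal(prod(ringmelt:::melt_box(p)), 2 * 16 / 0.85)
  st <- small_melt()
  expect_equal(nrow(st$pos) / prod(st$box), st$params$rho)
})

test_that("builder output is nonconcatenated, unknotted and bonded below r_max", {
  st <- small_melt()
  rep <- verify_topology(st)
  expect_true(rep$pass)
  expect_true(all(rep$linking == 0))
  expect_true(all(rep$knots == "unknot-consistent"))
  expect_lt(rep$bond_range[2], st$params$r_max)
})

test_that("builder is deterministic: same (params, seed) gives identical states", {
  p <- ring_params(N = 16, M = 2, N_h = 2)
  a <- build_melt(p, seed = 5, pushoff_steps = 1200, equil_steps = 500)
  b <- build_melt(p, seed = 5, pushoff_steps = 1200, equil_steps = 500)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  expect_identical(a$img, b$img)
})

test_that("Gauss linking number reproduces knot-theory invariants", {
  c1 <- circle3(64, R = 1)
  c2 <- circle3(64, R = 1, center = c(3, 0, 0))
  lk <- linking_number(c1, c2)
  expect_equal(as.integer(lk), 0L)
  # Hopf link: orthogonal circles through each other's centres
  c3 <- circle3(64, R = 1, center = c(1, 0, 0), plane = "xz")
  lkh <- linking_number(c1, c3)
  expect_equal(abs(as.integer(lkh)), 1L)
  expect_lt(abs(attr(lkh, "residual")), 0.01)
  # symmetry in arguments
  expect_equal(as.integer(linking_number(c3, c1)), as.integer(lkh))
  # touching contours are rejected
  expect_error(linking_number(c1, c1 + 1e-9), "ill-conditioned")
})

test_that("topology verification flags injected defects", {
  # concatenated pair injected by hand
  N <- 64
  pos <- rbind(circle3(N, R = 1, center = c(5, 5, 5)),
               circle3(N, R = 1, center = c(6, 5, 5), plane = "xz"))
  topo <- ringmelt:::ring_topology(2, N)
  st <- melt_state(pos, matrix(0L, 2 * N, 3), matrix(0, 2 * N, 3),
                   c(20, 20, 20), hot = rep(FALSE, 2 * N),
                   ring = rep(1:2, each = N), cyclic = c(TRUE, TRUE),
                   bonds = topo$bonds, angles = topo$angles,
                   params = ring_params(N = N, M = 2, r_max = 1.5))
  rep <- verify_topology(st, knot_screen = FALSE)
  expect_false(rep$pass)
  expect_equal(abs(rep$linking[1, 2]), 1)
  # bond length beyond the maximum extension is flagged
  st2 <- small_melt()
  st2$params$r_max <- 0.9 # every bond now exceeds r_max
  rep2 <- verify_topology(st2, knot_screen = FALSE)
  expect_false(rep2$bonds_ok)
  expect_false(rep2$pass)
})

test_that("activity assignment labels one contiguous arc per active ring", {
  st <- small_melt()
  N <- st$params$N
  st1 <- assign_activity(st, N_h = 5, M_a = 2, seed = 9)
  perring <- split(st1$hot, st1$ring)
  counts <- vapply(perring, sum, numeric(1))
  expect_equal(sort(unname(counts), decreasing = TRUE), c(5, 5, 0, 0))
  # contiguity on the cycle: arc has exactly one cold->hot transition
  for (h in perring[counts > 0]) {
    trans <- sum(h != c(h[-1], h[1]))
    expect_equal(trans, 2)
  }
  # N_h = 0 reproduces the equilibrium labelling
  st0 <- assign_activity(st, N_h = 0, M_a = 4, seed = 9)
  expect_false(any(st0$hot))
  # labelling survives contour rotation relabelling (arc stays contiguous)
  h <- perring[[which.max(counts)]]
  rot <- c(h[-(1:7)], h[1:7])
  expect_equal(sum(rot != c(rot[-1], rot[1])), 2)
})

test_that("cut_bonds removes the cold bond antipodal to the hot arc midpoint", {
  # hot arc at contour positions 1..50 of a 400-ring: midpoint 25.5 (1-based),
  # antipodal contour coordinate 224.5 (0-based), so the bond 225-226 in
  # 1-based indexing is removed
  st <- labelled_ring_state(400, hot_arc = 1:50)
  cut <- cut_bonds(st)
  expect_false(any(cut$cyclic))
  expect_equal(nrow(cut$bonds), 399)
  removed <- setdiff(paste(st$bonds[, 1], st$bonds[, 2]),
                     paste(cut$bonds[, 1], cut$bonds[, 2]))
  expect_equal(removed, "225 226")
  # chain ends are both cold, hot arc interior
  ord <- cut$chain_order[[1]]
  expect_false(cut$hot[ord[1]])
  expect_false(cut$hot[ord[400]])
  hotpos <- which(cut$hot[ord])
  expect_true(all(diff(hotpos) == 1)) # contiguous and interior
  expect_gt(min(hotpos), 1)
  expect_lt(max(hotpos), 400)
  # angles spanning the cut are dropped (2 per ring)
  expect_equal(nrow(cut$angles), 398)
})

test_that("cut_bonds on a fully passive melt opens every ring", {
  st <- small_melt()
  cut <- cut_bonds(st)
  expect_equal(nrow(cut$bonds), 4 * 31)
  expect_false(any(cut$cyclic))
})

test_that("ring unwrapping rejects contours winding around the torus", {
  st <- small_melt()
  expect_silent(ring_contour(st, 1))
  # a homologically wound "ring": marches once around the periodic box, so
  # the accumulated minimum-image bond vectors cannot close
  N <- 8; L <- 8
  pos <- cbind((0:(N - 1)) * L / N, 1, 1)
  topo <- ringmelt:::ring_topology(1, N)
  wind <- melt_state(pos, matrix(0L, N, 3), matrix(0, N, 3), c(L, L, L),
                     hot = rep(FALSE, N), ring = rep(1L, N), cyclic = TRUE,
                     bonds = topo$bonds, angles = topo$angles,
                     params = ring_params(N = N, M = 1))
  expect_error(ring_contour(wind, 1), "closure defect")
})
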