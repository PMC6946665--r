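# flat disc surface to pierce in controlled ways
disc_surface <- function(n = 64, R = 5) {
  minimize_area(triangulate_ring(circle3(n, R = R)))
}

test_that("piercing detection reports transversal crossings with signs", {
  surf <- disc_surface()
  # straight bond crossing the disc perpendicular: one +1 piercing
  seg <- rbind(c(0.3, 0.2, -4), c(0.3, 0.2, 4), c(8, 8, 4), c(8, 8, -4))
  pr <- find_piercings(surf, seg)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$sign, 1)
  expect_equal(pr$bond, 0)
  # unlinked hairpin passing through and back: 2 piercings, signs cancel
  hairpin <- rbind(c(0.5, 0, 2), c(0.5, 0, -2), c(1.5, 0, -2), c(1.5, 0, 2))
  pr2 <- find_piercings(surf, hairpin)
  expect_equal(nrow(pr2), 2)
  expect_equal(sum(pr2$sign), 0)
  # Hopf-linked contour: signed sum +-1 (concatenation anomaly)
  hopf <- circle3(32, R = 3, center = c(3, 0, 0), plane = "xz")
  pr3 <- find_piercings(surf, hopf)
  expect_equal(abs(sum(pr3$sign)), 1)
})

test_that("piercings agree with an independent brute-force intersector", {
  set.seed(21)
  for (rep in 1:3) {
    cont <- circle3(24, R = 2.5) + matrix(rnorm(72, 0, 0.5), 24, 3)
    surf <- minimize_area(triangulate_ring(cont), max_iters = 150,
                          target_edge = c(1, 0.7, 1.3)[rep])
    probe <- circle3(16, R = 2, center = c(runif(1, -1, 1),
                                           runif(1, -1, 1), 0),
                     plane = "xz") + matrix(rnorm(48, 0, 0.2), 16, 3)
    a <- find_piercings(surf, probe)
    b <- brute_piercings(surf, probe)
    nb <- if (is.null(b)) 0L else nrow(b)
    expect_equal(nrow(a), nb)
    if (nb > 0) {
      expect_equal(a$bond, b$bond)
      expect_equal(a$sign, b$sign)
    }
  }
})

test_that("separation length follows the alternating parity-sum definition", {
  # 2 piercings splitting N = 400 into 100/300
  sl <- separation_length(c(0, 100), 400)
  expect_equal(sl$L_sep, 100)
  expect_equal(sl$Q, 1 / 3)
  # 4 piercings with arcs 50, 150, 70, 130 -> min(50 + 70, 150 + 130) = 120
  b4 <- c(0, 50, 200, 270)
  sl4 <- separation_length(b4, 400)
  expect_equal(sl4$L_sep, 120)
  expect_equal(sl4$Q, 120 / 280)
  expect_equal(sl4$L_sep, brute_L_sep(b4, 400))
  # equal split: Q reaches its upper bound 1
  sle <- separation_length(c(0, 200), 400)
  expect_equal(sle$L_sep, 200)
  expect_equal(sle$Q, 1)
  # odd piercing count is a concatenation anomaly
  expect_error(separation_length(c(0, 10, 20), 400), "concatenation")
  # random cases against the explicit-walk oracle
  set.seed(22)
  for (i in 1:20) {
    k <- 2 * sample(1:4, 1)
    b <- sort(sample(0:399, k))
    expect_equal(separation_length(b, 400)$L_sep, brute_L_sep(b, 400))
  }
})

test_that("threading clusters follow the cutoff rule and are monotone", {
  fake <- data.frame(time = 0, i = c(1, 2, 4), j = c(2, 3, 5),
                     n_pierce = 2, L_sep = c(30, 12, 4), Q = 0.2,
                     anomaly = FALSE)
  class(fake) <- c("threading_table", "data.frame")
  attr(fake, "M") <- 6
  cl <- threading_clusters(fake, 10)
  expect_equal(cl$biggest, 3) # {1,2,3}
  expect_equal(cl$labels[1], cl$labels[2])
  expect_equal(cl$labels[2], cl$labels[3])
  cl2 <- threading_clusters(fake, 0.5)
  expect_equal(cl2$biggest, 3)
  expect_equal(sort(cl2$sizes, decreasing = TRUE), c(3, 2, 1))
  # empty table: all singletons
  empty <- fake[0, ]
  class(empty) <- c("threading_table", "data.frame")
  attr(empty, "M") <- 6
  expect_equal(threading_clusters(empty, 1)$biggest, 1)
  # biggest cluster is non-increasing in the cutoff
  sizes <- vapply(c(0, 3, 10, 25, 40), function(lc)
    threading_clusters(fake, lc)$biggest, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # passive-only biggest cluster
  cl3 <- threading_clusters(fake, 0.5, active = c(TRUE, rep(FALSE, 5)))
  expect_equal(cl3$biggest_passive, 2) # {4,5}
})

test_that("threading gain/loss are set-difference cardinalities", {
  expect_equal(unname(threading_gain_loss(c("1>2"), c("1>2"))), c(0, 0))
  expect_equal(unname(threading_gain_loss(character(0),
                                          c("1>2", "3>4", "5>6"))), c(3, 0))
  g <- threading_gain_loss(c("1>2"), c("3>4"))
  expect_equal(unname(g), c(1, 1)) # steady-state exchange, net zero
  expect_equal(g[["gain"]] - g[["loss"]], 0)
})

test_that("threading correlation and survival match two-state Markov closed forms", {
  p_on <- 0.05; p_off <- 0.12
  series <- markov_threading_series(4000, 60, p_on, p_off, seed = 5)
  phi <- threading_correlation(series, t0 = 1)
  expect_equal(phi$phi[1], 1)
  lam <- 1 - p_on - p_off
  pinf <- p_on / (p_on + p_off)
  theory <- pinf + (1 - pinf) * lam^phi$lag
  expect_lt(max(abs(phi$phi - theory)), 0.03)
  surv <- survival_distribution(series, t0 = 1)
  geo <- p_off * (1 - p_off)^(surv$lag - 1)
  live <- !surv$censored
  expect_lt(max(abs(surv$prob[live] - geo[live])), 0.03)
  # censored mass equals the survivor fraction
  expect_equal(surv$prob[surv$censored], (1 - p_off)^(max(surv$lag) - 1),
               tolerance = 0.05)
  # degenerate cases
  all_die <- list(c("1>2", "3>4"), character(0), character(0))
  sd <- survival_distribution(all_die, 1)
  expect_equal(sd$prob[1], 1)
  persist <- list(c("1>2"), c("1>2"), c("1>2"))
  expect_true(all(threading_correlation(persist, 1)$phi == 1))
  sp <- survival_distribution(persist, 1)
  expect_equal(sp$prob[sp$censored], 1)
})

test_that("threaded neighbour count is the directed pair total over M", {
  tb <- data.frame(time = 0, i = c(1, 2), j = c(2, 1), n_pierce = 2,
                   L_sep = 5, Q = 0.1, anomaly = FALSE)
  class(tb) <- c("threading_table", "data.frame")
  attr(tb, "M") <- 10
  expect_equal(threaded_neighbor_count(tb), 2 / 10) # i>j and j>i both count
  empty <- tb[0, ]
  class(empty) <- c("threading_table", "data.frame")
  attr(empty, "M") <- 10
  expect_equal(threaded_neighbor_count(empty), 0)
})

test_that("melt threading tables satisfy the nonconcatenation parity invariant", {
  st <- threading_melt()
  found <- 0
  for (f in 1:2) {
    if (f > 1) st <- md_advance(st, 4000, seed = 61, step_offset = 4000 * f)
    tb <- analyze_threading(st)
    pr <- attr(tb, "piercings")
    for (x in pr) {
      expect_equal(nrow(x) %% 2, 0)
      expect_equal(sum(x$sign), 0)
    }
    expect_false(any(tb$anomaly))
    if (nrow(tb)) {
      expect_true(all(tb$L_sep >= 1 & tb$L_sep <= st$params$N / 2))
      expect_true(all(tb$Q > 0 & tb$Q <= 1))
      found <- found + nrow(tb)
    }
    # cluster monotonicity on the real table
    sizes <- vapply(c(0.5, 2, 4, 8), function(lc)
      threading_clusters(tb, lc, M = 27)$biggest, numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("threading tables round-trip through TSV", {
  tb <- data.frame(time = 2.5, i = 1:2, j = c(3L, 4L), n_pierce = c(2L, 4L),
                   L_sep = c(5, 7), Q = c(0.2, 0.25), anomaly = FALSE)
  class(tb) <- c("threading_table", "data.frame")
  attr(tb, "M") <- 4
  f <- tempfile(fileext = ".tsv")
  write_threading_table(tb, f)
  r <- read_threading_table(f, M = 4)
  expect_equal(as.data.frame(r), as.data.frame(tb))
})
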