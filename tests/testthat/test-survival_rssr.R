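test_that("survivor values use the strictly-larger rule", {
  sc <- survival_curve(c(1, 2, 3, 4))
  expect_equal(sc$S[sc$t == 2], 0.5)           # 2 of 4 exceed 2
  expect_equal(oracle_survival_at(c(1, 2, 3, 4), 2.5), 0.5)
  # all durations equal d: S = 1 before d, 0 at d
  sc2 <- survival_curve(c(7, 7, 7))
  expect_equal(sc2$t, c(0, 7))
  expect_equal(sc2$S, c(1, 0))
  # zero-duration CRTs carry mass at t = 0
  sc3 <- survival_curve(c(0, 0, 5))
  expect_equal(sc3$S[sc3$t == 0], 1 / 3)
})

test_that("survival curves are proper survivor functions on random CRT sets", {
  for (seed in 1:6) {
    dt <- random_table(seed = seed)
    cs <- build_crts(dt, 5)
    sc <- survival_curve(cs)
    expect_true(all(sc$S >= 0 & sc$S <= 1))
    expect_true(all(diff(sc$S) < 0))            # strictly decreasing at knots
    expect_equal(sc$S[nrow(sc)], 0)             # zero at the maximum duration
    expect_equal(sc$t[1L], 0)
    # every stored value matches the definition
    expect_equal(sc$S, vapply(sc$t, function(t)
      oracle_survival_at(cs$duration, t), 0))
  }
  expect_error(survival_curve(numeric(0)), "empty")
})

test_that("interpolation is linear inside allowed spans", {
  # raw points (0, 1.0), (10, 0.5): midpoint and quarter values
  sc <- survival_curve(c(10, 10, 20, 20))     # points (0,1),(10,.5),(20,0)
  ic <- interpolate_curve(sc, grid_step = 1, t_max = 100)
  expect_equal(ic$values[ic$t == 5], 0.75)
  expect_equal(ic$values[ic$t == 15], 0.25)
  expect_true(all(ic$defined))
})

test_that("spans wider than t_max are discarded, raw points kept", {
  # durations {200 x4, 300}: raw points (0,1), (200,0.2), (300,0)
  sc <- survival_curve(c(200, 200, 200, 200, 300))
  ic <- interpolate_curve(sc, grid_step = 1, t_max = 100)
  inside <- ic$t > 0 & ic$t < 200
  expect_false(any(ic$defined[inside]))
  expect_true(all(is.na(ic$values[inside])))
  expect_true(all(ic$defined[ic$t >= 200]))   # gap 100 <= t_max allowed
  expect_true(ic$defined[ic$t == 0])          # knots always defined
  # undefined spans are non-increasing over each contiguous defined run
  expect_true(all(diff(ic$values[ic$t >= 200]) <= 0))
})

test_that("every defined grid value equals the two-point formula", {
  for (seed in 1:6) {
    dt <- random_table(seed = seed)
    sc <- survival_curve(build_crts(dt, 4))
    ic <- interpolate_curve(sc, grid_step = 2, t_max = 7)
    want <- vapply(ic$t, function(t)
      oracle_interp_at(sc$t, sc$S, t, t_max = 7), 0)
    expect_equal(ic$values, want)
    expect_equal(ic$defined, !is.na(want))
  }
})

test_that("rssr averages squared differences over the joint defined set", {
  a <- make_interp(c(1, 0.8, 0.6, 0.4, 0.2))
  expect_equal(rssr(a, a)$rssr, 0)
  b <- make_interp(c(1, 0.8, 0.6, 0.4, 0.2) - 0.1)
  r <- rssr(a, b)
  expect_equal(r$rssr, 0.01)                  # constant offset 0.1
  expect_equal(r$n_overlap, 5L)
  # random pair matches the brute-force loop
  set.seed(42)
  for (i in 1:5) {
    va <- runif(20); vb <- runif(20)
    da <- runif(20) > 0.3; db <- runif(20) > 0.3
    if (!any(da & db)) next
    x <- make_interp(va, da); y <- make_interp(vb, db)
    expect_equal(rssr(x, y), oracle_rssr(x, y))
    # symmetry
    expect_equal(rssr(x, y)$rssr, rssr(y, x)$rssr)
  }
})

test_that("rssr ignores points where either curve is undefined", {
  a <- make_interp(c(1, 0.5, 0.25, 0.1))
  b <- make_interp(c(1, 0.4, 0.2, 0.1), defined = c(TRUE, TRUE, FALSE, TRUE))
  r <- rssr(a, b)
  expect_equal(r$n_overlap, 3L)
  expect_equal(r$rssr, ((0.1)^2 + 0^2 + 0^2) / 3)
  # adding extra undefined points changes nothing
  a2 <- make_interp(c(a$values, 0.05, 0.01), defined = c(a$defined, FALSE, FALSE))
  expect_equal(rssr(a2, b), r)
  # renormalization: duplicating the defined span leaves the mean unchanged
  a3 <- make_interp(rep(c(1, 0.5, 0.25, 0.1), 2))
  b3 <- make_interp(rep(c(1, 0.4, 0.2, 0.1), 2),
                    defined = rep(c(TRUE, TRUE, FALSE, TRUE), 2))
  expect_equal(rssr(a3, b3)$rssr, r$rssr)
})

test_that("disjoint defined sets and mismatched grids are errors", {
  a <- make_interp(c(1, 0.5), defined = c(TRUE, FALSE))
  b <- make_interp(c(1, 0.5), defined = c(FALSE, TRUE))
  expect_error(rssr(a, b), "no overlap")
  d <- make_interp(c(1, 0.5), grid_step = 2)
  expect_error(rssr(a, d), "grid step")
})

test_that("profile is zero beyond the largest same-receiver gap", {
  dt <- detection_table(rep("A", 6), rep("f", 6), c(0, 2, 5, 9, 14, 20))
  p <- rssr_profile(dt, c(7, 10, 14, 20), grid_step = 1, t_max = 50)
  expect_true(all(p$rssr[p$mbp >= 7] == 0))   # largest gap is 6
  expect_equal(detect_mbp_star(p), 7)
})

test_that("profile matches an end-to-end oracle chain on a small table", {
  dt <- detection_table(c("A", "A", "A", "B", "B", "A", "A"),
                        c("f", "f", "f", "f", "f", "g", "g"),
                        c(0, 4, 16, 30, 33, 0, 20))
  grid <- c(5, 10, 15)
  p <- rssr_profile(dt, grid, grid_step = 2, t_max = 12)
  curves <- lapply(grid, function(m) {
    cs <- oracle_crts(dt, m)
    sc <- survival_curve(cs$duration)
    xs <- seq(0, max(sc$t), by = 2)
    vals <- vapply(xs, function(t) oracle_interp_at(sc$t, sc$S, t, 12), 0)
    make_interp(vals, defined = !is.na(vals), grid_step = 2)
  })
  for (i in 1:2) {
    want <- oracle_rssr(curves[[i]], curves[[i + 1]])
    expect_equal(p$rssr[i], want$rssr)
    expect_equal(p$n_overlap[i], want$n_overlap)
  }
})

test_that("mbp_star detection finds the terminal plateau", {
  prof <- function(v, mbp = seq(100, by = 100, length.out = length(v))) {
    structure(data.frame(mbp = mbp, mbp_next = mbp + 100, rssr = v,
                         n_overlap = 10L),
              class = c("rssr_profile", "data.frame"))
  }
  expect_equal(detect_mbp_star(prof(c(1, 0.5, 0.01, 0.005, 0.004))), 300)
  expect_equal(detect_mbp_star(prof(rep(0, 5))), 100)  # all-zero: first value
  # never stabilizes: steadily climbing tail above the floor criterion
  expect_true(is.na(detect_mbp_star(prof(c(0.001, 1, 2, 3, 4)))))
  # min_run longer than the stabilized tail
  expect_true(is.na(detect_mbp_star(prof(c(1, 0.5, 0.01, 0.005, 0.004)),
                                    min_run = 4)))
  # explicit relative-to-max criterion
  expect_equal(detect_mbp_star(prof(c(1, 0.5, 0.04, 0.03, 0.02)),
                               rel_threshold = 0.05), 300)
  empty <- structure(data.frame(mbp = numeric(0), mbp_next = numeric(0),
                                rssr = numeric(0), n_overlap = integer(0)),
                     class = c("rssr_profile", "data.frame"))
  expect_error(detect_mbp_star(empty), "empty")
})
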