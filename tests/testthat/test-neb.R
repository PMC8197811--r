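test_that("interpolate_path spaces images evenly with exact endpoints", {
  p <- interpolate_path(c(0, 0), c(1, 0), 5)
  expect_equal(p$images[, 1], c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(p$images[, 2], rep(0, 5))
  q <- interpolate_path(c(-0.3, 1.7), c(0.9, -0.2), 12)
  expect_identical(q$images[1, ], c(-0.3, 1.7))
  expect_identical(q$images[12, ], c(0.9, -0.2))
  seg <- sqrt(rowSums(diff(q$images)^2))
  expect_lt(max(seg) - min(seg), 1e-12)
  expect_error(interpolate_path(c(0, 0), c(0, 0)), "differ")
  expect_error(interpolate_path(c(0, 0), c(1, 0), 3), ">= 4")
})

test_that("symmetric surrogate band converges onto the known saddle", {
  pes <- model_pes("sn2", V0 = 15.4)
  path <- neb_optimize(pes, interpolate_path(c(-1, 0), c(1, 0), 12))
  expect_true(path$converged)
  i <- locate_ts(path)
  expect_lt(abs(path$images[i, 1]), 1e-3)
  expect_equal(barrier_from_path(path, "start"), 15.4, tolerance = 1e-3)
  expect_equal(barrier_from_path(path, "end"), 15.4, tolerance = 1e-3)
  # endpoints never move
  expect_identical(path$images[1, ], c(-1, 0))
  expect_identical(path$images[12, ], c(1, 0))
  # the climbing image satisfies the saddle criterion
  rep_ts <- verify_saddle(pes, path$images[i, ], tol = 1e-3)
  expect_true(rep_ts$is_saddle)
  expect_equal(rep_ts$n_negative, 1L)
})

test_that("MB band reproduces the grid+Newton oracle saddle", {
  pts <- mb_oracle_points(400)
  minima <- pts[pts$type == "minimum", ]
  # deepest and the far (0.62, 0.03) minimum; the highest saddle between
  # them is the oracle reference for the climbing image
  m1 <- unlist(minima[which.min(minima$energy), c("x", "y")])
  m2 <- unlist(minima[which.max(minima$x), c("x", "y")])
  pes <- model_pes("muller_brown")
  path <- neb_optimize(pes, interpolate_path(m1, m2, 16))
  expect_true(path$converged)
  i <- locate_ts(path)
  saddles <- pts[pts$type == "saddle", ]
  top <- saddles[which.max(saddles$energy), ]
  expect_lt(sqrt(sum((path$images[i, ] - c(top$x, top$y))^2)), 1e-2)
  expect_equal(path$energies[i], top$energy, tolerance = 1e-2)
  expect_equal(barrier_from_path(path, "start"),
               top$energy - minima$energy[which.min(minima$energy)],
               tolerance = 1e-2)
  v <- verify_saddle(pes, path$images[i, ], tol = 1e-2)
  expect_true(v$is_saddle)
  # forward minus reverse barrier equals the endpoint energy gap
  gap <- path$energies[1] - path$energies[nrow(path$images)]
  expect_equal(barrier_from_path(path, "end") -
                 barrier_from_path(path, "start"), gap)
})

test_that("an impossible budget reports non-convergence, not an error", {
  pes <- model_pes("sn2", V0 = 15.4)
  path <- neb_optimize(pes, interpolate_path(c(-1, 0.4), c(1, 0.4), 12),
                       neb_config(max_iter = 1))
  expect_false(path$converged)
  expect_equal(path$iterations, 1L)
})

test_that("identical configs give identical iteration histories", {
  pes <- model_pes("muller_brown")
  cfg <- neb_config(max_iter = 500)
  p1 <- neb_optimize(pes, interpolate_path(c(-0.55, 1.44), c(0.62, 0.03),
                                           10), cfg)
  p2 <- neb_optimize(pes, interpolate_path(c(-0.55, 1.44), c(0.62, 0.03),
                                           10), cfg)
  expect_identical(p1$max_force_history, p2$max_force_history)
  expect_identical(p1$images, p2$images)
})

test_that("locate_ts wants a strict interior maximum", {
  p <- interpolate_path(c(0, 0), c(4, 0), 5)
  p$energies <- c(0, 2, 5, 2, 0)
  expect_equal(locate_ts(p), 3L)
  p$energies <- c(0, 1, 2, 3, 4)
  expect_error(locate_ts(p), "no interior barrier")
  p$energies <- c(0, 3, 3, 1, 0)
  expect_warning(i <- locate_ts(p), "tie")
  expect_equal(i, 2L)
})

test_that("verify_saddle rejects minima and flat regions", {
  pes <- model_pes("muller_brown")
  pts <- mb_oracle_points(400)
  m <- pts[pts$type == "minimum", ][1, ]
  v <- verify_saddle(pes, c(m$x, m$y), tol = 1e-3)
  expect_false(v$is_saddle)
  expect_equal(v$n_negative, 0L)
  flat <- structure(list(name = "flat", params = list(),
                         energy = function(x, y) 1 + 0 * x,
                         gradient = NULL), class = "model_pes")
  expect_false(verify_saddle(flat, c(0.3, 0.3), tol = 1e-3)$is_saddle)
})

test_that("endpoint relocation from a saddle finds the adjacent minima", {
  pes <- model_pes("sn2", V0 = 15.4)
  ends <- relocate_endpoints(pes, c(0, 0), displacement = 0.1)
  got <- rbind(ends$start, ends$end)
  got <- got[order(got[, 1]), ]
  expect_equal(got, rbind(c(-1, 0), c(1, 0)), tolerance = 1e-3,
               ignore_attr = TRUE)
  flipped <- relocate_endpoints(pes, c(0, 0), displacement = -0.1)
  expect_equal(flipped$start, ends$end, tolerance = 1e-6)
  expect_equal(flipped$end, ends$start, tolerance = 1e-6)

  pts <- mb_oracle_points(400)
  saddles <- pts[pts$type == "saddle", ]
  top <- saddles[which.max(saddles$energy), ]  # (-0.822, 0.624)
  ends_mb <- relocate_endpoints(pes = model_pes("muller_brown"),
                                saddle = c(top$x, top$y),
                                displacement = 0.05)
  minima <- pts[pts$type == "minimum", ]
  near <- function(p) min(sqrt((minima$x - p[1])^2 + (minima$y - p[2])^2))
  expect_lt(near(ends_mb$start), 1e-4)
  expect_lt(near(ends_mb$end), 1e-4)
  expect_gt(sqrt(sum((ends_mb$start - ends_mb$end)^2)), 0.1)

  m <- minima[1, ]
  expect_error(relocate_endpoints(model_pes("muller_brown"),
                                  c(m$x, m$y)), "not a first-order saddle")
})
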