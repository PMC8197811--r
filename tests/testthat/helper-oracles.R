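# Independent oracles used across the suite. Everything here is written
# against its own formulas — none of it calls the package code paths it is
# used to check.

# Closed-form ordinary least squares for y ~ x.
ols_oracle <- function(x, y) {
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  yhat <- intercept + slope * x
  rss <- sum((y - yhat)^2)
  tss <- sum((y - ybar)^2)
  list(slope = slope, intercept = intercept,
       r_squared = 1 - rss / tss,
       residual_se = sqrt(rss / (length(x) - 2)),
       predict = function(x0) intercept + slope * x0)
}

# Own copy of the Muller-Brown formula (literature constants), vectorized.
mb_oracle_energy <- function(x, y) {
  A <- c(-200, -100, -170, 15); a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6); cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1); y0 <- c(0, 0.5, 1.5, 1)
  E <- 0
  for (i in 1:4)
    E <- E + A[i] * exp(a[i] * (x - x0[i])^2 +
                        b[i] * (x - x0[i]) * (y - y0[i]) +
                        cc[i] * (y - y0[i])^2)
  E
}

oracle_grad <- function(f, p, h = 1e-6) {
  c((f(p[1] + h, p[2]) - f(p[1] - h, p[2])) / (2 * h),
    (f(p[1], p[2] + h) - f(p[1], p[2] - h)) / (2 * h))
}

oracle_hess <- function(f, p, h = 1e-4) {
  f0 <- f(p[1], p[2])
  hxx <- (f(p[1] + h, p[2]) - 2 * f0 + f(p[1] - h, p[2])) / h^2
  hyy <- (f(p[1], p[2] + h) - 2 * f0 + f(p[1], p[2] - h)) / h^2
  hxy <- (f(p[1] + h, p[2] + h) - f(p[1] + h, p[2] - h) -
          f(p[1] - h, p[2] + h) + f(p[1] - h, p[2] - h)) / (4 * h^2)
  matrix(c(hxx, hxy, hxy, hyy), 2, 2)
}

# Dense-grid screen for stationary points followed by Newton refinement on
# the gradient. Returns a data.frame with location, energy, eigenvalues and
# type ("minimum", "saddle", "maximum").
oracle_stationary_points <- function(f, xlim, ylim, n = 400) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  E <- outer(xs, ys, f)
  # gradient magnitude on the interior grid via centered differences
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  gx <- (E[3:n, 2:(n - 1)] - E[1:(n - 2), 2:(n - 1)]) / (2 * dx)
  gy <- (E[2:(n - 1), 3:n] - E[2:(n - 1), 1:(n - 2)]) / (2 * dy)
  G <- sqrt(gx^2 + gy^2)
  m <- n - 2
  # local minima of |grad| over the 8-neighbourhood
  pad <- matrix(Inf, m + 2, m + 2)
  pad[2:(m + 1), 2:(m + 1)] <- G
  is_min <- G <= pmin(
    pad[1:m, 1:m], pad[1:m, 2:(m + 1)], pad[1:m, 3:(m + 2)],
    pad[2:(m + 1), 1:m], pad[2:(m + 1), 3:(m + 2)],
    pad[3:(m + 2), 1:m], pad[3:(m + 2), 2:(m + 1)], pad[3:(m + 2), 3:(m + 2)])
  cand <- which(is_min & G < 0.1 * max(G), arr.ind = TRUE)
  pts <- list()
  for (k in seq_len(nrow(cand))) {
    p <- c(xs[cand[k, 1] + 1], ys[cand[k, 2] + 1])
    ok <- TRUE
    for (it in 1:100) {
      g <- oracle_grad(f, p)
      if (sqrt(sum(g^2)) < 1e-9) break
      H <- oracle_hess(f, p)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) { ok <- FALSE; break }
      if (sqrt(sum(step^2)) > 0.5) step <- step * 0.5 / sqrt(sum(step^2))
      p <- p - step
    }
    if (!ok || sqrt(sum(oracle_grad(f, p)^2)) > 1e-6) next
    if (p[1] < xlim[1] || p[1] > xlim[2] ||
        p[2] < ylim[1] || p[2] > ylim[2]) next
    dup <- any(vapply(pts, function(q)
      sqrt(sum((q$p - p)^2)) < 1e-4, logical(1)))
    if (!dup) pts[[length(pts) + 1]] <- list(p = p)
  }
  rows <- lapply(pts, function(q) {
    ev <- sort(eigen(oracle_hess(f, q$p), symmetric = TRUE,
                     only.values = TRUE)$values)
    type <- if (all(ev > 0)) "minimum"
            else if (all(ev < 0)) "maximum" else "saddle"
    data.frame(x = q$p[1], y = q$p[2], energy = f(q$p[1], q$p[2]),
               ev1 = ev[1], ev2 = ev[2], type = type)
  })
  do.call(rbind, rows)
}

# Cached Muller-Brown stationary points at the standard resolution.
mb_oracle_points <- local({
  cache <- NULL
  function(n = 400) {
    if (is.null(cache) || attr(cache, "n") != n) {
      scalar_mb <- function(x, y) mb_oracle_energy(x, y)
      cache <<- oracle_stationary_points(scalar_mb, c(-1.6, 1.3),
                                         c(-0.4, 2.1), n = n)
      attr(cache, "n") <<- n
    }
    cache
  }
})

# Paper-style descriptor rows used by several scaling tests: the reported
# charge-transfer descriptors with the free-energy barriers.
qcat_demo_rows <- function() {
  data.frame(label = c("3", "2", "1", "0"),
             qcat = c(0.21, 0.17, 0.09, 0.05),
             barrier = c(15.4, 17.1, 19.3, 24.3),
             stringsAsFactors = FALSE)
}
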