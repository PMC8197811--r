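#' NEB optimizer configuration
#'
#' Collects the tunable parameters of the nudged-elastic-band run. The
#' defaults are deliberate, surfaced choices (none comes from any external
#' reference calculation): 12 images resolve the barrier region of smooth
#' 2-D surfaces; spring constant 1 keeps images evenly spread without
#' stiffening the band; the force tolerance 1e-3 (model units per length
#' unit) is small against the curvature of both registered surfaces.
#'
#' @param n_images Number of images including both endpoints (>= 4).
#' @param spring_k Spring constant between adjacent images.
#' @param max_force_tol Convergence threshold on the largest per-image NEB
#'   force norm.
#' @param max_iter Iteration budget; exceeding it flags the returned path as
#'   unconverged rather than raising an error.
#' @param climbing Enable climbing-image refinement. The climbing image is
#'   only activated once the plain band has reached 10 times
#'   `max_force_tol`, so that climbing never starts from an unequilibrated
#'   band.
#' @param optimizer `"fire"` (quenched-velocity minimizer, default) or
#'   `"sd"` (plain steepest descent, for debugging).
#' @param max_step Largest per-image displacement per iteration.
#' @param dt Initial FIRE time step.
#' @param seed Integer seed recorded in the config; the optimizer itself is
#'   deterministic, the seed exists so that any randomized restart strategy
#'   layered on top is reproducible.
#' @return A list of class `"neb_config"`.
#' @export
neb_config <- function(n_images = 12L, spring_k = 1.0,
                       max_force_tol = 1e-3, max_iter = 30000L,
                       climbing = TRUE, optimizer = c("fire", "sd"),
                       max_step = 0.05, dt = 0.01, seed = 1L) {
  optimizer <- match.arg(optimizer)
  n_images <- as.integer(n_images)
  if (n_images < 4L) stop("n_images must be >= 4", call. = FALSE)
  if (max_force_tol <= 0 || spring_k <= 0 || max_step <= 0 || dt <= 0)
    stop("tolerances, spring_k, max_step and dt must be positive",
         call. = FALSE)
  structure(list(n_images = n_images, spring_k = spring_k,
                 max_force_tol = max_force_tol,
                 max_iter = as.integer(max_iter), climbing = climbing,
                 optimizer = optimizer, max_step = max_step, dt = dt,
                 seed = as.integer(seed)),
            class = "neb_config")
}

new_neb_path <- function(images, energies = rep(NA_real_, nrow(images)),
                         converged = FALSE, iterations = 0L,
                         max_force_history = numeric(0L)) {
  structure(list(images = images, energies = energies,
                 converged = converged, iterations = iterations,
                 max_force_history = max_force_history),
            class = "neb_path")
}

#' @export
print.neb_path <- function(x, ...) {
  cat(sprintf("<neb_path: %d images, %s after %d iterations>\n",
              nrow(x$images),
              ifelse(x$converged, "converged", "NOT converged"),
              x$iterations))
  if (!anyNA(x$energies))
    cat(sprintf("  energy range [%.6g, %.6g]\n",
                min(x$energies), max(x$energies)))
  invisible(x)
}

#' Linear interpolation between two endpoints
#'
#' Builds the initial band: `n_images` evenly spaced points on the straight
#' segment from `start` to `end`, endpoints exact.
#'
#' @param start,end 2-vectors, distinct.
#' @param n_images Number of images including endpoints (>= 4).
#' @return A `"neb_path"` with unevaluated energies.
#' @export
interpolate_path <- function(start, end, n_images = 12L) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 2L, length(end) == 2L)
  if (identical(start, end))
    stop("start and end must differ", call. = FALSE)
  n_images <- as.integer(n_images)
  if (n_images < 4L) stop("n_images must be >= 4", call. = FALSE)
  t <- seq(0, 1, length.out = n_images)
  images <- cbind(start[1L] + t * (end[1L] - start[1L]),
                  start[2L] + t * (end[2L] - start[2L]))
  images[1L, ] <- start
  images[n_images, ] <- end
  new_neb_path(images)
}

# Improved (energy-weighted) tangent at interior image i.
neb_tangent <- function(images, energies, i) {
  rp <- images[i + 1L, ] - images[i, ]
  rm <- images[i, ] - images[i - 1L, ]
  ep <- energies[i + 1L]; e0 <- energies[i]; em <- energies[i - 1L]
  if (ep > e0 && e0 > em) {
    tau <- rp
  } else if (ep < e0 && e0 < em) {
    tau <- rm
  } else {
    dmax <- max(abs(ep - e0), abs(em - e0))
    dmin <- min(abs(ep - e0), abs(em - e0))
    tau <- if (ep > em) rp * dmax + rm * dmin else rp * dmin + rm * dmax
  }
  nrm <- sqrt(sum(tau^2))
  if (nrm == 0) tau <- rp / max(sqrt(sum(rp^2)), .Machine$double.eps)
  else tau <- tau / nrm
  tau
}

# Per-image NEB forces. Returns list(forces = matrix, climbing_index).
neb_forces <- function(pes, images, energies, spring_k, climbing_index) {
  m <- nrow(images)
  forces <- matrix(0, m, 2L)
  for (i in 2L:(m - 1L)) {
    tau <- neb_tangent(images, energies, i)
    g <- pes_gradient(pes, images[i, ])
    f_true <- -g
    if (!is.na(climbing_index) && i == climbing_index) {
      # climbing image: full force with the tangent component inverted,
      # no spring — drives the image uphill onto the saddle
      forces[i, ] <- f_true - 2 * sum(f_true * tau) * tau
    } else {
      f_perp <- f_true - sum(f_true * tau) * tau
      dp <- sqrt(sum((images[i + 1L, ] - images[i, ])^2))
      dm <- sqrt(sum((images[i, ] - images[i - 1L, ])^2))
      forces[i, ] <- f_perp + spring_k * (dp - dm) * tau
    }
  }
  forces
}

#' Optimize a band on a model surface
#'
#' Nudged-elastic-band optimization with the improved (energy-weighted)
#' tangent, spring forces acting along the tangent only and true forces
#' perpendicular to it, minimized by a quenched-velocity (FIRE-type)
#' integrator with a capped per-image step. When climbing is enabled, the
#' highest-energy interior image is switched to climbing mode — full force
#' with the tangent component inverted, springs released — once the plain
#' band's largest force norm falls below 10 times the tolerance, so the
#' climbing image converges onto the saddle point itself.
#'
#' Endpoints are never moved. Failure to reach the force tolerance within
#' the iteration budget is reported through the `converged` flag, not an
#' error.
#'
#' @param pes A `"model_pes"`.
#' @param path A `"neb_path"` (typically from [interpolate_path()]).
#' @param config A `"neb_config"`.
#' @return The optimized `"neb_path"` with per-image energies, convergence
#'   flag, iteration count and the per-iteration maximum-force history.
#' @export
neb_optimize <- function(pes, path, config = neb_config()) {
  stopifnot(inherits(pes, "model_pes"), inherits(path, "neb_path"),
            inherits(config, "neb_config"))
  images <- path$images
  m <- nrow(images)
  if (m < 4L) stop("band must have >= 4 images", call. = FALSE)
  start <- images[1L, ]; end <- images[m, ]

  energies <- vapply(seq_len(m),
                     function(i) pes$energy(images[i, 1L], images[i, 2L]),
                     numeric(1L))
  v <- matrix(0, m, 2L)
  dt <- config$dt
  alpha <- 0.1
  n_pos <- 0L
  hist <- numeric(0L)
  climbing_index <- NA_integer_
  converged <- FALSE
  iter <- 0L

  while (iter < config$max_iter) {
    iter <- iter + 1L
    f <- neb_forces(pes, images, energies, config$spring_k, climbing_index)
    fnorm <- sqrt(rowSums(f^2))
    maxf <- max(fnorm[2L:(m - 1L)])
    hist <- c(hist, maxf)

    climb_ready <- !config$climbing || !is.na(climbing_index)
    if (maxf < config$max_force_tol && climb_ready) {
      converged <- TRUE
      break
    }
    if (config$climbing && is.na(climbing_index) &&
        maxf < 10 * config$max_force_tol) {
      interior <- 2L:(m - 1L)
      climbing_index <- interior[which.max(energies[interior])]
      v[] <- 0  # reset momentum when the force field changes
      next
    }

    if (config$optimizer == "sd") {
      step <- dt * f
    } else {
      # FIRE: mix velocity toward the force direction, accelerate while
      # moving downhill, quench on any uphill power
      p <- sum(f * v)
      vn <- sqrt(sum(v^2)); fn <- sqrt(sum(f^2))
      if (fn > 0) v <- (1 - alpha) * v + alpha * vn * f / fn
      if (p > 0) {
        n_pos <- n_pos + 1L
        if (n_pos > 5L) {
          dt <- min(dt * 1.1, 10 * config$dt)
          alpha <- alpha * 0.99
        }
      } else {
        v[] <- 0
        dt <- dt * 0.5
        alpha <- 0.1
        n_pos <- 0L
      }
      v <- v + dt * f
      step <- dt * v
    }
    slen <- sqrt(rowSums(step^2))
    too_big <- slen > config$max_step
    if (any(too_big))
      step[too_big, ] <- step[too_big, ] * config$max_step / slen[too_big]
    step[1L, ] <- 0
    step[m, ] <- 0
    images <- images + step
    images[1L, ] <- start
    images[m, ] <- end
    energies <- vapply(seq_len(m),
                       function(i) pes$energy(images[i, 1L], images[i, 2L]),
                       numeric(1L))
  }
  new_neb_path(images, energies, converged, iter, hist)
}

#' Index of the transition-state image
#'
#' The highest-energy image of a band, required to be interior: a maximum
#' sitting on an endpoint means the band brackets no barrier. An exact
#' energy tie is broken toward the lowest index with a warning.
#'
#' @param path A `"neb_path"` with at least 3 images and evaluated energies.
#' @return 1-based image index.
#' @export
locate_ts <- function(path) {
  stopifnot(inherits(path, "neb_path"))
  e <- path$energies
  m <- length(e)
  if (m < 3L) stop("need at least 3 images", call. = FALSE)
  if (anyNA(e)) stop("path energies not evaluated", call. = FALSE)
  emax <- max(e)
  at <- which(e == emax)
  if (all(at %in% c(1L, m)))
    stop("no interior barrier: the maximum-energy image is an endpoint",
         call. = FALSE)
  at <- at[at != 1L & at != m]
  if (length(at) > 1L)
    warning("energy tie among images ", paste(at, collapse = ", "),
            "; taking the lowest index", call. = FALSE)
  at[1L]
}

#' Verify a first-order saddle point
#'
#' A point is accepted as a transition state iff its gradient norm is below
#' `tol` and its Hessian has exactly one negative eigenvalue — the 2-D
#' analogue of confirming a TS by a single imaginary vibrational frequency.
#'
#' @param pes A `"model_pes"`.
#' @param point 2-vector.
#' @param tol Gradient-norm tolerance (default 1e-3).
#' @return A list of class `"saddle_report"`: `location`, `energy`,
#'   `gradient_norm`, `eigenvalues` (ascending), `n_negative`, `is_saddle`.
#' @export
verify_saddle <- function(pes, point, tol = 1e-3) {
  stopifnot(inherits(pes, "model_pes"), length(point) == 2L,
            all(is.finite(point)))
  g <- pes_gradient(pes, point)
  h <- numerical_hessian(pes, point)
  gnorm <- sqrt(sum(g^2))
  nneg <- sum(h$eigenvalues < 0)
  structure(list(location = as.numeric(point),
                 energy = pes$energy(point[1L], point[2L]),
                 gradient_norm = gnorm,
                 eigenvalues = h$eigenvalues,
                 n_negative = nneg,
                 is_saddle = gnorm < tol && nneg == 1L),
            class = "saddle_report")
}

#' @export
print.saddle_report <- function(x, ...) {
  cat(sprintf("saddle report at (%.6g, %.6g): E = %.6g\n",
              x$location[1L], x$location[2L], x$energy))
  cat(sprintf("  |grad| = %.3g, eigenvalues (%.4g, %.4g) -> %s\n",
              x$gradient_norm, x$eigenvalues[1L], x$eigenvalues[2L],
              ifelse(x$is_saddle, "first-order saddle",
                     "not a first-order saddle")))
  invisible(x)
}

# Quench to the nearest minimum by damped FIRE dynamics on the raw PES.
quench_to_minimum <- function(pes, point, tol = 1e-8, max_iter = 50000L,
                              max_step = 0.05, dt0 = 0.02) {
  x <- as.numeric(point)
  v <- c(0, 0)
  dt <- dt0; alpha <- 0.1; n_pos <- 0L
  for (it in seq_len(max_iter)) {
    f <- -pes_gradient(pes, x)
    if (sqrt(sum(f^2)) < tol) return(list(point = x, iterations = it))
    p <- sum(f * v)
    vn <- sqrt(sum(v^2)); fn <- sqrt(sum(f^2))
    if (fn > 0) v <- (1 - alpha) * v + alpha * vn * f / fn
    if (p > 0) {
      n_pos <- n_pos + 1L
      if (n_pos > 5L) { dt <- min(dt * 1.1, 10 * dt0); alpha <- alpha * 0.99 }
    } else {
      v <- c(0, 0); dt <- dt * 0.5; alpha <- 0.1; n_pos <- 0L
    }
    v <- v + dt * f
    step <- dt * v
    sl <- sqrt(sum(step^2))
    if (sl > max_step) step <- step * max_step / sl
    x <- x + step
  }
  stop("quench did not converge within ", max_iter, " iterations",
       call. = FALSE)
}

#' Relocate reaction endpoints from a saddle point
#'
#' Displaces the verified saddle by `+/- displacement` along the
#' negative-curvature Hessian eigenvector (the imaginary-frequency mode in
#' the molecular picture) and quenches each displaced point downhill to the
#' adjacent minimum. This reproduces the usual protocol of locating the
#' final reactant and product complexes from the transition-state mode.
#'
#' @param pes A `"model_pes"`.
#' @param saddle 2-vector; should satisfy [verify_saddle()].
#' @param displacement Scalar displacement along the mode (default 0.1).
#' @param tol Gradient-norm tolerance for the quenched minima.
#' @return List with `start` and `end` 2-vectors (the minima reached along
#'   -mode and +mode respectively); flipping the displacement sign swaps
#'   them.
#' @export
relocate_endpoints <- function(pes, saddle, displacement = 0.1,
                               tol = 1e-8) {
  stopifnot(inherits(pes, "model_pes"), length(saddle) == 2L)
  h <- numerical_hessian(pes, saddle)
  eig <- eigen(h$hessian, symmetric = TRUE)
  if (sum(eig$values < 0) != 1L)
    stop("point is not a first-order saddle (", sum(eig$values < 0),
         " negative eigenvalues)", call. = FALSE)
  mode <- eig$vectors[, which.min(eig$values)]
  a <- quench_to_minimum(pes, saddle - displacement * mode, tol = tol)
  b <- quench_to_minimum(pes, saddle + displacement * mode, tol = tol)
  list(start = a$point, end = b$point)
}

#' Barrier height from an optimized band
#'
#' Energy of the transition-state image minus the energy of the chosen
#' reference endpoint.
#'
#' @param path A converged `"neb_path"` with an interior maximum.
#' @param reference `"start"` or `"end"`.
#' @return Barrier in the surface's energy units.
#' @export
barrier_from_path <- function(path, reference = c("start", "end")) {
  reference <- match.arg(reference)
  i <- locate_ts(path)
  ref <- if (reference == "start") path$energies[1L]
         else path$energies[length(path$energies)]
  path$energies[i] - ref
}

#' Write a band as TSV
#'
#' Columns `index, x, y, energy`, one row per image.
#'
#' @param path_obj A `"neb_path"`.
#' @param file Output TSV path.
#' @return Invisibly, `file`.
#' @export
write_neb_path <- function(path_obj, file) {
  stopifnot(inherits(path_obj, "neb_path"))
  df <- data.frame(index = seq_len(nrow(path_obj$images)),
                   x = path_obj$images[, 1L],
                   y = path_obj$images[, 2L],
                   energy = path_obj$energies)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
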