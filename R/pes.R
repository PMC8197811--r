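#' Analytic 2-D model potential-energy surfaces
#'
#' Two-dimensional analytic surfaces stand in for an electronic-structure
#' engine in the reaction-path pipeline: two dimensions is the smallest
#' setting in which a first-order saddle — one negative Hessian eigenvalue,
#' the 2-D analogue of a transition state with one imaginary vibrational
#' frequency — exists. Energies are in dimensionless model units.
#'
#' Registered surfaces:
#' \describe{
#'   \item{`sn2`}{A double-well SN2 surrogate
#'     \deqn{V = V_0 (x^2-1)^2 + \mathrm{asym}\, x + \tfrac{1}{2} k (y - c x)^2}
#'     with minima near \eqn{x = \pm 1} for small `asym`. With `asym = 0`
#'     and `c = 0` the surface is symmetric, the saddle sits exactly at the
#'     origin, and the barrier from either basin equals `V0`. Parameters:
#'     `V0 > 0` barrier scale, `asym` tilt, `k > 0` transverse stiffness,
#'     `c` valley skew.}
#'   \item{`muller_brown`}{The Müller–Brown surface, the standard benchmark
#'     for path-optimization methods: a sum of four Gaussian-exponential
#'     terms with the literature-standard constants fixed as module
#'     constants. Three minima and two first-order saddles.}
#' }
#'
#' @param name `"sn2"` or `"muller_brown"`.
#' @param ... Parameter overrides for the `sn2` surface (`V0`, `asym`, `k`,
#'   `c`); `muller_brown` takes none.
#' @return An object of class `"model_pes"`: list with `name`, `params`,
#'   `energy(x, y)` and analytic `gradient(x, y)` functions.
#' @examples
#' pes <- model_pes("sn2", V0 = 15.4)
#' pes$energy(0, 0)    # barrier top
#' pes$energy(1, 0)    # product basin
#' @export
model_pes <- function(name = c("sn2", "muller_brown"), ...) {
  name <- match.arg(name)
  switch(name,
         sn2 = sn2_surrogate_pes(...),
         muller_brown = muller_brown_pes())
}

#' @export
print.model_pes <- function(x, ...) {
  cat(sprintf("<model_pes '%s'>\n", x$name))
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname model_pes
#' @param V0 Barrier scale (> 0), default 1.
#' @param asym Linear tilt between the two basins, default 0.
#' @param k Transverse harmonic stiffness (> 0), default 1.
#' @param c Valley skew coupling, default 0.
#' @export
sn2_surrogate_pes <- function(V0 = 1, asym = 0, k = 1, c = 0) {
  stopifnot(is.finite(V0), V0 > 0, is.finite(asym), is.finite(k), k > 0,
            is.finite(c))
  force(V0); force(asym); force(k); force(c)
  energy <- function(x, y) {
    V0 * (x^2 - 1)^2 + asym * x + 0.5 * k * (y - c * x)^2
  }
  gradient <- function(x, y) {
    t <- y - c * x
    c(4 * V0 * x * (x^2 - 1) + asym - k * c * t,
      k * t)
  }
  structure(list(name = "sn2",
                 params = list(V0 = V0, asym = asym, k = k, c = c),
                 energy = energy, gradient = gradient),
            class = "model_pes")
}

# Literature-standard Müller-Brown constants.
.mb_A <- c(-200, -100, -170, 15)
.mb_a <- c(-1, -1, -6.5, 0.7)
.mb_b <- c(0, 0, 11, 0.6)
.mb_c <- c(-10, -10, -6.5, 0.7)
.mb_x0 <- c(1, 0, -0.5, -1)
.mb_y0 <- c(0, 0.5, 1.5, 1)

#' @rdname model_pes
#' @export
muller_brown_pes <- function() {
  energy <- function(x, y) {
    dx <- x - .mb_x0; dy <- y - .mb_y0
    sum(.mb_A * exp(.mb_a * dx^2 + .mb_b * dx * dy + .mb_c * dy^2))
  }
  gradient <- function(x, y) {
    dx <- x - .mb_x0; dy <- y - .mb_y0
    e <- .mb_A * exp(.mb_a * dx^2 + .mb_b * dx * dy + .mb_c * dy^2)
    c(sum(e * (2 * .mb_a * dx + .mb_b * dy)),
      sum(e * (.mb_b * dx + 2 * .mb_c * dy)))
  }
  structure(list(name = "muller_brown", params = list(),
                 energy = energy, gradient = gradient),
            class = "model_pes")
}

#' Central-difference gradient on a model surface
#'
#' @param pes A `"model_pes"`.
#' @param point 2-vector (x, y).
#' @param h Finite-difference step; default 1e-5 balances truncation against
#'   round-off for double precision.
#' @return 2-vector gradient.
#' @export
numerical_gradient <- function(pes, point, h = 1e-5) {
  stopifnot(inherits(pes, "model_pes"), h > 0, length(point) == 2L)
  x <- point[1L]; y <- point[2L]
  c((pes$energy(x + h, y) - pes$energy(x - h, y)) / (2 * h),
    (pes$energy(x, y + h) - pes$energy(x, y - h)) / (2 * h))
}

#' Central-difference Hessian on a model surface
#'
#' The symmetric 2x2 second-derivative matrix; its eigenvalue signature
#' classifies a stationary point (two positive: minimum; exactly one
#' negative: first-order saddle, the 2-D analogue of one imaginary
#' vibrational frequency).
#'
#' @param pes A `"model_pes"`.
#' @param point 2-vector (x, y).
#' @param h Finite-difference step; default 1e-4 (second derivatives lose
#'   more precision to round-off than first).
#' @return List with `hessian` (symmetric 2x2 matrix) and `eigenvalues`
#'   (ascending).
#' @export
numerical_hessian <- function(pes, point, h = 1e-4) {
  stopifnot(inherits(pes, "model_pes"), h > 0, length(point) == 2L)
  x <- point[1L]; y <- point[2L]
  f <- pes$energy
  f0 <- f(x, y)
  hxx <- (f(x + h, y) - 2 * f0 + f(x - h, y)) / h^2
  hyy <- (f(x, y + h) - 2 * f0 + f(x, y - h)) / h^2
  hxy <- (f(x + h, y + h) - f(x + h, y - h) -
          f(x - h, y + h) + f(x - h, y - h)) / (4 * h^2)
  H <- matrix(c(hxx, hxy, hxy, hyy), 2L, 2L)
  list(hessian = H, eigenvalues = sort(eigen(H, symmetric = TRUE,
                                             only.values = TRUE)$values))
}

# Gradient with analytic fallback to central differences.
pes_gradient <- function(pes, point) {
  if (!is.null(pes$gradient)) pes$gradient(point[1L], point[2L])
  else numerical_gradient(pes, point)
}
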