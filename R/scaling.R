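#' Fit a linear descriptor-barrier scaling relationship
#'
#' Fits the activation barrier (kcal/mol) against a single reactivity
#' descriptor by unweighted ordinary least squares:
#' \deqn{\Delta E^\ddagger = a \cdot x + b + \varepsilon}
#' This is the empirical linear scaling at the heart of the method: across a
#' series of active-site environments the barrier falls linearly as the
#' descriptor (distance difference or charge transfer) grows, and the fitted
#' line can then score an environment that was held out of the fit.
#'
#' Rows flagged `predict_only` and rows lacking the chosen descriptor or a
#' barrier are excluded from the fit. With only two points the line is the
#' exact interpolant; the coefficient of determination is then reported as 1
#' with a warning, since no residual degrees of freedom remain.
#'
#' @param rows A `"descriptor_table"` (see [descriptor_table()]) or any
#'   data.frame with columns `label`, the descriptor, and `barrier`.
#' @param descriptor `"dcat"` or `"qcat"` — which descriptor to fit on.
#' @return An object of class `"scaling_fit"`: a list with elements
#'   `descriptor`, `slope` (kcal/mol per descriptor unit), `intercept`
#'   (kcal/mol), `r_squared`, `residual_se` (kcal/mol), `n`, the fitted
#'   data (`x`, `y`, `labels`), and the underlying [stats::lm] fit.
#' @seealso [predict.scaling_fit()], [predict_barrier()],
#'   [compare_environments()]
#' @examples
#' tab <- data.frame(label = c("3", "2", "1", "0"),
#'                   qcat = c(0.21, 0.17, 0.09, 0.05),
#'                   barrier = c(15.4, 17.1, 19.3, 24.3))
#' fit <- fit_scaling(tab, "qcat")
#' coef(fit)
#' predict_barrier(fit, 0.04)
#' @export
fit_scaling <- function(rows, descriptor = c("qcat", "dcat")) {
  descriptor <- match.arg(descriptor)
  if (!all(c(descriptor, "barrier") %in% names(rows)))
    stop("rows must carry columns '", descriptor, "' and 'barrier'",
         call. = FALSE)
  hold <- if ("predict_only" %in% names(rows)) isTRUE_vec(rows$predict_only)
          else rep(FALSE, nrow(rows))
  keep <- !hold & !is.na(rows[[descriptor]]) & !is.na(rows$barrier)
  x <- as.numeric(rows[[descriptor]][keep])
  y <- as.numeric(rows$barrier[keep])
  labels <- if ("label" %in% names(rows)) as.character(rows$label[keep])
            else as.character(seq_along(x))
  n <- length(x)
  if (n < 2L)
    stop("scaling fit needs at least 2 environments with both a '",
         descriptor, "' value and a barrier; got ", n, call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate fit: all '", descriptor, "' values identical (",
         x[1L], ")", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  rss <- sum(stats::residuals(fit)^2)
  if (n == 2L) {
    warning("only 2 points: line is the exact interpolant; r_squared ",
            "reported as 1 and residual_se as 0", call. = FALSE)
    r2 <- 1
    sigma <- 0
  } else {
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    sigma <- sqrt(rss / (n - 2L))
  }
  structure(
    list(descriptor = descriptor, slope = slope, intercept = intercept,
         r_squared = r2, residual_se = sigma, n = n,
         x = x, y = y, labels = labels, lm_fit = fit),
    class = "scaling_fit"
  )
}

isTRUE_vec <- function(v) !is.na(v) & as.logical(v)

#' @export
print.scaling_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("Linear scaling: barrier ~ %s  (n = %d)\n", x$descriptor, x$n))
  cat(sprintf("  slope     %s kcal/mol per unit\n",
              format(x$slope, digits = digits)))
  cat(sprintf("  intercept %s kcal/mol\n",
              format(x$intercept, digits = digits)))
  cat(sprintf("  r^2       %s   residual SE %s kcal/mol\n",
              format(x$r_squared, digits = digits),
              format(x$residual_se, digits = digits)))
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.scaling_fit <- function(object, ...) {
  r <- object$y - (object$intercept + object$slope * object$x)
  names(r) <- object$labels
  r
}

#' @export
summary.scaling_fit <- function(object, ...) {
  s <- summary(object$lm_fit)
  out <- list(fit = object, lm_summary = s,
              slope_se = s$coefficients[2L, 2L],
              intercept_se = s$coefficients[1L, 2L])
  class(out) <- "summary.scaling_fit"
  out
}

#' @export
print.summary.scaling_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  slope SE  %s   intercept SE %s\n",
              format(x$slope_se, digits = 4L),
              format(x$intercept_se, digits = 4L)))
  invisible(x)
}

#' Predict barriers from a fitted scaling line
#'
#' Evaluates `slope * x + intercept` at new descriptor values, with the
#' standard error of prediction for a single new observation,
#' \deqn{s \sqrt{1 + 1/n + (x - \bar x)^2 / S_{xx}},}
#' and flags extrapolation whenever `x` lies outside the fitted descriptor
#' range. Extrapolation is permitted — scoring an out-of-series environment
#' is the method's main use — but always flagged.
#'
#' @param object A `"scaling_fit"`.
#' @param newdata Numeric vector of descriptor values (or a data.frame with
#'   a column named after the fitted descriptor).
#' @param ... Unused.
#' @return A data.frame with columns `x`, `fit` (kcal/mol), `se_pred`
#'   (kcal/mol) and `extrapolated`.
#' @export
predict.scaling_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata[[object$descriptor]]
  x <- as.numeric(newdata)
  if (anyNA(x) || any(!is.finite(x)))
    stop("descriptor values for prediction must be finite", call. = FALSE)
  xbar <- mean(object$x)
  sxx <- sum((object$x - xbar)^2)
  fit <- object$intercept + object$slope * x
  se <- object$residual_se *
    sqrt(1 + 1 / object$n + (x - xbar)^2 / sxx)
  rng <- range(object$x)
  data.frame(x = x, fit = fit, se_pred = se,
             extrapolated = x < rng[1L] | x > rng[2L])
}

#' Predict a single barrier with its prediction standard error
#'
#' Convenience wrapper around [predict.scaling_fit()] for one descriptor
#' value; warns when the value lies outside the fitted range.
#'
#' @param model A `"scaling_fit"`.
#' @param x One descriptor value.
#' @return Named numeric vector `c(barrier =, se =)` in kcal/mol, with
#'   attribute `extrapolated`.
#' @export
predict_barrier <- function(model, x) {
  stopifnot(inherits(model, "scaling_fit"), length(x) == 1L)
  p <- predict(model, x)
  if (p$extrapolated)
    warning("descriptor value ", format(x), " lies outside the fitted ",
            "range [", format(min(model$x)), ", ", format(max(model$x)),
            "]: prediction is an extrapolation", call. = FALSE)
  structure(c(barrier = p$fit, se = p$se_pred),
            extrapolated = p$extrapolated)
}

#' @export
plot.scaling_fit <- function(x, ...) {
  xlab <- switch(x$descriptor,
                 dcat = expression(D[cat] ~ "(Å)"),
                 qcat = expression(Q[cat] ~ "(e)"))
  graphics::plot(x$x, x$y, pch = 19, xlab = xlab,
                 ylab = "barrier (kcal/mol)", ...)
  graphics::abline(a = x$intercept, b = x$slope, col = "grey40")
  graphics::text(x$x, x$y, x$labels, pos = 3, cex = 0.8)
  invisible(x)
}

#' Simulate barriers from a fitted scaling line
#'
#' Draws new barrier vectors at the fitted descriptor values, adding
#' Gaussian noise with the fitted residual standard error.
#'
#' @param object A `"scaling_fit"`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns, one simulated barrier vector
#'   per column.
#' @export
simulate.scaling_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$intercept + object$slope * object$x
  out <- as.data.frame(replicate(
    nsim, mu + stats::rnorm(object$n, 0, object$residual_se)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$labels
  out
}

#' Barrier differences relative to a reference environment
#'
#' Computes `barrier(label) - barrier(reference)` for every environment.
#' Negative values mean the environment lowers the barrier relative to the
#' reference, i.e. catalysis; this is how stepwise barrier reductions along
#' a residue series are reported.
#'
#' @param rows A `"descriptor_table"` or data.frame with `label` and
#'   `barrier` columns.
#' @param reference Label of the reference environment.
#' @return Named numeric vector of barrier differences in kcal/mol, in row
#'   order.
#' @export
compare_environments <- function(rows, reference) {
  if (!all(c("label", "barrier") %in% names(rows)))
    stop("rows must carry 'label' and 'barrier' columns", call. = FALSE)
  ref <- match(as.character(reference), rows$label)
  if (is.na(ref))
    stop("unknown reference label '", reference, "'; available: ",
         paste(rows$label, collapse = ", "), call. = FALSE)
  d <- rows$barrier - rows$barrier[ref]
  names(d) <- rows$label
  d
}

#' Serialize a scaling fit to JSON
#' @param model A `"scaling_fit"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scaling_model <- function(model, path) {
  stopifnot(inherits(model, "scaling_fit"))
  jsonlite::write_json(
    list(descriptor = model$descriptor, slope = model$slope,
         intercept = model$intercept, r_squared = model$r_squared,
         residual_se = model$residual_se, n = model$n,
         x = model$x, y = model$y, labels = model$labels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a scaling fit from JSON
#' @param path Path written by [write_scaling_model()].
#' @return A `"scaling_fit"`.
#' @export
read_scaling_model <- function(path) {
  m <- jsonlite::fromJSON(path)
  fit <- stats::lm(m$y ~ m$x)
  structure(
    list(descriptor = m$descriptor, slope = m$slope,
         intercept = m$intercept, r_squared = m$r_squared,
         residual_se = m$residual_se, n = m$n,
         x = m$x, y = m$y, labels = m$labels, lm_fit = fit),
    class = "scaling_fit")
}
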