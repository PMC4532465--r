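#' Empirical survival curve of CRT durations
#'
#' The survivor function of a CRT set is \eqn{S(t)}: the fraction of CRT
#' durations strictly larger than \eqn{t}, pooled over all animals and
#' receivers in the set. The curve is stored as its values at the distinct
#' sorted durations (plus \eqn{t = 0}), which fully determine the step
#' function. By construction \eqn{S} is non-increasing, lies in \eqn{[0,1]}
#' and reaches 0 at the largest duration.
#'
#' @param crts a `crt_set` from [build_crts()], or a numeric vector of
#'   durations.
#' @return A `survival_curve`: a `data.frame` with columns `t` and `S`, and
#'   attributes `mbp`, `n` (number of CRTs pooled) and `time_unit`.
#' @examples
#' sc <- survival_curve(c(1, 2, 3, 4))
#' sc$S[sc$t == 2]   # 2 of 4 durations exceed 2
#' @export
survival_curve <- function(crts) {
  if (inherits(crts, "crt_set")) {
    durations <- crts$duration
    mbp <- attr(crts, "mbp")
    unit <- time_unit(crts)
  } else {
    durations <- as.numeric(crts)
    mbp <- NA_real_
    unit <- "steps"
  }
  if (length(durations) == 0L) stop("empty CRT set")
  if (any(durations < 0)) stop("negative durations")
  d <- sort(durations)
  n <- length(d)
  ud <- unique(d)
  s <- (n - findInterval(ud, d)) / n  # fraction strictly larger
  if (ud[1L] > 0) {
    ud <- c(0, ud)
    s <- c(1, s)
  }
  out <- data.frame(t = ud, S = s)
  attr(out, "mbp") <- mbp
  attr(out, "n") <- n
  attr(out, "time_unit") <- unit
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %d points from %d CRTs (mbp = %g %s), max duration %g\n",
              nrow(x), attr(x, "n"), attr(x, "mbp"), time_unit(x), max(x$t)))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, log = "y", xlab = NULL, ylab = "S(t)", ...) {
  if (is.null(xlab)) xlab <- sprintf("CRT duration t [%s]", time_unit(x))
  keep <- if (grepl("y", log)) x$S > 0 else rep(TRUE, nrow(x))
  plot(x$t[keep], x$S[keep], type = "s", log = log, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Regrid a survival curve by gap-limited linear interpolation
#'
#' CRT sets obtained at different MBPs put their survivor steps at different
#' durations, so curves are resampled onto a common regular grid
#' \eqn{t_i = i \Delta t} before comparison. Linear interpolation between two
#' consecutive raw points is performed only when their abscissa separation
#' is at most `t_max`; grid points falling inside a wider span are marked
#' undefined and that part of the curve is discarded from comparisons, as
#' are grid points beyond the last raw point. A grid point coinciding with a
#' raw point is always defined (its value is known exactly).
#'
#' @param curve a [survival_curve()].
#' @param grid_step regular resampling step \eqn{\Delta t} (> 0).
#' @param t_max largest raw-point separation across which interpolation is
#'   allowed (> 0).
#' @return An `interpolated_curve`: a list with elements `t` (grid),
#'   `values` (survival values, `NA` where undefined), `defined` (logical
#'   mask), `grid_step`, `t_max`, `mbp`.
#' @examples
#' sc <- survival_curve(c(0, 10, 10, 20))
#' ic <- interpolate_curve(sc, grid_step = 1, t_max = 100)
#' ic$values[ic$t == 5]   # midpoint of the span (0,0.75)-(10,0.25)
#' @export
interpolate_curve <- function(curve, grid_step, t_max) {
  stopifnot(inherits(curve, "survival_curve"))
  if (!is.numeric(grid_step) || grid_step <= 0) stop("grid_step must be > 0")
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be > 0")
  xr <- curve$t
  sr <- curve$S
  tg <- seq(0, max(xr), by = grid_step)
  if (length(xr) == 1L) {
    vals <- sr
    defined <- TRUE
  } else {
    vals <- stats::approx(xr, sr, xout = tg, method = "linear",
                          ties = "ordered")$y
    iv <- findInterval(tg, xr)          # raw interval containing each grid point
    span <- c(diff(xr), Inf)[iv]
    on_knot <- abs(tg - xr[iv]) <= 1e-9 * grid_step
    defined <- on_knot | span <= t_max
    vals[!defined] <- NA_real_
  }
  structure(list(t = tg, values = vals, defined = defined,
                 grid_step = grid_step, t_max = t_max,
                 mbp = attr(curve, "mbp")),
            class = "interpolated_curve")
}

#' @export
print.interpolated_curve <- function(x, ...) {
  cat(sprintf("interpolated_curve: mbp = %g, grid_step = %g, %d grid points (%d defined)\n",
              x$mbp, x$grid_step, length(x$t), sum(x$defined)))
  invisible(x)
}
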