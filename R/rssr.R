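#' Renormalized sum of squared residuals between two interpolated curves
#'
#' For two survival curves resampled on the same regular grid, the rSSR is
#' the sum of squared differences over the grid points where both curves
#' are defined, divided by the number \eqn{T} of those points:
#' \deqn{rSSR = \frac{1}{T} \sum_{i=1}^{T} [S_a(t_i) - S_b(t_i)]^2.}
#' Renormalizing by \eqn{T} keeps comparisons consistent when different
#' curve pairs overlap over differently sized defined regions.
#'
#' @param a,b `interpolated_curve` objects sharing the same `grid_step`.
#' @return A list with elements `rssr` (non-negative scalar) and
#'   `n_overlap` (\eqn{T}, the number of jointly defined grid points).
#' @examples
#' sc <- survival_curve(c(1, 2, 3, 4))
#' ic <- interpolate_curve(sc, 1, 100)
#' rssr(ic, ic)$rssr   # identical curves: 0
#' @export
rssr <- function(a, b) {
  stopifnot(inherits(a, "interpolated_curve"), inherits(b, "interpolated_curve"))
  if (a$grid_step != b$grid_step)
    stop("curves were interpolated with different grid steps")
  n <- min(length(a$t), length(b$t))  # beyond a curve's last point it is undefined
  joint <- a$defined[seq_len(n)] & b$defined[seq_len(n)]
  T_ <- sum(joint)
  if (T_ == 0L) stop("no overlap: curves share no defined grid points")
  dif <- a$values[seq_len(n)][joint] - b$values[seq_len(n)][joint]
  list(rssr = sum(dif * dif) / T_, n_overlap = T_)
}

#' rSSR profile of a detection table over an MBP grid
#'
#' Runs the full comparison pipeline: builds the CRT set at every MBP of
#' the grid, forms the pooled survival curve of CRT durations for each,
#' resamples the curves on the regular grid `grid_step` with discard
#' threshold `t_max`, and computes the rSSR between the curves of every
#' consecutive grid pair \eqn{(MBP_n, MBP_{n+1})}. The entry indexed by
#' \eqn{MBP_n} compares \eqn{MBP_n} with the next grid value. Pairs whose
#' interpolated curves share no defined grid points are dropped with a
#' warning.
#'
#' @param x a [detection_table()].
#' @param grid an [mbp_grid()] (>= 2 values).
#' @param grid_step resampling step \eqn{\Delta t} for [interpolate_curve()].
#' @param t_max interpolation discard threshold for [interpolate_curve()].
#' @param drop_zero passed to [build_crts()].
#' @return An `rssr_profile`: a `data.frame` with columns `mbp`, `mbp_next`,
#'   `rssr`, `n_overlap`, with attributes recording the scan parameters.
#' @seealso [detect_mbp_star()]
#' @export
rssr_profile <- function(x, grid, grid_step, t_max, drop_zero = FALSE) {
  grid <- as.numeric(grid)
  if (length(grid) < 2L) stop("grid needs >= 2 values")
  curves <- lapply(build_crts_over_grid(x, grid, drop_zero = drop_zero),
                   function(cs) interpolate_curve(survival_curve(cs),
                                                  grid_step, t_max))
  k <- length(grid) - 1L
  vals <- rep(NA_real_, k)
  t_ <- rep(NA_integer_, k)
  for (i in seq_len(k)) {
    r <- tryCatch(rssr(curves[[i]], curves[[i + 1L]]), error = function(e) NULL)
    if (!is.null(r)) {
      vals[i] <- r$rssr
      t_[i] <- r$n_overlap
    }
  }
  if (anyNA(vals)) {
    warning("dropping ", sum(is.na(vals)), " MBP pair(s) with no curve overlap")
  }
  keep <- !is.na(vals)
  out <- data.frame(mbp = grid[-length(grid)][keep],
                    mbp_next = grid[-1L][keep],
                    rssr = vals[keep], n_overlap = t_[keep])
  attr(out, "grid") <- grid
  attr(out, "grid_step") <- grid_step
  attr(out, "t_max") <- t_max
  attr(out, "time_unit") <- time_unit(x)
  class(out) <- c("rssr_profile", "data.frame")
  out
}

#' @export
print.rssr_profile <- function(x, ...) {
  cat(sprintf("rssr_profile: %d MBP pairs (%g .. %g %s), rSSR range %.3g .. %.3g\n",
              nrow(x), min(x$mbp), max(x$mbp_next), time_unit(x),
              min(x$rssr), max(x$rssr)))
  invisible(x)
}

#' @export
plot.rssr_profile <- function(x, log = "", xlab = NULL, ylab = "rSSR", ...) {
  if (is.null(xlab)) xlab <- sprintf("MBP [%s]", time_unit(x))
  keep <- if (grepl("y", log)) x$rssr > 0 else rep(TRUE, nrow(x))
  plot(x$mbp[keep], x$rssr[keep], type = "b", log = log,
       xlab = xlab, ylab = ylab, ...)
  star <- attr(x, "mbp_star")
  if (!is.null(star) && !is.na(star)) abline(v = star, lty = 2)
  invisible(x)
}

#' Detect the convergence timescale MBP*
#'
#' Operationalizes the visual criterion "the rSSR stabilized beyond this
#' MBP": the profile is scanned for the smallest grid value \eqn{m} such
#' that every entry at \eqn{MBP \ge m} (for at least `min_run` consecutive
#' entries, through the end of the grid by default) has already reached the
#' profile's terminal plateau. Returns `NA` when the profile never
#' stabilizes; a detected value at or near the end of the grid means the
#' grid should be extended.
#'
#' Because rSSR profiles typically span several orders of magnitude (the
#' first pair contrasts processing far below the noise timescale with the
#' first grid value), "stabilized" is judged against the terminal floor of
#' the profile, not against its maximum. The floor is estimated as the mean
#' rSSR of the last `tail_n` entries; an entry counts as stabilized when
#' its rSSR is at most `floor_factor` times the floor (indistinguishable
#' from the plateau fluctuation) or at most `zero_tol` times the profile
#' maximum (negligible outright — this guard handles plateaus at or near
#' exactly zero, where a multiple of the floor is ill-posed). Alternatively
#' a threshold relative to the profile maximum can be requested by passing
#' `rel_threshold`, which overrides the floor criterion. A profile whose
#' trailing level is well above its leading level (more than twice) is still
#' rising and is reported as not stabilized.
#'
#' @param profile an [rssr_profile()].
#' @param floor_factor multiple of the terminal floor below which an entry
#'   counts as stabilized (default 3).
#' @param tail_n number of trailing entries used to estimate the floor
#'   (default 5, capped at half the profile length).
#' @param zero_tol fraction of the profile maximum below which an entry is
#'   negligible regardless of the floor (default `1e-6`).
#' @param rel_threshold optional fraction of the profile maximum; when
#'   given, an entry is stabilized iff `rssr <= rel_threshold * max(rssr)`
#'   and the floor criterion is not used.
#' @param min_run minimum number of consecutive stabilized entries required,
#'   ending at the last entry; `NULL` (default) requires stabilization
#'   through the whole remainder of the grid.
#' @return The detected MBP* (a grid value), or `NA_real_`.
#' @examples
#' # toy profile: drops to the floor at its third grid value
#' p <- structure(data.frame(mbp = c(100, 200, 300, 400, 500),
#'                           mbp_next = c(200, 300, 400, 500, 600),
#'                           rssr = c(1, 0.5, 0.01, 0.005, 0.004),
#'                           n_overlap = 50L),
#'                class = c("rssr_profile", "data.frame"))
#' detect_mbp_star(p)   # 300
#' @export
detect_mbp_star <- function(profile, floor_factor = 3, tail_n = 5,
                            zero_tol = 1e-6, rel_threshold = NULL,
                            min_run = NULL) {
  stopifnot(inherits(profile, "rssr_profile"))
  if (nrow(profile) == 0L) stop("empty profile")
  ord <- order(profile$mbp)
  v <- profile$rssr[ord]
  m <- profile$mbp[ord]
  k <- length(v)
  if (!is.null(rel_threshold)) {
    threshold <- rel_threshold * max(v)
  } else {
    nt <- min(tail_n, max(1L, k %/% 2L))
    floor_level <- mean(v[(k - nt + 1L):k])
    # a trailing level well above the leading level means the profile is
    # still rising, not converging: no plateau to stabilize onto
    if (floor_level > 2 * mean(v[seq_len(nt)]) && floor_level > 0)
      return(NA_real_)
    threshold <- floor_factor * floor_level + zero_tol * max(v)
  }
  ok <- v <= threshold
  # the terminal stabilized run starts after the last non-stabilized entry
  last_bad <- if (any(!ok)) max(which(!ok)) else 0L
  first <- last_bad + 1L
  if (first > k) return(NA_real_)
  run <- k - first + 1L
  need <- if (is.null(min_run)) run else min_run
  if (run < need) return(NA_real_)
  m[first]
}
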