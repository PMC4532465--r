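#' Build the MBP grid
#'
#' The maximum blanking period is scanned over the regular grid
#' \eqn{MBP_n = n \Delta_{MBP}}, \eqn{n = 1, \dots, N}. Optionally a single
#' smaller base value (typically the sampling step of the data, e.g. 1
#' simulation step) is prepended so that the first rSSR pair contrasts the
#' finest possible processing with the first grid value.
#'
#' @param delta_mbp grid increment \eqn{\Delta_{MBP}} (> 0), in data time units.
#' @param n_max number of grid values \eqn{N} (>= 1).
#' @param base optional extra smallest value prepended to the grid; must be
#'   positive and smaller than `delta_mbp`. `NULL` for none.
#' @return An `mbp_grid`: a numeric vector of strictly increasing MBP
#'   values with attributes `delta_mbp` and `base`.
#' @examples
#' mbp_grid(100, 20, base = 1)   # 1, 100, 200, ..., 2000
#' mbp_grid(10, 12)              # 10 .. 120 (e.g. minutes)
#' @export
mbp_grid <- function(delta_mbp, n_max, base = NULL) {
  if (!is.numeric(delta_mbp) || length(delta_mbp) != 1L || delta_mbp <= 0)
    stop("delta_mbp must be a positive scalar")
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1)
    stop("n_max must be a positive integer")
  values <- seq_len(n_max) * delta_mbp
  if (!is.null(base)) {
    if (base <= 0 || base >= delta_mbp)
      stop("base must lie in (0, delta_mbp)")
    values <- c(base, values)
  }
  structure(values, delta_mbp = delta_mbp, base = base, class = "mbp_grid")
}

#' @export
print.mbp_grid <- function(x, ...) {
  cat(sprintf("mbp_grid: %d values, delta_mbp = %g%s\n", length(x),
              attr(x, "delta_mbp"),
              if (is.null(attr(x, "base"))) "" else sprintf(", base = %g", attr(x, "base"))))
  print(as.numeric(x))
  invisible(x)
}

#' Build continuous residence times for one MBP
#'
#' Scans each animal's detections in time order and cuts them into
#' continuous residence times (CRTs). A CRT at receiver \eqn{R_A} opens at a
#' first detection there and closes at the last detection at \eqn{R_A}
#' before either of two events: a detection of the same animal at a
#' different receiver (the switch rule — applied regardless of how much time
#' elapsed, with a new CRT opening at the other receiver at its detection
#' time), or a gap between consecutive same-receiver detections strictly
#' larger than `mbp` (a new CRT at \eqn{R_A} opens at the next detection).
#' A gap exactly equal to `mbp` does not split. Single detections yield
#' zero-duration CRTs, which are retained by default since they carry mass
#' in the survival curves.
#'
#' @param x a [detection_table()].
#' @param mbp maximum blanking period (> 0), in the table's time units.
#' @param drop_zero drop zero-duration CRTs (default `FALSE`).
#' @return A `crt_set`: a `data.frame` with columns `animal_id`,
#'   `receiver_id`, `start`, `end`, `duration`, `n_detections`, with
#'   attributes `mbp` and `time_unit`.
#' @examples
#' dt <- detection_table(rep("A", 3), rep("f", 3), c(0, 5, 12))
#' build_crts(dt, mbp = 6)  # gap 7 > 6 splits: durations 5 and 0
#' @export
build_crts <- function(x, mbp, drop_zero = FALSE) {
  stopifnot(inherits(x, "detection_table"))
  if (nrow(x) == 0L) stop("empty detection table")
  if (!is.numeric(mbp) || length(mbp) != 1L || mbp <= 0)
    stop("mbp must be a positive scalar")

  a <- x$animal_id; r <- x$receiver_id; tt <- x$time
  n <- length(tt)
  same_animal <- c(FALSE, a[-1L] == a[-n])
  same_recv <- c(FALSE, r[-1L] == r[-n])
  gap <- c(Inf, tt[-1L] - tt[-n])
  if (any(same_animal & !same_recv & gap == 0))
    warning("simultaneous detections of one animal at two receivers; treated as a switch in record order")
  new_crt <- !(same_animal & same_recv & gap <= mbp)
  starts <- which(new_crt)
  ends <- c(starts[-1L] - 1L, n)
  out <- data.frame(animal_id = a[starts], receiver_id = r[starts],
                    start = tt[starts], end = tt[ends],
                    duration = tt[ends] - tt[starts],
                    n_detections = ends - starts + 1L,
                    stringsAsFactors = FALSE)
  if (drop_zero) out <- out[out$duration > 0, , drop = FALSE]
  attr(out, "mbp") <- mbp
  attr(out, "time_unit") <- time_unit(x)
  class(out) <- c("crt_set", "data.frame")
  out
}

#' @export
print.crt_set <- function(x, ...) {
  cat(sprintf("crt_set: %d CRTs (mbp = %g %s), %d animals\n",
              nrow(x), attr(x, "mbp"), time_unit(x),
              length(unique(x$animal_id))))
  if (nrow(x) > 0L)
    cat(sprintf("  durations: min %g, median %g, max %g\n",
                min(x$duration), stats::median(x$duration), max(x$duration)))
  invisible(x)
}

#' Build CRT sets over an MBP grid
#'
#' Applies [build_crts()] independently at every grid value. As the MBP
#' grows, gap-rule boundaries disappear while switch-rule boundaries stay,
#' so the number of CRTs is non-increasing along the grid.
#'
#' @param x a [detection_table()].
#' @param grid an [mbp_grid()] or numeric vector of positive increasing MBPs.
#' @param drop_zero passed to [build_crts()].
#' @return A named list of `crt_set` objects, one per grid value.
#' @export
build_crts_over_grid <- function(x, grid, drop_zero = FALSE) {
  grid <- as.numeric(grid)
  if (length(grid) < 1L || any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing positive MBP values")
  out <- lapply(grid, function(m) build_crts(x, m, drop_zero = drop_zero))
  names(out) <- format(grid, trim = TRUE, scientific = FALSE)
  out
}

#' Export a CRT set to a delimited file
#'
#' @param x a `crt_set`.
#' @param path output path.
#' @param delim delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_crts <- function(x, path, delim = "\t") {
  stopifnot(inherits(x, "crt_set"))
  df <- as.data.frame(x)
  df$mbp <- attr(x, "mbp")
  utils::write.table(df, path, quote = FALSE, sep = delim, row.names = FALSE)
  invisible(path)
}
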