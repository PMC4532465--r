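#' Run a simulation and write its detection log
#'
#' Thin workhorse behind the `simulate` command-line subcommand: runs
#' [simulate_detections()], writes the detection log and a plain-text
#' provenance file (`<out>.params`) recording every model parameter and the
#' seed, so any output can be regenerated.
#'
#' @param config a [sim_config()].
#' @param out output path for the detection log.
#' @param format passed to [write_detections()].
#' @param seed RNG seed; overrides `config$seed` when given.
#' @return The detection table, invisibly.
#' @export
run_simulate <- function(config, out, format = c("supplementary", "generic"),
                         seed = NULL) {
  format <- match.arg(format)
  if (!is.null(seed)) config$seed <- seed
  dt <- simulate_detections(config)
  write_detections(dt, out, format = format)
  prov <- c(sprintf("crtscan %s", as.character(utils::packageVersion("crtscan"))),
            sprintf("scenario %d", config$scenario),
            sprintf("theta %g", config$theta),
            if (config$scenario == 1) sprintf("mu %g", config$mu)
            else c(sprintf("mu_inf %g", config$mu_inf),
                   sprintf("K %g", config$K),
                   sprintf("gamma %g", config$gamma)),
            sprintf("eta %g", config$eta),
            sprintf("n_fish %d", config$n_fish),
            sprintf("p %d", config$p),
            sprintf("n_steps %d", config$n_steps),
            sprintf("burn_in %d", config$burn_in),
            sprintf("seed %s", if (is.null(config$seed)) "NA" else config$seed),
            sprintf("n_detections %d", nrow(dt)))
  writeLines(prov, paste0(out, ".params"))
  invisible(dt)
}

#' Scan a detection log over an MBP grid and report MBP*
#'
#' End-to-end analysis behind the `scan` subcommand: builds CRT sets for
#' every value of the MBP grid, computes the rSSR profile between
#' consecutive-MBP survival curves and detects the convergence timescale
#' MBP*. When `out_dir` is given, writes `rssr_profile.tsv`, a per-MBP
#' survival-curve file `survival_mbp<value>.tsv`, and `report.txt` with
#' the full parameter set and the detected MBP*.
#'
#' @param x a [detection_table()] or a path passed to [read_detections()].
#' @param grid an [mbp_grid()].
#' @param grid_step,t_max interpolation parameters (see
#'   [interpolate_curve()]).
#' @param floor_factor,tail_n,zero_tol,rel_threshold,min_run MBP* detection
#'   parameters (see [detect_mbp_star()]).
#' @param drop_zero passed to [build_crts()].
#' @param out_dir optional output directory (created if needed).
#' @param format,... passed to [read_detections()] when `x` is a path.
#' @return A list with elements `profile` (an [rssr_profile()], with the
#'   detected value stored in its `mbp_star` attribute) and `mbp_star`.
#' @examples
#' cfg <- sim_config(1, theta = 0.02, mu = 0.02, eta = 1,
#'                   n_fish = 20, p = 2, n_steps = 2000, seed = 1)
#' dt <- simulate_detections(cfg)
#' run_scan(dt, mbp_grid(5, 10), grid_step = 1, t_max = 100)$mbp_star
#' @export
run_scan <- function(x, grid, grid_step, t_max, floor_factor = 3,
                     tail_n = 5, zero_tol = 1e-6, rel_threshold = NULL,
                     min_run = NULL, drop_zero = FALSE, out_dir = NULL,
                     format = "supplementary", ...) {
  if (is.character(x)) x <- read_detections(x, format = format, ...)
  stopifnot(inherits(x, "detection_table"))
  if (length(grid) < 2L) stop("grid needs >= 2 values")

  profile <- rssr_profile(x, grid, grid_step = grid_step, t_max = t_max,
                          drop_zero = drop_zero)
  star <- detect_mbp_star(profile, floor_factor = floor_factor,
                          tail_n = tail_n, zero_tol = zero_tol,
                          rel_threshold = rel_threshold, min_run = min_run)
  attr(profile, "mbp_star") <- star

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(profile),
                       file.path(out_dir, "rssr_profile.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
    for (m in as.numeric(grid)) {
      sc <- survival_curve(build_crts(x, m, drop_zero = drop_zero))
      utils::write.table(as.data.frame(sc),
                         file.path(out_dir,
                                   sprintf("survival_mbp%s.tsv",
                                           format(m, trim = TRUE, scientific = FALSE))),
                         quote = FALSE, sep = "\t", row.names = FALSE)
    }
    writeLines(c(sprintf("crtscan %s", as.character(utils::packageVersion("crtscan"))),
                 sprintf("n_detections %d", nrow(x)),
                 sprintf("time_unit %s", time_unit(x)),
                 sprintf("grid %s", paste(as.numeric(grid), collapse = " ")),
                 sprintf("grid_step %g", grid_step),
                 sprintf("t_max %g", t_max),
                 sprintf("detector %s",
                         if (is.null(rel_threshold))
                           sprintf("floor_factor %g tail_n %d zero_tol %g",
                                   floor_factor, as.integer(tail_n), zero_tol)
                         else sprintf("rel_threshold %g", rel_threshold)),
                 sprintf("min_run %s", if (is.null(min_run)) "all" else min_run),
                 sprintf("drop_zero %s", drop_zero),
                 sprintf("mbp_star %s", if (is.na(star)) "not detected" else star)),
               file.path(out_dir, "report.txt"))
  }
  list(profile = profile, mbp_star = star)
}

#' Named parameter presets for field-style scans
#'
#' Two ready-made scan parameterizations mirroring the typical applications
#' on FAD telemetry data (times in seconds):
#' \describe{
#'   \item{`fine`}{small-timescale scan isolating instrumental noise:
#'     MBP grid 10-120 min in 10-min increments, interpolation step 10 min,
#'     discard threshold 4 h.}
#'   \item{`diel`}{large-timescale scan capturing diel excursions:
#'     MBP grid 2-48 h in 2-h increments, interpolation step 10 min,
#'     discard threshold 4 h.}
#' }
#'
#' @return A named list of lists with elements `grid`, `grid_step`, `t_max`.
#' @export
scan_presets <- function() {
  list(fine = list(grid = mbp_grid(600, 12), grid_step = 600, t_max = 14400),
       diel = list(grid = mbp_grid(7200, 24), grid_step = 600, t_max = 14400))
}
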