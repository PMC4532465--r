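#' Construct a detection table
#'
#' A detection table is the raw input of every analysis in crtscan: one row
#' per acoustic detection, with the receiver that heard the tag, the animal
#' (tag) identifier and the detection time. Times are plain non-negative
#' numbers in a declared unit (seconds for field exports, abstract steps for
#' simulated data); no calendar handling is done.
#'
#' Rows are sorted by animal and then by time (a warning is issued when the
#' input was unordered); exact duplicates of the (animal, receiver, time)
#' triple are collapsed to a single record. Simultaneous detections of the
#' same animal at two different receivers are kept in input order and
#' resolved by the CRT builder.
#'
#' @param receiver_id vector of receiver identifiers (coerced to character).
#' @param animal_id vector of animal/tag identifiers (coerced to character).
#' @param time numeric vector of non-negative detection times.
#' @param time_unit label for the time unit (e.g. `"s"`, `"steps"`).
#' @return A `detection_table`: a `data.frame` with columns `receiver_id`,
#'   `animal_id`, `time`, carrying a `time_unit` attribute.
#' @examples
#' dt <- detection_table(c("R1", "R1", "R2"), c("f1", "f1", "f1"),
#'                       c(0, 30, 95), time_unit = "s")
#' dt
#' @seealso [read_detections()], [build_crts()]
#' @export
detection_table <- function(receiver_id, animal_id, time, time_unit = "steps") {
  n <- length(time)
  if (length(receiver_id) != n || length(animal_id) != n)
    stop("receiver_id, animal_id and time must have equal length")
  if (n == 0L) stop("no records")
  receiver_id <- as.character(receiver_id)
  animal_id <- as.character(animal_id)
  time <- as.numeric(time)
  if (anyNA(receiver_id) || anyNA(animal_id) || anyNA(time))
    stop("missing values in detection records")
  if (any(!nzchar(receiver_id)) || any(!nzchar(animal_id)))
    stop("empty receiver or animal identifiers")
  if (any(time < 0)) stop("negative detection times")

  ord <- order(animal_id, time, method = "radix")  # stable: ties keep input order
  if (is.unsorted(ord)) {
    warning("detections were not sorted by animal and time; sorting")
    receiver_id <- receiver_id[ord]
    animal_id <- animal_id[ord]
    time <- time[ord]
  }
  dup <- duplicated(data.frame(animal_id, receiver_id, time))
  if (any(dup)) {
    receiver_id <- receiver_id[!dup]
    animal_id <- animal_id[!dup]
    time <- time[!dup]
  }
  out <- data.frame(receiver_id = receiver_id, animal_id = animal_id,
                    time = time, stringsAsFactors = FALSE)
  attr(out, "time_unit") <- time_unit
  class(out) <- c("detection_table", "data.frame")
  out
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf("detection_table: %d detections, %d animals, %d receivers [time in %s]\n",
              nrow(x), length(unique(x$animal_id)),
              length(unique(x$receiver_id)), time_unit(x)))
  if (nrow(x) > 0L)
    cat(sprintf("  time range: %g .. %g\n", min(x$time), max(x$time)))
  invisible(x)
}

#' Time unit of a crtscan object
#' @param x a `detection_table` (or object carrying a `time_unit` attribute).
#' @return The unit label, or `"steps"` when none was recorded.
#' @export
time_unit <- function(x) {
  u <- attr(x, "time_unit")
  if (is.null(u)) "steps" else u
}

#' Read a detection log
#'
#' Two dialects are supported. `format = "supplementary"` is the whitespace
#' separated archive layout used for FAD telemetry exports: columns are
#' receiver (FAD) id, animal (fish) id, incremental time in seconds, followed
#' by an optional human-readable date (`DD MM YYYY h min sec`) which is
#' ignored — the incremental-seconds column is authoritative.
#' `format = "generic"` reads a delimited file with a header line; the column
#' names holding the three fields are configurable through `col_map`.
#'
#' @param path path to the text file.
#' @param format `"supplementary"` or `"generic"`.
#' @param delim field delimiter for the generic format (default: any
#'   whitespace). Ignored for the supplementary format.
#' @param col_map named character vector mapping the roles `receiver`,
#'   `animal`, `time` to column names in a generic file.
#' @param time_unit unit label stored on the result (`"s"` for the
#'   supplementary format by default).
#' @return A [detection_table()].
#' @examples
#' f <- tempfile()
#' writeLines(c("3 17 86400 01 07 2006 0 0 0",
#'              "3 17 86460 01 07 2006 0 1 0"), f)
#' read_detections(f, format = "supplementary")
#' @export
read_detections <- function(path,
                            format = c("supplementary", "generic"),
                            delim = NULL,
                            col_map = c(receiver = "receiver_id",
                                        animal = "animal_id",
                                        time = "time"),
                            time_unit = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "supplementary") {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    if (!any(keep)) stop("no records in ", path)
    lineno <- which(keep)
    fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop(sprintf("malformed line %d: fewer than 3 columns", lineno[which(nf < 3L)[1L]]))
    rec <- vapply(fields, `[[`, "", 1L)
    ani <- vapply(fields, `[[`, "", 2L)
    tim <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(tim))
      stop(sprintf("malformed line %d: non-numeric time", lineno[which(is.na(tim))[1L]]))
    if (any(tim < 0))
      stop(sprintf("malformed line %d: negative time", lineno[which(tim < 0)[1L]]))
    return(detection_table(rec, ani, tim,
                           time_unit = if (is.null(time_unit)) "s" else time_unit))
  }

  df <- utils::read.table(path, header = TRUE,
                          sep = if (is.null(delim)) "" else delim,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- unname(col_map[c("receiver", "animal", "time")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  tim <- suppressWarnings(as.numeric(df[[col_map[["time"]]]]))
  if (anyNA(tim)) {
    bad <- which(is.na(tim))[1L]
    stop(sprintf("malformed line %d: non-numeric time", bad + 1L))  # +1 for header
  }
  detection_table(df[[col_map[["receiver"]]]], df[[col_map[["animal"]]]], tim,
                  time_unit = if (is.null(time_unit)) "steps" else time_unit)
}

#' Write a detection log
#'
#' Writes either the three bare columns of the supplementary dialect
#' (receiver, animal, incremental time; the date columns are not
#' regenerated) or a headered delimited file readable by
#' [read_detections()] with `format = "generic"`.
#'
#' @param x a [detection_table()].
#' @param path output path.
#' @param format `"supplementary"` or `"generic"`.
#' @param delim delimiter for the generic format.
#' @return `path`, invisibly.
#' @export
write_detections <- function(x, path,
                             format = c("supplementary", "generic"),
                             delim = "\t") {
  stopifnot(inherits(x, "detection_table"))
  format <- match.arg(format)
  if (format == "supplementary") {
    utils::write.table(data.frame(x$receiver_id, x$animal_id,
                                  format(x$time, scientific = FALSE, trim = TRUE)),
                       path, quote = FALSE, sep = " ",
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(as.data.frame(x)[, c("receiver_id", "animal_id", "time")],
                       path, quote = FALSE, sep = delim, row.names = FALSE)
  }
  invisible(path)
}
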