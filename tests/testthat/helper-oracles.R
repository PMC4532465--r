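# Independent brute-force oracles and random fixtures. These deliberately
# re-derive every quantity with explicit loops, so they share no code with
# the package implementations they check.

# random detection table: per-animal detection times from positive integer
# gaps, receivers switching at random
random_table <- function(n_animals = 4, n_receivers = 3, n_det = 30,
                         max_gap = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rec <- character(0); ani <- character(0); tim <- numeric(0)
  for (a in seq_len(n_animals)) {
    k <- sample(2:n_det, 1)
    times <- cumsum(sample(1:max_gap, k, replace = TRUE))
    recv <- as.character(sample(seq_len(n_receivers), k, replace = TRUE))
    rec <- c(rec, recv); ani <- c(ani, rep(sprintf("a%d", a), k))
    tim <- c(tim, times)
  }
  detection_table(rec, ani, tim)
}

# brute-force CRT construction: split at every receiver switch, then split
# each same-receiver run at gaps strictly larger than mbp
oracle_crts <- function(dt, mbp) {
  res <- NULL
  df <- as.data.frame(dt)
  for (an in unique(df$animal_id)) {
    sub <- df[df$animal_id == an, , drop = FALSE]
    n <- nrow(sub)
    run_id <- 1L
    runs <- integer(n); runs[1L] <- 1L
    if (n > 1L) for (i in 2:n) {
      if (sub$receiver_id[i] != sub$receiver_id[i - 1L]) run_id <- run_id + 1L
      runs[i] <- run_id
    }
    for (rid in unique(runs)) {
      seg <- sub[runs == rid, , drop = FALSE]
      first <- 1L
      for (i in seq_len(nrow(seg))) {
        last_of_piece <- i == nrow(seg) ||
          (seg$time[i + 1L] - seg$time[i] > mbp)
        if (last_of_piece) {
          res <- rbind(res, data.frame(
            animal_id = an, receiver_id = seg$receiver_id[1L],
            start = seg$time[first], end = seg$time[i],
            duration = seg$time[i] - seg$time[first],
            n_detections = i - first + 1L, stringsAsFactors = FALSE))
          first <- i + 1L
        }
      }
    }
  }
  res[order(res$animal_id, res$start), , drop = FALSE]
}

# brute-force survivor value at a single time
oracle_survival_at <- function(durations, t) {
  sum(durations > t) / length(durations)
}

# brute-force gap-limited interpolation of one grid point
oracle_interp_at <- function(xr, sr, t, t_max) {
  for (j in seq_along(xr)) {
    if (abs(t - xr[j]) < 1e-12) return(sr[j])
  }
  for (j in seq_len(length(xr) - 1L)) {
    if (t > xr[j] && t < xr[j + 1L]) {
      if (xr[j + 1L] - xr[j] > t_max) return(NA_real_)
      w <- (t - xr[j]) / (xr[j + 1L] - xr[j])
      return((1 - w) * sr[j] + w * sr[j + 1L])
    }
  }
  NA_real_  # beyond the last raw point
}

# brute-force rssr accumulation over the joint defined mask
oracle_rssr <- function(a, b) {
  n <- min(length(a$t), length(b$t))
  ssq <- 0; T_ <- 0L
  for (i in seq_len(n)) {
    if (a$defined[i] && b$defined[i]) {
      ssq <- ssq + (a$values[i] - b$values[i])^2
      T_ <- T_ + 1L
    }
  }
  if (T_ == 0L) return(NULL)
  list(rssr = ssq / T_, n_overlap = T_)
}

# hand-built interpolated_curve for identity tests
make_interp <- function(values, defined = rep(TRUE, length(values)),
                        grid_step = 1, mbp = NA_real_) {
  vals <- values
  vals[!defined] <- NA_real_
  structure(list(t = (seq_along(values) - 1L) * grid_step, values = vals,
                 defined = defined, grid_step = grid_step, t_max = Inf,
                 mbp = mbp),
            class = "interpolated_curve")
}
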