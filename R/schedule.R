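#' Generate an alternating social / non-social stimulus schedule
#'
#' Emulates the block design used with 4- to 7-month-old infants: the session
#' opens with a rest period of at least 10 s, after which 8 s baseline blocks
#' (static images shown 1-3 s each) alternate with experimental blocks whose
#' condition alternates between social and non-social and whose duration is
#' drawn uniformly from 8-12 s.
#'
#' @param n_trials Number of experimental blocks (>= 1).
#' @param rng_seed Integer seed; identical seeds give identical schedules.
#' @param rest_s Initial rest duration in seconds (>= 10).
#' @param baseline_s Duration of each baseline block (default 8 s).
#' @param first_condition Condition of the first experimental block.
#' @return A `stim_schedule`: data frame with columns `condition`
#'   (`"baseline"`, `"social"`, `"non-social"`), `onset_s`, `duration_s`, and a
#'   list column `sub_durations_s` holding the 1-3 s sub-image partition of
#'   each baseline block. Attribute `total_duration_s` gives the session span.
#' @export
generate_schedule <- function(n_trials, rng_seed = 1L, rest_s = 10,
                              baseline_s = 8,
                              first_condition = c("social", "non-social")) {
  stop_if_not(is.numeric(n_trials) && length(n_trials) == 1 && n_trials >= 1,
              "n_trials must be a single number >= 1")
  stop_if_not(rest_s >= 10, "the session must start with a rest of >= 10 s")
  first_condition <- match.arg(first_condition)
  n_trials <- as.integer(n_trials)

  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(rng_seed))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    list(
      durations = stats::runif(n_trials, 8, 12),
      subs = lapply(seq_len(n_trials), function(i) partition_baseline(baseline_s))
    )
  })

  conds <- rep(c(first_condition,
                 setdiff(c("social", "non-social"), first_condition)),
               length.out = n_trials)
  condition <- character(0); onset <- numeric(0); duration <- numeric(0)
  subs <- list()
  t <- rest_s
  for (i in seq_len(n_trials)) {
    condition <- c(condition, "baseline"); onset <- c(onset, t)
    duration <- c(duration, baseline_s); subs <- c(subs, list(rng$subs[[i]]))
    t <- t + baseline_s
    condition <- c(condition, conds[i]); onset <- c(onset, t)
    duration <- c(duration, rng$durations[i]); subs <- c(subs, list(NULL))
    t <- t + rng$durations[i]
  }
  sched <- data.frame(condition = condition, onset_s = onset,
                      duration_s = duration, stringsAsFactors = FALSE)
  sched$sub_durations_s <- subs
  attr(sched, "total_duration_s") <- t + baseline_s  # trailing settle period
  class(sched) <- c("stim_schedule", "data.frame")
  validate_schedule(sched)
  sched
}

# Pseudorandom partition of `total` seconds into sub-images of 1-3 s.
partition_baseline <- function(total) {
  parts <- numeric(0)
  left <- total
  while (left > 3) {
    # keep the remainder reachable with 1-3 s pieces
    lo <- max(1, left - 3 * ceiling((left - 3) / 3) - 2)
    d <- stats::runif(1, max(1, lo), min(3, left - 1))
    parts <- c(parts, d)
    left <- left - d
  }
  c(parts, left)
}

validate_schedule <- function(sched) {
  stop_if_not(all(sched$condition %in% c("baseline", "social", "non-social")),
              "unknown condition label in schedule")
  stop_if_not(!is.unsorted(sched$onset_s, strictly = TRUE),
              "schedule onsets must be strictly increasing")
  ends <- sched$onset_s + sched$duration_s
  stop_if_not(all(sched$onset_s[-1] >= ends[-length(ends)] - 1e-9),
              "schedule blocks must not overlap")
  exper <- sched$condition != "baseline"
  stop_if_not(all(sched$duration_s[exper] >= 8 - 1e-9 &
                  sched$duration_s[exper] <= 12 + 1e-9),
              "experimental block durations must lie in [8, 12] s")
  invisible(sched)
}

#' Extract experimental (stimulus) blocks from a schedule
#' @param schedule A `stim_schedule`.
#' @param condition Optional condition filter (`"social"` or `"non-social"`).
#' @return Data frame with `condition`, `onset_s`, `duration_s`.
#' @export
experimental_blocks <- function(schedule, condition = NULL) {
  b <- schedule[schedule$condition != "baseline",
                c("condition", "onset_s", "duration_s")]
  if (!is.null(condition)) b <- b[b$condition == condition, , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Write / read a stimulus schedule as 3-column TSV
#'
#' Columns: `onset_s`, `duration_s`, `condition`. Times in seconds.
#' @param schedule A `stim_schedule`.
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(
    data.frame(onset_s = schedule$onset_s, duration_s = schedule$duration_s,
               condition = schedule$condition),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "condition")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("schedule file lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sched <- data.frame(condition = d$condition, onset_s = d$onset_s,
                      duration_s = d$duration_s, stringsAsFactors = FALSE)
  sched$sub_durations_s <- vector("list", nrow(sched))
  attr(sched, "total_duration_s") <- max(sched$onset_s + sched$duration_s) + 8
  class(sched) <- c("stim_schedule", "data.frame")
  validate_schedule(sched)
}
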