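# Wearable/phone biomarker ingestion and daily aggregation. Samples arrive
# as a long data frame (one row per sample); days are integer indices
# floor(time / 1440) on the study-local minute clock. Sleep episodes are
# intervals; a night's episodes are unioned before computing duration, and an
# episode spanning midnight counts towards the day on which it ends (the
# waking day), so "sleep_minutes" on day d reads as last night's sleep.

BIOMARKER_KINDS <- c("steps", "pulse_rate", "pulse_rate_variability", "sleep_episode")

empty_samples <- function() {
  data.frame(participant_id = character(0), kind = character(0),
             value = numeric(0), start = integer(0), end = integer(0),
             source = character(0), stringsAsFactors = FALSE)
}

# row-wise validity per the sample invariants; invalid rows are rejected by
# aggregate_daily with a logged count
sample_valid <- function(s) {
  ok <- s$kind %in% BIOMARKER_KINDS & s$start <= s$end &
    s$source %in% c("phone", "wearable")
  ok[s$kind == "steps"] <- ok[s$kind == "steps"] & s$value[s$kind == "steps"] >= 0
  pr <- s$kind == "pulse_rate"
  ok[pr] <- ok[pr] & s$value[pr] > 20 & s$value[pr] < 260
  se <- s$kind == "sleep_episode"
  ok[se] <- ok[se] & s$end[se] > s$start[se]
  ok & !is.na(ok)
}

# union of half-open intervals [start, end), total length in minutes
interval_union_minutes <- function(start, end) {
  if (!length(start)) return(0L)
  o <- order(start, method = "radix")
  start <- start[o]; end <- end[o]
  total <- 0L; cs <- start[[1]]; ce <- end[[1]]
  for (i in seq_along(start)[-1]) {
    if (start[[i]] <= ce) ce <- max(ce, end[[i]])
    else { total <- total + (ce - cs); cs <- start[[i]]; ce <- end[[i]] }
  }
  as.integer(total + (ce - cs))
}

#' Aggregate biomarker samples to daily summaries
#'
#' Produces one row per participant-day with at least one valid sample:
#' total step count, mean pulse rate, and sleep minutes (episodes unioned as
#' intervals so overlapping reports are not double-counted, capped at 1440).
#' When both a wearable and the phone report sleep for the same day, only
#' the wearable episodes are used: phone sleep is inferred from alarms and
#' non-usage and is lower fidelity than heart-rate-based wearable sleep.
#' Samples violating the field invariants (negative steps, implausible
#' pulse, zero-length sleep) are rejected; the count is attached as
#' attribute `rejected`.
#'
#' @param samples Data frame with columns `participant_id`, `kind` (one of
#'   `steps`, `pulse_rate`, `pulse_rate_variability`, `sleep_episode`),
#'   `value`, `start`, `end` (minutes; `end = start` for point samples),
#'   `source` (`phone`/`wearable`).
#' @return Data frame `participant_id, date, total_steps, mean_pulse,
#'   sleep_minutes, sources_present` sorted by participant then date.
#' @export
aggregate_daily <- function(samples) {
  stopifnot(all(c("participant_id", "kind", "value", "start", "end", "source")
                %in% names(samples)))
  valid <- sample_valid(samples)
  rejected <- sum(!valid)
  s <- samples[valid, , drop = FALSE]
  # attribution day: sleep episodes belong to the day they end, point/steps
  # samples to the day they start
  s$date <- ifelse(s$kind == "sleep_episode",
                   s$end %/% 1440L, s$start %/% 1440L)
  out <- list()
  for (pid in sort(unique(s$participant_id), method = "radix")) {
    sp <- s[s$participant_id == pid, , drop = FALSE]
    for (d in sort(unique(sp$date))) {
      sd <- sp[sp$date == d, , drop = FALSE]
      sl <- sd[sd$kind == "sleep_episode", , drop = FALSE]
      if (any(sl$source == "wearable")) sl <- sl[sl$source == "wearable", , drop = FALSE]
      pulse <- sd$value[sd$kind == "pulse_rate"]
      out[[length(out) + 1]] <- data.frame(
        participant_id = pid, date = as.integer(d),
        total_steps = sum(sd$value[sd$kind == "steps"]),
        mean_pulse = if (length(pulse)) mean(pulse) else NA_real_,
        sleep_minutes = min(interval_union_minutes(sl$start, sl$end), 1440L),
        sources_present = paste(sort(unique(sd$source)), collapse = "+"),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(participant_id = character(0), date = integer(0),
               total_steps = numeric(0), mean_pulse = numeric(0),
               sleep_minutes = integer(0), sources_present = character(0),
               stringsAsFactors = FALSE)
  attr(res, "rejected") <- rejected
  res
}

#' Default synthetic biomarker stream configuration
#'
#' Distribution parameters for [generate_biomarker_stream()], chosen to look
#' like a sedentary-to-moderately-active adult cohort: daily step totals
#' lognormal with median ~7000 steps, resting-to-ambulatory pulse readings
#' around 72 bpm, and ~7.5 h of sleep starting near 23:00. Phone-derived
#' sleep episodes get extra onset/duration noise relative to wearable
#' episodes, reflecting that phones infer sleep from alarms and non-usage
#' rather than heart-rate measurement.
#'
#' @param steps `meanlog`, `sdlog` of the lognormal daily total and
#'   `samples_per_day` (the total is split across the day's samples, so the
#'   daily sum follows the configured lognormal exactly).
#' @param pulse Normal `mean`/`sd` (bpm) and `readings_per_day`.
#' @param sleep Nightly onset (minutes into the day) and duration (minutes),
#'   both normal; `phone_extra_sd` is added to both sds for phone episodes.
#' @param sources Which sources report sleep (`"wearable"`, `"phone"`).
#' @export
biomarker_config <- function(
    steps = list(meanlog = log(7000), sdlog = 0.45, samples_per_day = 4L),
    pulse = list(mean = 72, sd = 8, readings_per_day = 6L),
    sleep = list(onset_mean = 1380L, onset_sd = 30, duration_mean = 450L,
                 duration_sd = 40, phone_extra_sd = 60),
    sources = c("wearable", "phone")) {
  stopifnot(steps$sdlog > 0, steps$samples_per_day >= 1,
            pulse$sd >= 0, sleep$duration_mean > 0,
            all(sources %in% c("wearable", "phone")))
  structure(list(steps = steps, pulse = pulse, sleep = sleep,
                 sources = sources), class = "biomarker_config")
}

#' Generate a synthetic biomarker sample stream
#'
#' Seeded, reproducible stand-in for phone/wearable health-data integrations:
#' per participant and day it emits step-count samples (a lognormal daily
#' total split multinomially across the day), pulse-rate readings, and one
#' sleep episode per configured source crossing midnight into the next day.
#' Per-participant random streams are derived from `(seed, participant)`, so
#' the stream for one participant does not depend on how many others exist.
#'
#' @param config A [biomarker_config()].
#' @param n_participants,n_days Cohort size and number of simulated days.
#' @param seed Integer seed.
#' @return Sample data frame in the format [aggregate_daily()] expects.
#' @export
generate_biomarker_stream <- function(config = biomarker_config(),
                                      n_participants, n_days, seed = 1L) {
  stopifnot(inherits(config, "biomarker_config"),
            n_participants >= 0, n_days >= 0)
  rows <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%03d", p)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(derive_seed(seed, pid, "biomarkers"))
    for (d in seq_len(n_days) - 1L) {
      day0 <- d * 1440L
      # steps: lognormal daily total, split across samples_per_day windows
      total <- round(rlnorm(1, config$steps$meanlog, config$steps$sdlog))
      k <- config$steps$samples_per_day
      split <- as.vector(rmultinom(1, total, rep(1 / k, k)))
      at <- day0 + as.integer(round(seq(8 * 60, 20 * 60, length.out = k)))
      for (j in seq_len(k))
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = pid, kind = "steps", value = split[[j]],
          start = at[[j]], end = at[[j]], source = "phone",
          stringsAsFactors = FALSE)
      # pulse readings at random daytime minutes
      nr <- config$pulse$readings_per_day
      pt <- day0 + sort(as.integer(runif(nr, 6 * 60, 23 * 60)))
      pv <- pmin(pmax(rnorm(nr, config$pulse$mean, config$pulse$sd), 21), 259)
      for (j in seq_len(nr))
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = pid, kind = "pulse_rate", value = pv[[j]],
          start = pt[[j]], end = pt[[j]], source = "wearable",
          stringsAsFactors = FALSE)
      # one sleep episode per source, crossing midnight into day d+1
      for (src in config$sources) {
        extra <- if (src == "phone") config$sleep$phone_extra_sd else 0
        onset <- day0 + round(rnorm(1, config$sleep$onset_mean,
                                    config$sleep$onset_sd + extra))
        dur <- max(60, round(rnorm(1, config$sleep$duration_mean,
                                   config$sleep$duration_sd + extra)))
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = pid, kind = "sleep_episode", value = NA_real_,
          start = as.integer(onset), end = as.integer(onset + dur),
          source = src, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  if (length(rows)) do.call(rbind, rows) else empty_samples()
}

#' Expose daily summaries as expression variables
#'
#' Turns [aggregate_daily()] output into an answer-history fragment binding
#' the variables `steps_today`, `mean_pulse_today` and
#' `sleep_minutes_last_night` (each timestamped at the end of its day), so
#' calculated variables and scheduling rules can reference biomarker data
#' exactly like questionnaire answers.
#'
#' @param summaries Data frame from [aggregate_daily()].
#' @return Answer data frame (`participant_id`, `time`, `variable`, `value`)
#'   suitable for [eval_context()].
#' @export
bind_as_variables <- function(summaries) {
  if (!nrow(summaries))
    return(data.frame(participant_id = character(0), time = integer(0),
                      variable = character(0), value = character(0),
                      stringsAsFactors = FALSE))
  one <- function(variable, value) {
    keep <- !is.na(value)
    data.frame(participant_id = summaries$participant_id[keep],
               time = summaries$date[keep] * 1440L + 1439L,
               variable = variable, value = as.character(value[keep]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("steps_today", summaries$total_steps),
               one("mean_pulse_today", summaries$mean_pulse),
               one("sleep_minutes_last_night", summaries$sleep_minutes))
  out[order(out$time, out$participant_id, out$variable, method = "radix"), ,
      drop = FALSE]
}
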