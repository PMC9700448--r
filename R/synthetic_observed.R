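# Synthetic patient-level reference dataset ("observed" stand-in).
#
# Emulates the statistical structure of a one-year extract of admitted
# patients: daily admitted counts from a truncated normal (the published
# mean 52 / SD 28 is incompatible with the published range 28-79 for an
# untruncated normal, so the range is honoured and the realised SD is
# smaller), and per-patient subprocess durations from the moment-matched
# triangular laws.  This is synthetic data standing in for a hospital
# record extract that cannot be obtained.

#' Generate a synthetic observed dataset
#'
#' @param year_days Number of days to generate (default 365).
#' @param seed Master seed (integer).
#' @param config An [admission_config()]; supplies duration moments and
#'   daily-count parameters.
#' @param start_date First admission date (ISO), default `"2019-01-01"`.
#' @return An `observed_dataset`: `patients` (admission_date, one
#'   `d_<subprocess>` column per stage, `total_pet`), `daily`
#'   (date, admitted).
#' @examples
#' obs <- generate_observed(year_days = 10, seed = 1)
#' nrow(obs$patients); range(obs$daily$admitted)
#' @export
generate_observed <- function(year_days = 365, seed = 1L, config = NULL,
                              start_date = "2019-01-01") {
  stopifnot(year_days >= 1)
  if (is.null(config)) config <- admission_config()
  da <- config$daily_admissions

  # truncated-normal daily counts via inverse CDF (deterministic in seed)
  cs <- rng_stream(seed, "observed:daily_counts")
  plo <- stats::pnorm(da$min, da$mean, da$sd)
  phi <- stats::pnorm(da$max, da$mean, da$sd)
  u <- stream_runif(cs, year_days)
  counts <- as.integer(round(stats::qnorm(plo + u * (phi - plo),
                                          da$mean, da$sd)))
  counts <- pmin(pmax(counts, da$min), da$max)   # guard rounding at edges

  n <- sum(counts)
  sp <- config$subprocesses
  dur <- matrix(0, n, nrow(sp),
                dimnames = list(NULL, paste0("d_", sp$name)))
  for (k in seq_len(nrow(sp))) {
    d <- fit_triangular_from_moments(sp$mean[k], sp$sd[k])
    s <- rng_stream(seed, paste0("observed:duration:", sp$name[k]))
    # stored at 1e-4 min so the CSV round-trip is lossless
    dur[, k] <- round(qtri(stream_runif(s, n), d), 4)
  }
  dates <- rep(as.Date(start_date) + seq_len(year_days) - 1L, times = counts)
  patients <- data.frame(admission_date = dates, dur,
                         total_pet = rowSums(dur))
  daily <- data.frame(date = as.Date(start_date) + seq_len(year_days) - 1L,
                      admitted = counts)
  structure(list(patients = patients, daily = daily, seed = as.integer(seed),
                 year_days = as.integer(year_days)),
            class = "observed_dataset")
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat(sprintf("synthetic observed dataset: %d patients over %d days (seed %d)\n",
              nrow(x$patients), x$year_days, x$seed))
  cat(sprintf("daily admitted: mean %.1f, range [%d, %d]; mean total PET %.1f min\n",
              mean(x$daily$admitted), min(x$daily$admitted),
              max(x$daily$admitted), mean(x$patients$total_pet)))
  invisible(x)
}

#' Export / read an observed dataset as CSV
#'
#' One row per patient with an ISO admission date and per-stage minutes;
#' a companion `<path>_daily.csv` holds the daily admitted counts.  The
#' pair round-trips losslessly through [read_observed()].
#'
#' @param dataset An `observed_dataset`.
#' @param path Output CSV path for the patient-level table.
#' @return Invisibly, `path`.
#' @export
export_observed <- function(dataset, path) {
  stopifnot(inherits(dataset, "observed_dataset"))
  utils::write.csv(dataset$patients, path, row.names = FALSE)
  daily_path <- sub("\\.csv$", "_daily.csv", path)
  if (identical(daily_path, path)) daily_path <- paste0(path, "_daily.csv")
  utils::write.csv(dataset$daily, daily_path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_observed
#' @export
read_observed <- function(path) {
  patients <- utils::read.csv(path, stringsAsFactors = FALSE)
  patients$admission_date <- as.Date(patients$admission_date)
  daily_path <- sub("\\.csv$", "_daily.csv", path)
  if (identical(daily_path, path)) daily_path <- paste0(path, "_daily.csv")
  daily <- utils::read.csv(daily_path, stringsAsFactors = FALSE)
  daily$date <- as.Date(daily$date)
  structure(list(patients = patients, daily = daily,
                 seed = NA_integer_, year_days = nrow(daily)),
            class = "observed_dataset")
}
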