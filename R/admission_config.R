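# The concrete admission-flow model: configuration, presets, scenarios.

.subprocess_names <- c("registration", "triage", "assessment",
                       "referral_to_medicine", "decision_to_admit",
                       "room_allocation", "physical_transfer")

#' Admission-pathway configuration
#'
#' Loads the default model parameters (subprocess duration moments and
#' staffing, arrival process, routing funnel, bed pools) from the packaged
#' configuration file and applies the chosen arrival preset.
#'
#' Presets:
#' * `"admitted_only"` (default for queueing runs): every simulated patient
#'   is an admitted patient traversing all seven stages, with exponential
#'   inter-arrival `1440 / 52` minutes (the observed 52 admissions/day).
#' * `"funnel"`: ED front-door arrivals with mean inter-arrival 5.78
#'   minutes, a referral fraction `30185 / 386889` applied after assessment
#'   and an admission fraction `19058 / 30185` after the decision stage.
#'
#' @param preset `"admitted_only"` or `"funnel"`.
#' @param config_file Path to a JSON configuration; defaults to the file
#'   shipped with the package.
#' @return An object of class `admitflow_config`.
#' @examples
#' cfg <- admission_config()
#' cfg$subprocesses$mean
#' @export
admission_config <- function(preset = c("admitted_only", "funnel"),
                             config_file = NULL) {
  preset <- match.arg(preset)
  if (is.null(config_file))
    config_file <- system.file("extdata", "default_config.json",
                               package = "admitflow", mustWork = TRUE)
  raw <- jsonlite::fromJSON(config_file)
  sp <- as.data.frame(raw$subprocesses)
  if (!identical(sp$name, .subprocess_names))
    stop("admission_config: malformed config (subprocess names/order)")
  pools <- as.data.frame(raw$bed_pools)
  pools$los_mean_minutes <- pools$los_hours * 60
  names(pools)[names(pools) == "beds"] <- "capacity"

  referral_fraction <- raw$annual_funnel$referrals / raw$annual_funnel$ed_visits
  admit_fraction <- raw$annual_funnel$admissions / raw$annual_funnel$referrals
  arrival_mean <- switch(preset,
    admitted_only = 1440 / raw$arrivals$admitted_per_day,
    funnel = raw$arrivals$funnel_mean_interarrival_min)

  cfg <- structure(list(
    preset = preset,
    subprocesses = sp,
    arrival_mean = arrival_mean,
    referral_fraction = if (preset == "funnel") referral_fraction else 1,
    admit_fraction = if (preset == "funnel") admit_fraction else 1,
    funnel = list(referral_fraction = referral_fraction,
                  admit_fraction = admit_fraction,
                  ed_visits = raw$annual_funnel$ed_visits,
                  referrals = raw$annual_funnel$referrals,
                  admissions = raw$annual_funnel$admissions),
    ed_boarding_capacity = raw$ed_boarding_capacity,
    bed_pools = pools,
    daily_admissions = raw$daily_admissions,
    monthly_admissions = raw$monthly_admissions,
    multipliers = stats::setNames(rep(1, nrow(sp)), sp$name),
    admitting_team = FALSE,
    queue_cap = raw$queue_cap,
    six_hour_target = raw$six_hour_target_min,
    shifts = raw$shifts
  ), class = "admitflow_config")
  cfg
}

#' @export
print.admitflow_config <- function(x, ...) {
  cat(sprintf("admitflow config (preset '%s'): 7 subprocesses, %d beds, arrivals every %.3g min\n",
              x$preset, sum(x$bed_pools$capacity), x$arrival_mean))
  print(x$subprocesses[, c("name", "mean", "sd", "servers")], row.names = FALSE)
  if (x$admitting_team)
    cat("admitting team active: referral + decision servers pooled\n")
  invisible(x)
}

#' The scenario library
#'
#' The tested staffing and bed-capacity interventions, shipped as data.
#' Staffing scenarios 1--8 add servers to a named station (scenario 6 adds
#' two); scenario 9 activates the admitting team (the referral and
#' decision-to-admit servers are pooled into one flexible group); scenario
#' 10 combines 6 and 9; scenarios a--d add 31/22/14/10 ward beds with their
#' stated staffing companions.
#'
#' @return A data.frame, one row per scenario.
#' @export
scenario_library <- function() {
  path <- system.file("extdata", "scenarios.csv", package = "admitflow",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
    id = "character", description = "character", station = "character",
    server_delta = "integer", ward_beds_delta = "integer",
    aau_beds_delta = "integer", amau_beds_delta = "integer",
    admitting_team = "logical"))
}

#' Apply an intervention scenario to a configuration
#'
#' Returns a modified copy; the base configuration is unchanged.
#'
#' @param config An [admission_config()].
#' @param id Scenario id: one of `"0"`..`"10"`, `"a"`..`"d"` (numbers are
#'   accepted).
#' @return The modified `admitflow_config`.
#' @examples
#' base <- admission_config()
#' s6 <- apply_scenario(base, 6)
#' s6$subprocesses$servers - base$subprocesses$servers
#' @export
apply_scenario <- function(config, id) {
  stopifnot(inherits(config, "admitflow_config"))
  id <- as.character(id)
  lib <- scenario_library()
  if (!id %in% lib$id)
    stop(sprintf("apply_scenario: unknown scenario id '%s' (valid: %s)",
                 id, paste(lib$id, collapse = ", ")))
  row <- lib[lib$id == id, ]
  out <- config
  if (nzchar(row$station) && row$server_delta != 0) {
    k <- match(row$station, out$subprocesses$name)
    out$subprocesses$servers[k] <- out$subprocesses$servers[k] + row$server_delta
  }
  out$bed_pools$capacity <- out$bed_pools$capacity +
    c(row$ward_beds_delta, row$aau_beds_delta, row$amau_beds_delta)
  if (row$admitting_team) out$admitting_team <- TRUE
  out$scenario <- id
  out
}

#' Draw bed-pool dispositions
#'
#' Draws inpatient destinations (ward / AAU / AMAU) with the configured
#' admission shares.  Inside a simulation the same draw is made from the
#' dedicated `disposition` substream; this standalone version backs the
#' share-calibration tests and ad-hoc use.
#'
#' @param n Number of patients.
#' @param pools Bed-pool data.frame (`config$bed_pools`).
#' @param stream An [rng_stream()].
#' @return Character vector of pool labels.
#' @export
allocate_bed <- function(n, pools, stream) {
  stopifnot(n >= 1, abs(sum(pools$share) - 1) < 1e-9)
  u <- stream_runif(stream, n)
  idx <- findInterval(u, cumsum(pools$share), rightmost.closed = TRUE) + 1L
  pools$pool[idx]
}

# Build the des_network for a configuration (queueing mode).
admission_network <- function(config) {
  sp <- config$subprocesses
  stations <- lapply(seq_len(nrow(sp)), function(k) {
    d <- fit_triangular_from_moments(sp$mean[k], sp$sd[k])
    m <- config$multipliers[[sp$name[k]]]
    grp <- if (config$admitting_team &&
               sp$name[k] %in% c("referral_to_medicine", "decision_to_admit"))
      "admitting_team" else sp$name[k]
    station(sp$name[k], sp$servers[k],
            service = local({
              dd <- d; mm <- m
              function(p) mm * qtri(p, dd)
            }),
            group = grp)
  })
  continue_prob <- rep(1, 6)
  continue_prob[3] <- config$referral_fraction
  continue_prob[5] <- config$admit_fraction
  des_network(stations,
              exponential_arrival(config$arrival_mean),
              continue_prob = continue_prob,
              beds = list(station = 6L, pools = config$bed_pools),
              queue_cap = config$queue_cap)
}

#' Build the base admission model
#'
#' In `direct` mode each subprocess consumes a sampled triangular sojourn
#' moment-matched to the observed durations, with no resource contention --
#' this is the validated reproduction of the observed pathway.  In
#' `queueing` mode each subprocess is a multi-server FIFO station whose
#' intrinsic service-time distribution is the same triangular law scaled by
#' a per-station multiplier (see [calibrate_service_times()]), so that
#' waiting emerges from contention and staffing scenarios have a causal
#' mechanism.
#'
#' @param mode `"direct"` or `"queueing"`.
#' @param config An [admission_config()]; defaults to the admitted-only
#'   preset.
#' @return An `admitflow_model` object.
#' @export
build_base_model <- function(mode = c("direct", "queueing"), config = NULL) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- admission_config()
  stopifnot(inherits(config, "admitflow_config"))
  model <- list(mode = mode, config = config)
  if (mode == "queueing") model$network <- admission_network(config)
  class(model) <- "admitflow_model"
  model
}

#' @export
print.admitflow_model <- function(x, ...) {
  cat(sprintf("admitflow model, %s mode (preset '%s')\n", x$mode,
              x$config$preset))
  invisible(x)
}
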