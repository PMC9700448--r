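#' Shift schedule for a station's server pool
#'
#' Staffing is organised in shifts covering the 24-hour day; the counts per
#' shift may differ.  Entities already in service at a shift boundary always
#' complete service (no preemption), so a capacity drop only takes effect as
#' busy servers free up.
#'
#' @param per_shift_counts Integer vector, one server count per shift.
#' @param shift_length Shift length in minutes; `shifts * shift_length` must
#'   equal 1440.
#' @return An object of class `shift_schedule`.
#' @examples
#' shift_schedule(c(2, 2, 1))          # two day shifts, thin night shift
#' @export
shift_schedule <- function(per_shift_counts, shift_length = 1440 / length(per_shift_counts)) {
  per_shift_counts <- as.integer(per_shift_counts)
  stopifnot(length(per_shift_counts) >= 1L, all(per_shift_counts >= 0L))
  if (length(per_shift_counts) * shift_length != 1440)
    stop("shift_schedule: shifts_per_day * shift_length must equal 1440 minutes")
  structure(list(shifts_per_day = length(per_shift_counts),
                 shift_length = shift_length,
                 per_shift_counts = per_shift_counts),
            class = "shift_schedule")
}

#' A FIFO multi-server station
#'
#' @param name Station label.
#' @param servers Integer server count (constant 24/7) or a
#'   [shift_schedule()].
#' @param service Service-time law: a [triangular_dist()] or a quantile
#'   function `function(p) minutes`.
#' @param group Resource-group label; stations sharing a label draw servers
#'   from one pooled group (global FIFO across their queues).  Defaults to
#'   the station's own name.
#' @return An object of class `des_station`.
#' @export
station <- function(name, servers, service, group = name) {
  if (inherits(service, "triangular_dist")) {
    d <- service
    service <- function(p) qtri(p, d)
  }
  stopifnot(is.function(service))
  if (!inherits(servers, "shift_schedule")) {
    servers <- as.integer(servers)
    stopifnot(length(servers) == 1L, servers >= 1L)
  }
  structure(list(name = as.character(name), servers = servers,
                 service = service, group = as.character(group)),
            class = "des_station")
}

.station_base_count <- function(st) {
  if (inherits(st$servers, "shift_schedule")) max(st$servers$per_shift_counts)
  else st$servers
}

#' A feed-forward queueing network
#'
#' Patients enter at station 1 and move through the stations in order.
#' `continue_prob[k]` is the probability that a patient leaving station `k`
#' proceeds to station `k + 1` (routing uniforms come from a dedicated
#' substream, so the routing decisions are shared across scenarios under a
#' common master seed).  An optional bed gate in front of one station makes
#' patients hold a bed from that station until `los` minutes after they
#' complete the final station.
#'
#' @param stations List of [station()] objects, in pathway order.
#' @param arrivals An [exponential_arrival()].
#' @param continue_prob Numeric vector of length `K - 1` (default all 1).
#' @param beds Optional list with elements `station` (index of the gated
#'   station), `pools` (data.frame with columns `pool`, `capacity`, `share`,
#'   `los_mean_minutes`).
#' @param queue_cap Instability guard: an error is raised if any waiting
#'   line exceeds this many entities (default `1e6`).
#' @return An object of class `des_network`.
#' @export
des_network <- function(stations, arrivals, continue_prob = NULL,
                        beds = NULL, queue_cap = 1e6) {
  stopifnot(length(stations) >= 1L,
            all(vapply(stations, inherits, TRUE, "des_station")),
            inherits(arrivals, "exponential_arrival"))
  K <- length(stations)
  if (is.null(continue_prob)) continue_prob <- rep(1, max(K - 1L, 0L))
  stopifnot(length(continue_prob) == K - 1L,
            all(continue_prob >= 0), all(continue_prob <= 1))
  if (!is.null(beds)) {
    stopifnot(is.list(beds), beds$station >= 1L, beds$station <= K,
              is.data.frame(beds$pools),
              all(c("pool", "capacity", "share", "los_mean_minutes") %in%
                    names(beds$pools)))
    if (abs(sum(beds$pools$share) - 1) > 1e-9)
      stop("des_network: bed-pool shares must sum to 1")
  }
  structure(list(stations = stations, arrivals = arrivals,
                 continue_prob = continue_prob, beds = beds,
                 queue_cap = queue_cap),
            class = "des_network")
}

# Group layout: map stations to resource groups; a group's capacity is the
# sum of the base server counts of its member stations.
.group_layout <- function(net) {
  groups <- vapply(net$stations, `[[`, "", "group")
  gnames <- unique(groups)
  gidx <- match(groups, gnames)
  caps <- vapply(gnames, function(g)
    sum(vapply(net$stations[groups == g], .station_base_count, 0L)), 0L)
  list(names = gnames, station_group = gidx, capacity = as.integer(caps))
}

# Shift-boundary capacity-change schedule over [0, t_max].
.cap_changes <- function(net, layout, t_max) {
  times <- numeric(0); grp <- integer(0); val <- integer(0)
  groups <- vapply(net$stations, `[[`, "", "group")
  for (g in seq_along(layout$names)) {
    members <- net$stations[groups == layout$names[g]]
    schedules <- Filter(function(st) inherits(st$servers, "shift_schedule"),
                        members)
    if (!length(schedules)) next
    # per-minute-of-day counts summed over members
    day <- rep(0L, 1440)
    for (st in members) {
      if (inherits(st$servers, "shift_schedule")) {
        sl <- st$servers$shift_length
        day <- day + rep(st$servers$per_shift_counts, each = sl)
      } else day <- day + st$servers
    }
    if (length(unique(day)) == 1L) next
    bnd <- which(diff(day) != 0)                   # minute-of-day boundaries
    bnd <- sort(unique(c(0L, bnd)))
    for (d in 0:ceiling(t_max / 1440)) {
      tt <- d * 1440 + bnd
      keep <- tt <= t_max
      times <- c(times, tt[keep])
      grp <- c(grp, rep(g, sum(keep)))
      val <- c(val, day[bnd[keep] + 1L])
    }
  }
  list(times = times, group = as.integer(grp), value = as.integer(val))
}

# Draw arrival times on [0, horizon] from the arrivals substream.
.draw_arrivals <- function(arr, stream, horizon) {
  out <- numeric(0); t <- 0
  repeat {
    gaps <- stream_rexp(stream, 4096L, mean = arr$mean_interarrival)
    tt <- t + cumsum(gaps)
    out <- c(out, tt)
    t <- tt[length(tt)]
    if (t > horizon) break
  }
  out[out <= horizon]
}

#' Run a network simulation
#'
#' Executes the discrete-event simulation over `[0, horizon]` days.  All
#' external arrivals up to the horizon are injected and the event list is
#' drained, so every patient who enters also completes (statistics
#' downstream exclude patients arriving before the warm-up ends).
#'
#' @param net A [des_network()].
#' @param horizon_days Run length in days (arrivals stop at the horizon).
#' @param warmup_days Warm-up period; patients arriving before it are
#'   flagged and excluded from statistics.
#' @param master_seed Master seed; every substream is derived from it.
#' @param rep Replication index (substream suffix), so replications are
#'   independent while scenarios sharing `(master_seed, rep)` use common
#'   random numbers.
#' @return A `des_run` object: per-patient timestamps, bed events, group
#'   utilisation diagnostics.
#' @export
run_network <- function(net, horizon_days, warmup_days = 0, master_seed = 1L,
                        rep = 1L) {
  stopifnot(horizon_days > warmup_days, warmup_days >= 0)
  horizon <- horizon_days * 1440
  warmup <- warmup_days * 1440
  K <- length(net$stations)
  sid <- function(lab) rng_stream(master_seed, sprintf("%s/rep%d", lab, rep))

  arrivals <- .draw_arrivals(net$arrivals, sid("arrivals"), horizon)
  n <- length(arrivals)
  if (n == 0L) stop("run_network: no arrivals within the horizon")

  service <- matrix(0, n, K)
  for (k in seq_len(K)) {
    u <- stream_runif(sid(paste0("service:", net$stations[[k]]$name)), n)
    service[, k] <- net$stations[[k]]$service(u)
  }

  last_station <- rep.int(K, n)
  if (K > 1L && any(net$continue_prob < 1)) {
    u <- matrix(stream_runif(sid("routing"), n * (K - 1L)), n, K - 1L)
    for (k in seq_len(K - 1L)) {
      stopped <- last_station == K & u[, k] >= net$continue_prob[k]
      last_station[stopped] <- k
    }
  }

  bed_station <- 0L; pool_id <- integer(n); pool_cap <- integer(0)
  los <- numeric(n)
  if (!is.null(net$beds)) {
    bed_station <- as.integer(net$beds$station)
    shares <- net$beds$pools$share
    u <- stream_runif(sid("disposition"), n)
    pool_id <- as.integer(findInterval(u, cumsum(shares),
                                       rightmost.closed = TRUE) + 1L)
    pool_cap <- as.integer(net$beds$pools$capacity)
    u_los <- stream_runif(sid("los"), n)
    los <- stats::qexp(u_los) * net$beds$pools$los_mean_minutes[pool_id]
    pool_id[last_station < K] <- 0L   # never reaches the bed gate
  }

  layout <- .group_layout(net)
  cc <- .cap_changes(net, layout, t_max = horizon * 2 + 1440)

  res <- .run_des_cpp(arrivals, service, layout$station_group,
                      layout$capacity, last_station, bed_station, pool_id,
                      pool_cap, los, net$queue_cap,
                      cc$times, cc$group, cc$value)

  station_names <- vapply(net$stations, `[[`, "", "name")
  colnames(res$t_queue) <- colnames(res$t_start) <- colnames(res$t_end) <-
    station_names

  structure(list(
    arrivals = arrivals, last_station = last_station, pool_id = pool_id,
    t_queue = res$t_queue, t_start = res$t_start, t_end = res$t_end,
    bed_queue_t = res$bed_queue_t, bed_seize_t = res$bed_seize_t,
    bed_release_t = res$bed_release_t,
    pool_capacity = pool_cap,
    busy_minutes = stats::setNames(res$busy_minutes, layout$names),
    group_capacity = stats::setNames(layout$capacity, layout$names),
    max_queue = stats::setNames(res$max_queue, layout$names),
    station_names = station_names, bed_station = bed_station,
    horizon = horizon, warmup = warmup, master_seed = master_seed,
    rep = rep, n = n), class = "des_run")
}

#' @export
print.des_run <- function(x, ...) {
  cat(sprintf("des_run: %d arrivals over %.1f days (warm-up %.1f), %d stations\n",
              x$n, x$horizon / 1440, x$warmup / 1440,
              length(x$station_names)))
  invisible(x)
}

#' Event log of a run
#'
#' One record per (patient, station, event) with
#' `kind` in `{arrive, start_service, end_service}`, ordered by time with
#' ties broken by patient then station order.
#'
#' @param run A `des_run`.
#' @return A data.frame with columns `time`, `patient`, `station`, `kind`.
#' @export
event_log <- function(run) {
  stopifnot(inherits(run, "des_run"))
  K <- length(run$station_names)
  recs <- list()
  for (k in seq_len(K)) {
    reached <- !is.na(run$t_queue[, k])
    if (!any(reached)) next
    idx <- which(reached)
    recs[[length(recs) + 1L]] <- data.frame(
      time = c(run$t_queue[idx, k], run$t_start[idx, k], run$t_end[idx, k]),
      patient = rep.int(idx, 3L),
      station = run$station_names[k],
      kind = rep(c("arrive", "start_service", "end_service"),
                 each = length(idx)),
      stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, recs)
  log <- log[!is.na(log$time), , drop = FALSE]
  ord <- order(log$time, log$patient,
               match(log$station, run$station_names),
               match(log$kind, c("arrive", "start_service", "end_service")))
  log <- log[ord, , drop = FALSE]
  rownames(log) <- NULL
  attr(log, "horizon") <- run$horizon
  log
}

#' Flow-conservation check
#'
#' Asserts, per station and globally, that arrivals equal departures plus
#' entities still in the system at the horizon, and that bed-pool occupancy
#' never exceeds capacity.  A violation is an engine bug and raises an
#' error.
#'
#' @param run A `des_run` (or an [event_log()] data.frame for the
#'   station-level identity only).
#' @return Invisibly, a data.frame report (one row per station).
#' @export
conservation_check <- function(run) {
  if (is.data.frame(run)) {
    h <- attr(run, "horizon")
    if (is.null(h)) h <- Inf
    stations <- unique(run$station)
    rep_df <- do.call(rbind, lapply(stations, function(s) {
      sub <- run[run$station == s & run$time <= h, ]
      arr <- sum(sub$kind == "arrive")
      dep <- sum(sub$kind == "end_service")
      data.frame(station = s, arrivals = arr, departures = dep,
                 in_system = arr - dep, stringsAsFactors = FALSE)
    }))
    if (is.null(rep_df))
      rep_df <- data.frame(station = character(), arrivals = integer(),
                           departures = integer(), in_system = integer())
    if (any(rep_df$in_system < 0))
      stop("conservation_check: departures exceed arrivals (engine bug)")
    return(invisible(rep_df))
  }
  stopifnot(inherits(run, "des_run"))
  h <- run$horizon
  K <- length(run$station_names)
  rep_df <- do.call(rbind, lapply(seq_len(K), function(k) {
    arr <- sum(run$t_queue[, k] <= h, na.rm = TRUE)
    dep <- sum(run$t_end[, k] <= h, na.rm = TRUE)
    data.frame(station = run$station_names[k], arrivals = arr,
               departures = dep, in_system = arr - dep,
               stringsAsFactors = FALSE)
  }))
  if (any(rep_df$in_system < 0))
    stop("conservation_check: departures exceed arrivals (engine bug)")
  # every injected patient completed its path after draining
  done <- vapply(seq_len(run$n), function(i)
    !is.na(run$t_end[i, run$last_station[i]]), TRUE)
  if (!all(done))
    stop("conservation_check: undrained patients at end of run (engine bug)")
  # bed occupancy never exceeds capacity
  if (run$bed_station > 0L) {
    seized <- run$bed_seize_t[!is.na(run$bed_seize_t)]
    rel <- run$bed_release_t[!is.na(run$bed_seize_t)]
    pools <- run$pool_id[!is.na(run$bed_seize_t)]
    for (pl in unique(pools)) {
      ev <- rbind(data.frame(t = seized[pools == pl], d = 1),
                  data.frame(t = rel[pools == pl], d = -1))
      ev <- ev[order(ev$t, ev$d), ]
      occ <- max(cumsum(ev$d))
      if (occ > run$pool_capacity[pl])
        stop("conservation_check: bed-pool occupancy exceeds capacity (engine bug)")
      attr(rep_df, paste0("max_occupancy_pool_", pl)) <- occ
    }
  }
  invisible(rep_df)
}

#' Sojourn-time summary of a run
#'
#' Mean time in system (queueing + service) per station, over patients
#' arriving after the warm-up.
#'
#' @param run A `des_run`.
#' @return Named numeric vector of mean sojourns in minutes.
#' @export
station_sojourns <- function(run) {
  keep <- run$arrivals >= run$warmup
  soj <- run$t_end[keep, , drop = FALSE] - run$t_queue[keep, , drop = FALSE]
  colMeans(soj, na.rm = TRUE)
}
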