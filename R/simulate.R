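#' Replication protocol
#'
#' The experimental protocol: number of independent replications, run
#' horizon, warm-up, and the master seed from which all substreams are
#' derived.
#'
#' @param replications Number of replications (>= 2 for any variance
#'   estimate; default 10).
#' @param horizon_days Run length per replication (default 180 days).
#' @param warmup_days Warm-up excluded from statistics (default 7 days).
#' @param master_seed Integer master seed.
#' @return An object of class `replication_protocol`.
#' @export
replication_protocol <- function(replications = 10, horizon_days = 180,
                                 warmup_days = 7, master_seed = 1L) {
  stopifnot(replications >= 1, horizon_days > warmup_days, warmup_days >= 0)
  structure(list(replications = as.integer(replications),
                 horizon_days = horizon_days, warmup_days = warmup_days,
                 master_seed = as.integer(master_seed %% 2147483647)),
            class = "replication_protocol")
}

# One direct-mode replication: no contention, each stage consumes a sampled
# sojourn from its fitted triangular law.  Uses the same substream layout as
# the queueing engine so both modes share routing/arrival fabric under a
# common master seed.
.simulate_direct_rep <- function(config, horizon_days, warmup_days,
                                 master_seed, rep) {
  horizon <- horizon_days * 1440
  sid <- function(lab) rng_stream(master_seed, sprintf("%s/rep%d", lab, rep))
  arrivals <- .draw_arrivals(exponential_arrival(config$arrival_mean),
                             sid("arrivals"), horizon)
  n <- length(arrivals)
  sp <- config$subprocesses
  K <- nrow(sp)
  dur <- matrix(NA_real_, n, K, dimnames = list(NULL, sp$name))
  for (k in seq_len(K)) {
    d <- fit_triangular_from_moments(sp$mean[k], sp$sd[k])
    dur[, k] <- qtri(stream_runif(sid(paste0("service:", sp$name[k])), n), d)
  }
  last_station <- rep.int(K, n)
  cp <- rep(1, K - 1)
  cp[3] <- config$referral_fraction
  cp[5] <- config$admit_fraction
  if (any(cp < 1)) {
    u <- matrix(stream_runif(sid("routing"), n * (K - 1)), n, K - 1)
    for (k in seq_len(K - 1)) {
      stopped <- last_station == K & u[, k] >= cp[k]
      last_station[stopped] <- k
    }
  }
  for (k in seq_len(K)) dur[last_station < k, k] <- NA_real_
  pool <- allocate_bed(n, config$bed_pools, sid("disposition"))
  pool[last_station < K] <- NA_character_
  admitted <- last_station == K
  pet <- ifelse(admitted, rowSums(dur), NA_real_)
  list(rep = rep,
       patients = data.frame(arrival = arrivals, admitted = admitted,
                             pool = pool, pet = pet,
                             in_warmup = arrivals < warmup_days * 1440),
       sojourns = dur, run = NULL)
}

# Shared random fabric for one queueing-mode replication: arrival times,
# per-station service uniforms, routing, bed disposition, length-of-stay
# uniforms.  Scenarios sharing (master_seed, rep) share every draw.
.queueing_fabric <- function(config, horizon, master_seed, rep) {
  sid <- function(lab) rng_stream(master_seed, sprintf("%s/rep%d", lab, rep))
  A <- .draw_arrivals(exponential_arrival(config$arrival_mean),
                      sid("arrivals"), horizon)
  n <- length(A)
  sp <- config$subprocesses
  K <- nrow(sp)
  u_serv <- matrix(0, n, K, dimnames = list(NULL, sp$name))
  for (k in seq_len(K))
    u_serv[, k] <- stream_runif(sid(paste0("service:", sp$name[k])), n)
  last_station <- rep.int(K, n)
  cp <- rep(1, K - 1)
  cp[3] <- config$referral_fraction
  cp[5] <- config$admit_fraction
  if (any(cp < 1)) {
    u <- matrix(stream_runif(sid("routing"), n * (K - 1)), n, K - 1)
    for (k in seq_len(K - 1)) {
      stopped <- last_station == K & u[, k] >= cp[k]
      last_station[stopped] <- k
    }
  }
  u_disp <- stream_runif(sid("disposition"), n)
  pool_idx <- as.integer(findInterval(u_disp, cumsum(config$bed_pools$share),
                                      rightmost.closed = TRUE) + 1L)
  u_los <- stream_runif(sid("los"), n)
  list(A = A, n = n, u_serv = u_serv, last_station = last_station,
       pool_idx = pool_idx, u_los = u_los)
}

# Run one single-station (or pooled two-station) queue through the C++ core.
.run_station_cpp <- function(arrivals, service, caps, last_sub, bed = NULL,
                             queue_cap = 1e6) {
  if (is.null(bed))
    .run_des_cpp(arrivals, service, seq_len(ncol(service)) * 0L + 1L,
                 as.integer(sum(caps)), as.integer(last_sub), 0L,
                 integer(length(arrivals)), integer(0),
                 numeric(length(arrivals)), queue_cap,
                 numeric(0), integer(0), integer(0))
  else
    .run_des_cpp(arrivals, service, 1L, as.integer(sum(caps)),
                 as.integer(last_sub), 1L, bed$pool_idx,
                 as.integer(bed$pool_capacity), bed$hold, queue_cap,
                 numeric(0), integer(0), integer(0))
}

# One queueing-mode replication under the station-decomposition model:
# every stage's queue is fed by the admitted-patient stream at the
# patients' ED arrival times; the admitting-team scenario couples the
# referral and decision stages into a true tandem queue with pooled
# servers; beds are held from room-allocation seizure until transfer
# sojourn + inpatient length of stay have elapsed.
.queueing_rep <- function(config, horizon_days, warmup_days, master_seed,
                          rep, stations = NULL, keep_events = FALSE) {
  horizon <- horizon_days * 1440
  fab <- .queueing_fabric(config, horizon, master_seed, rep)
  sp <- config$subprocesses
  K <- nrow(sp)
  if (is.null(stations)) stations <- seq_len(K)
  if (6L %in% stations) stations <- union(stations, 7L)  # beds need transfer
  mult <- config$multipliers[sp$name]
  service <- matrix(NA_real_, fab$n, K)
  for (k in seq_len(K)) {
    d <- fit_triangular_from_moments(sp$mean[k], sp$sd[k])
    service[, k] <- mult[[k]] * qtri(fab$u_serv[, k], d)
  }
  soj <- matrix(NA_real_, fab$n, K, dimnames = list(NULL, sp$name))
  util <- stats::setNames(rep(NA_real_, K), sp$name)
  events <- if (keep_events) list() else NULL
  log_events <- function(idx, k, tq, ts, te) {
    if (!keep_events) return()
    events[[length(events) + 1L]] <<- data.frame(
      time = c(tq, ts, te), patient = rep.int(idx, 3L),
      station = sp$name[k],
      kind = rep(c("arrive", "start_service", "end_service"),
                 each = length(idx)), stringsAsFactors = FALSE)
  }

  pooled <- isTRUE(config$admitting_team)
  plain <- setdiff(stations, c(6L, if (pooled) c(4L, 5L)))
  for (k in plain) {
    idx <- which(fab$last_station >= k)
    if (!length(idx)) next
    res <- .run_station_cpp(fab$A[idx], service[idx, k, drop = FALSE],
                            sp$servers[k], rep.int(1L, length(idx)),
                            queue_cap = config$queue_cap)
    soj[idx, k] <- res$t_end[, 1] - fab$A[idx]
    util[k] <- res$busy_minutes[1] / (sp$servers[k] * horizon)
    log_events(idx, k, fab$A[idx], res$t_start[, 1], res$t_end[, 1])
  }
  if (pooled && any(c(4L, 5L) %in% stations)) {
    idx <- which(fab$last_station >= 4L)
    if (length(idx)) {
      last_sub <- ifelse(fab$last_station[idx] >= 5L, 2L, 1L)
      cap <- sp$servers[4] + sp$servers[5]
      res <- .run_des_cpp(fab$A[idx], service[idx, c(4L, 5L), drop = FALSE],
                          c(1L, 1L), as.integer(cap), as.integer(last_sub),
                          0L, integer(length(idx)), integer(0),
                          numeric(length(idx)), config$queue_cap,
                          numeric(0), integer(0), integer(0))
      soj[idx, 4] <- res$t_end[, 1] - fab$A[idx]
      soj[idx, 5] <- res$t_end[, 2] - res$t_end[, 1]
      util[4] <- util[5] <- res$busy_minutes[1] / (cap * horizon)
      log_events(idx, 4L, fab$A[idx], res$t_start[, 1], res$t_end[, 1])
      sub2 <- last_sub == 2L
      log_events(idx[sub2], 5L, res$t_queue[sub2, 2], res$t_start[sub2, 2],
                 res$t_end[sub2, 2])
    }
  }
  if (6L %in% stations) {
    idx <- which(fab$last_station >= 6L)
    if (length(idx)) {
      hold <- soj[idx, 7] +
        stats::qexp(fab$u_los[idx]) *
          config$bed_pools$los_mean_minutes[fab$pool_idx[idx]]
      res <- .run_station_cpp(fab$A[idx], service[idx, 6L, drop = FALSE],
                              sp$servers[6], rep.int(1L, length(idx)),
                              bed = list(pool_idx = fab$pool_idx[idx],
                                         pool_capacity = config$bed_pools$capacity,
                                         hold = hold),
                              queue_cap = config$queue_cap)
      soj[idx, 6] <- res$t_end[, 1] - fab$A[idx]
      util[6] <- res$busy_minutes[1] / (sp$servers[6] * horizon)
      log_events(idx, 6L, fab$A[idx], res$t_start[, 1], res$t_end[, 1])
    }
  }
  admitted <- fab$last_station == K
  pet <- ifelse(admitted, rowSums(soj), NA_real_)
  pool <- ifelse(admitted, config$bed_pools$pool[fab$pool_idx], NA_character_)
  out <- list(rep = rep,
              patients = data.frame(arrival = fab$A, admitted = admitted,
                                    pool = pool, pet = pet,
                                    in_warmup = fab$A < warmup_days * 1440),
              sojourns = soj, utilization = util, run = NULL)
  if (keep_events) {
    log <- do.call(rbind, events)
    log <- log[!is.na(log$time), , drop = FALSE]
    ord <- order(log$time, log$patient, match(log$station, sp$name))
    out$events <- `rownames<-`(log[ord, , drop = FALSE], NULL)
  }
  out
}

.simulate_queueing_rep <- function(model, horizon_days, warmup_days,
                                   master_seed, rep) {
  .queueing_rep(model$config, horizon_days, warmup_days, master_seed, rep)
}

#' Simulate the admission model under a replication protocol
#'
#' Runs `protocol$replications` independent replications of the model (in
#' its direct or queueing mode) and returns the per-patient results.  Under
#' a fixed `(protocol$master_seed, replication)` pair, two models that
#' differ only in staffing/bed scenario share every random draw (common
#' random numbers).
#'
#' @param model An `admitflow_model` from [build_base_model()] (possibly
#'   with a scenario applied to its config before building).
#' @param protocol A [replication_protocol()].
#' @return An `admitflow_sim` object (list of per-replication results).
#' @examples
#' \donttest{
#' m <- build_base_model("direct")
#' sim <- simulate_model(m, replication_protocol(2, 30, 2, master_seed = 7))
#' summarize_replications(sim)$pet_mean
#' }
#' @export
simulate_model <- function(model, protocol = replication_protocol()) {
  stopifnot(inherits(model, "admitflow_model"),
            inherits(protocol, "replication_protocol"))
  reps <- lapply(seq_len(protocol$replications), function(r) {
    if (model$mode == "direct")
      .simulate_direct_rep(model$config, protocol$horizon_days,
                           protocol$warmup_days, protocol$master_seed, r)
    else
      .simulate_queueing_rep(model, protocol$horizon_days,
                             protocol$warmup_days, protocol$master_seed, r)
  })
  structure(list(model = model, protocol = protocol, reps = reps),
            class = "admitflow_sim")
}

#' @export
print.admitflow_sim <- function(x, ...) {
  cat(sprintf("admitflow simulation: %d replication(s), %s mode, %g days (+%g warm-up)\n",
              length(x$reps), x$model$mode, x$protocol$horizon_days,
              x$protocol$warmup_days))
  invisible(x)
}
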