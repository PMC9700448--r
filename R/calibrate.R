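#' Calibrate intrinsic service times for queueing mode
#'
#' The observed per-stage durations are sojourns (waiting + service), not
#' hands-on service times.  Queueing mode therefore scales each station's
#' triangular duration law by a multiplier in `(0, 1]`, chosen so that the
#' simulated steady-state mean sojourn at base staffing reproduces the
#' observed mean.  Each station's sojourn is monotone increasing in its own
#' multiplier, so the multiplier is found by monotone bisection against
#' station-local simulations (the same station-decomposition world used by
#' queueing-mode measurement); every bisection iteration reuses the same
#' random fabric (common random numbers), which makes the target function
#' deterministic and the bisection exact up to the evaluation protocol's
#' Monte-Carlo resolution.
#'
#' The physical-transfer stage is calibrated before room allocation because
#' bed holds span the transfer sojourn plus the inpatient length of stay.
#'
#' @param config An [admission_config()] at base staffing.
#' @param targets Named per-station target mean sojourns (minutes); default
#'   the configured observed means.
#' @param tol Convergence tolerance per station in minutes (default 2).
#' @param max_iter Maximum bisection iterations per station (default 30).
#' @param eval_reps,eval_days,warmup_days Evaluation protocol per
#'   iteration: replications, horizon and warm-up (defaults 2 x 1500 days,
#'   14-day warm-up; heavily loaded stations have relaxation times of weeks,
#'   so long horizons buy calibration accuracy cheaply).
#' @param master_seed Master seed; calibration uses replication indices
#'   9001+ so later measurement runs (indices 1..R) are independent of it.
#' @param verbose Print per-station progress.
#' @return An `admitflow_calibration`: `config` (with multipliers set),
#'   `report` (per-station multiplier, achieved sojourn, target, servers,
#'   utilisation, convergence flag).
#' @export
calibrate_service_times <- function(config, targets = NULL, tol = 2,
                                    max_iter = 30, eval_reps = 2,
                                    eval_days = 1500, warmup_days = 14,
                                    master_seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "admitflow_config"), tol > 0, max_iter >= 1)
  if (isTRUE(config$admitting_team))
    stop("calibrate_service_times: calibrate at base staffing (no admitting team)")
  sp <- config$subprocesses
  K <- nrow(sp)
  if (is.null(targets)) targets <- stats::setNames(sp$mean, sp$name)
  targets <- targets[sp$name]

  # arrival rate into each station (per minute), for the stability bracket
  cp <- rep(1, K - 1)
  cp[3] <- config$referral_fraction
  cp[5] <- config$admit_fraction
  lambda <- (1 / config$arrival_mean) * cumprod(c(1, cp))

  hi0 <- pmin(1, 0.98 * sp$servers / (lambda * sp$mean))
  lo0 <- rep(1e-3, K)
  if (any(hi0 <= lo0)) {
    bad <- sp$name[hi0 <= lo0]
    stop(sprintf(paste0(
      "calibrate_service_times: station(s) %s are fed faster than their ",
      "target sojourn allows (no stable multiplier in (0, 1])"),
      paste(bad, collapse = ", ")))
  }

  cfg <- config
  eval_station <- function(k) {
    acc <- 0; util <- 0
    for (r in seq_len(eval_reps)) {
      rr <- .queueing_rep(cfg, eval_days, warmup_days, master_seed,
                          rep = 9000L + r, stations = k)
      sel <- !rr$patients$in_warmup & !is.na(rr$sojourns[, k])
      acc <- acc + mean(rr$sojourns[sel, k])
      util <- util + rr$utilization[k]
    }
    c(sojourn = acc / eval_reps, util = unname(util) / eval_reps)
  }

  order_k <- c(1L, 2L, 3L, 4L, 5L, 7L, 6L)   # transfer before room
  report <- vector("list", K)
  for (k in order_k) {
    lo <- lo0[k]; hi <- hi0[k]
    m <- hi                                   # start from the feasible top
    achieved <- NA_real_; util <- NA_real_
    for (it in seq_len(max_iter)) {
      cfg$multipliers[[sp$name[k]]] <- m
      e <- eval_station(k)
      achieved <- e[["sojourn"]]; util <- e[["util"]]
      err <- achieved - targets[[k]]
      if (verbose)
        message(sprintf("%s iter %2d: m = %.5f, sojourn = %.2f (target %.1f)",
                        sp$name[k], it, m, achieved, targets[[k]]))
      if (abs(err) <= tol) break
      if (err < 0) lo <- m else hi <- m
      m <- (lo + hi) / 2
    }
    cfg$multipliers[[sp$name[k]]] <- m
    report[[k]] <- data.frame(
      station = sp$name[k], multiplier = m, target = targets[[k]],
      achieved = achieved, service_mean = m * sp$mean[k],
      servers = sp$servers[k], utilization = util,
      converged = abs(achieved - targets[[k]]) <= tol,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, report)
  if (!all(report$converged)) {
    bad <- report[!report$converged, ]
    stop(paste0(
      "calibrate_service_times: no convergence within max_iter for: ",
      paste(sprintf("%s (achieved %.1f vs target %.1f, utilization %.2f)",
                    bad$station, bad$achieved, bad$target, bad$utilization),
            collapse = "; ")))
  }
  structure(list(config = cfg, report = report, converged = TRUE),
            class = "admitflow_calibration")
}

#' @export
print.admitflow_calibration <- function(x, ...) {
  cat("admitflow service-time calibration\n")
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}
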