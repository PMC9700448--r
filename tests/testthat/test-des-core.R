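# Engine correctness against hand checks and queueing-theory closed forms.

test_that("two deterministic patients queue as hand-computed", {
  # 1 server, service 10 min, arrivals at t = 0 and t = 1
  res <- admitflow:::.run_des_cpp(
    arrivals = c(0, 1), service = matrix(10, 2, 1),
    station_group = 1L, group_capacity = 1L, last_station = c(1L, 1L),
    bed_station = 0L, pool_id = c(0L, 0L), pool_capacity = integer(0),
    los = c(0, 0), queue_cap = 1e6,
    cap_change_times = numeric(0), cap_change_group = integer(0),
    cap_change_value = integer(0))
  expect_equal(res$t_start[, 1], c(0, 10))   # second waits 9 minutes
  expect_equal(res$t_end[, 1], c(10, 20))
  # conservation after t = 20: 2 arrivals, 2 departures, 0 in system
  expect_equal(res$t_end[2, 1] - res$t_queue[2, 1], 19)
})

test_that("M/M/1 sojourn matches the closed form", {
  # utilization 0.5: inter-arrival mean 2, service mean 1 -> W = 2
  st <- station("svc", 1, service = function(p) stats::qexp(p, rate = 1))
  net <- des_network(list(st), exponential_arrival(2))
  run <- run_network(net, horizon_days = 400, warmup_days = 10,
                     master_seed = 42)
  expect_lt(abs(station_sojourns(run) - mm1_sojourn(0.5, 1)), 0.1)
  rep_df <- conservation_check(run)
  expect_identical(rep_df$arrivals, rep_df$departures + rep_df$in_system)
})

test_that("M/M/2 waiting time matches the Erlang-C oracle", {
  lambda <- 0.75; mu <- 0.5                     # a = 1.5 Erlangs, rho = 0.75
  st <- station("svc", 2, service = function(p) stats::qexp(p, rate = mu))
  net <- des_network(list(st), exponential_arrival(1 / lambda))
  run <- run_network(net, horizon_days = 200, warmup_days = 5,
                     master_seed = 9)
  w_sim <- station_sojourns(run) - 1 / mu
  expect_lt(abs(w_sim - mmc_wq(lambda, mu, 2)), 0.25)
})

test_that("erlang_c oracle has the right limits", {
  expect_equal(erlang_c(0.5, 1, 1), 0.5)         # M/M/1: C = rho
  expect_equal(mmc_wq(0.5, 1, 1), 1)             # rho/(mu - lambda)
  expect_equal(erlang_c(2, 1, 2), 1)             # at capacity
  expect_lt(erlang_c(0.75, 0.5, 3), erlang_c(0.75, 0.5, 2))
})

test_that("event logs are ordered, FIFO and bit-deterministic", {
  st <- station("svc", 1, service = function(p) stats::qexp(p, rate = 0.8))
  net <- des_network(list(st), exponential_arrival(2))
  r1 <- run_network(net, 30, 0, master_seed = 7)
  r2 <- run_network(net, 30, 0, master_seed = 7)
  expect_identical(event_log(r1), event_log(r2))

  log <- event_log(r1)
  expect_true(all(diff(log$time) >= 0))
  # per patient: arrive <= start <= end
  expect_true(all(r1$t_queue <= r1$t_start & r1$t_start <= r1$t_end))
  # FIFO: service starts in arrival order at a single-station queue
  starts <- log[log$kind == "start_service", ]
  expect_identical(starts$patient, sort(starts$patient))
  # conservation on the log view and on the empty log
  expect_no_error(conservation_check(log))
  empty <- data.frame(time = numeric(), patient = integer(),
                      station = character(), kind = character())
  rep0 <- conservation_check(empty)
  expect_identical(nrow(rep0), 0L)
})

test_that("adding a server never increases waiting (common random numbers)", {
  mk <- function(c_servers) {
    st <- station("svc", c_servers,
                  service = function(p) stats::qexp(p, rate = 0.6))
    run_network(des_network(list(st), exponential_arrival(2)),
                60, 2, master_seed = 13)
  }
  expect_lte(station_sojourns(mk(2)), station_sojourns(mk(1)))
  expect_lte(station_sojourns(mk(3)), station_sojourns(mk(2)))
})

test_that("unstable queues hit the waiting-line cap with a clear error", {
  st <- station("svc", 1, service = function(p) stats::qexp(p, rate = 0.01))
  net <- des_network(list(st), exponential_arrival(1), queue_cap = 50)
  expect_error(run_network(net, 10, 0, master_seed = 1), "instability")
})

test_that("shift schedules are validated and drive capacity changes", {
  expect_error(shift_schedule(c(2, 2), shift_length = 100), "1440")
  sched <- shift_schedule(c(3, 3, 1))     # thin night shift
  expect_identical(sched$shifts_per_day, 3L)

  st <- station("svc", sched, service = function(p) stats::qexp(p, 1))
  net <- des_network(list(st), exponential_arrival(1))
  run <- run_network(net, 20, 1, master_seed = 21)
  rep_df <- conservation_check(run)
  expect_identical(rep_df$arrivals, rep_df$departures + rep_df$in_system)
  # constant staffing at max(counts) can only be faster
  st2 <- station("svc", 3L, service = function(p) stats::qexp(p, 1))
  run2 <- run_network(des_network(list(st2), exponential_arrival(1)),
                      20, 1, master_seed = 21)
  expect_lte(station_sojourns(run2), station_sojourns(run))
})

test_that("bed gate caps occupancy and queues FIFO", {
  pools <- data.frame(pool = c("w", "x"), capacity = c(3L, 2L),
                      share = c(0.6, 0.4), los_mean_minutes = c(600, 600))
  sts <- list(station("pre", 5, service = function(p) stats::qexp(p, 1/5)),
              station("gated", 5, service = function(p) stats::qexp(p, 1/5)))
  net <- des_network(sts, exponential_arrival(15),
                     beds = list(station = 2L, pools = pools))
  run <- run_network(net, 30, 0, master_seed = 3)
  rep_df <- conservation_check(run)   # errors if occupancy > capacity
  occ1 <- attr(rep_df, "max_occupancy_pool_1")
  expect_lte(occ1, 3L)
  expect_gt(occ1, 0L)
})
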