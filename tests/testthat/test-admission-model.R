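test_that("default configuration carries the observed parameters exactly", {
  cfg <- admission_config()
  tab <- table1_moments()
  expect_identical(cfg$subprocesses$name, tab$name)
  expect_identical(cfg$subprocesses$mean, tab$mean)
  expect_identical(cfg$subprocesses$sd, tab$sd)
  expect_identical(cfg$subprocesses$order, 1:7)
  expect_equal(sum(cfg$subprocesses$mean), 976)

  expect_identical(cfg$bed_pools$pool, c("ward", "AAU", "AMAU"))
  expect_identical(cfg$bed_pools$capacity, c(173L, 24L, 51L))
  expect_equal(sum(cfg$bed_pools$capacity), 248)
  expect_equal(cfg$bed_pools$share, c(0.45, 0.35, 0.20))
  expect_identical(cfg$ed_boarding_capacity, 250L)

  # routing funnel fractions
  expect_equal(cfg$funnel$referral_fraction, 30185 / 386889)
  expect_equal(cfg$funnel$admit_fraction, 19058 / 30185)

  # presets
  expect_equal(cfg$arrival_mean, 1440 / 52)
  fcfg <- admission_config("funnel")
  expect_equal(fcfg$arrival_mean, 5.78)
  expect_equal(fcfg$referral_fraction, 30185 / 386889)
})

test_that("scenarios modify a copy of the configuration as specified", {
  base <- admission_config()
  expect_identical(apply_scenario(base, "0")$subprocesses,
                   base$subprocesses)
  expect_identical(apply_scenario(base, "0")$bed_pools, base$bed_pools)
  expect_false(apply_scenario(base, "0")$admitting_team)

  s6 <- apply_scenario(base, 6)
  delta <- s6$subprocesses$servers - base$subprocesses$servers
  expect_identical(delta, c(0L, 0L, 0L, 0L, 2L, 0L, 0L))
  expect_identical(s6$bed_pools, base$bed_pools)
  # base untouched
  expect_identical(base$subprocesses$servers[5],
                   admission_config()$subprocesses$servers[5])

  # scenario 10 is the composition of 6 and 9
  s10 <- apply_scenario(base, "10")
  s6_9 <- apply_scenario(apply_scenario(base, "6"), "9")
  expect_identical(s10$subprocesses, s6_9$subprocesses)
  expect_identical(s10$admitting_team, s6_9$admitting_team)
  expect_true(s10$admitting_team)

  sa <- apply_scenario(base, "a")
  expect_identical(sa$bed_pools$capacity - base$bed_pools$capacity,
                   c(31L, 0L, 0L))

  expect_error(apply_scenario(base, "zz"), "valid")
})

test_that("bed disposition draws follow the configured shares", {
  cfg <- admission_config()
  pools1 <- cfg$bed_pools; pools1$share <- c(1, 0, 0)
  expect_true(all(allocate_bed(500, pools1, rng_stream(1, "d")) == "ward"))

  draws <- allocate_bed(1e5, cfg$bed_pools, rng_stream(8, "disposition"))
  frac <- table(factor(draws, c("ward", "AAU", "AMAU"))) / 1e5
  for (i in 1:3) {
    p <- cfg$bed_pools$share[i]
    expect_lt(abs(frac[[i]] - p), 4 * sqrt(p * (1 - p) / 1e5))
  }
})

test_that("direct mode with zero SDs yields identical PETs equal to the sum", {
  cfg <- deterministic_config(60)
  sim <- simulate_model(build_base_model("direct", cfg),
                        replication_protocol(1, 10, 0, master_seed = 2))
  pet <- sim$reps[[1]]$patients$pet
  expect_true(all(pet == 420))
})

test_that("direct-mode mean PET converges to the sum of observed means", {
  sim <- simulate_model(build_base_model("direct"),
                        replication_protocol(1, 400, 0, master_seed = 6))
  pet <- sim$reps[[1]]$patients$pet
  # PET is a sum of 7 independent triangulars: sd = sqrt(sum sd_k^2)
  sd_pet <- sqrt(sum(table1_moments()$sd^2))
  expect_lt(abs(mean(pet) - 976), 4 * sd_pet / sqrt(length(pet)))
  # replication-result invariants
  s <- summarize_replications(sim)
  expect_gte(s$pet_mean, max(s$subprocess$mean))
  expect_lte(s$pet_iqr[1], s$pet_median)
  expect_lte(s$pet_median, s$pet_iqr[2])
})

test_that("queueing-mode bed pools never exceed capacity and hold FIFO", {
  cfg <- calibrated_config()
  cfg$bed_pools$capacity <- c(60L, 20L, 25L)   # tighten to force waiting
  rr <- admitflow:::.queueing_rep(cfg, 120, 7, 31L, 1L)
  # all admitted patients complete with positive stage sojourns
  sel <- rr$patients$admitted
  expect_true(all(rr$sojourns[sel, ] > 0, na.rm = TRUE))
  expect_true(all(rr$patients$pet[sel] >=
                    rowSums(rr$sojourns[sel, , drop = FALSE]) - 1e-9))
})
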