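p_default <- sim_params()

test_that("closed-form mass balance reproduces the scenario algebra", {
  ctl <- nAS25_titer_at_G1_exit(1, p_default, scenario("control"))
  expect_lt(abs(ctl$total - 1), 1e-6)       # homeostasis

  rosco <- nAS25_titer_at_G1_exit(1, p_default, scenario("roscovitine"))
  expect_equal(rosco$total, 0.5)

  both <- nAS25_titer_at_G1_exit(
    1, p_default, scenario(c("roscovitine", "rnai_nAS25"),
                           efficiency = 0.54))
  expect_equal(both$total, 0.5 * 0.46)      # exact scenario algebra: 0.23
  expect_equal(both$total / rosco$total, 0.46)

  dcas9 <- nAS25_titer_at_G1_exit(1, p_default, scenario("dcas9_block"))
  expect_equal(dcas9$total, 0.5 + 0.5 * (1 - 0.92))  # 46% reduction

  # titer scales linearly with the inherited pool
  expect_equal(nAS25_titer_at_G1_exit(2, p_default,
                                      scenario("roscovitine"))$total, 1)
  expect_error(nAS25_titer_at_G1_exit(-1, p_default, scenario("control")),
               ">= 0")
})

test_that("g1_duration is monotone with the documented limits", {
  expect_equal(g1_duration(0, p_default, noise = FALSE), p_default$G1_max)
  expect_lt(g1_duration(50, p_default, noise = FALSE),
            p_default$G1_min + 1e-6)
  n_grid <- seq(0, 3, by = 0.25)
  g <- g1_duration(n_grid, p_default, noise = FALSE)
  expect_true(all(diff(g) < 0))
  # control calibration: mean cycle within 5% of 900 min over 1e3 draws
  set.seed(8)
  g1 <- g1_duration(rep(p_default$masking_slope, 1000), p_default)
  cycle <- g1 + p_default$d_S + p_default$d_G2 + p_default$d_M
  expect_lt(abs(mean(cycle) - 900) / 900, 0.05)
})

test_that("division partitions titers per convention and conserves counts", {
  mother <- cell_state(1, phase = "M", nAS25_F0 = 0.6, nAS25_F1 = 0.4)
  kids <- divide_cell(mother, time = 900, ids = c(2L, 3L))
  # concentration convention: each daughter inherits the concentration
  expect_equal(kids[[1]]$nAS25_F0, 1.0)
  expect_equal(kids[[2]]$nAS25_F0, 1.0)
  expect_equal(kids[[1]]$generation, 1L)
  expect_equal(kids[[1]]$phase, "G0")
  expect_equal(kids[[1]]$nAS25_F1, 0)

  mother_n <- cell_state(1, phase = "M", nAS25_F0 = 1000, nAS25_F1 = 0)
  kids_n <- divide_cell(mother_n, 900, c(2L, 3L), partition = "binomial",
                        rng_seed = 4)
  expect_equal(kids_n[[1]]$nAS25_F0 + kids_n[[2]]$nAS25_F0, 1000)

  g1_cell <- cell_state(1, phase = "G1")
  expect_error(divide_cell(g1_cell, 100), "outside M")
})

test_that("simulator hits the control cycle length and titer homeostasis", {
  rec <- simulate_lineage(300, 1800, p_default, scenario("control"),
                          rng_seed = 2)
  cc <- nascycle:::completed_cycles(rec)
  expect_gt(length(cc), 500)
  expect_lt(abs(mean(cc) - 900) / 900, 0.05)
  # stochastic homeostasis: mean G1-exit titer within 5% of the pre-G1 titer
  expect_lt(abs(mean(rec$cells$g1_exit_titer) - 1), 0.05)
  # conservation of lineage bookkeeping: two daughters per division
  expect_equal(nrow(rec$events) * 2,
               sum(rec$cells$generation > 0))
})

test_that("empty and parked populations behave", {
  rec0 <- simulate_lineage(0, 100, p_default, scenario("control"),
                           rng_seed = 1)
  expect_equal(nrow(rec0$cells), 0L)
  expect_equal(nrow(rec0$events), 0L)
  ss <- simulate_lineage(50, 600, p_default, scenario("serum_starvation"),
                         rng_seed = 1)
  expect_equal(nrow(ss$events), 0L)
  expect_true(all(is.na(ss$cells$realized_G1)))
})

test_that("titer trajectory shows the 2-fold M-to-G1 drop then recovery", {
  tr <- titer_trajectory(p_default, scenario("control"), pre_G1_titer = 1)
  expect_equal(1 / min(tr$titer), 2)
  expect_equal(tr$titer[nrow(tr)], 1, tolerance = 1e-9)
  # survival estimated back from the stochastic record within 10%
  rec <- simulate_lineage(200, 1600, p_default, scenario("control"),
                          rng_seed = 6)
  s_hat <- estimate_survival(rec)
  expect_lt(abs(s_hat - p_default$s_survival) / p_default$s_survival, 0.1)
})

test_that("G2 arrest leaves the transmitted titer unchanged", {
  ra <- simulate_lineage(200, 900, p_default, scenario("ro3306_g2_arrest"),
                         rng_seed = 4)
  rc <- simulate_lineage(200, 900, p_default, scenario("control"),
                         rng_seed = 4)
  t_a <- mean(ra$cells$g1_exit_titer[ra$cells$generation == 0])
  t_c <- mean(rc$cells$g1_exit_titer[rc$cells$generation == 0])
  expect_lt(abs(t_a - t_c) / t_c, 0.05)
  expect_lt(nrow(ra$events), nrow(rc$events))  # arrest suppresses division
})

test_that("mother-daughter G1 coupling is negative, and absent at beta 0", {
  rec <- simulate_lineage(300, 1800, p_default, scenario("control"),
                          rng_seed = 2)
  cs <- compensation_statistics(rec)
  expect_gt(cs$n_pairs, 30)
  expect_lt(cs$g1_correlation, -0.2)
  # oscillation period tracks the interphase length within 20%
  expect_false(is.na(cs$oscillation_period))
  expect_lt(abs(cs$oscillation_period - cs$mean_interphase) /
              cs$mean_interphase, 0.2)

  p0 <- sim_params(beta = 1e-9)
  rec0 <- simulate_lineage(300, 1800, p0, scenario("control"), rng_seed = 2)
  cs0 <- compensation_statistics(rec0)
  expect_lt(abs(cs0$g1_correlation), 0.1)

  tiny <- simulate_lineage(3, 500, p_default, scenario("control"),
                           rng_seed = 1)
  expect_error(compensation_statistics(tiny), "too few")
})

test_that("identical seeds yield byte-identical exports", {
  f <- function() {
    rec <- simulate_lineage(60, 1200, p_default, scenario("control"),
                            rng_seed = 9)
    ev <- withr::local_tempfile(fileext = ".csv")
    ti <- withr::local_tempfile(fileext = ".csv")
    write_lineage_record(rec, ev, ti)
    c(tools::md5sum(ev), tools::md5sum(ti))
  }
  expect_identical(unname(f()), unname(f()))
})

test_that("parameter validation rejects impossible configurations", {
  expect_error(sim_params(s_survival = 1.2), "s_survival")
  expect_error(sim_params(G1_min = 500), "G1_min < G1_base")
  expect_error(sim_params(d_S = -1), "positive")
  expect_error(scenario("warp_drive"), "unknown scenario")
  expect_error(scenario("rnai_nAS25", efficiency = 2), "efficiency")
})
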