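fx <- hp_fixtures()
tgrid <- seq(0, 30, by = 1)

test_that("identical seeds give bit-identical stochastic trajectories", {
  a <- simulate_timecourse(list(fx$DP13), counts = 200, t_grid = tgrid,
                           seed = 11)
  b <- simulate_timecourse(list(fx$DP13), counts = 200, t_grid = tgrid,
                           seed = 11)
  expect_identical(a$amounts, b$amounts)
  c <- simulate_timecourse(list(fx$DP13), counts = 200, t_grid = tgrid,
                           seed = 12)
  expect_false(identical(a$amounts, c$amounts))
  expect_error(simulate_timecourse(list(fx$DP13), t_grid = tgrid),
               class = "hepseq_need_seed")
  expect_error(simulate_timecourse(list(fx$DP13), t_grid = c(-1, 0, 1),
                                   seed = 1), class = "hepseq_bad_grid")
})

test_that("exolytic digestion of a saturated pool shows DP2-only chromophores", {
  tc <- simulate_timecourse(list(fx$DP13), counts = 500, t_grid = tgrid,
                            seed = 5)
  vis_big <- tc$species$n_delta > 0 & tc$species$dp > 2
  expect_true(all(tc$amounts[, vis_big] == 0))
  expect_equal(exolytic_index(tc), 0)
  # mid-digestion, unsaturated disaccharides are present
  expect_gt(sum(tc$amounts[10, tc$species$n_delta > 0]), 0)
})

test_that("endolytic action creates larger unsaturated intermediates", {
  endo <- enzyme_spec("endoMut", "endo")
  tc <- simulate_timecourse(list(fx$DP13), counts = 200, enzyme = endo,
                            t_grid = tgrid, seed = 5)
  expect_gt(exolytic_index(tc), 0)
  # randomized pools and seeds: the exo signature is structural, not lucky
  for (seed in 1:10) {
    pool <- lapply(1:3, function(i) {
      ch <- generate_chain(chain_distribution(nre = "saturated"),
                           n_units = sample(3:6, 1), seed = seed * 10 + i)
      ch
    })
    tce <- simulate_timecourse(pool, counts = c(20, 20, 20), t_grid = tgrid,
                               seed = seed)
    expect_equal(exolytic_index(tce), 0)
  }
})

test_that("residues are conserved exactly (stochastic) and to tolerance (ODE)", {
  tc <- simulate_timecourse(list(fx$DP13), counts = 300, t_grid = tgrid,
                            seed = 3)
  expect_true(all(total_residues(tc) == 13 * 300))
  td <- simulate_timecourse(list(fx$DP13), counts = 300, t_grid = tgrid,
                            mode = "deterministic")
  expect_true(all(abs(total_residues(td) - 13 * 300) / (13 * 300) < 1e-6))
  tend <- simulate_timecourse(list(fx$DP13), counts = 100,
                              enzyme = enzyme_spec("endoMut", "endo"),
                              t_grid = tgrid, mode = "deterministic")
  expect_true(all(abs(total_residues(tend) - 13 * 100) / 1300 < 1e-6))
})

test_that("cumulative dUA and simulated A232 are non-decreasing", {
  for (mode in c("stochastic", "deterministic")) {
    tc <- simulate_timecourse(list(fx$DP13), counts = 300, t_grid = tgrid,
                              mode = mode, seed = 9)
    expect_true(all(diff(delta_ua_formed(tc)) > -1e-8))
    expect_true(all(diff(a232_signal(tc)) > -1e-5))
  }
})

test_that("stochastic and deterministic trajectories agree for large pools", {
  n <- 10000
  ts <- seq(0, 8, by = 2)
  st <- simulate_timecourse(list(fx$DP13), counts = n, t_grid = ts, seed = 21)
  de <- simulate_timecourse(list(fx$DP13), counts = n, t_grid = ts,
                            mode = "deterministic")
  expect_identical(colnames(st$amounts), colnames(de$amounts))
  for (j in seq_len(ncol(st$amounts))) {
    mc_se <- sqrt(pmax(de$amounts[, j], 1))  # Poisson-scale bound
    expect_true(all(abs(st$amounts[, j] - de$amounts[, j]) <= 3 * mc_se + 3))
  }
})

test_that("default rates reproduce the tetrasaccharide preference ordering", {
  rr <- relative_rate_check(default_rate_table(),
                            fx[c("P4_8", "P4_7", "P4_6", "P4_5", "P4_4")])
  expect_true(all(diff(rr) < 0))  # strictly decreasing P4-8 ... P4-4

  uni <- rate_table(setNames(numeric(0), character(0)), default = 1)
  ru <- relative_rate_check(uni, fx[c("P4_8", "P4_7", "P4_6", "P4_5", "P4_4")])
  expect_true(all(abs(ru - ru[1]) < 1e-12))
})

test_that("stochastic completion times order inversely to hazards", {
  meds <- vapply(c("P4_8", "P4_7", "P4_6", "P4_5", "P4_4"), function(nm)
    median(simulate_completion_times(fx[[nm]], n = 300, seed = 17)),
    numeric(1))
  expect_true(all(diff(meds) > 0))  # slowest substrate last
})

test_that("empty pools give empty time courses", {
  tc <- simulate_timecourse(list(), t_grid = tgrid, seed = 1)
  expect_equal(nrow(tc$species), 0L)
  expect_equal(exolytic_index(tc), 0)
  expect_equal(total_residues(tc), rep(0, length(tgrid)))
})
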