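traj <- function(scores, t0 = 4, dt = 0.5) {
  data.frame(t_hours = t0 + dt * (seq_along(scores) - 1), score = scores)
}

test_that("longest_run matches exhaustive enumeration and breaks ties early", {
  band <- function(x) x >= 0.2 & x <= 0.3
  v <- c(0.25, 0.25, 0.5, 0.25, 0.25, 0.25)
  expect_identical(longest_run(v, band), c(4L, 6L))
  expect_null(longest_run(c(0.5, 0.9), band))
  # two equal-length runs: the earlier one wins
  v2 <- c(0.25, 0.25, 0.9, 0.25, 0.25)
  expect_identical(longest_run(v2, band), c(1L, 2L))

  set.seed(77)
  for (i in 1:300) {
    x <- round(runif(sample(1:25, 1)), 2)
    got <- longest_run(x, band)
    want <- oracle_longest_run(x, band)
    expect_identical(got, if (is.null(want)) NULL else as.integer(want))
  }
})

test_that("timing estimators read the documented run endpoints", {
  cfg <- pipeline_config()

  # onset: last point of the longest in-band run
  st <- traj(c(rep(0.25, 5), rep(0.8, 5)), t0 = 4, dt = 0.5)
  expect_equal(detect_onset(st, cfg), 4 + 4 * 0.5)
  expect_true(is.na(detect_onset(traj(rep(0.9, 6)), cfg)))

  # high stable: first point of the longest high-band run
  st2 <- traj(rep(0.75, 6))
  expect_equal(detect_high_stable(st2, cfg), st2$t_hours[1])
  expect_true(is.na(detect_high_stable(traj(rep(0.5, 6)), cfg)))

  # terminal: strictly above 0.78; exact 0.78 never qualifies
  expect_true(is.na(terminal_time(traj(rep(0.78, 10)), cfg)))
  st3 <- traj(c(rep(0.9, 3), 0.5, rep(0.9, 5)))
  expect_equal(terminal_time(st3, cfg), st3$t_hours[5])

  # duration is the plain difference, NA-propagating
  st4 <- traj(c(rep(0.25, 3), 0.5, rep(0.75, 4)), t0 = 10, dt = 1.1)
  onset <- detect_onset(st4, cfg); high <- detect_high_stable(st4, cfg)
  expect_equal(differentiation_duration(st4, cfg), high - onset)
  expect_true(is.na(differentiation_duration(traj(rep(0.75, 5)), cfg)))

  # noisy band-straddling trajectories agree with the brute-force oracle
  set.seed(99)
  for (i in 1:50) {
    x <- runif(40)
    stx <- traj(x)
    r <- oracle_longest_run(x, function(v) v >= 0.2 & v <= 0.3)
    expect_equal(detect_onset(stx, cfg),
                 if (is.null(r)) NA_real_ else stx$t_hours[r[2]])
    r2 <- oracle_longest_run(x, function(v) v > 0.78)
    expect_equal(terminal_time(stx, cfg),
                 if (is.null(r2)) NA_real_ else stx$t_hours[r2[1]])
  }
})

test_that("timing estimators shift with a uniform time shift", {
  set.seed(11)
  st <- traj(runif(60), t0 = 2, dt = 0.25)
  sh <- st; sh$t_hours <- sh$t_hours + 3.25
  cfg <- pipeline_config(diff_window_hours = c(0, 100))
  for (f in list(detect_onset, detect_high_stable, terminal_time)) {
    a <- f(st, cfg); b <- f(sh, cfg)
    if (is.na(a)) expect_true(is.na(b)) else expect_equal(b, a + 3.25)
  }
})

test_that("score-time correlation is Spearman over the differentiation window", {
  cfg <- pipeline_config()
  up <- traj(seq(0.1, 0.9, length.out = 20), t0 = 7.5, dt = 0.35)
  expect_equal(score_time_correlation(up, cfg)$rho, 1)
  down <- up; down$score <- rev(down$score)
  expect_equal(score_time_correlation(down, cfg)$rho, -1)

  few <- traj(c(0.2, 0.8), t0 = 8, dt = 0.5)
  res <- score_time_correlation(few, cfg)
  expect_true(is.na(res$rho))
  expect_identical(res$n, 2L)

  # scores independent of time: mean rho within 3 SE of zero
  set.seed(23)
  rhos <- replicate(300, score_time_correlation(traj(runif(30), t0 = 7.5, dt = 0.25),
                                                cfg)$rho)
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)))
})

test_that("fusion coupling recovers exact and null relationships", {
  set.seed(41)
  term <- rnorm(40, 13, 1.5)
  tim <- data.frame(cell_id = paste0("c", 1:40), terminal_h = term)

  # exact 3 h gap: r = 1, all gaps 3
  fus <- data.frame(cell_id = tim$cell_id, fusion_time_hours = term + 3)
  fc <- fusion_coupling(tim, fus)
  expect_equal(fc$pearson_r, 1, tolerance = 1e-12)
  expect_equal(fc$gap_median, 3, tolerance = 1e-12)
  expect_equal(fc$data$gap_h, rep(3, 40), tolerance = 1e-12)

  # independent terminal and fusion times: negligible correlation
  set.seed(42)
  t2 <- rnorm(500, 13, 1.5)
  tim2 <- data.frame(cell_id = paste0("d", 1:500), terminal_h = t2)
  fus2 <- data.frame(cell_id = tim2$cell_id, fusion_time_hours = rnorm(500, 16, 1.5))
  expect_lt(abs(fusion_coupling(tim2, fus2)$pearson_r), 0.15)

  expect_error(fusion_coupling(tim[1:2, ], fus[1:2, ]), "at least 3")
})

test_that("the K-squared normality test reproduces reference values", {
  # expected statistics computed independently with scipy.stats.normaltest
  x_norm <- c(10.609434, 7.920032, 11.500902, 11.881129, 6.09793, 7.395641,
              10.255681, 9.367515, 9.966398, 8.293912, 11.758796, 11.555584,
              10.132061, 12.254482, 10.935019, 8.281415, 10.737502, 8.082235,
              11.756901, 9.900148, 9.630275, 8.638141, 12.445083, 9.690941,
              9.143344, 9.295733, 11.064618, 10.730888, 10.825465, 10.861642)
  r <- d_agostino_k2(x_norm)
  expect_equal(r$statistic, 1.9577805740, tolerance = 1e-8)
  expect_equal(r$p.value, 0.3757278176, tolerance = 1e-8)

  x_exp <- c(0.38868, 1.264207, 0.708491, 0.23793, 0.461088, 0.641557,
             0.343833, 0.321911, 0.878915, 0.296947, 1.333702, 1.390864,
             1.084083, 0.073028, 1.134068, 1.354338, 1.12204, 0.280049,
             0.320936, 0.165736, 0.354364, 0.02114, 0.167356, 1.315057,
             3.995756)
  r2 <- d_agostino_k2(x_exp)
  expect_equal(r2$statistic, 33.6798395678, tolerance = 1e-7)
  expect_equal(r2$p.value, 4.86e-8, tolerance = 1e-3)

  expect_error(d_agostino_k2(rnorm(5)), "n >= 8")
})

test_that("appending out-of-band scores does not move timing estimates", {
  cfg <- pipeline_config()
  st <- traj(c(rep(0.25, 4), rep(0.75, 3), rep(0.9, 5)), t0 = 8, dt = 0.5)
  base_onset <- detect_onset(st, cfg)
  base_term <- terminal_time(st, cfg)
  # appended mid-band (0.5) scores qualify for no run
  ext <- rbind(st, traj(rep(0.5, 6), t0 = max(st$t_hours) + 0.5, dt = 0.5))
  expect_equal(detect_onset(ext, cfg), base_onset)
  expect_equal(terminal_time(ext, cfg), base_term)
  # but a longer, separated qualifying run must win
  ext2 <- rbind(st, traj(c(0.5, rep(0.95, 10)), t0 = max(st$t_hours) + 0.5, dt = 0.5))
  expect_equal(terminal_time(ext2, cfg), max(st$t_hours) + 1)
})
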