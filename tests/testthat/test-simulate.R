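test_that("the simulator is deterministic and honours its count contracts", {
  sim <- sim_config(n_cells_per_condition = 10, seed = 42, duration_hours = 6,
                    onset_mean_h = 3, duration_mean_h = 1.5)
  a <- simulate_experiment(sim)
  b <- simulate_experiment(sim)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)

  n_diff <- length(unique(a$tracks$cell_id[a$tracks$condition == "ERKi"]))
  n_ctl <- length(unique(a$tracks$cell_id[a$tracks$condition == "DMSO"]))
  expect_identical(n_diff, 10L)
  expect_gte(n_ctl, 10L)

  # the caller's RNG stream is untouched
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(simulate_experiment(sim)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("sampled onsets match their configured distribution", {
  sim <- sim_config(n_cells_per_condition = 500, seed = 8, duration_hours = 21.5,
                    division_rate_per_cell_h = 0)
  ts <- simulate_experiment(sim)
  onsets <- ts$truth$onset_h[ts$truth$condition == "ERKi"]
  se <- sim$onset_sd_h / sqrt(length(onsets))
  expect_lt(abs(mean(onsets) - sim$onset_mean_h), 3 * se)
})

test_that("simulated populations reproduce the qualitative study structure", {
  ts <- small_study()$ts_train
  tr <- ts$tracks

  # ordering of the per-cell ground truth
  tru <- ts$truth[ts$truth$condition == "ERKi", ]
  expect_true(all(tru$onset_h < tru$terminal_h))
  expect_true(all(tru$terminal_h < tru$fusion_h))

  # differentiating cells slow down: late speed < early speed
  sp <- speed_series(ts)
  sp$condition <- tr$condition[match(sp$cell_id, tr$cell_id)]
  erki <- sp[sp$condition == "ERKi", ]
  expect_lt(mean(erki$value[erki$t_hours >= 16 & erki$t_hours <= 21]),
            mean(erki$value[erki$t_hours >= 2 & erki$t_hours <= 7]))

  # population actin of differentiating cells rises monotonically after the
  # mean onset (checked on hourly bins)
  am <- tr[tr$condition == "ERKi", ]
  bins <- floor(am$t_hours)
  curve <- tapply(am$actin_mean, bins, mean)
  rise <- curve[as.numeric(names(curve)) %in% 11:16]
  expect_true(all(diff(rise) > 0))  # strictly rising through the transition
  post <- curve[as.numeric(names(curve)) >= 11]
  expect_true(all(diff(post) > -3))  # plateau flat up to sampling noise
  expect_gt(post[length(post)], post[1] * 1.2)

  # control density grows as cells divide
  dens <- local_density(ts)
  dens$condition <- tr$condition[match(dens$cell_id, tr$cell_id)]
  ctl <- dens[dens$condition == "DMSO", ]
  expect_gt(mean(ctl$value[abs(ctl$t_hours - 20) < 0.5]),
            mean(ctl$value[abs(ctl$t_hours - 4) < 0.5]))

  # fused cells barely move
  fused_rows <- tr$state == "fused"
  if (any(fused_rows)) {
    sp_f <- sp[sp$cell_id %in% unique(tr$cell_id[fused_rows]), ]
    sp_f$state <- tr$state[match(paste(sp_f$cell_id, sp_f$frame),
                                 paste(tr$cell_id, tr$frame))]
    expect_lt(mean(sp_f$value[sp_f$state == "fused"]), 0.5)
  }
})

test_that("rendered actin frames agree with the generative window means", {
  cfg <- pipeline_config(pixel_size_um = 1, actin_window_um = 32)
  sim <- sim_config(n_cells_per_condition = 1, seed = 3, duration_hours = 1,
                    onset_mean_h = 0.8, onset_sd_h = 0, duration_mean_h = 0.5,
                    field_um = c(200, 200), division_rate_per_cell_h = 0)
  ts <- simulate_experiment(sim, cfg)

  # single cell, no background noise: window mean equals the blob integral
  img <- render_actin_frames(ts, sim, frames = 0L, pixel_size_um = 1,
                             sigma_um = 8, background_sd = 0)[[1]]
  cell <- ts$tracks[ts$tracks$frame == 0 & ts$tracks$condition == "ERKi", ]
  got <- quantify_actin_window(img, c(cell$x_um, cell$y_um), cfg)[["mean"]]
  # oracle: evaluate the Gaussian blob on the same 32x32 pixel grid
  cx <- floor(cell$x_um) + 1; cy <- floor(cell$y_um) + 1
  px <- (cx - 15):(cx + 16) - 0.5; py <- (cy - 15):(cy + 16) - 0.5
  blob <- cell$actin_mean * outer(exp(-(py - cell$y_um)^2 / 128),
                                  exp(-(px - cell$x_um)^2 / 128))
  expect_equal(got, mean(blob), tolerance = 1e-6)

  # no cells: pure background
  ts0 <- ts; ts0$tracks <- ts0$tracks[0, ]
  img0 <- render_actin_frames(ts0, sim, frames = 0L, background_sd = 0)[[1]]
  expect_true(all(img0 == 0))

  # two cells > 6 sigma apart do not contaminate each other's windows
  df2 <- data.frame(cell_id = c("a", "b"), condition = "custom", frame = 0L,
                    x_um = c(40, 160), y_um = c(40, 160),
                    actin_min = 1, actin_max = 1, actin_mean = c(100, 300),
                    actin_median = 1, actin_std = 0)
  ts2 <- track_set(df2, cfg)
  img2 <- render_actin_frames(ts2, sim, frames = 0L, background_sd = 0)[[1]]
  solo <- track_set(df2[1, ], cfg)
  img_solo <- render_actin_frames(solo, sim, frames = 0L, background_sd = 0)[[1]]
  wa <- quantify_actin_window(img2, c(40, 40), cfg)
  wa_solo <- quantify_actin_window(img_solo, c(40, 40), cfg)
  expect_equal(wa[["mean"]], wa_solo[["mean"]], tolerance = 1e-6)

  tiny_sim <- sim; tiny_sim$field_um <- c(30, 30)
  expect_error(render_actin_frames(ts, tiny_sim, sigma_um = 8), "too small")
})
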