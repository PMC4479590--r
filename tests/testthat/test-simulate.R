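test_that("bout schedules tile the day window exactly", {
  cfg <- sim_config(seed = 1, day_window = c(0, 7200))
  segs <- simulate_bout_schedule(cfg, seed = 31)
  expect_equal(segs$t_start[1], 0)
  expect_equal(segs$t_end[nrow(segs)], 7200)
  expect_equal(segs$t_start[-1], segs$t_end[-nrow(segs)])  # no gaps/overlaps

  only_f <- sim_config(seed = 1, day_window = c(0, 3600),
                       schedule = list(median_s = c(Foraging = 600),
                                       sdlog = 0.6))
  segs <- simulate_bout_schedule(only_f, seed = 32)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$behaviour, "Foraging")
  expect_equal(segs$t_end - segs$t_start, 3600)
})

test_that("bout durations follow the configured log-normal distribution", {
  cfg <- sim_config(seed = 1, day_window = c(0, 4e6),
                    schedule = list(median_s = c(Foraging = 600,
                                                 Walking = 180),
                                    sdlog = 0.6))
  segs <- simulate_bout_schedule(cfg, seed = 33)
  segs <- segs[-nrow(segs), ]              # last bout is truncated
  durs <- split(segs$t_end - segs$t_start, segs$behaviour)
  expect_gt(min(lengths(durs)), 1000)
  for (b in names(durs)) {
    med <- cfg$schedule$median_s[[b]]
    want_mean <- med * exp(cfg$schedule$sdlog^2 / 2)
    se <- sd(durs[[b]]) / sqrt(length(durs[[b]]))
    expect_lt(abs(mean(durs[[b]]) - want_mean), 3 * se + 0.5)
  }
})

test_that("true paths follow the behaviour kinematics", {
  lying <- sim_config(seed = 2, day_window = c(0, 600),
                      schedule = list(median_s = c(Lying = 900), sdlog = 0.6))
  segs <- simulate_bout_schedule(lying, seed = 34)
  path <- simulate_true_path(segs, lying, seed = 35)
  expect_equal(length(unique(path$x)), 1)
  expect_equal(length(unique(path$y)), 1)

  walk_kin <- default_kinematics()
  walk_kin$speed_sd[walk_kin$behaviour == "Walking"] <- 0
  walk_kin$heading_sd[walk_kin$behaviour == "Walking"] <- 0
  straight <- sim_config(seed = 3, day_window = c(0, 600),
                         kinematics = walk_kin,
                         schedule = list(median_s = c(Walking = 900),
                                         sdlog = 0.6))
  segs <- simulate_bout_schedule(straight, seed = 36)
  path <- simulate_true_path(segs, straight, seed = 37)
  d60 <- sqrt(diff(path$x, lag = 60)^2 + diff(path$y, lag = 60)^2)
  expect_equal(d60, rep(60, length(d60)), tolerance = 1e-9)
  # collinear: all turning angles zero
  ang <- gpsbehaviour:::turning_angles_xy(path$x, path$y)
  expect_equal(max(abs(ang)), 0, tolerance = 1e-6)
})

test_that("per-minute displacement orders Walking > Foraging > Resting", {
  cfg <- sim_config(seed = 4, day_window = c(0, 6 * 3600))
  study <- simulate_study(cfg)
  path <- study$true_path
  segs <- study$truth_segments
  disp <- function(b) {
    rows <- segs[segs$behaviour == b, ]
    rows <- rows[rows$t_end - rows$t_start >= 60, ]
    unlist(lapply(seq_len(nrow(rows)), function(i) {
      sel <- path$t >= rows$t_start[i] & path$t <= rows$t_end[i]
      x <- path$x[sel]; y <- path$y[sel]
      sqrt(diff(x, lag = 60)^2 + diff(y, lag = 60)^2)
    }))
  }
  expect_gt(mean(disp("Walking")), mean(disp("Foraging")))
  expect_gt(mean(disp("Foraging")), 2 * mean(disp("Lying")) + 1)
})

test_that("positional error is unbiased iid noise of the right scale", {
  path <- data.frame(t = 1:10000, x = 0, y = 0)
  expect_identical(apply_positional_error(path, 0, seed = 1), path)
  noisy <- apply_positional_error(path, 2.1, seed = 38)
  r <- sqrt(noisy$x^2 + noisy$y^2)
  want <- 2.1 * sqrt(pi / 2)                       # Rayleigh mean
  expect_lt(abs(mean(r) - want), 3 * sd(r) / sqrt(length(r)))
  other <- apply_positional_error(path, 2.1, seed = 39)
  expect_lt(abs(cor(noisy$x, other$x)), 0.05)
})

test_that("smoothing is the identity at alpha one and preserves constants", {
  path <- data.frame(t = 1:100, x = rnorm(100), y = rnorm(100))
  expect_identical(apply_smoothing(path, 1), path)
  const <- data.frame(t = 1:100, x = 5, y = -3)
  sm <- apply_smoothing(const, 0.3)
  expect_equal(sm$x, rep(5, 100), tolerance = 1e-12)
  expect_equal(sm$y, rep(-3, 100), tolerance = 1e-12)
})

test_that("stronger smoothing suppresses the stationary high-angle artefact", {
  path <- data.frame(t = 1:20000, x = 0, y = 0)
  noisy <- apply_positional_error(path, 2.1, seed = 40)
  frac <- vapply(c(1, 0.5, 0.35, 0.2), function(a) {
    sm <- apply_smoothing(noisy, a)
    ang <- gpsbehaviour:::turning_angles_xy(sm$x, sm$y)
    mean(ang > 90, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
})

test_that("studies are reproducible and sample fixes on the exact grid", {
  cfg <- sim_config(seed = 5, day_window = c(0, 3600), fix_interval_s = 60)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$trajectory$fixes, s2$trajectory$fixes)
  expect_identical(s1$truth_segments, s2$truth_segments)
  expect_equal(nrow(s1$trajectory$fixes), 3600 / 60 + 1)
  expect_equal(diff(s1$trajectory$fixes$t), rep(60, 60))
  # truth covers the whole trajectory span
  expect_lte(s1$truth_segments$t_start[1], min(s1$trajectory$fixes$t))
  expect_gte(max(s1$truth_segments$t_end), max(s1$trajectory$fixes$t))
})

test_that("simulated studies round-trip through the file formats", {
  st <- tiny_study(seed = 16, minutes = 30)
  fixes <- withr::local_tempfile(fileext = ".csv")
  obs <- withr::local_tempfile(fileext = ".csv")
  write_sim_study(st, fixes, obs)
  traj <- read_fix_table(fixes)[[1]]
  expect_equal(traj$fixes$x, st$trajectory$fixes$x, tolerance = 1e-9)
  expect_equal(traj$interval_s, st$trajectory$interval_s)
  segs <- read_observation_log(obs)
  expect_equal(segs$behaviour, st$truth_segments$behaviour)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(seed = 1, fix_interval_s = 7, base_dt = 2),
               "multiple")
  kin <- default_kinematics()
  kin$speed_mean[kin$behaviour == "Lying"] <- 1
  expect_error(sim_config(seed = 1, kinematics = kin), "stationary")
  kin <- default_kinematics()
  expect_lt(kin$heading_sd[kin$behaviour == "Walking"],
            kin$heading_sd[kin$behaviour == "Foraging"])
})
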