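test_that("default clips match the recording protocol", {
  prof <- subject_profile(seed = 1)
  seq <- generate_base_motion("SLST", prof, simulation_config(seed = 1))
  expect_equal(n_frames(seq), 450)  # 15 s x 30 fps
  expect_equal(dim(seq$coords)[2], 25)
  expect_false(any(seq$missing))
  expect_true(all(seq$coords[, , 1] >= 0 & seq$coords[, , 1] <= 1280))
  expect_true(all(seq$coords[, , 2] >= 0 & seq$coords[, , 2] <= 720))
})

test_that("a noiseless ideal execution keeps the trunk vertical and hits depth", {
  prof <- subject_profile(seed = 4)
  cfg <- simulation_config(noise_sd = 0, natural_variation = FALSE, seed = 4)
  seq <- generate_base_motion("SLST", prof, cfg)
  spine <- compute_signal(seq, default_catalogue()[["Spine"]])
  expect_lt(diff(range(spine$values)), 1e-6)  # constant orientation
  knee <- compute_signal(seq, default_catalogue()[["RHipRKneeRAnkle"]])
  depth_target <- 100 + prof$depth_offset
  expect_lt(abs(min(knee$values) - depth_target), 2)
  expect_gt(max(knee$values), 170)
  # with natural variation on, the trunk stays within +-2 degrees of vertical
  seqv <- generate_base_motion("SLST", prof,
                               simulation_config(noise_sd = 0, seed = 4))
  spinev <- compute_signal(seqv, default_catalogue()[["Spine"]])
  expect_true(all(abs(spinev$values - (-90)) <= 2 + 1e-9))
})

test_that("generated frames pass pose validation and round-trip the reader", {
  prof <- subject_profile(seed = 6)
  cfg <- simulation_config(duration_s = 2, seed = 6)
  seq <- generate_base_motion("SDT", prof, cfg)
  path <- tempfile(fileext = ".jsonl")
  on.exit(unlink(path))
  write_openpose_jsonl(seq, path)
  back <- read_pose_sequence(path, fps = 30, test_id = "SDT")
  expect_equal(n_frames(back), n_frames(seq))
  expect_false(any(back$missing))
})

test_that("error injection is the identity at magnitude zero", {
  prof <- subject_profile(seed = 9)
  cfg <- simulation_config(duration_s = 3, seed = 9)
  seq <- generate_base_motion("SLST", prof, cfg)
  for (mode in motionscreen:::ERROR_MODES) {
    expect_identical(inject_error(seq, mode, 0), seq)
  }
  expect_error(inject_error(seq, "jazz_hands", 1), class = "configuration_error")
  expect_error(inject_error(seq, "tremor", -1), class = "bad_argument")
})

test_that("each error mode moves its targeted signal, monotonically", {
  prof <- subject_profile(seed = 10)
  cfg <- simulation_config(duration_s = 5, noise_sd = 0,
                           natural_variation = FALSE, seed = 10)
  base <- generate_base_motion("SLST", prof, cfg)
  cat15 <- default_catalogue()
  rom_of <- function(seq, sig) range_of_movement(compute_signal(seq, cat15[[sig]]))
  # forward lean: Spine orientation ROM grows by about the injected angle
  rom0 <- rom_of(base, "Spine")
  rom15 <- rom_of(inject_error(base, "forward_lean", 15), "Spine")
  expect_equal(rom15 - rom0, 15, tolerance = 0.5)
  # hip drop: Hips pair orientation tilts by about the injected angle
  expect_equal(rom_of(inject_error(base, "hip_drop", 12), "Hips") -
                 rom_of(base, "Hips"), 12, tolerance = 0.5)
  # tremor: knee-angle signal variance strictly increases
  v0 <- stats::var(compute_signal(base, cat15[["RHipRKneeRAnkle"]])$values)
  v1 <- stats::var(compute_signal(inject_error(base, "tremor", 3),
                                  cat15[["RHipRKneeRAnkle"]])$values)
  expect_gt(v1, v0)
  # shallow squat raises the knee-angle minimum; loss of balance and arm
  # deviation move their distance/angle targets; all monotone in magnitude
  grids <- list(
    # shallow squat raises the knee-angle minimum
    shallow_squat = function(m) min(compute_signal(
      inject_error(base, "shallow_squat", m), cat15[["RHipRKneeRAnkle"]])$values),
    # balance loss tilts the planted-ankle shank, widening the knee sweep
    loss_of_balance = function(m) rom_of(
      inject_error(base, "loss_of_balance", m), "RHipRKneeRAnkle"),
    gross_arm_deviation = function(m) rom_of(
      inject_error(base, "gross_arm_deviation", m), "RWristMidHip"),
    forward_lean = function(m) rom_of(inject_error(base, "forward_lean", m), "Spine"),
    hip_drop = function(m) rom_of(inject_error(base, "hip_drop", m), "Hips"),
    tremor = function(m) stats::var(compute_signal(
      inject_error(base, "tremor", m), cat15[["RHipRKneeRAnkle"]])$values)
  )
  for (mode in names(grids)) {
    resp <- vapply(c(0, 10, 25), grids[[mode]], 0)
    expect_true(all(diff(resp) > 0), label = paste(mode, "monotone response"))
  }
})

test_that("simulated raters reproduce truth when perfect and chance when blind", {
  set.seed(301)
  truth <- matrix(stats::rbinom(200 * 2, 1, 0.5), 200, 2,
                  dimnames = list(NULL, c("p1", "p2")))
  perfect <- simulate_raters(truth, rep(list(c(1, 1)), 3), seed = 2)
  for (p in 1:2) {
    expect_equal(unname(perfect[, 1, p]), unname(truth[, p]))
    expect_equal(fleiss_kappa(perfect[, , p]), 1)
  }
  blind <- simulate_raters(matrix(stats::rbinom(1500, 1, 0.5), ncol = 1),
                           rep(list(c(0.5, 0.5)), 3), seed = 3)
  expect_lt(abs(fleiss_kappa(blind[, , 1])), 0.05)
})

test_that("accurate raters approach the enumerated two-category kappa", {
  # closed form for iid raters with sens = spec = q on balanced truth:
  # P(rating = 1) = 1/2; agreement of a rater pair = E[a^2 + (1-a)^2] where
  # a = P(rate 1 | truth) in {q, 1-q} -> Pbar = q^2 + (1-q)^2, Pe = 1/2
  q <- 0.9
  pbar <- q^2 + (1 - q)^2
  kappa_expected <- (pbar - 0.5) / (1 - 0.5)
  set.seed(302)
  truth <- matrix(stats::rbinom(500, 1, 0.5), ncol = 1)
  r <- simulate_raters(truth, rep(list(c(0.9, 0.9)), 3), seed = 4)
  expect_lt(abs(fleiss_kappa(r[, , 1]) - kappa_expected), 0.05)
})

test_that("cohort generation is reproducible and honors prevalence", {
  cfg <- simulation_config(n_subjects = 6, duration_s = 2, tests = "SLST",
                           seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$true_labels, d2$true_labels)
  expect_identical(d1$ratings, d2$ratings)
  expect_identical(lapply(d1$sequences, `[[`, "coords"),
                   lapply(d2$sequences, `[[`, "coords"))
  # zero prevalence: no errors at all
  cfg0 <- simulation_config(n_subjects = 5, duration_s = 2, tests = "SLST",
                            error_prevalence = setNames(rep(0, 6),
                                                        motionscreen:::ERROR_MODES),
                            seed = 8)
  expect_true(all(generate_dataset(cfg0)$true_labels == 0))
  # prevalence 0.25 for one mode at n = 200: binomial 95% envelope
  cfg25 <- simulation_config(
    n_subjects = 200, duration_s = 1, tests = "SLST",
    error_prevalence = setNames(c(0.25, rep(0, 5)), motionscreen:::ERROR_MODES),
    seed = 9)
  frac <- mean(generate_dataset(cfg25)$true_labels[, "loss_of_balance"])
  expect_lt(abs(frac - 0.25), 0.07)
})
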