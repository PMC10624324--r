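test_that("joint angle matches hand-worked and degenerate configurations", {
  expect_equal(joint_angle(c(0, 0), c(1, 0), c(2, 0)), 180)   # vertex between
  expect_equal(joint_angle(c(0, 1), c(0, 0), c(1, 0)), 90)
  # cos = 2 / (sqrt(5) * 2) -> 63.4349 degrees
  expect_equal(joint_angle(c(1, 2), c(0, 0), c(2, 0)), 63.43494882, tolerance = 1e-8)
  expect_error(joint_angle(c(0, 0), c(0, 0), c(1, 0)), class = "degenerate_geometry")
})

test_that("pair orientation follows the image y-flip convention, quadrant-aware", {
  expect_equal(pair_orientation(c(0, 0), c(1, 0)), 0)
  # B above A on screen -> +90
  expect_equal(pair_orientation(c(100, 200), c(100, 100)), 90)
  # B below-right on screen -> -45
  expect_equal(pair_orientation(c(0, 0), c(1, 1)), -45)
  expect_equal(pair_orientation(c(0, 0), c(-1, 0)), 180)  # range (-180, 180]
  expect_error(pair_orientation(c(3, 3), c(3, 3)), class = "degenerate_geometry")
})

test_that("relative distance normalizes by the frame's trunk length", {
  expect_equal(relative_distance(c(5, 5), c(5, 5), c(0, 0), c(0, 100)), 0)
  expect_equal(relative_distance(c(0, 0), c(0, 100), c(0, 0), c(0, 100)), 1)
  expect_equal(relative_distance(c(0, 0), c(50, 0), c(0, 0), c(0, 100)), 0.5)
  expect_error(relative_distance(c(0, 0), c(1, 1), c(10, 10), c(10, 10.5)),
               class = "degenerate_normalizer")
})

test_that("all three signal families agree with independent trigonometric oracles", {
  set.seed(401)
  for (i in 1:1000) {
    pts <- matrix(stats::runif(8, -100, 100), 4, 2)
    if (min(dist(pts)) < 1e-3) next
    expect_equal(joint_angle(pts[1, ], pts[2, ], pts[3, ]),
                 oracle_joint_angle(pts[1, ], pts[2, ], pts[3, ]),
                 tolerance = 1e-9)
    expect_equal(pair_orientation(pts[1, ], pts[2, ]),
                 oracle_pair_orientation(pts[1, ], pts[2, ]),
                 tolerance = 1e-9)
    expect_equal(relative_distance(pts[1, ], pts[2, ], pts[3, ], pts[4, ], eps = 0),
                 sqrt(sum((pts[2, ] - pts[1, ])^2)) /
                   sqrt(sum((pts[4, ] - pts[3, ])^2)),
                 tolerance = 1e-9)
  }
})

test_that("similarity-transform invariances and equivariances hold", {
  set.seed(402)
  for (i in 1:200) {
    pts <- matrix(stats::runif(8, -50, 50), 4, 2)
    if (min(dist(pts)) < 1e-3) next
    theta <- stats::runif(1, -pi, pi)
    scale <- stats::runif(1, 0.1, 5)
    shift <- stats::runif(2, -500, 500)
    tp <- random_similarity(pts, theta, scale, shift)
    # joint angle invariant; symmetric in A and C
    expect_equal(joint_angle(tp[1, ], tp[2, ], tp[3, ]),
                 joint_angle(pts[1, ], pts[2, ], pts[3, ]), tolerance = 1e-8)
    expect_equal(joint_angle(pts[3, ], pts[2, ], pts[1, ]),
                 joint_angle(pts[1, ], pts[2, ], pts[3, ]), tolerance = 1e-12)
    # relative distance invariant under the whole-frame similarity
    expect_equal(relative_distance(tp[1, ], tp[2, ], tp[3, ], tp[4, ], eps = 0),
                 relative_distance(pts[1, ], pts[2, ], pts[3, ], pts[4, ], eps = 0),
                 tolerance = 1e-8)
    # orientation: translation/scale invariant, rotation equivariant
    # (a +theta rotation of image coordinates is a -theta rotation of the
    # physical scene after the y-flip, so the orientation drops by theta)
    base <- pair_orientation(pts[1, ], pts[2, ])
    shifted <- pair_orientation(tp[1, ], tp[2, ])
    delta <- (base - shifted - theta * 180 / pi) %% 360
    expect_lt(min(delta, 360 - delta), 1e-6)
  }
})

test_that("signals over sequences propagate the missingness mask", {
  prof <- subject_profile(seed = 2)
  cfg <- simulation_config(duration_s = 2, noise_sd = 0, seed = 2)
  seq <- generate_base_motion("SLST", prof, cfg)
  def <- default_catalogue()[["RHipRKneeRAnkle"]]
  seq$missing[4, kp_idx_test(10)] <- TRUE   # RKnee missing in frame 4
  sig <- compute_signal(seq, def)
  expect_false(sig$valid[4])
  expect_true(is.na(sig$values[4]))
  expect_true(all(sig$valid[-4]))
  # constant pose: repeat one frame -> constant signal
  const <- seq
  for (i in seq_len(n_frames(const))) const$coords[i, , ] <- seq$coords[1, , ]
  const$missing[] <- FALSE
  sigc <- compute_signal(const, def)
  expect_equal(diff(range(sigc$values)), 0)
  # relative-distance signals also invalidate frames with a missing normalizer
  seq2 <- generate_base_motion("SLST", prof, cfg)
  seq2$missing[2, kp_idx_test(1)] <- TRUE   # Neck
  sigr <- compute_signal(seq2, default_catalogue()[["RWristMidHip"]])
  expect_false(sigr$valid[2])
  # all frames invalid -> empty-signal error
  seq3 <- generate_base_motion("SLST", prof, cfg)
  seq3$missing[, kp_idx_test(10)] <- TRUE
  expect_error(compute_signal(seq3, def), class = "empty_signal")
})

test_that("the default catalogue reproduces the published 15 definitions", {
  cat15 <- default_catalogue()
  expect_length(cat15, 15)
  expect_equal(cat15[["Spine"]]$category, "pair_orientation")
  expect_equal(cat15[["Spine"]]$keypoints, c(1L, 8L))
  expect_equal(cat15[["RHipRKneeRAnkle"]]$category, "joint_angle")
  expect_equal(cat15[["RHipRKneeRAnkle"]]$keypoints, c(9L, 10L, 11L))
  # the printed index tuples are authoritative, anatomy notwithstanding
  expect_equal(cat15[["RWristMidHip"]]$keypoints, c(4L, 7L))
  expect_equal(cat15[["RWristLWrist"]]$keypoints, c(4L, 8L))
  counts <- table(vapply(cat15, `[[`, "", "category"))
  expect_equal(as.integer(counts[c("pair_orientation", "joint_angle", "relative_distance")]),
               c(3L, 7L, 5L))
})

test_that("a YAML catalogue override round-trips through signal_def", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c(
    "- name: KneeAngle",
    "  category: joint_angle",
    "  keypoints: [9, 10, 11]",
    "- name: Trunk",
    "  category: relative_distance",
    "  keypoints: [1, 8]"), path)
  cat2 <- read_catalogue_yaml(path)
  expect_length(cat2, 2)
  expect_equal(cat2[["KneeAngle"]]$keypoints, c(9L, 10L, 11L))
  expect_error(signal_def("bad", "joint_angle", c(1, 2)), class = "bad_argument")
  expect_error(signal_def("bad", "pair_orientation", c(1, 1)), class = "bad_argument")
})
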