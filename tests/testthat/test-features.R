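prep <- function(s) preprocess_stream(s)

test_that("end error is the minimal circular arc to the reference", {
  s <- random_stream(50)
  s$heading[50] <- 90
  cl <- prep(s)
  expect_equal(end_error(cl, 90), 0)
  expect_equal(end_error(cl, 0), 90)
  s$heading[50] <- 350
  expect_equal(end_error(prep(s), 10), 20)
  expect_equal(end_error(prep(s), 10 + 360), 20) # invariant under +360
})

test_that("every feature matches its brute-force loop oracle on random streams", {
  set.seed(31)
  for (rep in 1:25) {
    s <- random_stream(n = sample(350:700, 1))
    s$az <- abs(s$az) + 1 # keep the flip detector quiescent: gravity up
    cl <- prep(s)
    ref <- stats::runif(1, 0, 360)

    expect_equal(end_error(cl, ref),
      oracle_min_arc(s$heading[nrow(s)], ref),
      tolerance = 1e-9
    )
    expect_equal(total_angular_displacement(cl),
      oracle_total_displacement(cl$heading_unwrapped),
      tolerance = 1e-9
    )
    tl <- tilt_max(cl)
    expect_equal(tl[["x"]], oracle_max_magnitude(s$gx), tolerance = 1e-9)
    expect_equal(tl[["y"]], oracle_max_magnitude(s$gy), tolerance = 1e-9)
    expect_equal(tl[["z"]], oracle_max_magnitude(s$gz), tolerance = 1e-9)
    acc <- average_acceleration(cl)
    expect_equal(acc[["x"]], oracle_mean(s$ax), tolerance = 1e-9)
    for (iv in c(0.1, 0.5)) {
      roc <- gyro_rate_of_change(cl, iv)
      expect_equal(roc[["y"]], oracle_block_average(s$gy, iv, 0.003),
        tolerance = 1e-9
      )
      jrk <- average_jerk(cl, iv)
      expect_equal(jrk[["x"]], oracle_jerk(s$ax, iv, 0.003),
        tolerance = 1e-9
      )
      jrk_s <- average_jerk(cl, iv, mode = "signed")
      expect_equal(jrk_s[["x"]], oracle_jerk(s$ax, iv, 0.003, absolute = FALSE),
        tolerance = 1e-9
      )
    }
  }
})

test_that("block-feature degenerate cases behave as defined", {
  s <- random_stream(400)
  s$gx <- rep(2.5, 400)
  s$ax <- rep(1.25, 400)
  cl <- prep(s)
  expect_equal(gyro_rate_of_change(cl, 0.1)[["x"]], 2.5)
  expect_equal(gyro_rate_of_change(cl, 0.5)[["x"]], 2.5)
  expect_equal(average_jerk(cl, 0.1)[["x"]], 0)
  # linear ramp: constant block-sum difference, equal across block pairs
  s2 <- random_stream(600)
  s2$ax <- seq_len(600) * 0.01
  cl2 <- prep(s2)
  per <- round(0.1 / 0.003)
  expected <- per * per * 0.01 / 0.1
  expect_equal(average_jerk(cl2, 0.1)[["x"]], expected, tolerance = 1e-9)
  expect_error(average_jerk(prep(random_stream(200)), 0.5), "blocks")
})

test_that("displacement dominates the net heading change, with equality iff monotone", {
  set.seed(77)
  for (rep in 1:20) {
    steps <- stats::runif(200, -40, 40)
    s <- random_stream(201)
    s$heading <- wrap_heading(cumsum(c(90, steps)))
    cl <- prep(s)
    tad <- total_angular_displacement(cl)
    net <- abs(cl$heading_unwrapped[201] - cl$heading_unwrapped[1])
    expect_gte(tad + 1e-9, net)
    monotone <- all(steps >= 0) || all(steps <= 0)
    expect_equal(isTRUE(all.equal(tad, net, tolerance = 1e-9)), monotone)
  }
  mono <- random_stream(181)
  mono$heading <- seq(90, 0, by = -0.5)
  expect_equal(total_angular_displacement(prep(mono)), 90)
})

test_that("feature vectors have the fixed 27-column layout and are deterministic", {
  set.seed(12)
  prof <- sample_participant("e34")
  s <- simulate_trial_response(prof, 90, 270)
  cl <- prep(s)
  fv1 <- extract_features(cl, 270)
  fv2 <- extract_features(cl, 270)
  expect_identical(fv1, fv2)
  expect_equal(names(fv1), feature_names())
  expect_length(feature_names(), 27)
  expect_gte(fv1$end_error, 0)
  expect_lte(fv1$end_error, 180)
  expect_gte(fv1$hesitations, 0)
  expect_equal(fv1$hesitations, round(fv1$hesitations))
})

test_that("hesitation counting recovers simulator ground truth at default noise", {
  set.seed(55)
  nets <- net_rotation(vrt_protocol())$net_rotation_deg
  n <- 200
  hits <- 0
  for (i in seq_len(n)) {
    prof <- sample_participant(sample(c("e33", "e34"), 1))
    s <- simulate_trial_response(prof, sample(nets, 1), stats::runif(1, 0, 360))
    k_true <- attr(s, "truth")$hesitations_inserted
    hits <- hits + (count_hesitations(prep(s)) == k_true)
  }
  expect_gte(hits / n, 0.9)
})

test_that("feature tables carry labels and demographics for every trial row", {
  co <- generate_cohort(small_config(seed = 19))
  ft <- extract_feature_table(co)
  expect_equal(nrow(ft), 14 * 9)
  expect_true(all(feature_names() %in% names(ft)))
  expect_true(all(ft$group %in% c("e33", "e34")))
  expect_false(anyNA(ft))
})

test_that("the correlation filter drops one column of near-duplicate pairs", {
  set.seed(2)
  tab <- tibble::tibble(
    group = rep(c("e33", "e34"), 10),
    a = stats::rnorm(20)
  )
  tab$b <- tab$a + stats::rnorm(20, 0, 1e-4)
  tab$c <- stats::rnorm(20)
  out <- filter_correlated(tab)
  expect_equal(setdiff(names(tab), names(out)), "b")
})
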