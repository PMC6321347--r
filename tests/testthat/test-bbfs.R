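test_that("a scripted dissociation is detected at the analytic crossing frame", {
  base <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  sc <- event_script(
    base,
    list(list(pair = c(1L, 2L), start_frame = 40, end_frame = 60,
              start_dist = 0.74, end_dist = 3.0)),
    n_frames = 100, vibration_amplitude = 0, seed = 1)
  mt <- make_trajectory(sc)
  # linear interpolation crosses r_ref = 0.744 within the first step
  expect_equal(mt$truth$frame, 41L)
  ev <- detect_events(mt$trajectory)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 41L)
  expect_equal(ev$kind, "broken")
})

test_that("a vibrating but intact diatomic yields no events", {
  base <- geometry(c("O", "H"), rbind(c(0, 0, 0), c(0.96, 0, 0)))
  sc <- event_script(base, list(), n_frames = 80,
                     vibration_amplitude = 0.02, seed = 5)
  mt <- make_trajectory(sc)
  expect_equal(nrow(mt$truth), 0)
  expect_equal(nrow(detect_events(mt$trajectory)), 0)
})

test_that("simultaneous breaking and forming are both reported", {
  base <- geometry(c("H", "H", "O", "O"),
                   rbind(c(0, 0, 0), c(0.70, 0, 0),
                         c(50, 0, 0), c(52.5, 0, 0)))
  sc <- event_script(
    base,
    list(list(pair = c(1L, 2L), start_frame = 20, end_frame = 40,
              start_dist = 0.70, end_dist = 2.5),
         list(pair = c(3L, 4L), start_frame = 22, end_frame = 42,
              start_dist = 2.5, end_dist = 1.2)),
    n_frames = 90, vibration_amplitude = 0, seed = 2)
  mt <- make_trajectory(sc)
  ev <- detect_events(mt$trajectory)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$kind, c("broken", "formed"))
  expect_equal(dplyr::arrange(ev, .data$i)[, c("frame", "i", "j", "kind")],
               mt$truth[order(mt$truth$i), ],
               ignore_attr = TRUE)
})

test_that("debouncing suppresses chatter and is monotone in the window", {
  # hand-built trajectory: bond flickers open for 3 frames, then breaks for good
  d_seq <- c(rep(0.70, 10), rep(0.80, 3), rep(0.70, 10), rep(2.5, 12))
  frames <- purrr::map(d_seq, function(d) {
    geometry(c("H", "H"), rbind(c(0, 0, 0), c(d, 0, 0)))
  })
  traj <- trajectory(frames)
  ev5 <- detect_events(traj, debounce = 5)
  expect_equal(nrow(ev5), 1)       # flicker removed
  expect_equal(ev5$frame, 24L)
  ev1 <- detect_events(traj, debounce = 1)
  expect_equal(nrow(ev1), 3)       # flicker kept: open, close, break
  for (d in 1:8) {
    expect_lte(nrow(detect_events(traj, debounce = d + 1)),
               nrow(detect_events(traj, debounce = d)))
  }
})

test_that("events are grouped by frame gaps", {
  ev <- tibble::tibble(frame = c(50L, 52L), i = c(1L, 2L), j = c(2L, 3L),
                       kind = c("broken", "formed"))
  expect_equal(unique(group_events(ev, gap = 5)$group), 1L)
  ev2 <- dplyr::mutate(ev, frame = c(50L, 200L))
  expect_equal(group_events(ev2, gap = 5)$group, c(1L, 2L))
  empty <- detect_events(
    trajectory(purrr::map(1:3, function(i) {
      geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.7, 0, 0)))
    })))
  expect_equal(nrow(group_events(empty)), 0)
})

test_that("candidate extraction takes the window midpoint and is self-consistent", {
  base <- geometry(c("H", "H", "O", "O"),
                   rbind(c(0, 0, 0), c(0.70, 0, 0),
                         c(50, 0, 0), c(52.5, 0, 0)))
  sc <- event_script(
    base,
    list(list(pair = c(1L, 2L), start_frame = 20, end_frame = 24,
              start_dist = 0.70, end_dist = 2.5),
         list(pair = c(3L, 4L), start_frame = 26, end_frame = 30,
              start_dist = 2.5, end_dist = 1.2)),
    n_frames = 60, vibration_amplitude = 0, seed = 3)
  mt <- make_trajectory(sc)
  ge <- group_events(detect_events(mt$trajectory), gap = 15)
  cands <- extract_candidates(mt$trajectory, ge)
  expect_length(cands, 1)
  cd <- cands[[1]]
  expect_equal(cd$frame_mid, (min(ge$frame) + max(ge$frame)) %/% 2)
  expect_equal(cd$active_atoms, 1:4)
  expect_false(identical(cd$reactant_graph$A, cd$product_graph$A))
  expect_false(cd$flagged)
  # reactant connectivity has 1-2 bonded and 3-4 apart; product the reverse
  expect_equal(cd$reactant_graph$A[1, 2], 1)
  expect_equal(cd$product_graph$A[1, 2], 0)
  expect_equal(cd$reactant_graph$A[3, 4], 0)
  expect_equal(cd$product_graph$A[3, 4], 1)
})

test_that("null reactions are dropped and boundary windows flagged", {
  # break then re-form the same bond inside one group: net change zero
  d_seq <- c(rep(0.70, 6), rep(2.5, 8), rep(0.70, 20))
  frames <- purrr::map(d_seq, function(d) {
    geometry(c("H", "H"), rbind(c(0, 0, 0), c(d, 0, 0)))
  })
  traj <- trajectory(frames)
  ge <- group_events(detect_events(traj, debounce = 5), gap = 20)
  expect_equal(nrow(ge), 2)
  expect_length(extract_candidates(traj, ge), 0)

  # an event right at the start of a trajectory is flagged
  d2 <- c(0.70, rep(2.5, 20))
  traj2 <- trajectory(purrr::map(d2, function(d) {
    geometry(c("H", "H"), rbind(c(0, 0, 0), c(d, 0, 0)))
  }))
  ge2 <- group_events(detect_events(traj2))
  cands2 <- extract_candidates(traj2, ge2)
  expect_length(cands2, 1)
  expect_true(cands2[[1]]$flagged)
})
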