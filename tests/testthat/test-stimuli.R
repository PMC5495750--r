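test_that("cue set is the complete 3x3 conjunction factorial", {
  cues <- cue_set()
  expect_length(cues, 9)
  oris <- vapply(cues, `[[`, numeric(1), "orientation")
  sfs <- vapply(cues, `[[`, numeric(1), "spatial_frequency")
  expect_setequal(unique(oris), c(15, 75, 135))
  expect_setequal(unique(sfs), c(1, 2, 3))
  expect_equal(nrow(unique(cbind(oris, sfs))), 9)  # all conjunctions distinct
  expect_true(all(vapply(cues, `[[`, numeric(1), "diameter") == 5))
})

test_that("rendered Gabors respect geometry and carrier frequency", {
  g <- render_gabor(gabor_spec(15, 1, 5), 32)
  expect_equal(dim(g$pixels), c(160, 160))
  expect_true(all(is.finite(g$pixels)))
  ## mean luminance far outside the envelope equals the background
  corner <- g$pixels[1:10, 1:10]
  expect_equal(mean(corner), 0.5, tolerance = 1e-3)

  ## rotating the pixel grid by 90 degrees matches rotating the spec
  g0 <- render_gabor(gabor_spec(20, 2, 3), 24)
  g90 <- render_gabor(gabor_spec(110, 2, 3), 24)
  rot <- t(g0$pixels)[, nrow(g0$pixels):1]
  expect_lt(max(abs(rot - g90$pixels)), 0.02)

  ## doubling pixels_per_degree doubles the carrier period in pixels:
  ## zero-crossing spacing along the modulation axis doubles
  px16 <- render_gabor(gabor_spec(0, 1, 4), 16)$pixels
  px32 <- render_gabor(gabor_spec(0, 1, 4), 32)$pixels
  mid16 <- which(diff(sign(px16[32, ] - 0.5)) != 0)
  mid32 <- which(diff(sign(px32[64, ] - 0.5)) != 0)
  expect_equal(mean(diff(mid32)), 2 * mean(diff(mid16)), tolerance = 0.1)

  expect_error(gabor_spec(10, -1), "spatial_frequency")
  expect_error(gabor_spec(10, 1, diameter = 0), "diameter")
  expect_error(render_gabor(gabor_spec(0, 1, diameter = 0.1), 32), ">= 16")
})

test_that("search displays share the untried dimension and contain the cue feature once", {
  cue <- gabor_spec(75, 2, 5)
  for (seed in 1:5) {
    d <- search_display("SF", cue, seed = seed)
    expect_length(d$items, 6)
    sfs <- vapply(d$items, `[[`, numeric(1), "spatial_frequency")
    oris <- vapply(d$items, `[[`, numeric(1), "orientation")
    expect_equal(sum(sfs == 2), 1)          # cue SF appears exactly once
    expect_equal(anyDuplicated(sfs), 0)     # six distinct SFs
    expect_equal(length(unique(oris)), 1)   # shared orientation
    expect_false(unique(oris) %in% c(15, 75, 135))  # never-cued orientation
    expect_equal(d$radius, 8.37)
    expect_true(d$target_side %in% c("left", "right"))
    expect_equal(vapply(d$items, `[[`, numeric(1),
                        "spatial_frequency")[d$target_index], 2)

    o <- search_display("ORIENTATION", cue, seed = seed)
    oris <- vapply(o$items, `[[`, numeric(1), "orientation")
    sfs <- vapply(o$items, `[[`, numeric(1), "spatial_frequency")
    expect_equal(sum(oris == 75), 1)
    expect_equal(anyDuplicated(oris), 0)
    expect_equal(length(unique(sfs)), 1)
    expect_false(unique(sfs) %in% c(1, 2, 3))  # never-cued SF
  }
  expect_error(search_display("EXACT", cue), "not implemented")
})

test_that("De Bruijn instruction order counterbalances all 3-grams cyclically", {
  for (seed in 1:5) {
    s <- de_bruijn_order(seed = seed)
    expect_length(s, 27)
    expect_true(all(table(s) == 9))
    grams <- vapply(0:26, function(i)
      paste(s[(c(i, i + 1, i + 2) %% 27) + 1], collapse = "|"), "")
    expect_equal(length(unique(grams)), 27)  # every 3-gram exactly once
  }
})

test_that("jitter values are log-spaced with exact endpoints", {
  j <- jitter_values(1, 2.5)
  expect_length(j, 9)
  expect_equal(j[1], 1)
  expect_equal(j[9], 2.5)
  expect_true(all(diff(j) > 0))
  expect_equal(diff(range(j[-1] / j[-9])), 0, tolerance = 1e-12)  # constant ratio
  j2 <- jitter_values(2.5, 6.5)
  expect_equal(range(j2), c(2.5, 6.5))
  expect_error(jitter_values(3, 2), "lo")
})

test_that("block schedules satisfy the counterbalancing and jitter-conservation invariants", {
  b <- block_schedule(seed = 7)
  expect_equal(nrow(b), 27)
  expect_true(all(table(b$task) == 9))
  expect_true(all(table(b$task, b$cue_id) == 1))  # each cue once per instruction
  expect_equal(sort(b$cue_duration), sort(rep(jitter_values(1, 2.5), 3)))
  expect_equal(sort(b$delay_duration), sort(rep(jitter_values(2.5, 6.5), 3)))
  expect_true(all(b$search_duration == 4))
  expect_true(all(diff(b$instruction_onset) > 0))
  ## phases are contiguous within a trial
  expect_equal(b$cue_onset, b$instruction_onset + 1)
  expect_equal(b$delay_onset, b$cue_onset + b$cue_duration)
  expect_equal(b$search_onset, b$delay_onset + b$delay_duration)
})

test_that("cue and delay jitter assignments are orthogonal across seeds", {
  r <- vapply(1:100, function(s) {
    b <- block_schedule(seed = s)
    cor(b$cue_duration, b$delay_duration)
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.05)
})

test_that("session schedules concatenate blocks with cumulative onsets", {
  s <- session_schedule(8, seed = 2)
  expect_equal(nrow(s), 216)
  expect_equal(sum(s$task == "SF"), 72)
  expect_equal(sum(s$task == "ORIENTATION"), 72)
  expect_false(is.unsorted(s$instruction_onset, strictly = TRUE))
  ev <- schedule_events(s)
  expect_setequal(unique(ev$phase), c("instruction", "cue", "delay", "search"))
  expect_equal(sum(ev$phase == "cue"), 216)
  ## all 18 analysis conditions appear in both periods
  expect_setequal(intersect(unique(ev$trial_type), condition_set()$label),
                  condition_set()$label)
})

test_that("inverse efficiency is accuracy-weighted reaction time", {
  expect_equal(inverse_efficiency(2, 1), 2)
  expect_equal(inverse_efficiency(1, 0.5), 2)
  expect_equal(inverse_efficiency(1.97, 0.814), 1.97 / 0.814)
  expect_error(inverse_efficiency(1, 0), "undefined")
})
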