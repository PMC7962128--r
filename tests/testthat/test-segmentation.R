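test_that("mid-swing detection finds sinusoid crests at analytic positions", {
  # 5 periods of 128 samples; crest of period k at 0-based sample 32+128k,
  # i.e. R index 33 + 128k
  x <- 100 * sin(2 * pi * (0:(5 * 128 - 1)) / 128)
  sig <- angvel_signal(x, sample_rate = 128)
  expect_equal(detect_midswing(sig), 33L + 128L * (0:4))
})

test_that("constant and sub-threshold signals yield no mid-swing", {
  expect_length(detect_midswing(angvel_signal(rep(7, 256))), 0)
  small <- angvel_signal(10 * sin(2 * pi * (0:255) / 128))
  expect_length(detect_midswing(small), 0)  # peaks below min_peak
})

test_that("min_separation suppresses the smaller of two close peaks", {
  x <- rep(0, 256)
  x[100] <- 80
  x[120] <- 90   # 20 samples apart at 128 Hz = 0.156 s < 0.4 s
  x[230] <- 70
  sig <- angvel_signal(x)
  expect_equal(detect_midswing(sig), c(120L, 230L))
})

test_that("heel strike is the first negative trough after mid-swing", {
  syn <- synthesize_leg(gait_template(), abnormality_profile(),
                        n_gaits = 6, seed = 4)
  ms <- syn$midswing_indices
  hs <- detect_heelstrike(syn$signal, ms)
  x <- syn$signal$samples
  for (k in seq_along(ms)) {
    expect_false(is.na(hs[k]))
    expect_gt(hs[k], ms[k])
    expect_lt(x[hs[k]], 0)
    # local minimum, and no earlier negative local minimum in between
    expect_lt(x[hs[k]], x[hs[k] - 1])
    expect_lte(x[hs[k]], x[hs[k] + 1])
    between <- if (hs[k] - ms[k] > 2) (ms[k] + 1):(hs[k] - 1) else integer(0)
    inner <- setdiff(between, c(ms[k], ms[k] + 1))
    if (length(inner)) {
      is_neg_min <- x[inner] < x[inner - 1] & x[inner] <= x[inner + 1] &
        x[inner] < 0
      expect_false(any(is_neg_min))
    }
  }
})

test_that("heel strike requires a negative local minimum", {
  # strictly positive after the peak: no event
  x <- c(rep(1, 10), 60, 55, 50, 45, 40, 35, 30, 25, 20, rep(15, 40))
  sig <- angvel_signal(x, sample_rate = 16)
  expect_true(is.na(detect_heelstrike(sig, 11L)))
  # monotone decreasing tail crossing zero without a turning point
  x2 <- c(rep(1, 10), 60, seq(50, -60, length.out = 50))
  sig2 <- angvel_signal(x2, sample_rate = 16)
  expect_true(is.na(detect_heelstrike(sig2, 11L)))
})

test_that("cycle splitting partitions the spanned samples", {
  sig <- angvel_signal(seq_len(40), sample_rate = 16)
  cycles <- split_cycles(sig, c(10L, 20L, 30L))
  expect_length(cycles, 2)
  expect_equal(lengths(cycles), c(10L, 10L))
  expect_equal(cycles[[1]], sig$samples[10:19],
               ignore_attr = TRUE)
  expect_equal(unlist(cycles), sig$samples[10:29], ignore_attr = TRUE)
  expect_length(split_cycles(sig, c(5L, 25L)), 1)
  expect_length(split_cycles(sig, 15L), 0)
})

test_that("normalization maps cycles onto 100 points exactly", {
  expect_equal(normalize_cycle(rep(7, 37)), rep(7, 100))
  ramp <- 0:127
  expect_equal(normalize_cycle(ramp), (0:99) * 1.28)
  expect_error(normalize_cycle(3), "degenerate")
})

test_that("normalization agrees with an independent interpolation oracle", {
  set.seed(21)
  for (L in c(100, 87, 128, 143)) {
    x <- rnorm(L, sd = 50)
    expect_equal(normalize_cycle(x), lin_interp_oracle(x, 100),
                 tolerance = 1e-12)
  }
})

test_that("normalization is idempotent and amplitude-equivariant", {
  set.seed(8)
  x <- rnorm(128, sd = 60)
  once <- normalize_cycle(x)
  expect_equal(normalize_cycle(once), once, tolerance = 1e-12)
  expect_equal(normalize_cycle(3 * x), 3 * once, tolerance = 1e-12)
})

test_that("end-to-end segmentation recovers planted cycles", {
  # noise-free: exact recovery
  syn <- synthesize_leg(gait_template(), abnormality_profile(),
                        n_gaits = 21, seed = 13)
  seg <- segment_signal(syn$signal)
  expect_equal(nrow(seg$cycles), 20)
  expect_identical(seg$midswing_indices, syn$midswing_indices)

  # default tremor: within +-1 cycle per 100
  profile <- abnormality_profile(hip_hiking = TRUE, back_knee = TRUE,
                                 tremor_sd = 15)
  syn2 <- synthesize_leg(gait_template(), profile, n_gaits = 101, seed = 6)
  seg2 <- segment_signal(syn2$signal)
  expect_lte(abs(nrow(seg2$cycles) - 100), 1)
})

test_that("the optional low-pass hook smooths before peak picking", {
  skip_if_not_installed("signal")
  profile <- abnormality_profile(tremor_sd = 15)
  syn <- synthesize_leg(gait_template(), profile, n_gaits = 30, seed = 17)
  plain <- detect_midswing(syn$signal)
  filtered <- detect_midswing(syn$signal, lowpass_hz = 10)
  expect_equal(length(filtered), length(plain))
})
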