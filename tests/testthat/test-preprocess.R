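make_rec <- function(data, fs = 300, events = NULL) {
  ch <- rsvp_channels()[seq_len(nrow(data))]
  if (is.null(events))
    events <- data.frame(sample = integer(0), onset_ms = numeric(0),
                         class = character(0), trial = integer(0),
                         position = integer(0))
  structure(list(data = data, fs = fs, channels = ch, events = events,
                 meta = list()), class = "rsvp_recording")
}

test_that("band-pass preserves in-band tones and the notch removes 60 Hz", {
  fs <- 300
  t <- (0:(6 * fs - 1)) / fs
  mid <- (fs + 1):(5 * fs)
  rms <- function(x) sqrt(mean(x^2))
  rec10 <- make_rec(matrix(sin(2 * pi * 10 * t), 1))
  rec60 <- make_rec(matrix(sin(2 * pi * 60 * t), 1))
  y10 <- bandpass_notch(rec10)$data[1, ]
  y60 <- bandpass_notch(rec60)$data[1, ]
  expect_gt(rms(y10[mid]) / rms(rec10$data[1, mid]), 0.95)
  expect_lt(rms(y60[mid]) / rms(rec60$data[1, mid]), 0.10)
})

test_that("filtering an all-zero record returns zeros and validates edges", {
  rec <- make_rec(matrix(0, 2, 900))
  expect_true(all(bandpass_notch(rec)$data == 0))
  expect_error(bandpass_notch(rec, low_hz = 0), "band edges")
  expect_error(bandpass_notch(rec, high_hz = 200), "band edges")
})

test_that("resampling halves 300 Hz data and rescales events", {
  ev <- data.frame(sample = c(1L, 601L), onset_ms = c(0, 2000),
                   class = c("target", "nontarget"), trial = 1:2,
                   position = c(1L, 1L))
  rec <- make_rec(matrix(rnorm(2 * 3000), 2), fs = 300, events = ev)
  ds <- resample_recording(rec, 150)
  expect_equal(ds$fs, 150)
  expect_equal(ncol(ds$data), 1500)
  expect_equal(ds$events$sample, c(1L, 301L))
  expect_identical(resample_recording(rec, 300), rec)
  expect_error(resample_recording(rec, 600), "target_fs")
})

test_that("channel pooling is the samplewise arithmetic mean", {
  d <- matrix(0, 7, 10)
  d[3, ] <- 1; d[7, ] <- 2; d[5, ] <- 3; d[6, ] <- 4    # Pz, Oz, PO7, PO8
  rec <- make_rec(d)
  pooled <- pool_channels(rec)
  expect_equal(unname(pooled$data["POOL", ]), rep(2.5, 10))
  # singleton subset equals the channel itself
  solo <- pool_channels(rec, "Pz")
  expect_equal(unname(solo$data["POOL", ]), unname(d[3, ]))
  expect_error(pool_channels(rec, c("Pz", "XX")), "not present")
})

test_that("pooling commutes with linear filtering", {
  set.seed(1)
  rec <- make_rec(matrix(rnorm(7 * 1800), 7))
  a <- pool_channels(bandpass_notch(rec))$data["POOL", ]
  b <- bandpass_notch(pool_channels(rec))$data["POOL", ]
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("epoching yields the documented epoch and sample counts", {
  ep <- prep_epochs(1, 30, seed = 5)
  expect_equal(dim(ep$data), c(300, 8, 375))   # 7 channels + POOL, 2.5 s @150
  expect_equal(sum(ep$labels == "target"), 30)
  ep_erp <- prep_epochs(1, 30, seed = 5, window = c(-200, 800))
  expect_equal(dim(ep_erp$data)[3], 150)       # 1 s @ 150 Hz
  # epoch count conservation: epochs + dropped = events
  expect_equal(dim(ep$data)[1] + length(ep$dropped), 300)
})

test_that("stimulus onset maps to the t = 0 sample, half-open windows", {
  ev <- data.frame(sample = 301L, onset_ms = 2000, class = "target",
                   trial = 1L, position = 1L)
  d <- matrix(0, 1, 600); d[1, 301] <- 5
  rec <- make_rec(d, fs = 150, events = ev)
  ep <- epoch_recording(rec, c(-200, 800))
  expect_equal(ep$times[1], -200)
  i0 <- which(ep$times == 0)
  expect_equal(unname(ep$data[1, 1, i0]), 5)
  expect_equal(dim(ep$data)[3], 150)
})

test_that("out-of-bounds epochs are dropped with a warning", {
  ev <- data.frame(sample = c(10L, 900L), onset_ms = c(60, 6000),
                   class = c("target", "nontarget"), trial = 1:2,
                   position = c(1L, 1L))
  rec <- make_rec(matrix(rnorm(1000), 1), fs = 150, events = ev)
  expect_warning(ep <- epoch_recording(rec, c(-1250, 1250)), "dropped")
  expect_equal(dim(ep$data)[1], 0)
  expect_equal(ep$dropped, c(1, 2))
})

test_that("filtering commutes with epoching on the continuous record", {
  sch <- make_schedule(1, 3, 10, seed = 2)
  rec <- synthesize_recording(sch, sim_params(seed = 2))
  filt <- bandpass_notch(rec)
  ep1 <- epoch_recording(filt, c(-500, 500))
  # same thing computed per epoch from the filtered record directly
  ev <- filt$events
  off <- round(-500 / 1000 * filt$fs)
  n <- round(1000 / 1000 * filt$fs)
  for (j in c(1, 15)) {
    s0 <- ev$sample[j] + off
    expect_equal(ep1$data[j, , ], filt$data[, s0:(s0 + n - 1)])
  }
})
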