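test_that("the layer grid spans 4-16 Hz in 48 logarithmic steps", {
  f <- layer_freqs()
  expect_length(f, 48)
  expect_equal(f[1], 4)
  expect_equal(f[48], 16)
  expect_true(all(diff(f) > 0))
  # logarithmic spacing: constant ratio between adjacent layers
  expect_equal(diff(log(f)), rep(log(4) / 47, 47), tolerance = 1e-12)
})

test_that("every layer's argmax localizes a tone at its center frequency", {
  fs <- 150
  t <- (0:374) / fs
  grid <- layer_freqs()
  data <- array(0, c(48, 1, 375))
  for (k in 1:48) data[k, 1, ] <- sin(2 * pi * grid[k] * t)
  sc <- cwt_scaleogram(make_epochs(data, fs = fs))
  # brute force over layers: time-averaged magnitude per layer
  for (k in 1:48) {
    prof <- rowMeans(matrix(sc$data[k, 1, , 100:275], nrow = 48))
    expect_equal(which.max(prof), k)
  }
})

test_that("the transform is linear in input amplitude and zero-preserving", {
  fs <- 150
  x <- sin(2 * pi * 10 * (0:374) / fs)
  data <- array(0, c(2, 1, 375))
  data[1, 1, ] <- x
  data[2, 1, ] <- 2 * x
  sc <- cwt_scaleogram(make_epochs(data, fs = fs), layers = c(10, 30))
  expect_lt(max(abs(2 * sc$data[1, 1, , ] - sc$data[2, 1, , ])), 1e-9)
  zero <- cwt_scaleogram(make_epochs(array(0, c(1, 1, 375)), fs = fs),
                         layers = 1)
  expect_true(all(zero$data == 0))
})

test_that("epochs shorter than the wavelet support are rejected", {
  short <- make_epochs(array(rnorm(100), c(1, 1, 100)), fs = 150)
  expect_error(cwt_scaleogram(short), "too short")
})

test_that("z-transformed baselines have mean 0 and sd 1 per series", {
  ep <- prep_epochs(1, 10, seed = 4)
  sc <- cwt_scaleogram(ep, channels = c("POOL", "Pz"), layers = c(1, 25, 48))
  z <- ztransform(sc)
  bidx <- which(z$times >= -600 & z$times < -100)
  for (e in c(1, 50)) for (ch in 1:2) for (l in 1:3) {
    b <- z$data[e, ch, l, bidx]
    expect_lt(abs(mean(b)), 1e-9)
    expect_lt(abs(sd(b) - 1), 1e-9)
  }
  expect_equal(z$units, "zscore")
  expect_error(ztransform(z), "already")
})

test_that("constant epochs are excluded as degenerate", {
  data <- array(rnorm(3 * 1 * 375), c(3, 1, 375))
  data[2, 1, ] <- 0
  ep <- make_epochs(data, fs = 150, window = c(-1250, 1250),
                    labels = c("target", "nontarget", "target"))
  sc <- cwt_scaleogram(ep, layers = 25)
  expect_message(z <- ztransform(sc), "degenerate")
  expect_equal(z$excluded, 2)
  expect_equal(dim(z$data)[1], 2)
  expect_equal(z$labels, c("target", "target"))
})

test_that("IAF layer selection minimizes distance with lower-frequency ties", {
  grid <- layer_freqs()
  expect_equal(select_iaf_layer(grid, 4), 1)
  expect_equal(select_iaf_layer(grid, 16), 48)
  # brute force nearest layer for 10 Hz
  expect_equal(select_iaf_layer(grid, 10), which.min(abs(grid - 10)))
  # an exact midpoint resolves to the lower layer
  mid <- (grid[20] + grid[21]) / 2
  expect_equal(select_iaf_layer(grid, mid), 20)
  expect_error(select_iaf_layer(grid, 3), "outside")
})

test_that("alpha activity summarizes medians, attenuation and the U test", {
  labels <- c(rep("target", 10), rep("nontarget", 90))
  z0 <- make_zscaleogram(array(0, c(100, 1, 1, 375)), channels = "POOL",
                         labels = labels)
  a0 <- alpha_activity(z0, 1, source = "POOL")
  expect_equal(a0$attenuation, 0)
  zd <- array(0, c(100, 1, 1, 375))
  zd[labels == "target", , , ] <- -1
  zd[labels == "nontarget", , , ] <- 1
  ad <- alpha_activity(make_zscaleogram(zd, channels = "POOL",
                                        labels = labels), 1, source = "POOL")
  expect_equal(ad$attenuation, -2)
  expect_equal(unname(ad$class_medians), c(-1, 1))
  expect_lt(ad$mwu_p, 1e-6)
})

test_that("attenuation grows monotonically with the injected depth", {
  atts <- sapply(c(0, 0.25, 0.5, 0.75), function(d) {
    ep <- prep_epochs(1, 20, seed = 9, erd_depth = d)
    k <- select_iaf_layer(layer_freqs(), 10)
    z <- ztransform(cwt_scaleogram(ep, channels = "POOL", layers = k))
    alpha_activity(z, 1)$attenuation
  })
  expect_true(all(diff(atts) < 0))
})

test_that("wavelet magnitude agrees with a Hilbert-envelope oracle", {
  # alpha-only scenario with d = 0.5: the z-scored target response must be
  # clearly negative while non-targets stay near baseline
  ep <- prep_epochs(1, 20, seed = 10, n200_amp = 0, p300_amp = 0,
                    ssvep_amp = 0, noise_amp = 1)
  k <- select_iaf_layer(layer_freqs(), 10)
  z <- ztransform(cwt_scaleogram(ep, channels = "POOL", layers = k))
  a <- alpha_activity(z, 1)
  expect_lt(a$class_medians["target"], -1)
  expect_lt(abs(a$class_medians["nontarget"]),
            abs(a$class_medians["target"]) / 2)
})
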