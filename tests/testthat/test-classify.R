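test_that("balanced accuracy is the mean of per-class recalls", {
  y <- c(rep("target", 10), rep("nontarget", 90))
  expect_equal(balanced_accuracy(y, y), 1.0)
  expect_equal(balanced_accuracy(y, rep("nontarget", 100)), 0.5)
  # recalls 0.6 and 0.8 -> 0.7
  pred <- y
  pred[1:4] <- "nontarget"                 # target recall 0.6
  pred[11:28] <- "target"                  # non-target recall 0.8
  expect_equal(balanced_accuracy(y, pred), 0.7)
  expect_error(balanced_accuracy(rep("target", 5), rep("target", 5)),
               "both classes")
})

test_that("alpha features concatenate four channels of the IAF layer", {
  labels <- c(rep("target", 5), rep("nontarget", 45))
  z <- make_zscaleogram(array(rnorm(50 * 4 * 1 * 375), c(50, 4, 1, 375)),
                        channels = posterior_channels(), labels = labels)
  f <- extract_alpha_features(z, 1, c(300, 800))
  expect_equal(dim(f$X), c(50, 4 * 75))    # 500 ms at 150 Hz per channel
  expect_equal(f$y, labels)
  z0 <- make_zscaleogram(array(0, c(10, 4, 1, 375)),
                         channels = posterior_channels())
  expect_true(all(extract_alpha_features(z0, 1)$X == 0))
  expect_error(extract_alpha_features(z, 1, c(300, 800), c("Pz", "XX")),
               "not present")
})

test_that("the uniform-random control sits at chance on 9:1 data", {
  set.seed(1)
  labels <- rep(c("target", rep("nontarget", 9)), 100)
  f <- new_features_for_test(matrix(rnorm(1000 * 4), 1000), labels)
  res <- train_eval(f, "uniform_random", cv_spec(10, 0.2), seed = 2)
  expect_lt(abs(res$mean_balanced_acc - 0.5), 0.05)
  expect_length(res$per_split_balanced_acc, 10)
})

test_that("linearly separable features are classified perfectly", {
  labels <- c(rep("target", 20), rep("nontarget", 180))
  X <- cbind(ifelse(labels == "target", 5, -5) + rnorm(200, sd = 0.1),
             rnorm(200))
  f <- new_features_for_test(X, labels)
  res <- train_eval(f, "logreg_l2", cv_spec(5, 0.2), seed = 3)
  expect_equal(res$mean_balanced_acc, 1.0)
})

test_that("training is deterministic given the seed", {
  f <- ref_alpha_features()
  for (m in c("logreg_l2", "uniform_random", "tangent_space")) {
    r1 <- train_eval(f, m, cv_spec(3, 0.2), seed = 11)
    r2 <- train_eval(f, m, cv_spec(3, 0.2), seed = 11)
    expect_identical(r1$per_split_balanced_acc, r2$per_split_balanced_acc)
  }
})

test_that("all discriminative alpha models beat chance on the reference", {
  f <- ref_alpha_features()
  accs <- sapply(c("logreg_l2", "svc", "tangent_space"), function(m)
    train_eval(f, m, cv_spec(5, 0.2), seed = 4)$mean_balanced_acc)
  expect_true(all(accs > 0.55))
  rnd <- train_eval(f, "uniform_random", cv_spec(5, 0.2), seed = 4)
  expect_true(all(accs >= rnd$mean_balanced_acc))
})

test_that("label shuffling drives models to chance", {
  set.seed(21)
  f <- ref_alpha_features()
  accs <- replicate(40, {
    fp <- f
    fp$y <- sample(fp$y)
    train_eval(fp, "logreg_l2", cv_spec(2, 0.2),
               seed = sample.int(1e6, 1))$mean_balanced_acc
  })
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("the tuning grid has the documented geometry", {
  pts <- tuning_grid_points(50)
  expect_length(pts$baseline_starts, 10)
  expect_length(pts$response_starts, 9)
  expect_equal(range(pts$baseline_starts), c(-1050, -600))
  expect_equal(range(pts$response_starts), c(150, 550))
  expect_error(tuning_grid_points(0), "positive")
})

test_that("window tuning never scores below the default pair", {
  ep <- prep_epochs(1, 20, seed = 14)
  tg <- tune_windows(ep, 10, grid_step_ms = 150, cv = cv_spec(3, 0.2),
                     seed = 5)
  expect_gte(tg$best_score, tg$default_score)
  expect_true(tg$best["baseline_start_ms"] %in% tg$baseline_starts)
  # default pair is on the default 50 ms grid
  pts <- tuning_grid_points(50)
  expect_true(-600 %in% pts$baseline_starts && 300 %in% pts$response_starts)
})

test_that("tuning tracks a late-shifted attenuation window", {
  ep <- prep_epochs(1, 20, seed = 15, erd_window = c(450, 950))
  tg <- tune_windows(ep, 10, grid_step_ms = 100, cv = cv_spec(3, 0.2),
                     seed = 6)
  expect_gt(tg$best["response_start_ms"], 300)
})

test_that("rda/kde beats the alpha models and collapses under shuffling", {
  ep <- prep_epochs(1, 30, seed = 5, window = c(0, 500))
  res <- rda_kde_eval(ep, cv_spec(5, 0.2), seed = 7)
  f <- ref_alpha_features(1, 30, 5)
  alpha_accs <- sapply(c("logreg_l2", "svc", "tangent_space"), function(m)
    train_eval(f, m, cv_spec(5, 0.2), seed = 7)$mean_balanced_acc)
  expect_gt(res$mean_balanced_acc, 0.5)
  expect_true(all(res$mean_balanced_acc >= alpha_accs))
  # shuffled labels -> chance
  set.seed(9)
  eps <- ep
  eps$labels <- sample(ep$labels)
  ress <- rda_kde_eval(eps, cv_spec(5, 0.2), seed = 8)
  expect_lt(abs(ress$mean_balanced_acc - 0.5), 0.12)
  # zero-variance input errors
  epz <- make_epochs(array(0, c(20, 2, 75)), fs = 150, window = c(0, 500),
                     labels = rep(c("target", "nontarget"), 10))
  expect_error(rda_kde_eval(epz, cv_spec(2, 0.2), seed = 1),
               "zero-variance")
})
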