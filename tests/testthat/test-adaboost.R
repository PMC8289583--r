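test_that("weighted error sums the weights of mistakes", {
  expect_equal(weighted_error(c("a", "b"), c("a", "b"), c(0.5, 0.5)), 0)
  expect_equal(weighted_error(c("b", "a"), c("a", "b"), c(0.5, 0.5)), 1)
  expect_equal(weighted_error(c("a", "a", "a", "b"), c("a", "a", "a", "a"),
                              rep(0.25, 4)), 0.25)
  expect_error(weighted_error("a", "a", 0.7), "sum to 1")
})

test_that("alpha follows the half-log-odds formula and is monotone", {
  expect_equal(boost_alpha(0.5), 0)
  expect_equal(boost_alpha(0.25), 0.5 * log(3))
  e_grid <- seq(0.01, 0.49, by = 0.02)
  a_grid <- boost_alpha(e_grid)
  expect_true(all(diff(a_grid) < 0))
  expect_true(all(a_grid > 0))
  expect_true(is.finite(boost_alpha(0)) && boost_alpha(0) > 10)
})

test_that("the weight update matches the hand-computed recursion", {
  # 2 samples, uniform weights, sample 2 wrong, alpha = (1/2) ln 3
  w <- update_boost_weights(c(0.5, 0.5), c("a", "a"), c("a", "b"),
                            0.5 * log(3))
  expect_equal(w, c(0.25, 0.75))
  # alpha = 0 leaves weights unchanged
  expect_equal(update_boost_weights(c(0.3, 0.7), c("a", "b"), c("b", "b"), 0),
               c(0.3, 0.7))
  # normalization contract on random inputs
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    w0 <- runif(n)
    w0 <- w0 / sum(w0)
    pred <- sample(c("a", "b"), n, replace = TRUE)
    lab <- sample(c("a", "b"), n, replace = TRUE)
    expect_equal(sum(update_boost_weights(w0, pred, lab, runif(1, 0, 2))), 1,
                 tolerance = 1e-12)
  }
})

test_that("the training trajectory matches the brute-force recursion", {
  # toys of <= 8 samples; levels(factor) == sort(unique) keeps the stump
  # tie-break identical between the package and the oracle
  toys <- list(
    list(x = data.frame(u = c(1, 2, 3, 4, 5, 6), v = c(2, 1, 4, 3, 6, 5)),
         y = c("a", "a", "b", "a", "b", "b")),
    list(x = data.frame(u = c(0.1, 0.4, 0.35, 0.8, 0.75, 0.9, 0.2, 0.6)),
         y = c("a", "b", "a", "b", "b", "b", "a", "a")),
    list(x = data.frame(u = c(1, 2, 3, 4, 5, 6, 7, 8),
                        v = c(1, 1, 2, 2, 3, 3, 4, 4)),
         y = c("a", "a", "b", "b", "c", "c", "a", "b"))
  )
  for (toy in toys) {
    rounds <- 4
    fit <- fit_adaboost(toy$x, toy$y, rounds = rounds, base = "stump",
                        resample = FALSE)
    oracle <- brute_force_boost(toy$x, toy$y, rounds)
    for (m in seq_len(rounds)) {
      expect_equal(fit$errors[m], oracle[[m]]$e, tolerance = 1e-12)
      expect_equal(fit$alphas[m], oracle[[m]]$alpha, tolerance = 1e-12)
    }
  }
})

test_that("a separable toy trains to perfect accuracy", {
  set.seed(1)
  x <- data.frame(f1 = c(rnorm(10, 0), rnorm(10, 6)),
                  f2 = c(rnorm(10, 0), rnorm(10, -6)))
  y <- rep(c("a", "b"), each = 10)
  fit <- fit_adaboost(x, y, rounds = 3, num_trees = 15, seed = 2)
  expect_equal(mean(predict(fit, x) == y), 1)
})

test_that("a single round reduces to its one base learner", {
  set.seed(3)
  x <- data.frame(f = rnorm(30))
  y <- ifelse(x$f > 0, "pos", "neg")
  fit <- fit_adaboost(x, y, rounds = 1, num_trees = 20, seed = 5)
  single <- fit$learners[[1]]$predict(fit$learners[[1]]$model, x)
  expect_equal(as.character(predict(fit, x)), as.character(single))
})

test_that("prediction is an alpha-weighted vote with ordered tie-breaks", {
  # two frozen constant learners that disagree: the higher-alpha one wins
  const_learner <- function(lab, classes) {
    list(model = list(),
         predict = function(model, x) factor(rep(lab, nrow(x)),
                                             levels = classes))
  }
  model <- structure(
    list(learners = list(const_learner("V", aami_classes()),
                         const_learner("N", aami_classes())),
         alphas = c(1.0, 0.2), errors = c(NA, NA),
         classes = aami_classes(), n_features = 1, feature_names = "f",
         config = list(base = "custom")),
    class = "adaboost_rf"
  )
  pred <- predict(model, data.frame(f = 1:3))
  expect_equal(as.character(pred), rep("V", 3))
  # equal alphas: tie broken by class order (N before V)
  model$alphas <- c(0.5, 0.5)
  expect_equal(as.character(predict(model, data.frame(f = 1))), "N")
  expect_error(predict(model, data.frame(g = 1)), "lacks training feature")
})

test_that("binary weighted voting reproduces the sign rule", {
  # enumerate all prediction patterns of 2 learners on labels {-1, +1}
  classes <- c("-1", "1")
  for (p1 in classes) for (p2 in classes) for (a1 in c(0.3, 1)) {
    for (a2 in c(0.4, 0.9)) {
      score <- a1 * as.numeric(p1) + a2 * as.numeric(p2)
      expected <- if (score > 0) "1" else "-1"   # sign(sum alpha_m G_m)
      cl <- function(lab) list(model = NULL,
                               predict = function(model, x) {
                                 factor(rep(lab, nrow(x)), levels = classes)
                               })
      model <- structure(
        list(learners = list(cl(p1), cl(p2)), alphas = c(a1, a2),
             classes = classes, n_features = 1, feature_names = "f",
             config = list()),
        class = "adaboost_rf"
      )
      expect_equal(as.character(predict(model, data.frame(f = 0))), expected)
    }
  }
})

test_that("rounds with error above one half reset weights and retry", {
  set.seed(4)
  x <- data.frame(f = rnorm(12))
  y <- factor(rep(c("a", "b", "c"), 4))
  # adversarial learner: always predicts a label that is wrong everywhere
  bad <- list(fit = function(x, y, w = NULL) list(),
              predict = function(model, x) {
                factor(rep("c", nrow(x)), levels = c("a", "b", "c"))
              })
  expect_error(
    fit_adaboost(x, rep(c("a", "b"), 6), rounds = 1, base = bad,
                 max_retries = 2),
    "round 1.*above 0.5"
  )
  # error exactly at the threshold does not trigger the reset
  half <- list(fit = function(x, y, w = NULL) list(),
               predict = function(model, x) {
                 factor(rep(c("a", "b"), length.out = nrow(x)),
                        levels = c("a", "b"))
               })
  fit <- fit_adaboost(data.frame(f = 1:4), c("a", "a", "b", "b"),
                      rounds = 1, base = half, resample = FALSE)
  expect_equal(fit$errors[1], 0.5)
})

test_that("fit and predict are deterministic under a fixed seed", {
  gen <- synth_ecg(balanced_config(n_beats = 120, seed = 31))
  ft <- ground_truth_features(gen$truth, 360,
                              n_samples = nrow(gen$record$signal))
  x <- ft[, c("p_wave", "qrs_wave", "t_wave", "rr_interval")]
  f1 <- fit_adaboost(x, ft$label, rounds = 3, num_trees = 10, seed = 7)
  f2 <- fit_adaboost(x, ft$label, rounds = 3, num_trees = 10, seed = 7)
  expect_identical(f1$alphas, f2$alphas)
  expect_identical(predict(f1, x), predict(f2, x))
  expect_error(fit_adaboost(x, rep("N", nrow(x)), rounds = 2), "2 classes")
})

test_that("weights stay normalized through an imbalanced training run", {
  gen <- synth_ecg(synth_config(n_beats = 400, seed = 33, noise = no_noise))
  ft <- ground_truth_features(gen$truth, 360,
                              n_samples = nrow(gen$record$signal))
  x <- ft[, c("p_wave", "qrs_wave", "t_wave", "qt_interval", "rr_interval")]
  fit <- fit_adaboost(x, ft$label, rounds = 5, num_trees = 15, seed = 9)
  expect_length(fit$alphas, 5)
  expect_true(all(is.finite(fit$alphas)))
  expect_true(all(fit$errors >= 0 & fit$errors <= 0.5))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 5)
  expect_equal(glance(fit)$n_classes, 5)
})
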