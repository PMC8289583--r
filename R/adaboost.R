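# AdaBoost ensemble with random-forest base learners.
#
# The boosting recursion follows the classical binary equations —
# e_m = sum_j w_j I(G_m(x_j) != y_j), alpha_m = (1/2) ln((1-e_m)/e_m),
# w_{m+1,i} proportional to w_{m,i} exp(+alpha_m) on mistakes and
# exp(-alpha_m) otherwise, renormalized by z_m — extended to five classes by
# SAMME-style weighted voting. Class imbalance is handled per round by a
# balanced weighted bootstrap: minority classes enter in full, majority
# classes are drawn weight-proportionally. A round whose error exceeds 0.5
# resets the weights to uniform and redraws (bounded retries).

#' Weighted classification error
#'
#' `e_m = sum_j w_j * I(pred_j != y_j)` over normalized weights.
#'
#' @param predictions,labels Equal-length label vectors.
#' @param weights Non-negative weights summing to 1 (tolerance 1e-9).
#' @return Error in \[0, 1\].
#' @export
weighted_error <- function(predictions, labels, weights) {
  stopifnot(length(predictions) == length(labels),
            length(weights) == length(labels))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  sum(weights[as.character(predictions) != as.character(labels)])
}

#' Boosting round weight alpha
#'
#' `alpha_m = (1/2) ln((1 - e_m) / e_m)`, with `e_m` clamped to
#' `[eps, 1 - eps]` so a perfect base learner gets a large finite vote.
#' Decreasing in `e_m`; zero at `e_m = 0.5`.
#'
#' @param e_m Weighted error.
#' @param eps Clamping bound (default 1e-10).
#' @return Finite alpha.
#' @export
boost_alpha <- function(e_m, eps = 1e-10) {
  e <- pmin(pmax(e_m, eps), 1 - eps)
  0.5 * log((1 - e) / e)
}

#' One boosting weight update
#'
#' Multiplies each weight by `exp(+alpha)` if misclassified and `exp(-alpha)`
#' otherwise, then divides by the normalizer `z_m` so the weights again sum
#' to 1 (the multiclass generalization of the classical +/-1 update).
#'
#' @param weights Current normalized weights.
#' @param predictions,labels Base-learner predictions and true labels.
#' @param alpha Round weight from [boost_alpha()].
#' @return Updated normalized weights.
#' @export
update_boost_weights <- function(weights, predictions, labels, alpha) {
  miss <- as.character(predictions) != as.character(labels)
  w <- weights * exp(ifelse(miss, alpha, -alpha))
  z <- sum(w)
  if (z == 0) stop("degenerate weights: normalizer is zero")
  w / z
}

# balanced weighted bootstrap: minority classes (count below the uniform
# share) enter in full; the remainder is drawn with replacement from the
# majority pool with probability proportional to the current weights
balanced_bootstrap <- function(labels, weights) {
  n <- length(labels)
  counts <- table(labels)
  counts <- counts[counts > 0]
  minority <- names(counts)[counts < n / length(counts)]
  keep <- which(labels %in% minority)
  pool <- setdiff(seq_len(n), keep)
  n_draw <- n - length(keep)
  if (length(pool) == 0) return(sample.int(n, n, replace = TRUE, prob = weights))
  drawn <- sample(pool, n_draw, replace = TRUE, prob = weights[pool])
  c(keep, drawn)
}

# base learner constructors: list(fit(x, y, w) -> model, predict(model, x))
learner_ranger <- function(num_trees, mtry = NULL, seed = 1L) {
  list(
    fit = function(x, y, w = NULL) {
      ranger::ranger(x = x, y = y, num.trees = num_trees, mtry = mtry,
                     case.weights = w, seed = seed, num.threads = 1)
    },
    predict = function(model, x) {
      # fixed seed: ranger breaks tied tree votes randomly otherwise
      predict(model, data = x, num.threads = 1, seed = seed)$predictions
    }
  )
}

# deterministic weighted decision stump: best (feature, midpoint threshold)
# by weighted error; each side predicts its weight-majority class. Ties break
# toward the earlier feature, lower threshold, and class level order.
learner_stump <- function() {
  fit <- function(x, y, w = NULL) {
    x <- as.matrix(x)
    if (is.null(w)) w <- rep(1 / nrow(x), nrow(x))
    classes <- levels(y)
    best <- NULL
    for (j in seq_len(ncol(x))) {
      vals <- sort(unique(x[, j]))
      if (length(vals) < 2) next
      thr_grid <- (vals[-1] + vals[-length(vals)]) / 2
      for (thr in thr_grid) {
        left <- x[, j] <= thr
        maj <- function(mask) {
          if (!any(mask)) return(classes[1])
          ww <- vapply(classes, function(cl) sum(w[mask & y == cl]), numeric(1))
          classes[which.max(ww)]
        }
        cl_l <- maj(left)
        cl_r <- maj(!left)
        pred <- ifelse(left, cl_l, cl_r)
        err <- sum(w[pred != as.character(y)])
        if (is.null(best) || err < best$err - 1e-15) {
          best <- list(j = j, thr = thr, left = cl_l, right = cl_r, err = err)
        }
      }
    }
    if (is.null(best)) {
      best <- list(j = 1L, thr = Inf, left = levels(y)[which.max(table(y))],
                   right = levels(y)[1], err = NA_real_)
    }
    best$classes <- classes
    best
  }
  predict_fn <- function(model, x) {
    x <- as.matrix(x)
    factor(ifelse(x[, model$j] <= model$thr, model$left, model$right),
           levels = model$classes)
  }
  list(fit = fit, predict = predict_fn)
}

#' Fit an AdaBoost ensemble of random forests
#'
#' Runs `rounds` boosting iterations. Each round draws a balanced weighted
#' bootstrap (all minority-class beats plus a weight-proportional draw from
#' the majority pool), fits a random forest on it, computes the weighted
#' error on the full training set, converts it to the round vote
#' `alpha_m = (1/2) ln((1-e_m)/e_m)`, and reweights the samples. If a round's
#' error exceeds 0.5 its weights are reset to uniform and the bootstrap is
#' redrawn without advancing the round counter (up to `max_retries` times).
#' Everything is deterministic under `seed`.
#'
#' @param x Feature data frame/tibble or matrix (feature columns only).
#' @param y Class labels (coerced to the AAMI factor order when the labels
#'   are AAMI classes, otherwise to a factor).
#' @param rounds Number of boosting rounds M (default 10).
#' @param num_trees Trees per forest (default 70, the sweep optimum).
#' @param mtry Features per split (default: ranger's `sqrt(p)`).
#' @param base Base learner: `"ranger"` (random forest), `"stump"`
#'   (deterministic weighted decision stump, mainly for verification), or a
#'   custom `list(fit = function(x, y, w), predict = function(model, x))`.
#' @param resample Use the balanced weighted bootstrap (default TRUE). With
#'   `FALSE` the base learner is fit on the full set with the current
#'   weights as case weights — the configuration under which the boosting
#'   trajectory can be checked against the closed-form recursion.
#' @param seed Integer seed.
#' @param max_retries Redraw budget per round for the error > 0.5 rule.
#' @return Object of class `"adaboost_rf"`: base learners, `alphas`,
#'   per-round errors, class levels and the configuration.
#' @export
fit_adaboost <- function(x, y, rounds = 10, num_trees = 70, mtry = NULL,
                         base = "ranger", resample = TRUE,
                         seed = 1L, max_retries = 5) {
  custom <- is.list(base)
  if (!custom) base <- match.arg(base, c("ranger", "stump"))
  x <- as.data.frame(x)
  y <- if (all(as.character(y) %in% aami_classes())) {
    as_aami_factor(y)
  } else {
    factor(y)
  }
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("need at least 2 classes to fit a classifier")
  if (rounds < 1) stop("rounds must be >= 1")
  n <- nrow(x)
  set.seed(as.integer(seed))
  w <- rep(1 / n, n)
  learners <- vector("list", rounds)
  alphas <- numeric(rounds)
  errors <- numeric(rounds)
  for (m in seq_len(rounds)) {
    retries <- 0
    repeat {
      lrn <- if (custom) {
        base
      } else if (base == "ranger") {
        learner_ranger(num_trees, mtry, seed = as.integer(seed) + m + retries)
      } else {
        learner_stump()
      }
      if (resample) {
        idx <- balanced_bootstrap(y, w)
        model <- lrn$fit(x[idx, , drop = FALSE], y[idx])
      } else {
        model <- lrn$fit(x, y, w)
      }
      pred <- lrn$predict(model, x)
      e_m <- weighted_error(pred, y, w)
      if (e_m <= 0.5) break
      retries <- retries + 1
      if (retries > max_retries) {
        stop("round ", m, ": base-learner error stayed above 0.5 after ",
             max_retries, " resampling retries")
      }
      w <- rep(1 / n, n)   # restore initial weights and redraw
    }
    alpha <- boost_alpha(e_m)
    learners[[m]] <- list(model = model, predict = lrn$predict)
    alphas[m] <- alpha
    errors[m] <- e_m
    w <- update_boost_weights(w, pred, y, alpha)
  }
  structure(
    list(learners = learners, alphas = alphas, errors = errors,
         classes = levels(y), n_features = ncol(x),
         feature_names = colnames(x),
         config = list(rounds = rounds, num_trees = num_trees, mtry = mtry,
                       base = if (custom) "custom" else base,
                       resample = resample, seed = seed)),
    class = "adaboost_rf"
  )
}

#' Predict heartbeat classes with a fitted ensemble
#'
#' Weighted vote: `label = argmax_k sum_m alpha_m I(G_m(x) = k)`; ties break
#' in class order (N, S, V, F, Q). In the binary +/-1 case this reduces to
#' the classical `sign(sum_m alpha_m G_m(x))` rule.
#'
#' @param object An `adaboost_rf` model.
#' @param newdata Feature data frame with the training columns.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.adaboost_rf <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!is.null(object$feature_names)) {
    missing_cols <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing_cols) > 0) {
      stop("newdata lacks training feature column(s): ",
           paste(head(missing_cols, 5), collapse = ", "))
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         object$n_features)
  }
  votes <- matrix(0, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in seq_along(object$learners)) {
    pred <- as.character(object$learners[[m]]$predict(
      object$learners[[m]]$model, newdata))
    for (k in object$classes) {
      votes[pred == k, k] <- votes[pred == k, k] + object$alphas[m]
    }
  }
  # max.col with ties.method "first" honors the class order for ties
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.adaboost_rf <- function(x, ...) {
  cat(sprintf("<adaboost_rf: %d rounds of %s (%s trees), classes: %s>\n",
              length(x$learners), x$config$base,
              if (x$config$base == "ranger") x$config$num_trees else "-",
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Tidy the boosting trajectory
#'
#' @param x An `adaboost_rf` model.
#' @param ... Unused.
#' @return Tibble with one row per round: `round`, `error`, `alpha`.
#' @export
tidy.adaboost_rf <- function(x, ...) {
  tibble::tibble(round = seq_along(x$alphas), error = x$errors,
                 alpha = x$alphas)
}

#' One-row model summary
#'
#' @param x An `adaboost_rf` model.
#' @param ... Unused.
#' @return Tibble with rounds, trees, feature count, class count and the
#'   mean base-learner error.
#' @export
glance.adaboost_rf <- function(x, ...) {
  tibble::tibble(rounds = length(x$alphas),
                 num_trees = x$config$num_trees,
                 n_features = x$n_features,
                 n_classes = length(x$classes),
                 mean_error = mean(x$errors))
}
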