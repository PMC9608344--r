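# The four base learners behind the majority-voting ensemble. Each fit_*()
# takes a numeric feature matrix `x` (rows = scans, already standardized and
# imputed by the caller), a 0/1 outcome `y`, per-sample class weights `w`,
# and returns an object whose predict_prob() gives P(class 1).
#
# Logistic regression, random forest and the RBF support-vector machine are
# delegated to glmnet, ranger and e1071; adaptive boosting (SAMME with
# depth-1 rpart stumps) is implemented here.

fit_learner <- function(learner, x, y, w, params, seed = 1L) {
  switch(learner,
    lr = fit_lr(x, y, w, C = params$C),
    rf = fit_rf(x, y, w, trees = params$trees, depth = params$depth, seed = seed),
    svm = fit_svm(x, y, w, C = params$C, gamma = params$gamma, seed = seed),
    adb = fit_adaboost(x, y, w, trees = params$trees, lr = params$lr, seed = seed),
    abort(paste0("unknown learner: ", learner))
  )
}

predict_prob <- function(fit, x) {
  switch(fit$learner,
    lr = as.numeric(predict(fit$model, newx = x, type = "response")),
    rf = {
      p <- predict(fit$model, data = as.data.frame(x))$predictions
      as.numeric(p[, "1"])
    },
    svm = {
      p <- attr(predict(fit$model, newdata = x, probability = TRUE),
                "probabilities")
      as.numeric(p[, "1"])
    },
    adb = predict_adaboost(fit, x),
    abort(paste0("unknown learner: ", fit$learner))
  )
}

# Ridge-penalized logistic regression; the grid parameter C follows the
# convention that larger C means weaker regularization (lambda = 1 / C).
fit_lr <- function(x, y, w, C) {
  model <- suppressWarnings(glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                          alpha = 0, lambda = 1 / C, weights = w,
                          standardize = FALSE))
  list(learner = "lr", model = model)
}

fit_rf <- function(x, y, w, trees, depth, seed = 1L) {
  d <- as.data.frame(x)
  d$.y <- factor(y, levels = c(0, 1))
  model <- ranger::ranger(
    dependent.variable.name = ".y", data = d,
    num.trees = trees, max.depth = depth,
    probability = TRUE, case.weights = w,
    seed = seed, num.threads = 1
  )
  list(learner = "rf", model = model)
}

fit_svm <- function(x, y, w, C, gamma, seed = 1L) {
  yf <- factor(y, levels = c(0, 1))
  # class weights (not case weights): scale the cost per class
  cw <- unique_class_weights(y, w)
  model <- with_seed(seed, e1071::svm(
    x, yf, kernel = "radial", cost = C, gamma = gamma,
    class.weights = cw, probability = TRUE, scale = FALSE
  ))
  list(learner = "svm", model = model)
}

unique_class_weights <- function(y, w) {
  cw <- tapply(w, factor(y, levels = c(0, 1)), function(v) v[1])
  cw[is.na(cw)] <- 1
  stats::setNames(as.numeric(cw), c("0", "1"))
}

# Discrete AdaBoost (SAMME) with depth-1 rpart stumps. Sample weights start
# at the class weights; the returned score is the alpha-weighted vote
# fraction for class 1, which serves as the ensemble probability.
fit_adaboost <- function(x, y, w, trees, lr, seed = 1L) {
  d <- as.data.frame(x)
  d$.y <- factor(y, levels = c(0, 1))
  wts <- w / sum(w)
  stumps <- list()
  alphas <- numeric(0)
  eps <- 1e-10
  with_seed(seed, {
    for (m in seq_len(trees)) {
      fit <- rpart::rpart(.y ~ ., data = d, weights = wts * nrow(d),
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 1, cp = -1, minsplit = 2,
                            minbucket = 1, xval = 0))
      pred <- as.integer(as.character(predict(fit, d, type = "class")))
      err <- sum(wts[pred != y])
      if (err >= 0.5) break       # weak learner no better than chance
      alpha <- lr * log((1 - err + eps) / (err + eps))
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      if (err <= eps) break       # perfect stump: stop boosting
      wts <- wts * exp(alpha * (pred != y))
      wts <- wts / sum(wts)
    }
  })
  if (length(stumps) == 0) {
    # degenerate: fall back to the weighted class prior
    prior <- sum(w[y == 1]) / sum(w)
    return(list(learner = "adb", stumps = list(), alphas = numeric(0),
                prior = prior))
  }
  list(learner = "adb", stumps = stumps, alphas = alphas, prior = NULL)
}

predict_adaboost <- function(fit, x) {
  if (length(fit$stumps) == 0) return(rep(fit$prior, nrow(x)))
  d <- as.data.frame(x)
  votes <- vapply(fit$stumps, function(s) {
    as.numeric(as.character(predict(s, d, type = "class")))
  }, numeric(nrow(d)))
  votes <- matrix(votes, nrow = nrow(d))
  as.numeric(votes %*% fit$alphas / sum(fit$alphas))
}

# inverse-class-frequency sample weights on scan counts
class_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  n <- length(y)
  w <- n / (2 * pmax(as.numeric(tab), 1))
  unname(w[y + 1])
}

# per-learner hyperparameter grids; intervals follow the tuning protocol
# (LR C in [1,100]; RF trees in [10,500], depth in [1,10]; SVM C, gamma in
# [1,100]; AdaBoost trees in [10,500], learning rate in [0.1,3]), ordered so
# the first max breaks ties toward the smaller model
default_grids <- function() {
  list(
    lr = tibble::tibble(C = c(1, 10, 100)),
    rf = tidyr::expand_grid(trees = c(10, 100, 500), depth = c(1, 3, 10)),
    svm = tidyr::expand_grid(C = c(1, 10, 100), gamma = c(1, 10, 100)),
    adb = tidyr::expand_grid(trees = c(10, 100, 500), lr = c(0.1, 1, 3))
  )
}

# minimal one-point grids, useful for calibration studies where
# hyperparameter search is irrelevant
minimal_grids <- function() {
  list(
    lr = tibble::tibble(C = 1),
    rf = tibble::tibble(trees = 100, depth = 3),
    svm = tibble::tibble(C = 1, gamma = 1),
    adb = tibble::tibble(trees = 50, lr = 1)
  )
}
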