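#' The six classifier configurations
#'
#' Constructs a classifier specification with the pipeline's fixed
#' hyperparameters:
#'
#' * `poly_svm` — support vector machine with a 3rd-order polynomial kernel;
#' * `rbf_svm` — SVM with a radial (Gaussian) kernel, `gamma = 1 /
#'   (n_features * var(X))`;
#' * `random_forest` — 1000 trees of depth 5;
#' * `knn` — 1 nearest neighbour;
#' * `elastic_net_logistic` — logistic regression with elastic-net penalty,
#'   mixing weight 0.98 on the L2 term (L2-dominant, i.e. near-ridge) and
#'   penalty strength `lambda = 1`;
#' * `dnn` — the in-package multilayer perceptron with hidden layers
#'   100, 150, 200, 150, 46, 20, 10 and one sigmoid output neuron.
#'
#' Unprinted hyperparameters keep the defaults listed here and can be
#' overridden through `...`.
#'
#' @param name Classifier family name.
#' @param ... Named hyperparameter overrides (e.g. `epochs`, `lambda`).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("poly_svm", "rbf_svm", "random_forest",
                                     "knn", "elastic_net_logistic", "dnn"),
                            ...) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(sprintf("unknown classifier name: %s", name[1]),
                                             class = "thetanav_config_error"))
  defaults <- switch(name,
    poly_svm = list(degree = 3, cost = 1),
    rbf_svm = list(cost = 1),
    random_forest = list(num_trees = 1000, max_depth = 5),
    knn = list(k = 1),
    elastic_net_logistic = list(l2_share = 0.98, lambda = 1),
    dnn = list(hidden = c(100, 150, 200, 150, 46, 20, 10), epochs = 200, lr = 1e-3))
  hp <- modifyList(defaults, list(...))
  structure(list(name = name, hyper = hp,
                 scale_sensitive = name != "random_forest"),
            class = "classifier_spec")
}

#' All six default classifier specifications
#' @return Named list of [classifier_spec()] objects.
#' @export
default_classifiers <- function() {
  names <- c("poly_svm", "rbf_svm", "random_forest", "knn",
             "elastic_net_logistic", "dnn")
  setNames(lapply(names, classifier_spec), names)
}

# orientation-safe decision values for class "1" from an e1071 svm
svm_score_1 <- function(model, X) {
  dv <- attr(predict(model, X, decision.values = TRUE), "decision.values")
  pair <- strsplit(colnames(dv), "/")[[1]]
  if (pair[1] == "1") as.numeric(dv) else -as.numeric(dv)
}

#' Train one classifier on a feature matrix
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix (standardised by the caller where the
#'   learner is scale-sensitive).
#' @param y Binary 0/1 labels.
#' @param seed Integer seed for stochastic learners.
#' @return A model object of class `thetanav_model` whose
#'   [score_classifier()] returns a continuous class-1 score.
#' @export
train_classifier <- function(spec, X, y, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  hp <- spec$hyper
  # inverse-frequency class weights: leave-one-out training folds are
  # unbalanced by one subject, which otherwise biases scores against the
  # held-out subject's class
  cw <- length(y) / (2 * c(`0` = sum(y == 0), `1` = sum(y == 1)))
  w <- unname(cw[as.character(y)])
  fit <- switch(spec$name,
    poly_svm = with_seed(seed,
      e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "polynomial",
                 degree = hp$degree, cost = hp$cost, scale = FALSE,
                 class.weights = cw)),
    rbf_svm = with_seed(seed,
      e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                 gamma = 1 / (ncol(X) * max(var(as.vector(X)), 1e-12)),
                 cost = hp$cost, scale = FALSE, class.weights = cw)),
    random_forest = ranger::ranger(
      y = factor(y, levels = c(0, 1)), x = as.data.frame(X),
      num.trees = hp$num_trees, max.depth = hp$max_depth,
      probability = TRUE, seed = seed, num.threads = 1,
      class.weights = unname(cw)),
    knn = list(train = X, cl = factor(y, levels = c(0, 1)), k = hp$k),
    elastic_net_logistic = withCallingHandlers(
      glmnet::glmnet(X, y, family = "binomial", alpha = 1 - hp$l2_share,
                     lambda = hp$lambda, weights = w),
      # small leave-one-out folds trip glmnet's small-class advisory
      warning = function(w_) {
        if (grepl("fewer than 8", conditionMessage(w_))) {
          invokeRestart("muffleWarning")
        }
      }),
    dnn = mlp_fit(X, y, hidden = hp$hidden, epochs = hp$epochs, lr = hp$lr,
                  seed = seed, weights = w))
  structure(list(name = spec$name, fit = fit, features = colnames(X)),
            class = "thetanav_model")
}

#' Continuous class-1 scores from a trained classifier
#'
#' SVMs return orientation-corrected signed margins, the random forest its
#' class-vote fraction, 1-NN the 0/1 nearest-neighbour vote, the penalised
#' logistic model and the MLP their predicted probabilities.
#'
#' @param model A `thetanav_model` from [train_classifier()].
#' @param X Feature matrix on the training scale.
#' @return Numeric score vector (higher = more learner-like).
#' @export
score_classifier <- function(model, X) {
  X <- as.matrix(X)
  switch(model$name,
    poly_svm = ,
    rbf_svm = svm_score_1(model$fit, X),
    random_forest = as.numeric(predict(model$fit, data = as.data.frame(X),
                                       num.threads = 1)$predictions[, "1"]),
    knn = as.numeric(class::knn(model$fit$train, X, model$fit$cl,
                                k = model$fit$k) == "1"),
    elastic_net_logistic = as.numeric(predict(model$fit, X, type = "response")),
    dnn = predict(model$fit, X))
}
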