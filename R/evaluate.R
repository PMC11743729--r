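#' Predict discrete grades for a feature table
#'
#' Generic prediction interface shared by belief rule bases and the
#' baseline classifier adapters, so that [compare_models()] can score any
#' mix of assessors on identical data.
#'
#' @param object A fitted assessor.
#' @param newdata Data frame of feature records.
#' @param ... Passed to methods.
#' @return Integer vector of grade indices in `1..N`.
#' @export
predict_grades <- function(object, newdata, ...) UseMethod("predict_grades")

#' @rdname predict_grades
#' @export
predict_grades.belief_rule_base <- function(object, newdata, ...) {
  brb_infer_matrix(dataset_features(newdata, object), object)$grade
}

#' Score an assessor on labelled records
#'
#' Runs the assessor on every record and reports the fraction of correctly
#' predicted grades, the mean squared error of the continuous output
#' against the true grades' utilities (for a belief rule base; baselines
#' are scored on their predicted grade's utility), and the full confusion
#' matrix.
#'
#' @param model An assessor with a [predict_grades()] method (for a
#'   `belief_rule_base` the utility MSE uses the model's continuous
#'   output).
#' @param data Labelled data frame (`grade` column required).
#' @param brb Reference rule base supplying grade labels and utilities when
#'   `model` is not itself a `belief_rule_base`.
#' @return An object of class `brb_evaluation`: `accuracy`, `mse`,
#'   `confusion` (true x predicted counts), `n_records`.
#' @export
evaluate_model <- function(model, data,
                           brb = if (inherits(model, "belief_rule_base"))
                             model else NULL) {
  if (!nrow(data)) stop("empty dataset", call. = FALSE)
  if (!"grade" %in% names(data))
    stop("dataset has no 'grade' column: evaluation needs labels",
         call. = FALSE)
  if (is.null(brb))
    stop("a reference rule base is needed to score a baseline assessor",
         call. = FALSE)
  N <- length(brb$grade_labels)
  if (inherits(model, "belief_rule_base")) {
    inf <- brb_infer_matrix(dataset_features(data, model), model)
    pred <- inf$grade
    yhat <- inf$utility
  } else {
    pred <- predict_grades(model, data)
    if (any(pred < 1L | pred > N))
      stop("assessor predicted a grade outside 1..N", call. = FALSE)
    yhat <- brb$grade_utilities[pred]
  }
  truth <- data$grade
  conf <- table(factor(truth, levels = seq_len(N), labels = brb$grade_labels),
                factor(pred, levels = seq_len(N), labels = brb$grade_labels),
                dnn = c("true", "predicted"))
  structure(list(accuracy = mean(pred == truth),
                 mse = mean((yhat - brb$grade_utilities[truth])^2),
                 confusion = unclass(conf),
                 n_records = nrow(data)),
            class = "brb_evaluation")
}

#' @export
print.brb_evaluation <- function(x, ...) {
  cat(sprintf("accuracy %.3f | utility MSE %.4f | n = %d\n",
              x$accuracy, x$mse, x$n_records))
  print(x$confusion)
  invisible(x)
}

#' Compare several assessors on identical labelled data
#'
#' @param models Named list of assessors (belief rule bases and/or
#'   [fit_baseline()] adapters).
#' @param data Labelled data frame.
#' @param brb Reference rule base for grade labels/utilities (defaults to
#'   the first `belief_rule_base` in `models`).
#' @return A data frame with one row per assessor (`model`, `accuracy`,
#'   `mse`, `n_records`); the individual `brb_evaluation` objects are
#'   attached as the `"reports"` attribute.
#' @export
compare_models <- function(models, data, brb = NULL) {
  if (!length(models) || is.null(names(models)) || any(!nzchar(names(models))))
    stop("'models' must be a non-empty named list", call. = FALSE)
  if (is.null(brb)) {
    is_brb <- vapply(models, inherits, logical(1), "belief_rule_base")
    if (any(is_brb)) brb <- models[[which(is_brb)[1L]]]
  }
  reports <- lapply(models, evaluate_model, data = data, brb = brb)
  out <- data.frame(model = names(models),
                    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
                    mse = vapply(reports, `[[`, numeric(1), "mse"),
                    n_records = vapply(reports, `[[`, integer(1), "n_records"),
                    row.names = NULL)
  attr(out, "reports") <- reports
  out
}

#' Fit an off-the-shelf baseline classifier as a comparison assessor
#'
#' Thin, seeded adapters around established implementations: a single
#' hidden-layer feed-forward network (`nnet`) and a support-vector
#' classifier with radial kernel (`e1071`), plus a trivial constant
#' predictor. Their internals are deliberately not re-implemented; they
#' exist only as comparison points for the rule-base model.
#'
#' @param type `"nnet"`, `"svm"` or `"constant"`.
#' @param data Labelled training data frame.
#' @param brb Reference rule base (defines the feature columns and grades).
#' @param seed Integer seed for the stochastic fits.
#' @param constant_grade Grade index predicted by the `"constant"` type.
#' @param ... Extra arguments passed to the underlying fit function
#'   (e.g. `size` for `nnet`, `cost`/`gamma` for `svm`).
#' @return An object of class `brb_baseline` with a [predict_grades()]
#'   method.
#' @export
fit_baseline <- function(type = c("nnet", "svm", "constant"), data, brb,
                         seed = 1L, constant_grade = 1L, ...) {
  type <- match.arg(type)
  N <- length(brb$grade_labels)
  fn <- brb_feature_names(brb)
  fit <- NULL
  if (type != "constant") {
    if (!"grade" %in% names(data))
      stop("baseline fitting needs labelled data", call. = FALSE)
    X <- dataset_features(data, brb)
    colnames(X) <- fn
    df <- data.frame(X, grade = factor(data$grade, levels = seq_len(N)))
    set.seed(as.integer(seed))
    fit <- switch(type,
      nnet = {
        if (!requireNamespace("nnet", quietly = TRUE))
          stop("package 'nnet' is required for the feed-forward baseline",
               call. = FALSE)
        nnet::nnet(grade ~ ., data = df, size = 8, decay = 1e-3,
                   maxit = 300, trace = FALSE, ...)
      },
      svm = {
        if (!requireNamespace("e1071", quietly = TRUE))
          stop("package 'e1071' is required for the support-vector baseline",
               call. = FALSE)
        e1071::svm(grade ~ ., data = df, kernel = "radial", ...)
      })
  }
  structure(list(type = type, fit = fit, feature_names = fn,
                 n_grades = N, constant_grade = as.integer(constant_grade),
                 seed = as.integer(seed)),
            class = "brb_baseline")
}

#' @rdname predict_grades
#' @export
predict_grades.brb_baseline <- function(object, newdata, ...) {
  if (object$type == "constant")
    return(rep(object$constant_grade, nrow(newdata)))
  X <- as.data.frame(newdata[object$feature_names])
  pred <- switch(object$type,
    nnet = nnet_predict_class(object$fit, X),
    svm = as.integer(as.character(stats::predict(object$fit, X))))
  as.integer(pred)
}

# nnet::predict.nnet(type = "class") drops factor levels never predicted;
# decode via the class index instead
nnet_predict_class <- function(fit, X) {
  p <- stats::predict(fit, X, type = "raw")
  if (is.null(dim(p))) return(ifelse(p > 0.5, 2L, 1L))
  as.integer(colnames(p)[max.col(p, ties.method = "first")])
}

#' Plot predicted against true grades
#'
#' A jittered scatter of predicted versus true grade for one or more
#' assessors on the same data, a compact visual analogue of the usual
#' assessment-result figures.
#'
#' @param data Labelled data frame.
#' @param models Named list of assessors.
#' @param brb Reference rule base (see [compare_models()]).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the list of predicted-grade vectors.
#' @export
plot_grade_predictions <- function(data, models, brb = NULL, ...) {
  if (is.null(brb)) {
    is_brb <- vapply(models, inherits, logical(1), "belief_rule_base")
    if (any(is_brb)) brb <- models[[which(is_brb)[1L]]]
  }
  N <- length(brb$grade_labels)
  preds <- lapply(models, function(m)
    if (inherits(m, "belief_rule_base"))
      predict_grades(m, data) else predict_grades(m, data))
  cols <- seq_along(models) + 1L
  graphics::plot(NA, xlim = c(0.5, N + 0.5), ylim = c(0.5, N + 0.5),
                 xlab = "true grade", ylab = "predicted grade",
                 xaxt = "n", yaxt = "n", ...)
  graphics::axis(1, at = seq_len(N), labels = brb$grade_labels)
  graphics::axis(2, at = seq_len(N), labels = brb$grade_labels)
  graphics::abline(0, 1, col = "grey60", lty = 2)
  for (i in seq_along(preds))
    graphics::points(jitter(data$grade, 0.6), jitter(preds[[i]], 0.6),
                     col = cols[i], pch = 16, cex = 0.5)
  graphics::legend("topleft", legend = names(models), col = cols,
                   pch = 16, bty = "n")
  invisible(preds)
}
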