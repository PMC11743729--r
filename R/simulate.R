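#' Configuration for the synthetic patient-record generator
#'
#' @param n_records Number of records to generate (default 2000, the size
#'   of the study design the generator emulates).
#' @param train_fraction Fraction of records earmarked for training when a
#'   split is requested (default 0.8: 1600 train / 400 test at n = 2000).
#' @param scheme Feature sampling scheme: `"uniform"` draws each attribute
#'   uniformly over its referential range; `"stratified"` rejection-samples
#'   features until the truth model assigns a target grade drawn from
#'   `grade_proportions`.
#' @param grade_proportions Target grade proportions for the stratified
#'   scheme (default uniform over the grades).
#' @param label_noise Probability in `[0, 1)` of replacing a record's label
#'   with a uniformly drawn *other* grade.
#' @param feature_noise Per-attribute Gaussian observation noise expressed
#'   as a fraction of each attribute's referential range (default 0.02);
#'   recycled over attributes. Noisy features are clamped back into range.
#' @param seed Integer seed; the whole generation is reproducible from it.
#' @param max_tries Retry budget per record for stratified rejection
#'   sampling.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_records = 2000L, train_fraction = 0.8,
                              scheme = c("uniform", "stratified"),
                              grade_proportions = NULL,
                              label_noise = 0, feature_noise = 0.02,
                              seed = 1L, max_tries = 10000L) {
  scheme <- match.arg(scheme)
  stopifnot(n_records >= 1L, train_fraction > 0, train_fraction < 1,
            label_noise >= 0, label_noise < 1, all(feature_noise >= 0),
            max_tries >= 1L)
  structure(list(n_records = as.integer(n_records),
                 train_fraction = train_fraction, scheme = scheme,
                 grade_proportions = grade_proportions,
                 label_noise = label_noise, feature_noise = feature_noise,
                 seed = as.integer(seed), max_tries = as.integer(max_tries)),
            class = "simulation_config")
}

#' Simulate labelled patient records from a ground-truth rule base
#'
#' Draws feature vectors (per the configured scheme), labels each record
#' with the truth model's discrete grade, optionally corrupts labels
#' (uniform flips) and features (Gaussian observation noise, clamped back
#' to the referential range). Labels are assigned before observation noise
#' is added, emulating a clinician grading the true state while the robot's
#' sensors record a noisy measurement.
#'
#' @param truth A `belief_rule_base` acting as the data-generating model;
#'   defaults to the bundled trained reference model.
#' @param cfg A [simulation_config()].
#' @return A data frame with the lower-cased attribute names as feature
#'   columns plus an integer `grade` column.
#' @export
simulate_dataset <- function(truth = brb_trained_reference(),
                             cfg = simulation_config()) {
  stopifnot(inherits(truth, "belief_rule_base"),
            inherits(cfg, "simulation_config"))
  validate_brb(truth)
  N <- length(truth$grade_labels)
  rng <- brb_ranges(truth)
  n <- cfg$n_records
  set.seed(cfg$seed)

  if (cfg$scheme == "uniform") {
    X <- sapply(seq_along(truth$attributes), function(i)
      stats::runif(n, rng[1L, i], rng[2L, i]))
    X <- matrix(X, nrow = n)
    grade <- brb_infer_matrix(X, truth)$grade
  } else {
    props <- cfg$grade_proportions
    if (is.null(props)) props <- rep(1 / N, N)
    if (length(props) != N || any(props < 0) || sum(props) <= 0)
      stop("grade_proportions must be N nonnegative values", call. = FALSE)
    props <- props / sum(props)
    target <- sample.int(N, n, replace = TRUE, prob = props)
    X <- matrix(NA_real_, n, length(truth$attributes))
    grade <- integer(n)
    pending <- seq_len(n)
    tries <- 0L
    while (length(pending)) {
      tries <- tries + 1L
      if (tries > cfg$max_tries) {
        missing <- sort(unique(target[pending]))
        stop(sprintf(
          "stratified sampling retry budget exhausted; grade(s) %s unreachable under the truth model",
          paste(truth$grade_labels[missing], collapse = ", ")),
          call. = FALSE)
      }
      cand <- sapply(seq_along(truth$attributes), function(i)
        stats::runif(length(pending), rng[1L, i], rng[2L, i]))
      cand <- matrix(cand, nrow = length(pending))
      g <- brb_infer_matrix(cand, truth)$grade
      hit <- g == target[pending]
      if (any(hit)) {
        rows <- pending[hit]
        X[rows, ] <- cand[hit, , drop = FALSE]
        grade[rows] <- g[hit]
        pending <- pending[!hit]
      }
    }
  }

  if (cfg$label_noise > 0) {
    flip <- stats::runif(n) < cfg$label_noise
    if (any(flip)) {
      shift <- sample.int(N - 1L, sum(flip), replace = TRUE)
      grade[flip] <- 1L + (grade[flip] - 1L + shift) %% N
    }
  }

  sds <- rep_len(cfg$feature_noise, ncol(X)) * (rng[2L, ] - rng[1L, ])
  for (i in seq_len(ncol(X))) {
    if (sds[i] > 0)
      X[, i] <- pmin(pmax(X[, i] + stats::rnorm(n, 0, sds[i]), rng[1L, i]),
                     rng[2L, i])
  }

  out <- as.data.frame(X)
  names(out) <- brb_feature_names(truth)
  out$grade <- grade
  out
}

#' Split a dataset into disjoint train and test parts
#'
#' Shuffled partition: `floor(train_fraction * T)` records go to the
#' training set, the remainder to the test set.
#'
#' @param data Data frame of records.
#' @param train_fraction Fraction in `(0, 1)`.
#' @param seed Integer seed for the shuffle.
#' @return A list with data frames `train` and `test`.
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  Tn <- nrow(data)
  n_train <- floor(train_fraction * Tn)
  if (n_train < 1L || n_train >= Tn)
    stop("split would leave an empty train or test partition", call. = FALSE)
  set.seed(as.integer(seed))
  idx <- sample.int(Tn)
  list(train = data[idx[seq_len(n_train)], , drop = FALSE],
       test = data[idx[(n_train + 1L):Tn], , drop = FALSE])
}

#' Randomly perturb a rule base's trainable parameters
#'
#' Adds independent uniform jitter of `±magnitude` to every belief degree,
#' rule weight and attribute weight, then projects back to the feasible set
#' (boxes plus per-rule belief sums at most 1). Magnitude 0 is the
#' identity. Useful for building imperfect "expert" initialisations in
#' parameter-recovery experiments.
#'
#' @param truth A `belief_rule_base`.
#' @param magnitude Nonnegative jitter half-width.
#' @param seed Integer seed.
#' @return A feasible `belief_rule_base`.
#' @export
perturb_rulebase <- function(truth, magnitude = 0.2, seed = 1L) {
  stopifnot(inherits(truth, "belief_rule_base"), magnitude >= 0)
  if (magnitude == 0) return(truth)
  set.seed(as.integer(seed))
  p <- pack_parameters(truth)
  p <- p + stats::runif(length(p), -magnitude, magnitude)
  repair_rulebase(unpack_parameters(p, truth, validate = FALSE))
}
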