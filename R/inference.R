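#' Matching degrees of an input against each attribute's referential values
#'
#' For an input value lying between two adjacent referential values the
#' belief is split between them by linear interpolation: with
#' `A_l <= x <= A_{l+1}` the degree at `A_l` is
#' `(A_{l+1} - x) / (A_{l+1} - A_l)`, the degree at `A_{l+1}` is its
#' complement, and all other referential values get 0. Inputs outside the
#' referential range are clamped to the nearest boundary value (degree 1
#' there), which preserves the per-attribute sum-to-1 invariant.
#'
#' @param x Numeric vector of attribute values, one per attribute.
#' @param attributes List of [attribute_spec()] objects, same length as `x`.
#' @return An object of class `matching_profile`: a list with one named
#'   numeric vector of matching degrees per attribute. Each vector sums
#'   to 1 and has at most two consecutive nonzero entries.
#' @examples
#' a <- attribute_spec("ARTUL", c("S", "N", "B"), c(4, 8, 12))
#' compute_matching_degrees(6, list(a))
#' @export
compute_matching_degrees <- function(x, attributes) {
  x <- as.numeric(x)
  if (length(x) != length(attributes))
    stop(sprintf("expected %d attribute values, got %d",
                 length(attributes), length(x)), call. = FALSE)
  if (any(!is.finite(x)))
    stop("attribute values must be finite", call. = FALSE)
  out <- lapply(seq_along(x), function(i) {
    a <- attributes[[i]]
    d <- matching_one(x[i], a$ref_values)
    names(d) <- a$labels
    d
  })
  names(out) <- vapply(attributes, `[[`, character(1), "name")
  structure(out, class = "matching_profile")
}

# internal scalar matching against one referential grid, with clamping
matching_one <- function(xi, refs) {
  J <- length(refs)
  xi <- min(max(xi, refs[1L]), refs[J])
  l <- findInterval(xi, refs, all.inside = TRUE)
  d <- numeric(J)
  d[l] <- (refs[l + 1L] - xi) / (refs[l + 1L] - refs[l])
  d[l + 1L] <- 1 - d[l]
  d
}

#' @export
print.matching_profile <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%s: %s\n", nm,
                paste(sprintf("%s=%.4g", names(x[[nm]]), x[[nm]]),
                      collapse = " ")))
  invisible(x)
}

#' Rule activation weights from a matching profile
#'
#' Rule `k`'s activation weight combines its rule weight with the product of
#' its antecedents' matching degrees raised to normalised attribute weights:
#' `w_k = theta_k * prod_i a_i(k)^dbar_i`, normalised to sum to 1 over all
#' rules, with `dbar_i = delta_i / max_j delta_j`. A rule whose antecedent
#' does not match the input at all (some matching degree 0) gets weight 0
#' regardless of its attribute weights.
#'
#' @param m A `matching_profile` from [compute_matching_degrees()].
#' @param brb A `belief_rule_base`.
#' @return Numeric vector of `L` activation weights summing to 1, of class
#'   `activation_profile`.
#' @export
compute_activation_weights <- function(m, brb) {
  stopifnot(inherits(m, "matching_profile"),
            inherits(brb, "belief_rule_base"))
  if (length(m) != length(brb$attributes))
    stop("matching profile does not match the rule base's attributes",
         call. = FALSE)
  dbar <- brb$attribute_weights / max(brb$attribute_weights)
  w <- brb$theta
  for (i in seq_along(m))
    w <- w * m[[i]][brb$antecedents[, i]] ^ dbar[i]
  tot <- sum(w)
  if (tot <= 0)
    stop("no rule activated: all rule activation numerators are zero",
         call. = FALSE)
  structure(unname(w / tot), class = "activation_profile")
}

#' Analytic evidential-reasoning aggregation of activated rules
#'
#' Combines the consequent belief distributions of all activated rules into
#' one belief distribution using the analytic form of the evidential
#' reasoning (ER) rule. With activation weights `w_k`, rule beliefs
#' `beta[k, j]` and per-rule total assigned mass `s_k = sum_j beta[k, j]`:
#'
#' \deqn{\hat\beta_j = \frac{\mu[\prod_k(w_k\beta_{j,k} + 1 - w_k s_k)
#'   - \prod_k(1 - w_k s_k)]}{1 - \mu\prod_k(1 - w_k)}}
#'
#' where `1/mu = sum_j prod_k(w_k beta[k,j] + 1 - w_k s_k) -
#' (N - 1) prod_k(1 - w_k s_k)` and `N` is the number of grades. When every
#' activated rule is complete (`s_k = 1`) the output sums to 1; incomplete
#' rules leave residual unassigned mass.
#'
#' @param w Activation weights summing to 1 (an `activation_profile` or a
#'   plain numeric vector).
#' @param brb A `belief_rule_base` supplying the rule beliefs.
#' @return Numeric vector of `N` aggregated belief degrees, named by grade.
#' @export
aggregate_er <- function(w, brb) {
  stopifnot(inherits(brb, "belief_rule_base"))
  w <- as.numeric(w)
  B <- brb$beliefs
  if (length(w) != nrow(B))
    stop("need one activation weight per rule", call. = FALSE)
  if (any(w < -1e-12 | w > 1 + 1e-12) || abs(sum(w) - 1) > 1e-9)
    stop("activation weights must lie in [0, 1] and sum to 1", call. = FALSE)
  out <- er_analytic(w, B)
  names(out) <- brb$grade_labels
  out
}

# internal: analytic ER combination of L weighted belief rows (L x N);
# pure math, shared by aggregate_er and exercised directly by the
# oracle-equivalence tests
er_analytic <- function(w, B) {
  N <- ncol(B)
  s <- rowSums(B)
  t1 <- vapply(seq_len(N), function(j) prod(w * B[, j] + 1 - w * s),
               numeric(1))
  t2 <- prod(1 - w * s)
  t3 <- prod(1 - w)
  mu_inv <- sum(t1) - (N - 1) * t2
  denom <- mu_inv - t3
  if (!is.finite(denom) || denom <= 1e-12)
    stop("degenerate evidential-reasoning combination (zero denominator)",
         call. = FALSE)
  pmin(pmax((t1 - t2) / denom, 0), 1)
}

#' Expected utility of a belief distribution
#'
#' The belief-weighted sum of the grade utilities,
#' `sum_j u(D_j) * beta_j`. By default the residual unassigned mass of an
#' incomplete distribution contributes nothing (the literal expected-utility
#' reading); `renormalize = TRUE` divides the beliefs by their sum first.
#'
#' @param beliefs Numeric vector of belief degrees over the grades.
#' @param brb A `belief_rule_base` supplying the grade utilities.
#' @param renormalize Divide by the total belief mass before scoring.
#' @return A single numeric utility in `[u(D_1), u(D_N)]` (for complete or
#'   renormalised beliefs).
#' @export
expected_utility <- function(beliefs, brb, renormalize = FALSE) {
  stopifnot(inherits(brb, "belief_rule_base"))
  beliefs <- as.numeric(beliefs)
  u <- brb$grade_utilities
  if (length(beliefs) != length(u))
    stop("belief vector length must equal the number of grades",
         call. = FALSE)
  if (renormalize) {
    tot <- sum(beliefs)
    if (tot <= 0) stop("cannot renormalize a zero belief mass", call. = FALSE)
    beliefs <- beliefs / tot
  }
  sum(u * beliefs)
}

#' Map a continuous utility to a discrete grade
#'
#' Nearest-utility rule: returns the grade whose utility is closest to the
#' input, breaking ties toward the lower (healthier) grade. Small numerical
#' overshoot beyond the utility range is clamped.
#'
#' @param utility Numeric vector of utilities.
#' @param brb A `belief_rule_base`.
#' @return Integer vector of grade indices in `1..N`.
#' @export
classify_grade <- function(utility, brb) {
  stopifnot(inherits(brb, "belief_rule_base"))
  u <- brb$grade_utilities
  utility <- pmin(pmax(as.numeric(utility), u[1L]), u[length(u)])
  # nearest utility == interval of the midpoints; left-open intervals put a
  # utility sitting exactly on a midpoint into the lower grade
  mids <- (u[-length(u)] + u[-1L]) / 2
  1L + findInterval(utility, mids, left.open = TRUE)
}

#' Assess one patient record with a belief rule base
#'
#' Runs the full inference pass: matching degrees of the input against each
#' attribute's referential values, rule activation weights, evidential
#' reasoning aggregation, expected utility, and discrete grade.
#'
#' @param x Numeric vector of attribute values (ARTUL, RTT, MAMS in the
#'   bundled models), one per attribute, in attribute units.
#' @param brb A `belief_rule_base`.
#' @param renormalize Renormalise an incomplete aggregated belief before
#'   computing the utility (default `FALSE`: residual mass scores zero).
#' @return An object of class `brb_assessment`: a list with `beliefs`
#'   (aggregated belief distribution, named by grade), `utility`, `grade`
#'   (index), `grade_label`, `activation` (per-rule activation weights) and
#'   `matching` (the matching profile).
#' @examples
#' brb <- brb_expert_initial()
#' assess(c(4, 5, 5), brb)
#' @export
assess <- function(x, brb, renormalize = FALSE) {
  stopifnot(inherits(brb, "belief_rule_base"))
  m <- compute_matching_degrees(x, brb$attributes)
  w <- compute_activation_weights(m, brb)
  b <- aggregate_er(w, brb)
  y <- expected_utility(b, brb, renormalize = renormalize)
  g <- classify_grade(y, brb)
  structure(list(beliefs = b, utility = y, grade = g,
                 grade_label = brb$grade_labels[g],
                 activation = w, matching = m),
            class = "brb_assessment")
}

#' @export
print.brb_assessment <- function(x, ...) {
  cat(sprintf("Grade %s (utility %.4f)\n", x$grade_label, x$utility))
  cat("beliefs:",
      paste(sprintf("%s=%.4f", names(x$beliefs), x$beliefs), collapse = " "),
      "\n")
  invisible(x)
}

#' Assess many records at once
#'
#' Vectorised inference over a feature table; equivalent to calling
#' [assess()] row by row but computed with matrix operations (this is the
#' hot path of training, where the model is re-evaluated on the full
#' training set at every objective evaluation).
#'
#' @param data Data frame or matrix whose first columns (or the columns
#'   named after the rule base's attributes, lower-cased) hold the feature
#'   values.
#' @param brb A `belief_rule_base`.
#' @param renormalize As in [assess()].
#' @return A data frame with one row per record: the aggregated belief per
#'   grade (`beta_*` columns), `utility` and `grade`.
#' @export
assess_dataset <- function(data, brb, renormalize = FALSE) {
  X <- dataset_features(data, brb)
  inf <- brb_infer_matrix(X, brb, renormalize = renormalize)
  out <- as.data.frame(inf$beliefs)
  names(out) <- paste0("beta_", brb$grade_labels)
  out$utility <- inf$utility
  out$grade <- inf$grade
  out
}

# internal: extract the T x M feature matrix from a data frame / matrix,
# preferring columns named after the attributes
dataset_features <- function(data, brb) {
  fn <- brb_feature_names(brb)
  if (is.data.frame(data)) {
    if (all(fn %in% names(data))) {
      X <- as.matrix(data[fn])
    } else {
      keep <- setdiff(names(data), "grade")
      if (length(keep) != length(fn))
        stop(sprintf("expected feature columns %s",
                     paste(fn, collapse = ", ")), call. = FALSE)
      X <- as.matrix(data[keep])
    }
  } else {
    X <- as.matrix(data)
    if (ncol(X) != length(fn))
      stop("feature matrix has the wrong number of columns", call. = FALSE)
  }
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("feature values must be finite numbers", call. = FALSE)
  X
}

# internal: per-attribute matching matrices (T x J_i) for a feature matrix;
# these depend only on the data and referential values, never on the
# trainable parameters, so training precomputes them once
matching_matrices <- function(X, brb) {
  Tn <- nrow(X)
  lapply(seq_along(brb$attributes), function(i) {
    refs <- brb$attributes[[i]]$ref_values
    J <- length(refs)
    xi <- pmin(pmax(X[, i], refs[1L]), refs[J])
    l <- findInterval(xi, refs, all.inside = TRUE)
    lo <- (refs[l + 1L] - xi) / (refs[l + 1L] - refs[l])
    Mi <- matrix(0, Tn, J)
    Mi[cbind(seq_len(Tn), l)] <- lo
    Mi[cbind(seq_len(Tn), l + 1L)] <- Mi[cbind(seq_len(Tn), l + 1L)] + 1 - lo
    Mi
  })
}

# internal: compiled forward pass over a whole dataset -> output utilities;
# mirrors brb_infer_matrix (cross-checked in the tests)
brb_utilities_fast <- function(mm, brb) {
  dbar <- brb$attribute_weights / max(brb$attribute_weights)
  cpp_brb_utilities(mm, brb$antecedents, brb$theta, dbar, brb$beliefs,
                    brb$grade_utilities)
}

# internal vectorised inference core: X is T x M, returns list with
# T x N belief matrix, utility vector and grade vector
brb_infer_matrix <- function(X, brb, renormalize = FALSE) {
  dims <- brb_dims(brb)
  Tn <- nrow(X)
  B <- brb$beliefs
  dbar <- brb$attribute_weights / max(brb$attribute_weights)

  # per-attribute matching matrices, raised to normalised attribute weights
  act <- matrix(brb$theta, Tn, dims["L"], byrow = TRUE)
  for (i in seq_len(dims["M"])) {
    refs <- brb$attributes[[i]]$ref_values
    J <- length(refs)
    xi <- pmin(pmax(X[, i], refs[1L]), refs[J])
    l <- findInterval(xi, refs, all.inside = TRUE)
    lo <- (refs[l + 1L] - xi) / (refs[l + 1L] - refs[l])
    Mi <- matrix(0, Tn, J)
    Mi[cbind(seq_len(Tn), l)] <- lo
    Mi[cbind(seq_len(Tn), l + 1L)] <- Mi[cbind(seq_len(Tn), l + 1L)] + 1 - lo
    if (dbar[i] != 1) Mi <- Mi ^ dbar[i]
    act <- act * Mi[, brb$antecedents[, i], drop = FALSE]
  }
  tot <- rowSums(act)
  if (any(tot <= 0))
    stop(sprintf("no rule activated for record %s", which(tot <= 0)[1L]),
         call. = FALSE)
  W <- act / tot

  # analytic ER aggregation, vectorised over records
  s <- rowSums(B)
  N <- dims[["N"]]
  t1 <- matrix(1, Tn, N)
  t2 <- rep(1, Tn)
  t3 <- rep(1, Tn)
  for (k in seq_len(dims["L"])) {
    wk <- W[, k]
    base <- 1 - wk * s[k]
    for (j in seq_len(N)) t1[, j] <- t1[, j] * (wk * B[k, j] + base)
    t2 <- t2 * base
    t3 <- t3 * (1 - wk)
  }
  denom <- rowSums(t1) - (N - 1) * t2 - t3
  if (any(!is.finite(denom) | denom <= 1e-12))
    stop("degenerate evidential-reasoning combination (zero denominator)",
         call. = FALSE)
  bel <- (t1 - t2) / denom
  bel[bel < 0] <- 0
  bel[bel > 1] <- 1
  mass <- if (renormalize) rowSums(bel) else 1
  utility <- as.numeric(bel %*% brb$grade_utilities) / mass
  list(beliefs = bel, utility = utility,
       grade = classify_grade(utility, brb))
}
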