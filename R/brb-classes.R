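#' Define an antecedent attribute with its referential values
#'
#' An attribute is matched against a small ordered set of referential
#' (anchor) values, each carrying a semantic label such as "Small" /
#' "Normal" / "Big". Inputs falling between two adjacent referential values
#' are matched to both by linear interpolation.
#'
#' @param name Short identifier, e.g. `"ARTUL"`.
#' @param labels Character vector of semantic labels, one per referential
#'   value, e.g. `c("S", "N", "B")`.
#' @param ref_values Strictly increasing numeric vector of quantised
#'   referential values, in the attribute's own units.
#' @return An object of class `attribute_spec`.
#' @examples
#' attribute_spec("ARTUL", c("S", "N", "B"), c(4, 8, 12))
#' @export
attribute_spec <- function(name, labels, ref_values) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  labels <- as.character(labels)
  ref_values <- as.numeric(ref_values)
  if (length(labels) != length(ref_values))
    stop("'labels' and 'ref_values' must have equal length", call. = FALSE)
  if (length(ref_values) < 2L)
    stop("an attribute needs at least 2 referential values", call. = FALSE)
  if (!all(is.finite(ref_values)))
    stop("referential values must be finite", call. = FALSE)
  if (any(diff(ref_values) <= 0))
    stop("referential values must be strictly increasing", call. = FALSE)
  if (anyDuplicated(labels))
    stop("referential-value labels must be unique within an attribute",
         call. = FALSE)
  structure(list(name = name, labels = labels, ref_values = ref_values),
            class = "attribute_spec")
}

#' @export
print.attribute_spec <- function(x, ...) {
  cat(sprintf("<attribute %s> %s\n", x$name,
              paste(sprintf("%s=%g", x$labels, x$ref_values), collapse = ", ")))
  invisible(x)
}

#' Construct a belief rule base
#'
#' A belief rule base (BRB) is a set of IF-THEN rules whose antecedents
#' refer to referential values of the input attributes and whose consequent
#' is a belief distribution over ordered outcome grades. Each rule carries a
#' rule weight `theta` in `[0, 1]`; each attribute carries a weight `delta`
#' in `[0, 1]`. Grade utilities give every grade a numeric score; the
#' model's continuous output is the belief-weighted expected utility.
#'
#' The rule list is stored in matrix form: `antecedents` holds one
#' referential-value index per attribute per rule, and `beliefs` one row of
#' belief degrees per rule. Rules must cover the full antecedent grid (one
#' rule per combination of referential values, no duplicates); with three
#' attributes of three referential values each this gives 27 rules.
#'
#' @param attributes List of [attribute_spec()] objects (length `M`).
#' @param antecedents Integer matrix `L x M`; entry `[k, i]` is the index of
#'   attribute `i`'s referential value used by rule `k`.
#' @param theta Numeric vector of `L` rule weights in `[0, 1]`.
#' @param beliefs Numeric matrix `L x N` of consequent belief degrees
#'   `beta[k, j]`; each row has entries in `[0, 1]` summing to at most 1
#'   (rows summing to less than 1 are "incomplete" rules).
#' @param attribute_weights Numeric vector of `M` attribute weights in
#'   `[0, 1]`. Default: all 1.
#' @param grade_labels Character vector of `N` grade names, ordered from
#'   best to worst health state. Default `c("I","II","III","IV")`.
#' @param grade_utilities Strictly increasing numeric vector of `N` grade
#'   utilities. Default `1:N`.
#' @param note Optional free-text provenance note carried through
#'   serialisation.
#' @return An object of class `belief_rule_base`.
#' @seealso [brb_full_grid()] to build the antecedent grid in canonical
#'   order, [assess()] for inference, [train_brb()] for parameter learning.
#' @export
belief_rule_base <- function(attributes, antecedents, theta, beliefs,
                             attribute_weights = rep(1, length(attributes)),
                             grade_labels = c("I", "II", "III", "IV"),
                             grade_utilities = seq_along(grade_labels),
                             note = NULL) {
  if (!is.list(attributes) || !length(attributes) ||
      !all(vapply(attributes, inherits, logical(1), "attribute_spec")))
    stop("'attributes' must be a non-empty list of attribute_spec objects",
         call. = FALSE)
  antecedents <- as.matrix(antecedents)
  storage.mode(antecedents) <- "integer"
  beliefs <- as.matrix(beliefs)
  brb <- structure(list(
    attributes = attributes,
    antecedents = antecedents,
    theta = as.numeric(theta),
    beliefs = beliefs,
    attribute_weights = as.numeric(attribute_weights),
    grade_labels = as.character(grade_labels),
    grade_utilities = as.numeric(grade_utilities),
    note = if (is.null(note)) NULL else as.character(note)[1L]
  ), class = "belief_rule_base")
  validate_brb(brb)
}

#' Validate a belief rule base
#'
#' Checks every structural invariant: dimensions, antecedent index ranges,
#' full-grid coverage without duplicates, box constraints on all weights and
#' beliefs, per-rule belief sums at most 1 (tolerance 1e-9), and strictly
#' increasing grade utilities.
#'
#' @param brb A `belief_rule_base`.
#' @param tol Absolute tolerance on belief sums.
#' @return `brb`, invisibly usable, after passing all checks; otherwise an
#'   error naming the violated invariant and the offending rule.
#' @export
validate_brb <- function(brb, tol = 1e-9) {
  M <- length(brb$attributes)
  L <- nrow(brb$antecedents)
  N <- length(brb$grade_labels)
  sizes <- vapply(brb$attributes, function(a) length(a$ref_values), integer(1))
  if (ncol(brb$antecedents) != M)
    stop("antecedent matrix must have one column per attribute", call. = FALSE)
  if (length(brb$theta) != L)
    stop("need one rule weight per rule", call. = FALSE)
  if (!all(dim(brb$beliefs) == c(L, N)))
    stop("belief matrix must be n_rules x n_grades", call. = FALSE)
  if (length(brb$attribute_weights) != M)
    stop("need one attribute weight per attribute", call. = FALSE)
  if (length(brb$grade_utilities) != N)
    stop("need one utility per grade", call. = FALSE)
  for (i in seq_len(M)) {
    idx <- brb$antecedents[, i]
    if (any(idx < 1L | idx > sizes[i]))
      stop(sprintf("rule antecedent index out of range for attribute '%s'",
                   brb$attributes[[i]]$name), call. = FALSE)
  }
  if (L != prod(sizes))
    stop(sprintf("expected the full antecedent grid of %d rules, got %d",
                 prod(sizes), L), call. = FALSE)
  key <- apply(brb$antecedents, 1L, paste, collapse = ",")
  if (anyDuplicated(key))
    stop(sprintf("duplicate rule antecedent: (%s)", key[anyDuplicated(key)]),
         call. = FALSE)
  if (any(!is.finite(brb$theta)) || any(brb$theta < 0 | brb$theta > 1))
    stop("rule weights theta must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(brb$attribute_weights)) ||
      any(brb$attribute_weights < 0 | brb$attribute_weights > 1))
    stop("attribute weights delta must lie in [0, 1]", call. = FALSE)
  if (max(brb$attribute_weights) <= 0)
    stop("at least one attribute weight must be positive", call. = FALSE)
  if (any(!is.finite(brb$beliefs)) ||
      any(brb$beliefs < -tol | brb$beliefs > 1 + tol))
    stop("belief degrees must lie in [0, 1]", call. = FALSE)
  bad <- which(rowSums(brb$beliefs) > 1 + tol)
  if (length(bad))
    stop(sprintf("rule %d: belief degrees sum to %.6f > 1",
                 bad[1L], sum(brb$beliefs[bad[1L], ])), call. = FALSE)
  if (any(diff(brb$grade_utilities) <= 0))
    stop("grade utilities must be strictly increasing", call. = FALSE)
  brb
}

#' Build a full-grid belief rule base in canonical rule order
#'
#' Enumerates one rule per combination of referential values, with the last
#' attribute varying fastest (the order in which expert rule tables are
#' conventionally printed: `(S,S,S), (S,S,N), (S,S,H), (S,N,S), ...`).
#'
#' @inheritParams belief_rule_base
#' @param beliefs `L x N` belief matrix with rows in canonical grid order,
#'   where `L` is the product of the attributes' referential-value counts.
#' @param theta Rule weights; a single value is recycled. Default 1.
#' @return A `belief_rule_base`.
#' @export
brb_full_grid <- function(attributes, beliefs,
                          theta = 1,
                          attribute_weights = rep(1, length(attributes)),
                          grade_labels = c("I", "II", "III", "IV"),
                          grade_utilities = seq_along(grade_labels),
                          note = NULL) {
  sizes <- vapply(attributes, function(a) length(a$ref_values), integer(1))
  grid <- as.matrix(rev(expand.grid(rev(lapply(sizes, seq_len)))))
  dimnames(grid) <- NULL
  L <- nrow(grid)
  theta <- rep_len(as.numeric(theta), L)
  belief_rule_base(attributes, grid, theta, beliefs,
                   attribute_weights = attribute_weights,
                   grade_labels = grade_labels,
                   grade_utilities = grade_utilities, note = note)
}

#' Tabulate the rules of a belief rule base
#'
#' @param brb A `belief_rule_base`.
#' @return A data frame with one row per rule: the antecedent referential
#'   labels, the rule weight and the consequent belief degrees.
#' @export
brb_rules <- function(brb) {
  stopifnot(inherits(brb, "belief_rule_base"))
  ante <- vapply(seq_along(brb$attributes), function(i) {
    brb$attributes[[i]]$labels[brb$antecedents[, i]]
  }, character(nrow(brb$antecedents)))
  ante <- as.data.frame(ante, stringsAsFactors = FALSE)
  names(ante) <- vapply(brb$attributes, `[[`, character(1), "name")
  bel <- as.data.frame(brb$beliefs)
  names(bel) <- paste0("beta_", brb$grade_labels)
  cbind(rule = seq_len(nrow(ante)), ante, theta = brb$theta, bel)
}

#' @export
print.belief_rule_base <- function(x, ...) {
  cat(sprintf("Belief rule base: %d attributes, %d rules, %d grades\n",
              length(x$attributes), nrow(x$antecedents),
              length(x$grade_labels)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  for (a in x$attributes) {
    cat("  ")
    print(a)
  }
  cat("  attribute weights:",
      paste(format(x$attribute_weights), collapse = ", "), "\n")
  cat("  grades:",
      paste(sprintf("%s (u=%g)", x$grade_labels, x$grade_utilities),
            collapse = ", "), "\n")
  invisible(x)
}

# internal: number of attributes / rules / grades
brb_dims <- function(brb) {
  c(M = length(brb$attributes),
    L = nrow(brb$antecedents),
    N = length(brb$grade_labels))
}

# internal: feature range matrix (2 x M: low, high)
brb_ranges <- function(brb) {
  vapply(brb$attributes, function(a) range(a$ref_values), numeric(2))
}

# internal: lower-cased attribute names, the canonical dataset column names
brb_feature_names <- function(brb) {
  tolower(vapply(brb$attributes, `[[`, character(1), "name"))
}
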