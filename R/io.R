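#' Read a belief rule base from a JSON document
#'
#' The document has sections `attributes` (name, labels, ref_values),
#' `attribute_weights`, `grade_labels`, `grade_utilities` and `rules`; each
#' rule gives its antecedent as semantic referential labels (human-readable
#' against printed rule tables), its weight `theta` and its consequent
#' `beliefs`. Every structural invariant is re-validated at load; unknown
#' fields are rejected.
#'
#' @param path Path to a rule-base JSON file.
#' @return A validated `belief_rule_base`.
#' @seealso [write_rulebase()], [brb_expert_initial()], [brb_trained_reference()]
#' @export
read_rulebase <- function(path) {
  if (!file.exists(path))
    stop(sprintf("rule-base file not found: %s", path), call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  allowed <- c("schema_version", "note", "attributes", "attribute_weights",
               "grade_labels", "grade_utilities", "rules")
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown))
    stop(sprintf("unknown rule-base document field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  required <- setdiff(allowed, c("note", "schema_version"))
  missing <- setdiff(required, names(doc))
  if (length(missing))
    stop(sprintf("rule-base document is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  attrs <- lapply(doc$attributes, function(a) {
    extra <- setdiff(names(a), c("name", "labels", "ref_values"))
    if (length(extra))
      stop(sprintf("unknown attribute field(s): %s",
                   paste(extra, collapse = ", ")), call. = FALSE)
    attribute_spec(a$name, unlist(a$labels), unlist(a$ref_values))
  })

  L <- length(doc$rules)
  M <- length(attrs)
  N <- length(doc$grade_labels)
  ante <- matrix(NA_integer_, L, M)
  theta <- numeric(L)
  beliefs <- matrix(NA_real_, L, N)
  for (k in seq_len(L)) {
    r <- doc$rules[[k]]
    extra <- setdiff(names(r), c("antecedent", "theta", "beliefs"))
    if (length(extra))
      stop(sprintf("rule %d: unknown field(s): %s", k,
                   paste(extra, collapse = ", ")), call. = FALSE)
    lab <- unlist(r$antecedent)
    if (length(lab) != M)
      stop(sprintf("rule %d: expected %d antecedent labels", k, M),
           call. = FALSE)
    for (i in seq_len(M)) {
      j <- match(lab[i], attrs[[i]]$labels)
      if (is.na(j))
        stop(sprintf("rule %d: label '%s' is not a referential value of %s",
                     k, lab[i], attrs[[i]]$name), call. = FALSE)
      ante[k, i] <- j
    }
    theta[k] <- as.numeric(r$theta)
    b <- as.numeric(unlist(r$beliefs))
    if (length(b) != N)
      stop(sprintf("rule %d: expected %d belief degrees, got %d",
                   k, N, length(b)), call. = FALSE)
    if (sum(b) > 1 + 1e-9)
      stop(sprintf("rule %d: belief degrees sum to %.6f > 1", k, sum(b)),
           call. = FALSE)
    beliefs[k, ] <- b
  }
  belief_rule_base(attrs, ante, theta, beliefs,
                   attribute_weights = as.numeric(unlist(doc$attribute_weights)),
                   grade_labels = unlist(doc$grade_labels),
                   grade_utilities = as.numeric(unlist(doc$grade_utilities)),
                   note = doc$note)
}

#' Write a belief rule base to a JSON document
#'
#' Canonical serialisation: a write/read round-trip reproduces every
#' parameter to full double precision, and save-load-save produces a
#' byte-identical file.
#'
#' @param brb A `belief_rule_base`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rulebase <- function(brb, path) {
  validate_brb(brb)
  doc <- list(schema_version = 1L)
  if (!is.null(brb$note)) doc$note <- jsonlite::unbox(brb$note)
  doc$attributes <- lapply(brb$attributes, function(a)
    list(name = jsonlite::unbox(a$name), labels = a$labels,
         ref_values = a$ref_values))
  doc$attribute_weights <- brb$attribute_weights
  doc$grade_labels <- brb$grade_labels
  doc$grade_utilities <- brb$grade_utilities
  doc$rules <- lapply(seq_len(nrow(brb$antecedents)), function(k) {
    lab <- vapply(seq_along(brb$attributes), function(i)
      brb$attributes[[i]]$labels[brb$antecedents[k, i]], character(1))
    list(antecedent = lab, theta = jsonlite::unbox(brb$theta[k]),
         beliefs = brb$beliefs[k, ])
  })
  doc$schema_version <- jsonlite::unbox(doc$schema_version)
  # I(17) significant digits: lossless for IEEE doubles
  json <- jsonlite::toJSON(doc, digits = I(17), pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' The expert-elicited initial rule base bundled with the package
#'
#' A 27-rule, 4-grade rule base over ARTUL (referential values 4/8/12),
#' RTT (5/10/15) and MAMS (5/8/11), with consequent belief
#' distributions elicited from rehabilitation clinicians, all rule and
#' attribute weights 1, and grade utilities 1-4. This is the conventional
#' starting point for training.
#'
#' @return A `belief_rule_base`.
#' @export
brb_expert_initial <- function() {
  read_rulebase(system.file("extdata", "expert_initial.json",
                            package = "brbrehab", mustWork = TRUE))
}

#' The trained reference rule base bundled with the package
#'
#' The same structure as [brb_expert_initial()] but with consequent belief
#' degrees refined by training against clinical assessments; it serves as
#' the default ground-truth model of the synthetic patient-record
#' generator. Rule and attribute weights are 1 (only the belief degrees of
#' this reference set are published).
#'
#' @return A `belief_rule_base`.
#' @export
brb_trained_reference <- function() {
  read_rulebase(system.file("extdata", "trained_reference.json",
                            package = "brbrehab", mustWork = TRUE))
}

#' Read a patient-record dataset from CSV
#'
#' Expects a header with the three feature columns `artul,rtt,mams` and an
#' optional `grade` column with values in `1..4`. Malformed cells are
#' reported with their row number.
#'
#' @param path CSV file path.
#' @param n_grades Number of valid grades for the `grade` column.
#' @return A data frame with numeric feature columns and, if present, an
#'   integer `grade` column.
#' @export
read_dataset <- function(path, n_grades = 4L) {
  if (!file.exists(path))
    stop(sprintf("dataset file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feat <- setdiff(names(df), "grade")
  if (length(feat) < 1L)
    stop("dataset has no feature columns", call. = FALSE)
  for (cn in feat) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("column '%s': non-numeric value at row %d",
                   cn, bad[1L]), call. = FALSE)
    df[[cn]] <- v
  }
  if ("grade" %in% names(df)) {
    g <- suppressWarnings(as.integer(df$grade))
    bad <- which(is.na(g) | g < 1L | g > n_grades)
    if (length(bad))
      stop(sprintf("column 'grade': invalid grade at row %d (must be 1..%d)",
                   bad[1L], n_grades), call. = FALSE)
    df$grade <- g
  }
  df
}

#' Write a patient-record dataset to CSV
#'
#' @param data Data frame of records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
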