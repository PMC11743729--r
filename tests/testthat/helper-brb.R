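# In-code builders for rule bases used across the tests.

# the three study attributes with their referential values
study_attributes <- function() {
  list(
    attribute_spec("ARTUL", c("S", "N", "B"), c(4, 8, 12)),
    attribute_spec("RTT",   c("S", "N", "L"), c(5, 10, 15)),
    attribute_spec("MAMS",  c("S", "N", "H"), c(5, 8, 11))
  )
}

# expert-elicited consequent belief table, 27 rules in canonical grid order
expert_belief_table <- function() {
  matrix(c(
    1,   0,   0,   0,
    0.9, 0.1, 0,   0,
    0.8, 0.2, 0,   0,
    0.9, 0.1, 0,   0,
    0.8, 0.2, 0,   0,
    0.7, 0.3, 0,   0,
    0.6, 0.3, 0.1, 0,
    0.5, 0.4, 0.1, 0,
    0,   0.9, 0.1, 0,
    0.8, 0.2, 0,   0,
    0.4, 0.5, 0.1, 0,
    0.3, 0.4, 0.3, 0,
    0.2, 0.6, 0.2, 0,
    0.1, 0.2, 0.7, 0,
    0,   0.3, 0.7, 0,
    0,   0.1, 0.9, 0,
    0,   0,   1,   0,
    0,   0,   0.9, 0.1,
    0,   0.3, 0.6, 0.1,
    0,   0.2, 0.7, 0.1,
    0,   0.1, 0.8, 0.1,
    0,   0,   0.7, 0.3,
    0,   0,   0.3, 0.7,
    0,   0,   0.1, 0.9,
    0,   0,   0.2, 0.8,
    0,   0,   0.1, 0.9,
    0,   0,   0,   1
  ), ncol = 4, byrow = TRUE)
}

# trained reference consequent belief table, same order
trained_belief_table <- function() {
  matrix(c(
    0.835, 0.150, 0.013, 0.000,
    0.814, 0.176, 0.010, 0.000,
    0.723, 0.237, 0.030, 0.010,
    0.812, 0.117, 0.064, 0.007,
    0.837, 0.105, 0.047, 0.011,
    0.643, 0.348, 0.008, 0.001,
    0.489, 0.377, 0.103, 0.031,
    0.466, 0.279, 0.228, 0.027,
    0.027, 0.813, 0.132, 0.028,
    0.774, 0.196, 0.030, 0.000,
    0.496, 0.386, 0.107, 0.011,
    0.319, 0.376, 0.245, 0.060,
    0.197, 0.631, 0.123, 0.049,
    0.089, 0.217, 0.597, 0.097,
    0.013, 0.321, 0.564, 0.102,
    0.003, 0.064, 0.877, 0.056,
    0.032, 0.005, 0.899, 0.064,
    0.001, 0.006, 0.900, 0.093,
    0.010, 0.280, 0.632, 0.078,
    0.002, 0.121, 0.796, 0.081,
    0.006, 0.012, 0.843, 0.139,
    0.004, 0.053, 0.698, 0.245,
    0.003, 0.027, 0.325, 0.645,
    0.003, 0.064, 0.182, 0.751,
    0.006, 0.009, 0.311, 0.674,
    0.001, 0.003, 0.082, 0.914,
    0.007, 0.021, 0.036, 0.936
  ), ncol = 4, byrow = TRUE)
}

# a tiny rule base with a single two-level attribute -> exactly two rules,
# handy for exercising the aggregation step with hand-picked weights
two_rule_brb <- function(b1 = c(1, 0, 0, 0), b2 = c(0, 1, 0, 0),
                         theta = c(1, 1)) {
  belief_rule_base(
    attributes = list(attribute_spec("X", c("lo", "hi"), c(0, 1))),
    antecedents = matrix(1:2, ncol = 1),
    theta = theta,
    beliefs = rbind(b1, b2)
  )
}

# random full-grid rule base: 1-2 attributes, 2-4 referential values each,
# 2-5 grades, random (optionally incomplete) consequents
random_brb <- function(complete = TRUE) {
  M <- sample(1:2, 1)
  attrs <- lapply(seq_len(M), function(i) {
    J <- sample(2:4, 1)
    attribute_spec(paste0("A", i), paste0("v", seq_len(J), "_", i),
                   sort(stats::runif(J, 0, 10)) + seq_len(J) * 1e-3)
  })
  N <- sample(2:5, 1)
  L <- prod(vapply(attrs, function(a) length(a$ref_values), integer(1)))
  B <- matrix(stats::runif(L * N), L, N)
  B <- B / rowSums(B)
  if (!complete) B <- B * stats::runif(L, 0.5, 1)
  brb_full_grid(attrs, B,
                theta = stats::runif(L, 0.2, 1),
                attribute_weights = stats::runif(M, 0.3, 1),
                grade_labels = paste0("G", seq_len(N)),
                grade_utilities = cumsum(stats::runif(N, 0.5, 2)))
}

# random in-range input for a rule base
random_input <- function(brb) {
  vapply(brb$attributes, function(a)
    stats::runif(1, min(a$ref_values), max(a$ref_values)), numeric(1))
}
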