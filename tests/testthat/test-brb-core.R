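test_that("matching degrees interpolate linearly between referential values", {
  attrs <- study_attributes()

  # input on a referential value is matched there alone
  m <- compute_matching_degrees(c(4, 5, 5), attrs)
  expect_equal(unname(m$ARTUL), c(1, 0, 0))
  expect_equal(unname(m$RTT), c(1, 0, 0))

  # halfway between two anchors splits the degree evenly
  m <- compute_matching_degrees(c(6, 13, 20), attrs)
  expect_equal(unname(m$ARTUL), c(0.5, 0.5, 0))
  # (15 - 13) / (15 - 10) = 0.4 at the middle anchor
  expect_equal(unname(m$RTT), c(0, 0.4, 0.6))
  # out-of-range input is clamped to the boundary anchor
  expect_equal(unname(m$MAMS), c(0, 0, 1))

  m <- compute_matching_degrees(c(-10, 2, 3), attrs)
  expect_equal(unname(m$ARTUL), c(1, 0, 0))
})

test_that("matching degrees reject bad input", {
  attrs <- study_attributes()
  expect_error(compute_matching_degrees(c(4, 5), attrs), "expected 3")
  expect_error(compute_matching_degrees(c(4, NA, 5), attrs), "finite")
  expect_error(compute_matching_degrees(c(4, Inf, 5), attrs), "finite")
})

test_that("matching degrees sum to 1 per attribute for any finite input", {
  set.seed(42)
  for (rep in 1:100) {
    J <- sample(2:6, 1)
    refs <- sort(stats::rnorm(J, sd = 10)) + seq_len(J) * 1e-6
    a <- attribute_spec("A", paste0("v", seq_len(J)), refs)
    x <- stats::rnorm(1, mean(refs), 3 * stats::sd(refs))
    d <- compute_matching_degrees(x, list(a))[[1L]]
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= 0 & d <= 1))
    # at most two nonzero degrees, and adjacent
    nz <- which(d > 0)
    expect_lte(length(nz), 2L)
    if (length(nz) == 2L) expect_equal(unname(diff(nz)), 1L)
  }
})

test_that("activation weights follow the weighted matching-degree product", {
  brb <- brb_full_grid(study_attributes(), expert_belief_table())

  # exact corner point: one-hot activation
  w <- compute_activation_weights(
    compute_matching_degrees(c(4, 5, 5), brb$attributes), brb)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(unclass(w)[1L], 1)
  expect_true(all(unclass(w)[-1L] == 0))

  # input between two ARTUL anchors activates the two matching rules evenly
  w <- compute_activation_weights(
    compute_matching_degrees(c(6, 5, 5), brb$attributes), brb)
  on <- which(unclass(w) > 0)
  expect_equal(on, c(1L, 10L))  # (S,S,S) and (N,S,S)
  expect_equal(unclass(w)[on], c(0.5, 0.5))

  # rule weights tilt the split: (0.2 * 0.5, 0.6 * 0.5) / 0.4
  theta <- rep(0.8, 27)
  theta[1L] <- 0.2
  theta[10L] <- 0.6
  brb2 <- brb_full_grid(study_attributes(), expert_belief_table(),
                        theta = theta)
  w <- compute_activation_weights(
    compute_matching_degrees(c(6, 5, 5), brb2$attributes), brb2)
  expect_equal(unclass(w)[c(1L, 10L)], c(0.25, 0.75))
  expect_equal(sum(w), 1)
})

test_that("all-zero activation numerators raise an explicit error", {
  brb <- brb_full_grid(study_attributes(), expert_belief_table(), theta = 0)
  m <- compute_matching_degrees(c(6, 7, 8), brb$attributes)
  expect_error(compute_activation_weights(m, brb), "no rule activated")
})

test_that("activation weights normalise over random rule bases and inputs", {
  set.seed(7)
  for (rep in 1:60) {
    brb <- random_brb()
    m <- compute_matching_degrees(random_input(brb), brb$attributes)
    w <- compute_activation_weights(m, brb)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(unclass(w) >= 0 & unclass(w) <= 1))
  }
})

test_that("ER aggregation handles one-hot and symmetric cases exactly", {
  # single activated rule returns its consequent unchanged
  brb <- two_rule_brb(b1 = c(0.3, 0.4, 0.2, 0.1))
  expect_equal(unname(aggregate_er(c(1, 0), brb)), c(0.3, 0.4, 0.2, 0.1),
               tolerance = 1e-12)

  # consensus on a degenerate distribution is preserved
  brb <- two_rule_brb(b1 = c(1, 0, 0, 0), b2 = c(1, 0, 0, 0))
  expect_equal(unname(aggregate_er(c(0.5, 0.5), brb)), c(1, 0, 0, 0),
               tolerance = 1e-12)

  # symmetric disagreement splits the belief evenly
  brb <- two_rule_brb(b1 = c(1, 0, 0, 0), b2 = c(0, 1, 0, 0))
  got <- unname(aggregate_er(c(0.5, 0.5), brb))
  oracle <- er_combine_oracle(c(0.5, 0.5), rbind(c(1, 0, 0, 0),
                                                 c(0, 1, 0, 0)))
  expect_equal(got, c(0.5, 0.5, 0, 0), tolerance = 1e-12)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("ER aggregation rejects invalid activation profiles", {
  brb <- two_rule_brb()
  expect_error(aggregate_er(c(0.7, 0.7), brb), "sum to 1")
  expect_error(aggregate_er(c(1, 0, 0), brb), "one activation weight per rule")
})

test_that("aggregated beliefs of complete rules sum to 1", {
  set.seed(11)
  for (rep in 1:60) {
    brb <- random_brb(complete = TRUE)
    res <- assess(random_input(brb), brb)
    expect_equal(sum(res$beliefs), 1, tolerance = 1e-9)
    expect_true(all(res$beliefs >= 0 & res$beliefs <= 1))
  }
})

test_that("expected utility is the belief-weighted grade score", {
  brb <- two_rule_brb()
  expect_identical(expected_utility(c(1, 0, 0, 0), brb), 1)
  expect_identical(expected_utility(c(0, 0, 0, 1), brb), 4)
  expect_identical(expected_utility(c(0.5, 0.5, 0, 0), brb), 1.5)
  expect_error(expected_utility(c(0.5, 0.5), brb), "number of grades")

  # residual mass of an incomplete distribution scores 0 by default,
  # renormalisation spreads it proportionally
  expect_equal(expected_utility(c(0.4, 0.4, 0, 0), brb), 1.2)
  expect_equal(expected_utility(c(0.4, 0.4, 0, 0), brb, renormalize = TRUE),
               1.5)
})

test_that("grade classification is nearest-utility with ties broken low", {
  brb <- two_rule_brb()  # utilities 1:4
  expect_identical(classify_grade(1.0, brb), 1L)
  expect_identical(classify_grade(2.49, brb), 2L)
  expect_identical(classify_grade(2.5, brb), 2L)   # tie -> lower grade
  expect_identical(classify_grade(2.51, brb), 3L)
  expect_identical(classify_grade(c(0.5, 4.6), brb), c(1L, 4L))  # clamped
})

test_that("assess composes the full inference pipeline", {
  expert <- brb_full_grid(study_attributes(), expert_belief_table())

  res <- assess(c(4, 5, 5), expert)
  expect_equal(unname(res$beliefs), c(1, 0, 0, 0))
  expect_equal(res$utility, 1)
  expect_identical(res$grade, 1L)
  expect_identical(res$grade_label, "I")

  res <- assess(c(12, 15, 11), expert)
  expect_equal(unname(res$beliefs), c(0, 0, 0, 1))
  expect_equal(res$utility, 4)
  expect_identical(res$grade, 4L)

  trained <- brb_full_grid(study_attributes(), trained_belief_table())
  res <- assess(c(4, 5, 5), trained)
  expect_equal(unname(res$beliefs), c(0.835, 0.15, 0.013, 0),
               tolerance = 1e-12)
  # literal expected utility of the slightly incomplete consequent
  expect_equal(res$utility, 0.835 * 1 + 0.15 * 2 + 0.013 * 3,
               tolerance = 1e-12)
  expect_equal(res$utility, 1.174, tolerance = 1e-9)
  res_rn <- assess(c(4, 5, 5), trained, renormalize = TRUE)
  expect_equal(res_rn$utility, 1.174 / 0.998, tolerance = 1e-9)
})

test_that("utility stays within the grade-utility bounds", {
  set.seed(13)
  for (rep in 1:40) {
    complete <- rep %% 2 == 0
    brb <- random_brb(complete = complete)
    u <- brb$grade_utilities
    x <- random_input(brb)
    res <- assess(x, brb)
    expect_lte(res$utility, max(u) + 1e-9)
    if (complete) {
      expect_gte(res$utility, min(u) - 1e-9)
    } else {
      # residual unassigned mass scores zero under the literal reading, so
      # only the renormalised utility is guaranteed to respect the lower
      # bound
      rn <- assess(x, brb, renormalize = TRUE)
      expect_gte(rn$utility, min(u) - 1e-9)
      expect_lte(rn$utility, max(u) + 1e-9)
      expect_lte(res$utility, rn$utility + 1e-9)
    }
  }
})

test_that("rule order does not affect the assessment", {
  set.seed(17)
  expert <- brb_full_grid(study_attributes(), expert_belief_table(),
                          theta = stats::runif(27, 0.3, 1),
                          attribute_weights = c(0.9, 0.6, 1))
  perm <- sample(27)
  shuffled <- belief_rule_base(
    expert$attributes, expert$antecedents[perm, ], expert$theta[perm],
    expert$beliefs[perm, ], attribute_weights = expert$attribute_weights)
  for (x in list(c(5, 7, 9), c(10.2, 11.7, 6.1), c(8, 10, 8))) {
    a <- assess(x, expert)
    b <- assess(x, shuffled)
    expect_equal(a$beliefs, b$beliefs, tolerance = 1e-12)
    expect_equal(a$utility, b$utility, tolerance = 1e-12)
  }
})

test_that("batch assessment matches record-by-record inference", {
  set.seed(19)
  brb <- brb_full_grid(study_attributes(), trained_belief_table(),
                       theta = stats::runif(27, 0.4, 1),
                       attribute_weights = c(1, 0.7, 0.8))
  X <- cbind(artul = stats::runif(50, 4, 12),
             rtt = stats::runif(50, 5, 15),
             mams = stats::runif(50, 5, 11))
  batch <- assess_dataset(as.data.frame(X), brb)
  for (r in c(1, 17, 50)) {
    one <- assess(X[r, ], brb)
    expect_equal(unlist(batch[r, 1:4], use.names = FALSE),
                 unname(one$beliefs), tolerance = 1e-12)
    expect_equal(batch$utility[r], one$utility, tolerance = 1e-12)
    expect_identical(batch$grade[r], one$grade)
  }
})

test_that("compiled training kernel agrees with the reference R path", {
  set.seed(23)
  brb <- brb_full_grid(study_attributes(), trained_belief_table(),
                       theta = stats::runif(27, 0.3, 1),
                       attribute_weights = c(0.8, 1, 0.5))
  X <- cbind(stats::runif(200, 2, 14), stats::runif(200, 4, 16),
             stats::runif(200, 4, 12))
  mm <- brbrehab:::matching_matrices(X, brb)
  y_fast <- brbrehab:::brb_utilities_fast(mm, brb)
  y_ref <- brbrehab:::brb_infer_matrix(X, brb)$utility
  expect_equal(y_fast, y_ref, tolerance = 1e-12)
})
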