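test_that("parameter packing round-trips and has the expected layout", {
  brb <- brb_full_grid(study_attributes(), trained_belief_table(),
                       theta = seq(0.5, 1, length.out = 27),
                       attribute_weights = c(0.9, 0.8, 1))
  p <- pack_parameters(brb)
  expect_length(p, 27 + 3 + 4 * 27)  # theta, delta, beta blocks
  expect_equal(p[1:27], brb$theta)
  expect_equal(p[28:30], brb$attribute_weights)
  expect_equal(p[31:34], brb$beliefs[1L, ])  # grade-fastest within rule

  back <- unpack_parameters(p, brb)
  expect_equal(pack_parameters(back), p)
  expect_equal(back$beliefs, brb$beliefs)
  expect_error(unpack_parameters(p[-1], brb), "expected 138 parameters")
})

test_that("feasibility repair projects onto the constraint set", {
  brb <- brb_full_grid(study_attributes(), expert_belief_table())
  bad <- brb
  bad$theta[3] <- 1.7
  bad$attribute_weights[2] <- -0.4
  bad$beliefs[5, ] <- c(0.9, 0.5, 0.2, 0.1)  # sums to 1.7
  fixed <- repair_rulebase(bad)
  expect_true(all(fixed$theta >= 0 & fixed$theta <= 1))
  expect_true(all(fixed$attribute_weights >= 0 &
                    fixed$attribute_weights <= 1))
  expect_lte(max(rowSums(fixed$beliefs)), 1 + 1e-12)
  # already-feasible parameters pass through untouched
  expect_equal(pack_parameters(repair_rulebase(brb)), pack_parameters(brb))
})

test_that("MSE objective matches hand-computed residuals", {
  expert <- brb_full_grid(study_attributes(), expert_belief_table())
  p <- pack_parameters(expert)

  # two records whose model outputs are exactly 1 and 3:
  # labels II and III give residuals (1-2) and (3-3) -> MSE 0.5
  d <- data.frame(artul = c(4, 8), rtt = c(5, 15), mams = c(5, 8),
                  grade = c(2L, 3L))
  obj <- mse_objective(p, d, expert)
  expect_equal(obj$mse, 0.5)
  expect_equal(obj$residuals, c(-1, 0))

  # self-consistent corner records with one-hot consequents: zero error
  d0 <- data.frame(artul = c(4, 8, 12), rtt = c(5, 15, 15),
                   mams = c(5, 8, 11), grade = c(1L, 3L, 4L))
  expect_equal(mse_objective(p, d0, expert)$mse, 0, tolerance = 1e-12)

  expect_error(mse_objective(p, d[0, ], expert), "empty")
  expect_gte(mse_objective(pmax(p - 0.05, 0), d, expert)$mse, 0)
})

test_that("the truth model's MSE is a floor for noise-free generated data", {
  truth <- brb_trained_reference()
  dat <- simulate_dataset(truth, simulation_config(
    n_records = 300, feature_noise = 0, seed = 5))
  floor_mse <- mse_objective(pack_parameters(truth), dat, truth)$mse
  # the continuous output is quantised to a grade, so the floor is > 0 but
  # bounded by the worst within-cell quantisation error
  expect_gte(floor_mse, 0)
  expect_lte(floor_mse, 0.25)
})

test_that("training from the generating model is a fixed point", {
  truth <- brb_trained_reference()
  dat <- simulate_dataset(truth, simulation_config(
    n_records = 200, feature_noise = 0, seed = 9))
  fit <- train_brb(truth, dat, training_config(max_iter = 10, seed = 1))
  expect_lte(fit$report$final_mse, fit$report$initial_mse + 1e-9)
  # the generator sits at (or numerically near) a local optimum already
  expect_lt(fit$report$initial_mse - fit$report$final_mse, 5e-3)
})

test_that("training reduces the objective and keeps parameters feasible", {
  truth <- brb_trained_reference()
  init <- brb_expert_initial()
  dat <- simulate_dataset(truth, simulation_config(n_records = 400, seed = 3))
  fit <- train_brb(init, dat, training_config(max_iter = 30, seed = 3))

  expect_lte(fit$report$final_mse, fit$report$initial_mse)
  p <- pack_parameters(fit$brb)
  expect_true(all(p >= -1e-6 & p <= 1 + 1e-6))
  expect_lte(max(rowSums(fit$brb$beliefs)), 1 + 1e-6)
  expect_true(is.finite(fit$report$final_mse))
  expect_identical(fit$report$n_records, 400L)
})

test_that("an infeasible initialisation is repaired before training", {
  init <- brb_expert_initial()
  init$beliefs[2, ] <- c(0.9, 0.4, 0, 0)  # sums to 1.3
  dat <- simulate_dataset(brb_trained_reference(),
                          simulation_config(n_records = 100, seed = 4))
  expect_message(
    fit <- train_brb(init, dat, training_config(max_iter = 5, seed = 1)),
    "repaired by projection")
  expect_lte(max(rowSums(fit$brb$beliefs)), 1 + 1e-6)
})

test_that("frozen parameter blocks stay at their initial values", {
  init <- brb_expert_initial()
  dat <- simulate_dataset(brb_trained_reference(),
                          simulation_config(n_records = 200, seed = 6))
  fit <- train_brb(init, dat, training_config(max_iter = 15, seed = 1,
                                              free = "beta"))
  expect_equal(fit$brb$theta, init$theta)
  expect_equal(fit$brb$attribute_weights, init$attribute_weights)
  expect_lte(fit$report$final_mse, fit$report$initial_mse)
})

test_that("training is deterministic given data, init and config", {
  init <- brb_expert_initial()
  dat <- simulate_dataset(brb_trained_reference(),
                          simulation_config(n_records = 200, seed = 8))
  cfg <- training_config(max_iter = 15, seed = 42)
  f1 <- train_brb(init, dat, cfg)
  f2 <- train_brb(init, dat, cfg)
  expect_identical(pack_parameters(f1$brb), pack_parameters(f2$brb))
  expect_identical(f1$report$final_mse, f2$report$final_mse)
})

test_that("a perturbed initialisation recovers the generating model", {
  truth <- brb_trained_reference()
  ok <- 0L
  for (s in 1:10) {
    dat <- simulate_dataset(truth, simulation_config(
      n_records = 600, feature_noise = 0, seed = 100 + s))
    parts <- split_dataset(dat, 2 / 3, seed = s)
    init <- perturb_rulebase(truth, magnitude = 0.2, seed = 200 + s)
    fit <- train_brb(init, parts$train, training_config(max_iter = 30,
                                                        seed = s))
    acc_init <- evaluate_model(init, parts$test)$accuracy
    acc_fit <- evaluate_model(fit$brb, parts$test)$accuracy
    mse_truth <- evaluate_model(truth, parts$test)$mse
    mse_fit <- evaluate_model(fit$brb, parts$test)$mse
    if (acc_fit >= acc_init && mse_fit <= 2 * mse_truth) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})
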