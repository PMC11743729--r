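#' Flatten trainable rule-base parameters into a vector
#'
#' The trainable parameters are the rule weights `theta` (L), the attribute
#' weights `delta` (M) and the consequent belief degrees `beta` (N per
#' rule), packed as `[theta_1..theta_L, delta_1..delta_M,
#' beta_{1,1}..beta_{N,1}, ..., beta_{1,L}..beta_{N,L}]` — length
#' `L + M + N*L` (138 for the bundled 27-rule, 3-attribute, 4-grade model).
#' Referential values and grade utilities are fixed and do not appear.
#'
#' @param brb A `belief_rule_base`.
#' @return Numeric parameter vector.
#' @seealso [unpack_parameters()]
#' @export
pack_parameters <- function(brb) {
  stopifnot(inherits(brb, "belief_rule_base"))
  c(brb$theta, brb$attribute_weights, as.vector(t(brb$beliefs)))
}

#' Rebuild a rule base from a flat parameter vector
#'
#' Inverse of [pack_parameters()]: writes the packed `theta`, `delta` and
#' `beta` values back into a template rule base (pack then unpack is the
#' identity).
#'
#' @param params Numeric vector of length `L + M + N*L`.
#' @param template A `belief_rule_base` supplying structure (attributes,
#'   antecedent grid, grades, utilities).
#' @param validate Re-validate the result (disable on the optimiser's hot
#'   path, where intermediate iterates may sit slightly outside the
#'   feasible set).
#' @return A `belief_rule_base`.
#' @export
unpack_parameters <- function(params, template, validate = TRUE) {
  dims <- brb_dims(template)
  L <- dims[["L"]]; M <- dims[["M"]]; N <- dims[["N"]]
  if (length(params) != L + M + N * L)
    stop(sprintf("expected %d parameters, got %d", L + M + N * L,
                 length(params)), call. = FALSE)
  out <- template
  out$theta <- params[seq_len(L)]
  out$attribute_weights <- params[L + seq_len(M)]
  out$beliefs <- matrix(params[-seq_len(L + M)], L, N, byrow = TRUE)
  if (validate) validate_brb(out) else out
}

#' Repair an infeasible rule base by projection
#'
#' Clips all rule weights, attribute weights and belief degrees to `[0, 1]`
#' and scales down any rule's belief vector whose sum exceeds 1, producing
#' the nearest simple feasible point. A feasible rule base is returned
#' unchanged.
#'
#' @param brb A (possibly infeasible) `belief_rule_base`.
#' @return A feasible `belief_rule_base`.
#' @export
repair_rulebase <- function(brb) {
  brb$theta <- pmin(pmax(brb$theta, 0), 1)
  brb$attribute_weights <- pmin(pmax(brb$attribute_weights, 0), 1)
  if (max(brb$attribute_weights) <= 0) brb$attribute_weights[] <- 1
  B <- pmin(pmax(brb$beliefs, 0), 1)
  rs <- rowSums(B)
  over <- rs > 1
  if (any(over)) B[over, ] <- B[over, , drop = FALSE] / rs[over]
  brb$beliefs <- B
  validate_brb(brb)
}

#' Training targets: utility of each labelled grade
#'
#' A record labelled with grade `g` is assigned the target output
#' `y^r = u(D_g)` under the rule base's grade utilities.
#'
#' @param data Labelled data frame (with a `grade` column).
#' @param brb A `belief_rule_base`.
#' @return Numeric vector of target utilities.
#' @export
grade_targets <- function(data, brb) {
  if (!"grade" %in% names(data))
    stop("dataset has no 'grade' column: labels are required", call. = FALSE)
  brb$grade_utilities[data$grade]
}

#' Mean squared error of a parameter vector on labelled data
#'
#' Unpacks `params` into the template rule base, evaluates the model on
#' every record, and returns the mean squared difference between the
#' model's continuous output utility and the target utility of the true
#' grade, `MSE = (1/T) * sum_i (yhat_i - y^r_i)^2`.
#'
#' @param params Packed parameter vector ([pack_parameters()]).
#' @param data Labelled data frame.
#' @param template A `belief_rule_base` giving the fixed structure.
#' @return An object of class `brb_objective`: list with `mse` and
#'   per-record `residuals` (`yhat - y^r`).
#' @export
mse_objective <- function(params, data, template) {
  if (!nrow(data)) stop("empty dataset", call. = FALSE)
  brb <- unpack_parameters(params, template, validate = FALSE)
  X <- dataset_features(data, template)
  yhat <- brb_infer_matrix(X, brb)$utility
  res <- yhat - grade_targets(data, template)
  structure(list(mse = mean(res^2), residuals = res),
            class = "brb_objective")
}

#' Training configuration
#'
#' @param max_iter Maximum optimiser iterations (default 500).
#' @param tol Convergence tolerance on the objective (default 1e-6).
#' @param constraint_tol Feasibility tolerance on the returned parameters.
#' @param penalty Weight of the quadratic penalty on per-rule belief-sum
#'   violations during optimisation (the final result is always projected
#'   back to the feasible set).
#' @param n_starts Number of optimisation starts; starts beyond the first
#'   are seeded random perturbations of the initial rule base.
#' @param seed Integer seed controlling multi-start perturbations.
#' @param free Character subset of `c("theta", "delta", "beta")` naming the
#'   parameter blocks the optimiser may move; the rest stay at their
#'   initial values.
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_iter = 500L, tol = 1e-6,
                            constraint_tol = 1e-6, penalty = 1000,
                            n_starts = 1L, seed = 1L,
                            free = c("theta", "delta", "beta")) {
  stopifnot(max_iter >= 1L, tol > 0, constraint_tol > 0, penalty >= 0,
            n_starts >= 1L)
  free <- match.arg(free, c("theta", "delta", "beta"), several.ok = TRUE)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 constraint_tol = constraint_tol, penalty = penalty,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 free = free),
            class = "training_config")
}

#' Train a belief rule base by constrained MSE minimisation
#'
#' Learns rule weights, attribute weights and consequent belief degrees
#' from labelled records by minimising the mean squared error between the
#' model's continuous output and the utility of each record's true grade,
#' subject to the box constraints `0 <= theta_k, delta_i, beta_{n,k} <= 1`
#' and the per-rule mass constraints `sum_n beta_{n,k} <= 1`.
#'
#' The optimiser is a box-constrained quasi-Newton method (L-BFGS-B) with
#' finite-difference gradients; the belief-sum constraints are enforced by
#' a quadratic exterior penalty during the search and exactly by projection
#' afterwards. An accept-if-better guard returns the (repaired) initial
#' rule base whenever the optimised candidate does not improve the
#' objective, so the final MSE never exceeds the initial MSE. The whole
#' procedure is deterministic given `data`, `init` and `cfg`.
#'
#' @param init Initial `belief_rule_base` (an infeasible one is repaired by
#'   projection before training starts, with a message).
#' @param data Labelled data frame (feature columns + `grade`).
#' @param cfg A [training_config()].
#' @return A list of class `brb_training` with elements `brb` (the trained
#'   rule base), and `report`: initial/final MSE, iterations, objective
#'   evaluation counts, optimiser convergence code and message, whether the
#'   candidate was accepted, and the start that won.
#' @export
train_brb <- function(init, data, cfg = training_config()) {
  stopifnot(inherits(init, "belief_rule_base"),
            inherits(cfg, "training_config"))
  if (!nrow(data)) stop("empty training dataset", call. = FALSE)
  repaired <- repair_rulebase(init)
  if (any(abs(pack_parameters(repaired) - pack_parameters(init)) > 1e-12))
    message("initial rule base was infeasible; repaired by projection")
  init <- repaired

  dims <- brb_dims(init)
  L <- dims[["L"]]; M <- dims[["M"]]; N <- dims[["N"]]
  x_init <- pack_parameters(init)
  free_idx <- sort(unique(c(
    if ("theta" %in% cfg$free) seq_len(L),
    if ("delta" %in% cfg$free) L + seq_len(M),
    if ("beta" %in% cfg$free) L + M + seq_len(N * L)
  )))
  if (!length(free_idx))
    stop("no free parameter block selected", call. = FALSE)

  X <- dataset_features(data, init)
  yr <- grade_targets(data, init)
  mm <- matching_matrices(X, init)
  u <- init$grade_utilities

  # compiled forward pass; the matching matrices never change during
  # training, only theta / delta / beta do
  obj_full <- function(x) {
    theta <- x[seq_len(L)]
    delta <- x[L + seq_len(M)]
    dmax <- max(delta)
    if (dmax <= 0) return(1e6)
    B <- matrix(x[-seq_len(L + M)], L, N, byrow = TRUE)
    yhat <- tryCatch(
      cpp_brb_utilities(mm, init$antecedents, theta, delta / dmax, B, u),
      error = function(e) NULL)
    if (is.null(yhat)) return(1e6)
    mse <- mean((yhat - yr)^2)
    excess <- rowSums(B) - 1
    mse + cfg$penalty * sum(pmax(excess, 0)^2)
  }
  obj_free <- function(xf) {
    x <- x_init
    x[free_idx] <- xf
    obj_full(x)
  }
  # forward-difference gradient that never steps outside the [0, 1] box
  # (switches to a backward step at the upper bound); optim's built-in
  # differencing ignores the bounds, which derails the line search when
  # the start sits on a box face
  fd_step <- 1e-7
  grad_free <- function(xf) {
    f0 <- obj_free(xf)
    g <- numeric(length(xf))
    for (p in seq_along(xf)) {
      h <- if (xf[p] + fd_step <= 1) fd_step else -fd_step
      xp <- xf
      xp[p] <- xp[p] + h
      g[p] <- (obj_free(xp) - f0) / h
    }
    g
  }

  initial_mse <- mse_objective(x_init, data, init)$mse
  best <- list(par = x_init, value = initial_mse, mse = initial_mse,
               convergence = NA_integer_, message = "initial parameters",
               counts = c(`function` = 1L, gradient = 0L),
               accepted = FALSE, start = 0L)

  starts <- vector("list", cfg$n_starts)
  starts[[1L]] <- x_init
  if (cfg$n_starts > 1L) {
    for (s in 2:cfg$n_starts)
      starts[[s]] <- pack_parameters(
        perturb_rulebase(init, magnitude = 0.1, seed = cfg$seed + s))
  }

  for (s in seq_along(starts)) {
    x0 <- starts[[s]][free_idx]
    fit <- tryCatch(
      stats::optim(x0, obj_free, gr = grad_free, method = "L-BFGS-B",
                   lower = 0, upper = 1,
                   control = list(maxit = cfg$max_iter,
                                  # tol is a relative objective-reduction
                                  # tolerance; factr is in units of machine eps
                                  factr = max(cfg$tol / 1e3 /
                                                .Machine$double.eps, 10))),
      error = function(e) list(par = x0, value = Inf, convergence = 99L,
                               message = conditionMessage(e),
                               counts = c(`function` = NA, gradient = NA)))
    x_cand <- x_init
    x_cand[free_idx] <- fit$par
    # exact feasibility, then score without penalty
    cand <- repair_rulebase(unpack_parameters(x_cand, init, validate = FALSE))
    cand_mse <- mse_objective(pack_parameters(cand), data, init)$mse
    if (cand_mse < best$mse - 0) {
      best <- list(par = pack_parameters(cand), value = fit$value,
                   mse = cand_mse, convergence = fit$convergence,
                   message = if (is.null(fit$message)) "" else fit$message,
                   counts = fit$counts, accepted = TRUE, start = s)
    }
  }

  trained <- unpack_parameters(best$par, init, validate = TRUE)
  report <- list(
    initial_mse = initial_mse,
    final_mse = best$mse,
    improved = best$accepted,
    iterations = unname(best$counts["gradient"]),
    n_objective_evals = unname(best$counts["function"]),
    convergence = best$convergence,
    message = best$message,
    winning_start = best$start,
    n_starts = cfg$n_starts,
    n_records = nrow(data),
    n_free_parameters = length(free_idx)
  )
  structure(list(brb = trained, report = report), class = "brb_training")
}

#' @export
print.brb_training <- function(x, ...) {
  r <- x$report
  cat(sprintf("BRB training: MSE %.6f -> %.6f on %d records (%s)\n",
              r$initial_mse, r$final_mse, r$n_records,
              if (isTRUE(r$improved)) "improved" else "kept initial"))
  invisible(x)
}
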