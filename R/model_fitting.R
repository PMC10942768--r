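# Internal: drop missed trials and validate a choice table for fitting.
prep_choices <- function(choices) {
  need <- c("recipient", "reward_credits", "effort_level", "decision")
  miss <- setdiff(need, names(choices))
  if (length(miss))
    stop("choice table is missing columns: ", paste(miss, collapse = ", "))
  kept <- choices[choices$decision != "missed", , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("all trials are missed; nothing to fit")
  kept$work <- as.integer(kept$decision == "work")
  kept
}

# Internal: packed parameter vector <-> full (K_self, K_other, beta_self,
# beta_other) set, according to the model's sharing schemes.
par_names <- function(model) {
  c(if (model$k_scheme == "separate") c("K_self", "K_other") else "K",
    if (model$beta_scheme == "separate") c("beta_self", "beta_other")
    else "beta")
}

expand_par <- function(model, par) {
  if (model$k_scheme == "separate") {
    K_self <- par[["K_self"]]; K_other <- par[["K_other"]]
  } else K_self <- K_other <- par[["K"]]
  if (model$beta_scheme == "separate") {
    beta_self <- par[["beta_self"]]; beta_other <- par[["beta_other"]]
  } else beta_self <- beta_other <- par[["beta"]]
  c(K_self = K_self, K_other = K_other,
    beta_self = beta_self, beta_other = beta_other)
}

#' Negative log-likelihood of a choice model
#'
#' Sum over non-missed trials of \eqn{-\ln P(\text{observed decision})},
#' with the work probability from the softmax rule applied to the
#' recipient-appropriate discount parameter and temperature. Probabilities
#' are floored at \code{p_floor} before logs so the objective stays finite
#' at extreme temperatures.
#'
#' @param model An [effort_model()].
#' @param params Named vector or list with \code{K_self}, \code{K_other},
#'   \code{beta_self}, \code{beta_other} (for shared schemes the pair must
#'   be equal; a single \code{K}/\code{beta} entry is also accepted).
#' @param choices Choice-record data.frame; missed trials are excluded.
#' @param p_floor Probability floor applied before taking logs.
#' @return Non-negative scalar.
#' @export
negative_log_likelihood <- function(model, params, choices,
                                    p_floor = 1e-12) {
  stopifnot(inherits(model, "effort_model"))
  params <- unlist(params)
  if (!"K_self" %in% names(params))
    params <- expand_par(model, params)
  kept <- prep_choices(choices)
  is_self <- kept$recipient == "self"
  K <- ifelse(is_self, params[["K_self"]], params[["K_other"]])
  beta <- ifelse(is_self, params[["beta_self"]], params[["beta_other"]])
  sv <- subjective_value(model$form, kept$reward_credits,
                         kept$effort_level, K)
  p_work <- choice_probability(beta, sv)
  p_obs <- ifelse(kept$work == 1L, p_work, 1 - p_work)
  -sum(log(pmax(p_obs, p_floor)))
}

#' Fit an effort-discounting choice model by maximum likelihood
#'
#' Minimises the negative log-likelihood over the bounded parameter box
#' (K in \code{k_bounds}, default [0, 1.5]; beta in \code{beta_bounds})
#' with L-BFGS-B from \code{n_restarts} seeded uniform initialisations,
#' keeping the best restart. Missed trials are excluded from the
#' likelihood and from the sample size used in the BIC.
#'
#' @param choices Choice records for one participant (data.frame with
#'   \code{recipient}, \code{reward_credits}, \code{effort_level},
#'   \code{decision}).
#' @param model An [effort_model()]; default is the recipient-specific
#'   parabolic model with one temperature, the usual winner for this task.
#' @param k_bounds,beta_bounds Length-2 numeric bounds for K and beta.
#' @param n_restarts Number of random initialisations (>= 1).
#' @param seed Integer seed; refitting identical data with an identical
#'   seed gives an identical result.
#' @return An object of class \code{effort_fit}: the model spec, the full
#'   parameter set, log-likelihood, trial count, BIC, restart diagnostics.
#' @examples
#' d <- generate_design(participant_id = "p1", seed = 2)
#' a <- agent_params("p1", "control", K_self = 0.2, K_other = 0.5,
#'                   beta_self = 5)
#' ch <- simulate_agent_choices(a, d, seed = 3, include_force = FALSE)
#' fit <- fit_effort_model(ch, n_restarts = 5, seed = 4)
#' coef(fit)
#' @export
fit_effort_model <- function(choices,
                             model = effort_model("parabolic", "separate",
                                                  "shared"),
                             k_bounds = c(0, 1.5),
                             beta_bounds = c(0, 30),
                             n_restarts = 20L, seed = 1L) {
  stopifnot(inherits(model, "effort_model"))
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  if (length(k_bounds) != 2L || diff(k_bounds) <= 0 ||
      length(beta_bounds) != 2L || diff(beta_bounds) <= 0)
    stop("bounds must be increasing length-2 vectors")
  kept <- prep_choices(choices)
  pn <- par_names(model)
  lower <- ifelse(startsWith(pn, "K"), k_bounds[1], beta_bounds[1])
  upper <- ifelse(startsWith(pn, "K"), k_bounds[2], beta_bounds[2])
  names(lower) <- names(upper) <- pn

  # precompute trial vectors once; the objective and its analytic
  # gradient only re-evaluate SV and the logistic terms
  is_self <- kept$recipient == "self"
  R <- kept$reward_credits; E <- kept$effort_level
  work <- kept$work == 1L
  form <- model$form
  sep_k <- model$k_scheme == "separate"
  sep_b <- model$beta_scheme == "separate"
  E2 <- E^2
  unpack <- function(par) {
    if (sep_k) {
      K <- numeric(length(E)); K[is_self] <- par[1]; K[!is_self] <- par[2]
      bidx <- 3L
    } else { K <- rep(par[1], length(E)); bidx <- 2L }
    if (sep_b) {
      beta <- numeric(length(E))
      beta[is_self] <- par[bidx]; beta[!is_self] <- par[bidx + 1L]
    } else beta <- rep(par[bidx], length(E))
    list(K = K, beta = beta)
  }
  sv_fun <- switch(form,
    linear     = function(K) R - K * E,
    hyperbolic = function(K) R / (1 + K * E),
    parabolic  = function(K) R - K * E2)
  dsv_dK <- switch(form,
    linear     = function(K) -E,
    hyperbolic = function(K) -R * E / (1 + K * E)^2,
    parabolic  = function(K) -E2)
  obj <- function(par) {
    u <- unpack(par)
    p_work <- stats::plogis(u$beta * (sv_fun(u$K) - 1))
    p_obs <- ifelse(work, p_work, 1 - p_work)
    -sum(log(pmax(p_obs, 1e-12)))
  }
  grad <- function(par) {
    u <- unpack(par)
    sv <- sv_fun(u$K)
    d <- sv - 1
    p_work <- stats::plogis(u$beta * d)
    # d logLik / dx, x = beta * (sv - 1)
    g <- ifelse(work, 1 - p_work, -p_work)
    gK_trial <- g * u$beta * dsv_dK(u$K)
    gb_trial <- g * d
    gr <- c(
      if (sep_k) c(sum(gK_trial[is_self]), sum(gK_trial[!is_self]))
      else sum(gK_trial),
      if (sep_b) c(sum(gb_trial[is_self]), sum(gb_trial[!is_self]))
      else sum(gb_trial))
    -gr
  }

  rng <- local_rng(seed)
  on.exit(rng())
  inits <- matrix(stats::runif(n_restarts * length(pn),
                               rep(lower, each = n_restarts),
                               rep(upper, each = n_restarts)),
                  nrow = n_restarts)
  best <- NULL; best_idx <- NA_integer_; any_conv <- FALSE
  fails <- character(0)
  for (r in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(inits[r, ], obj, grad, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) e)
    if (inherits(res, "error")) { fails <- c(fails, conditionMessage(res));
      next }
    if (res$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) { best <- res;
      best_idx <- r }
  }
  if (is.null(best))
    stop("optimiser failed on all ", n_restarts, " restarts: ",
         paste(unique(fails), collapse = "; "))
  par <- best$par; names(par) <- pn
  n_used <- nrow(kept)
  logL <- -best$value
  structure(
    list(model = model,
         params = expand_par(model, par),
         par = par,
         log_likelihood = logL,
         n_trials_used = n_used,
         bic = bic_score(length(pn), n_used, logL),
         n_restarts = n_restarts,
         converged = any_conv,
         best_restart_index = best_idx,
         k_bounds = k_bounds, beta_bounds = beta_bounds,
         participant_id = if ("participant_id" %in% names(choices))
           choices$participant_id[1] else NA_character_,
         choices = kept),
    class = "effort_fit"
  )
}

#' Bayesian information criterion
#'
#' \eqn{BIC = k \ln(n) - 2 \ln \hat L}; lower is better.
#'
#' @param n_par Number of free parameters.
#' @param n_obs Number of observations (non-missed trials).
#' @param log_lik Maximised log-likelihood.
#' @return Scalar BIC.
#' @examples
#' bic_score(3, 150, -80) # 175.032
#' @export
bic_score <- function(n_par, n_obs, log_lik) {
  if (n_obs < 1L) stop("n_obs must be >= 1")
  n_par * log(n_obs) - 2 * log_lik
}

#' @export
print.effort_fit <- function(x, ...) {
  cat("Effort-discounting fit:", model_name(x$model),
      if (!is.na(x$participant_id)) paste0("(", x$participant_id, ")"),
      "\n")
  print(round(x$par, 4))
  cat(sprintf("logLik %.3f on %d trials, BIC %.3f (%d restarts%s)\n",
              x$log_likelihood, x$n_trials_used, x$bic, x$n_restarts,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
summary.effort_fit <- function(object, ...) {
  x <- object
  ch <- x$choices
  cat("Model:", model_name(x$model), "  participant:",
      x$participant_id, "\n\nParameters (", length(x$par),
      " free):\n", sep = "")
  print(round(x$params, 4))
  cat(sprintf("\nlogLik: %.3f   BIC: %.3f   trials used: %d\n",
              x$log_likelihood, x$bic, x$n_trials_used))
  p <- stats::predict(x, ch)
  cat(sprintf("Mean P(work): %.3f   observed work rate: %.3f\n",
              mean(p), mean(ch$work)))
  cat(sprintf("Work rate self: %.3f   other: %.3f\n",
              mean(ch$work[ch$recipient == "self"]),
              mean(ch$work[ch$recipient == "other"])))
  invisible(x)
}

#' @export
coef.effort_fit <- function(object, full = FALSE, ...) {
  if (full) object$params else object$par
}

#' @export
logLik.effort_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$par),
            nobs = object$n_trials_used, class = "logLik")
}

#' Predicted work probabilities from a fitted model
#'
#' @param object An \code{effort_fit}.
#' @param newdata Trial table with \code{recipient}, \code{reward_credits},
#'   \code{effort_level}; defaults to the fitted trials.
#' @param ... Unused.
#' @return Vector of P(work) per trial.
#' @export
predict.effort_fit <- function(object, newdata = object$choices, ...) {
  is_self <- newdata$recipient == "self"
  K <- ifelse(is_self, object$params[["K_self"]],
              object$params[["K_other"]])
  beta <- ifelse(is_self, object$params[["beta_self"]],
                 object$params[["beta_other"]])
  sv <- subjective_value(object$model$form, newdata$reward_credits,
                         newdata$effort_level, K)
  choice_probability(beta, sv)
}

#' @export
residuals.effort_fit <- function(object, ...) {
  object$choices$work - stats::predict(object)
}

#' Simulate choices from a fitted model
#'
#' @param object An \code{effort_fit}.
#' @param nsim Number of simulated choice sets.
#' @param seed Integer seed.
#' @param design Trial table to simulate over; defaults to the fitted
#'   trials.
#' @param ... Unused.
#' @return A list of \code{nsim} data.frames, each the design plus a
#'   simulated \code{decision} column.
#' @export
simulate.effort_fit <- function(object, nsim = 1, seed = 1L,
                                design = object$choices, ...) {
  rng <- local_rng(seed)
  on.exit(rng())
  p <- stats::predict(object, design)
  lapply(seq_len(nsim), function(i) {
    out <- design
    out$decision <- ifelse(stats::runif(nrow(design)) < p, "work", "rest")
    out
  })
}

#' Plot fitted discount curves
#'
#' Subjective value of a mid-range offer across effort levels, for self
#' and other recipients, under the fitted parameters.
#'
#' @param x An \code{effort_fit}.
#' @param reward Reward level to display (credits).
#' @param ... Passed to \code{matplot}.
#' @export
plot.effort_fit <- function(x, reward = 6, ...) {
  E <- 0:5
  sv_self <- c(reward, subjective_value(x$model$form, reward, 1:5,
                                        x$params[["K_self"]]))
  sv_other <- c(reward, subjective_value(x$model$form, reward, 1:5,
                                         x$params[["K_other"]]))
  graphics::matplot(E, cbind(sv_self, sv_other), type = "b", pch = 16,
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "Effort level", ylab = "Subjective value
 (credits)",
                    main = paste("Discounting of a", reward,
                                 "credit offer"), ...)
  graphics::abline(h = rest_value(), lty = 3)
  graphics::legend("bottomleft", c("self", "other", "rest"),
                   col = c("firebrick", "steelblue", "black"),
                   lty = c(1, 1, 3), pch = c(16, 16, NA), bty = "n")
  invisible(x)
}

#' Fit every candidate model to every participant
#'
#' @param choices Stacked choice records with a \code{participant_id}
#'   column.
#' @param models List of [effort_model()] specs (default: the full
#'   twelve-model family).
#' @param n_restarts,seed,k_bounds,beta_bounds Passed to
#'   [fit_effort_model()]; each participant x model cell gets its own
#'   deterministic sub-seed.
#' @return Data.frame, one row per participant x model: parameters,
#'   log-likelihood, n_trials_used, bic, convergence flag.
#' @export
fit_model_family <- function(choices, models = enumerate_models(),
                             n_restarts = 10L, seed = 1L,
                             k_bounds = c(0, 1.5), beta_bounds = c(0, 30)) {
  ids <- unique(choices$participant_id)
  rows <- vector("list", length(ids) * length(models))
  k <- 0L
  for (i in seq_along(ids)) {
    ch <- choices[choices$participant_id == ids[i], ]
    for (j in seq_along(models)) {
      k <- k + 1L
      fit <- fit_effort_model(ch, models[[j]], k_bounds, beta_bounds,
                              n_restarts,
                              seed = seed + 7919L * i + 104729L * j)
      rows[[k]] <- data.frame(
        participant_id = ids[i], model = model_name(models[[j]]),
        n_par = length(fit$par),
        K_self = fit$params[["K_self"]], K_other = fit$params[["K_other"]],
        beta_self = fit$params[["beta_self"]],
        beta_other = fit$params[["beta_other"]],
        log_likelihood = fit$log_likelihood,
        n_trials_used = fit$n_trials_used, bic = fit$bic,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare candidate models by summed BIC
#'
#' Ranks the model family by BIC summed over participants; the lowest
#' total wins, with ties broken in favour of fewer parameters. Requires a
#' complete participant x model fit table.
#'
#' @param fits Fit table from [fit_model_family()].
#' @return An object of class \code{effort_model_comparison}: a ranking
#'   data.frame (\code{model}, \code{n_par}, \code{total_bic},
#'   \code{delta_bic}, \code{rank}) and the winning [effort_model()].
#' @export
compare_models <- function(fits) {
  tab <- table(fits$participant_id, fits$model)
  if (any(tab != 1L)) {
    gaps <- which(tab != 1L, arr.ind = TRUE)
    stop("incomplete fit table; missing or duplicated cells: ",
         paste(rownames(tab)[gaps[, 1]], colnames(tab)[gaps[, 2]],
               sep = " x ", collapse = ", "))
  }
  agg <- stats::aggregate(bic ~ model + n_par, data = fits, FUN = sum)
  names(agg)[names(agg) == "bic"] <- "total_bic"
  agg <- agg[order(agg$total_bic, agg$n_par), ]
  agg$delta_bic <- agg$total_bic - agg$total_bic[1]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  structure(
    list(ranking = agg[, c("model", "n_par", "total_bic", "delta_bic",
                           "rank")],
         winner = parse_model_name(agg$model[1]),
         n_participants = nrow(tab)),
    class = "effort_model_comparison"
  )
}

#' @export
print.effort_model_comparison <- function(x, ...) {
  cat("Model comparison over", x$n_participants,
      "participants (summed BIC, lower is better):\n")
  print(transform(x$ranking, total_bic = round(total_bic, 1),
                  delta_bic = round(delta_bic, 1)), row.names = FALSE)
  cat("Winner:", model_name(x$winner), "\n")
  invisible(x)
}

#' Parameter-recovery study for the fitting procedure
#'
#' Simulates agents with known parameters, refits the generating model,
#' and summarises how well the generating parameters are retrieved:
#' Pearson correlation, bias and RMSE per parameter, and (optionally) the
#' model-identification rate — the proportion of agents for which the
#' generating model attains the lowest BIC among the full family.
#'
#' @param n_agents Number of simulated agents.
#' @param model Generating (and refitted) model spec.
#' @param K_range True K values are drawn uniformly from this range.
#' @param beta True softmax temperature (common to all agents).
#' @param design Trial-schedule configuration.
#' @param n_restarts Restarts per fit.
#' @param seed Integer seed.
#' @param identify If \code{TRUE}, additionally fit all twelve models per
#'   agent and report the identification rate (slower).
#' @return An object of class \code{recovery_report}: per-parameter
#'   \code{correlation}, \code{bias}, \code{rmse}; \code{truth} and
#'   \code{recovered} data.frames; \code{identification_rate}.
#' @export
parameter_recovery <- function(n_agents = 50L,
                               model = effort_model("parabolic",
                                                    "separate", "shared"),
                               K_range = c(0.05, 1.0), beta = 5,
                               design = design_config(),
                               n_restarts = 10L, seed = 1L,
                               identify = FALSE) {
  rng <- local_rng(seed)
  on.exit(rng())
  K_self <- stats::runif(n_agents, K_range[1], K_range[2])
  K_other <- stats::runif(n_agents, K_range[1], K_range[2])
  if (model$k_scheme == "shared") K_other <- K_self
  sub_seeds <- sample.int(.Machine$integer.max, 3L * n_agents)
  pn <- par_names(model)
  truth <- data.frame(K_self = K_self, K_other = K_other,
                      beta_self = beta, beta_other = beta)
  rec <- matrix(NA_real_, n_agents, 4,
                dimnames = list(NULL, names(truth)))
  identified <- rep(NA, n_agents)
  for (i in seq_len(n_agents)) {
    id <- sprintf("rec%03d", i)
    des <- generate_design(design, id, seed = sub_seeds[3 * i - 2])
    ag <- agent_params(id, "control", model,
                       K_self = K_self[i], K_other = K_other[i],
                       beta_self = beta, beta_other = beta)
    ch <- simulate_agent_choices(ag, des, miss_rate = 0,
                                 seed = sub_seeds[3 * i - 1],
                                 include_force = FALSE)
    fit <- fit_effort_model(ch, model, n_restarts = n_restarts,
                            seed = sub_seeds[3 * i])
    rec[i, ] <- fit$params
    if (identify) {
      fam <- fit_model_family(ch, n_restarts = max(3L, n_restarts %/% 3L),
                              seed = sub_seeds[3 * i])
      cmp <- compare_models(fam)
      identified[i] <- identical(model_name(cmp$winner),
                                 model_name(model))
    }
  }
  recovered <- as.data.frame(rec)
  free <- unique(c(
    if (model$k_scheme == "separate") c("K_self", "K_other") else "K_self",
    if (model$beta_scheme == "separate") c("beta_self", "beta_other")
    else "beta_self"))
  stat <- function(f) vapply(free, function(p) f(truth[[p]],
                                                 recovered[[p]]),
                             numeric(1))
  structure(
    list(correlation = stat(function(t, r)
           if (stats::sd(t) == 0 || stats::sd(r) == 0) NA_real_
           else stats::cor(t, r)),
         bias = stat(function(t, r) mean(r - t)),
         rmse = stat(function(t, r) sqrt(mean((r - t)^2))),
         truth = truth, recovered = recovered,
         identification_rate = if (identify) mean(identified) else NA_real_,
         model = model, n_agents = n_agents, beta = beta, seed = seed),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery:", model_name(x$model), "-", x$n_agents,
      "agents, true beta =", x$beta, "\n")
  print(round(rbind(correlation = x$correlation, bias = x$bias,
                    rmse = x$rmse), 3))
  if (!is.na(x$identification_rate))
    cat("Model-identification rate:",
        round(x$identification_rate, 3), "\n")
  invisible(x)
}

#' Model-identification study across replicate populations
#'
#' Repeatedly simulates a population of agents from a generating model,
#' fits the full twelve-model family to every agent, and records which
#' model wins the summed-BIC comparison in each replicate population.
#'
#' @param n_populations Number of replicate populations.
#' @param n_agents Agents per population.
#' @param model Generating model spec.
#' @param K_range Uniform range for true K values.
#' @param beta True softmax temperature.
#' @param design Trial-schedule configuration.
#' @param n_restarts Restarts per fit (family fits; kept small for speed).
#' @param seed Integer seed.
#' @return List: \code{winners} (character per population),
#'   \code{rate_generating} (proportion won by the generating model),
#'   \code{model}.
#' @export
identification_study <- function(n_populations = 20L, n_agents = 40L,
                                 model = effort_model("parabolic",
                                                      "separate",
                                                      "shared"),
                                 K_range = c(0.05, 1.0), beta = 5,
                                 design = design_config(),
                                 n_restarts = 3L, seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  pop_seeds <- sample.int(.Machine$integer.max, n_populations)
  winners <- character(n_populations)
  for (p in seq_len(n_populations)) {
    rp <- local_rng(pop_seeds[p])
    K_self <- stats::runif(n_agents, K_range[1], K_range[2])
    K_other <- stats::runif(n_agents, K_range[1], K_range[2])
    sub_seeds <- sample.int(.Machine$integer.max, 2L * n_agents)
    rp()
    chs <- vector("list", n_agents)
    for (i in seq_len(n_agents)) {
      id <- sprintf("pop%02d_ag%03d", p, i)
      des <- generate_design(design, id, seed = sub_seeds[2 * i - 1])
      ag <- agent_params(id, "control", model,
                         K_self = K_self[i], K_other = K_other[i],
                         beta_self = beta, beta_other = beta)
      chs[[i]] <- simulate_agent_choices(ag, des, miss_rate = 0,
                                         seed = sub_seeds[2 * i],
                                         include_force = FALSE)
    }
    fam <- fit_model_family(do.call(rbind, chs), n_restarts = n_restarts,
                            seed = pop_seeds[p])
    winners[p] <- model_name(compare_models(fam)$winner)
  }
  list(winners = winners,
       rate_generating = mean(winners == model_name(model)),
       model = model)
}

#' Trial-level subjective-value regressor (chosen minus unchosen)
#'
#' For each non-missed trial, the signed difference between the SV of the
#' chosen and the non-chosen option under the fitted parameters:
#' work-chosen trials give \eqn{SV_{work} - 1}, rest-chosen trials give
#' \eqn{1 - SV_{work}}. Missed trials are excluded from the output and
#' returned separately (they are handled as their own regressor
#' downstream).
#'
#' @param fit An \code{effort_fit}.
#' @param choices Choice records for the same participant (defaults to
#'   the fitted trials).
#' @return Data.frame with identifying columns (\code{participant_id},
#'   \code{run}, \code{trial_index} where present), \code{recipient},
#'   \code{decision} and \code{sv_diff}; attribute \code{"missed"} holds
#'   the excluded missed-trial rows.
#' @export
sv_regressor <- function(fit, choices = fit$choices) {
  if (!is.na(fit$participant_id) &&
      "participant_id" %in% names(choices) &&
      any(choices$participant_id != fit$participant_id))
    stop("choices belong to a different participant than the fit")
  missed <- choices[choices$decision == "missed", , drop = FALSE]
  kept <- choices[choices$decision != "missed", , drop = FALSE]
  is_self <- kept$recipient == "self"
  K <- ifelse(is_self, fit$params[["K_self"]], fit$params[["K_other"]])
  sv_work <- subjective_value(fit$model$form, kept$reward_credits,
                              kept$effort_level, K)
  sv_diff <- ifelse(kept$decision == "work",
                    sv_work - rest_value(), rest_value() - sv_work)
  idc <- intersect(c("participant_id", "run", "trial_index"), names(kept))
  out <- cbind(kept[, idc, drop = FALSE],
               kept[, c("recipient", "decision"), drop = FALSE],
               sv_diff = sv_diff)
  rownames(out) <- NULL
  attr(out, "missed") <- missed
  out
}
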