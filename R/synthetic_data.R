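#' Ground-truth parameters for one synthetic participant
#'
#' @param participant_id Identifier.
#' @param group \code{"stress"} or \code{"control"}.
#' @param model An [effort_model()] generating this agent's choices.
#' @param K_self,K_other Discount-rate parameters, in [0, 1.5].
#' @param beta_self,beta_other Softmax temperatures, >= 0. Under a shared-
#'   beta model pass equal values.
#' @param svo_angle Social value orientation angle in degrees (slider
#'   measure range is about -16.26 to 61.39; higher = more prosocial).
#' @param mvc Maximum voluntary contraction in arbitrary force units.
#' @return A list of class \code{agent_params}.
#' @export
agent_params <- function(participant_id, group = c("control", "stress"),
                         model = effort_model("parabolic", "separate",
                                              "shared"),
                         K_self, K_other = K_self,
                         beta_self, beta_other = beta_self,
                         svo_angle = 19.3, mvc = 100) {
  group <- match.arg(group)
  stopifnot(inherits(model, "effort_model"))
  ks <- c(K_self, K_other)
  if (any(ks < 0) || any(ks > 1.5))
    stop("K parameters must lie in [0, 1.5]")
  if (any(c(beta_self, beta_other) < 0)) stop("beta must be non-negative")
  if (!is.finite(svo_angle)) stop("svo_angle must be finite")
  if (model$k_scheme == "shared" && K_self != K_other)
    stop("shared-K model but K_self != K_other")
  if (model$beta_scheme == "shared" && beta_self != beta_other)
    stop("shared-beta model but beta_self != beta_other")
  structure(
    list(participant_id = participant_id, group = group, model = model,
         K_self = K_self, K_other = K_other,
         beta_self = beta_self, beta_other = beta_other,
         svo_angle = svo_angle, mvc = mvc),
    class = "agent_params"
  )
}

#' Simulate one agent's choices over a trial schedule
#'
#' Each non-missed decision is a Bernoulli draw with
#' \eqn{p = P(work) = logistic(\beta_r (SV_{work} - 1))}, where the
#' recipient-appropriate K and beta are used (K_self, beta_self on self
#' trials; K_other, beta_other on other trials) and SV comes from the
#' agent's discount form. Work choices trigger a simulated grip-force
#' attempt: success yields the offered credits, failure yields none; rest
#' always yields 1 credit; missed trials yield 0.
#'
#' @param agent An [agent_params()] object.
#' @param design Trial schedule from [generate_design()].
#' @param miss_rate Probability a trial receives no response, in [0, 0.1].
#' @param skill Probability a work attempt reaches the required force.
#' @param seed Integer seed; output is deterministic given all arguments.
#' @param include_force If \code{TRUE}, simulate a grip-force trace per work
#'   trial and record its normalised area; if \code{FALSE} (cheaper, for
#'   large simulation studies) success is a direct Bernoulli(skill) draw and
#'   \code{force_auc_norm} is \code{NA}.
#' @return Data.frame of choice records: the design columns plus
#'   \code{decision} (work/rest/missed), \code{success},
#'   \code{credits_earned} and \code{force_auc_norm}.
#' @export
simulate_agent_choices <- function(agent, design, miss_rate = 0.01,
                                   skill = 0.98, seed = 1L,
                                   include_force = TRUE) {
  stopifnot(inherits(agent, "agent_params"))
  if (miss_rate < 0 || miss_rate > 0.1)
    stop("miss_rate must lie in [0, 0.1]")
  rng <- local_rng(seed)
  on.exit(rng())
  n <- nrow(design)
  is_self <- design$recipient == "self"
  K <- ifelse(is_self, agent$K_self, agent$K_other)
  beta <- ifelse(is_self, agent$beta_self, agent$beta_other)
  sv_work <- subjective_value(agent$model$form, design$reward_credits,
                              design$effort_level, K)
  p_work <- choice_probability(beta, sv_work)
  missed <- stats::runif(n) < miss_rate
  work <- stats::runif(n) < p_work
  decision <- ifelse(missed, "missed", ifelse(work, "work", "rest"))
  success <- rep(FALSE, n)
  force_auc_norm <- rep(NA_real_, n)
  for (i in which(decision == "work")) {
    if (include_force) {
      tr <- simulate_force_trace(design$effort_pct_mvc[i], agent$mvc,
                                 skill = skill,
                                 seed = NULL) # inherit scoped RNG stream
      success[i] <- tr$success
      force_auc_norm[i] <- force_auc(tr$trace, agent$mvc)
    } else {
      success[i] <- stats::runif(1) < skill
    }
  }
  credits <- integer(n)
  credits[decision == "rest"] <- 1L
  credits[decision == "work" & success] <-
    design$reward_credits[decision == "work" & success]
  out <- design
  out$decision <- decision
  out$success <- success
  out$credits_earned <- credits
  out$force_auc_norm <- force_auc_norm
  out
}

#' Simulate a 3-second grip-force trace and its success outcome
#'
#' The attempt ramps up, holds near a target level for about 1.5 s, then
#' releases. The target is above the required threshold with probability
#' \code{skill} and below it otherwise; success is then determined from the
#' trace itself: the force must stay at or above the threshold for at least
#' one contiguous second within the 3-s window.
#'
#' @param effort_pct Required effort as percent of MVC (30--70).
#' @param mvc Participant's maximum voluntary contraction (force units).
#' @param skill Probability the held force exceeds the threshold.
#' @param seed Integer seed, or \code{NULL} to draw from the current RNG
#'   stream.
#' @param hz Sampling rate of the trace in samples per second.
#' @return List with \code{trace} (data.frame \code{time}, \code{force}),
#'   \code{success} (logical) and \code{threshold} (force units).
#' @export
simulate_force_trace <- function(effort_pct, mvc, skill = 0.98,
                                 seed = NULL, hz = 50) {
  if (effort_pct < 30 || effort_pct > 70)
    stop("effort_pct must be in 30..70")
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    on.exit(rng())
  }
  threshold <- effort_pct / 100 * mvc
  time <- seq(0, 3, by = 1 / hz)
  # target hold level: slightly above threshold on skilled attempts,
  # short of it otherwise
  hit <- stats::runif(1) < skill
  level <- if (hit) threshold * stats::runif(1, 1.08, 1.20)
           else threshold * stats::runif(1, 0.70, 0.92)
  ramp_up <- 0.5; hold_end <- 2.2
  shape <- ifelse(time < ramp_up, time / ramp_up,
                  ifelse(time <= hold_end, 1,
                         pmax(0, 1 - (time - hold_end) / 0.6)))
  force <- level * shape * (1 + stats::rnorm(length(time), 0, 0.015))
  force <- pmin(pmax(force, 0), mvc)
  trace <- data.frame(time = time, force = force)
  list(trace = trace, success = trace_success(trace, threshold),
       threshold = threshold)
}

#' Judge a force trace against the squeeze rule
#'
#' Success requires the force to stay at or above \code{threshold} for at
#' least \code{min_hold} contiguous seconds within the trace window.
#'
#' @param trace Data.frame with \code{time} and \code{force}.
#' @param threshold Required force level.
#' @param min_hold Required contiguous hold duration in seconds.
#' @return Logical.
#' @export
trace_success <- function(trace, threshold, min_hold = 1) {
  above <- trace$force >= threshold
  if (!any(above)) return(FALSE)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    if (trace$time[ends[j]] - trace$time[starts[j]] >= min_hold)
      return(TRUE)
  }
  FALSE
}

#' Population configuration for synthetic-cohort simulation
#'
#' Defaults describe a two-group (stress manipulation vs. control) cohort
#' matching the study design this package models: 45 control and 46 stress
#' participants, each completing the default 150-trial schedule. Generative
#' effect sizes are the package's own choices (the source study does not
#' publish generative magnitudes): the stress group receives an additive
#' +0.15 shift on K_other, and K_other decreases with SVO angle so that
#' more prosocial participants work more for the other.
#'
#' @param n_control,n_stress Group sizes.
#' @param K_self_mean,K_self_sd Normal parameters for K_self, truncated to
#'   [0, 1.5].
#' @param K_other_mean,K_other_sd Same for K_other (before shifts).
#' @param beta_mean,beta_sd Normal parameters for the softmax temperature,
#'   truncated to [0.2, 30].
#' @param stress_K_other_shift Additive shift on K_other in the stress
#'   group (0 gives a null population).
#' @param svo_mean,svo_sd SVO angle distribution in degrees.
#' @param svo_coupling Decrease in K_other per 1 SD increase in SVO angle.
#' @param stress_baseline_rating,stress_peak_rating Perceived-stress
#'   trajectory parameters (1--7 scale): baseline level and stress-group
#'   peak increment.
#' @param cortisol_baseline,cortisol_peak Salivary cortisol trajectory
#'   parameters (nmol/l): baseline and stress-group peak increment.
#' @param rating_noise_sd,cortisol_noise_sd Measurement noise SDs.
#' @param control_peak_frac Control-group peak amplitude as a fraction of
#'   the stress group's (small but nonzero: scanning itself is mildly
#'   stressful).
#' @param miss_rate Trial miss rate.
#' @param skill Squeeze success probability.
#' @param model Generating model spec for every agent.
#' @param design Trial schedule configuration.
#' @return A list of class \code{population_config}.
#' @export
population_config <- function(n_control = 45L, n_stress = 46L,
                              K_self_mean = 0.30, K_self_sd = 0.15,
                              K_other_mean = 0.35, K_other_sd = 0.15,
                              beta_mean = 5, beta_sd = 2,
                              stress_K_other_shift = 0.15,
                              svo_mean = 19.3, svo_sd = 8.4,
                              svo_coupling = 0.08,
                              stress_baseline_rating = 2.0,
                              stress_peak_rating = 2.5,
                              cortisol_baseline = 5.0,
                              cortisol_peak = 6.0,
                              rating_noise_sd = 0.3,
                              cortisol_noise_sd = 0.8,
                              control_peak_frac = 0.15,
                              miss_rate = 0.01, skill = 0.98,
                              model = effort_model("parabolic", "separate",
                                                   "shared"),
                              design = design_config()) {
  if (n_control < 1L || n_stress < 1L) stop("group sizes must be >= 1")
  if (any(c(K_self_sd, K_other_sd, beta_sd, svo_sd,
            rating_noise_sd, cortisol_noise_sd) < 0))
    stop("standard deviations must be non-negative")
  structure(mget(names(formals(population_config))),
            class = "population_config")
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

#' Simulate a synthetic two-group cohort
#'
#' Draws ground-truth agents from the population configuration, generates
#' each agent's trial schedule and choices, and (optionally) perceived-
#' stress and cortisol series. Ground truth is returned losslessly so that
#' recovery studies can compare fitted against generating parameters.
#'
#' @param config A [population_config()].
#' @param seed Integer seed.
#' @param stress_series Simulate perceived-stress/cortisol series too?
#' @param include_force Passed to [simulate_agent_choices()].
#' @return A list of class \code{population_sim} with elements
#'   \code{agents} (data.frame of ground truth), \code{choices} (stacked
#'   choice records), and \code{stress} (long series data.frame or NULL).
#' @export
simulate_population <- function(config = population_config(), seed = 1L,
                                stress_series = TRUE,
                                include_force = TRUE) {
  stopifnot(inherits(config, "population_config"))
  rng <- local_rng(seed)
  on.exit(rng())
  n <- config$n_control + config$n_stress
  group <- rep(c("control", "stress"),
               c(config$n_control, config$n_stress))
  ids <- sprintf("sim%03d", seq_len(n))
  svo <- stats::rnorm(n, config$svo_mean, config$svo_sd)
  K_self <- rtrunc_norm(n, config$K_self_mean, config$K_self_sd, 0, 1.5)
  svo_z <- if (config$svo_sd > 0) (svo - config$svo_mean) / config$svo_sd
           else rep(0, n)
  K_other <- pmin(pmax(
    stats::rnorm(n, config$K_other_mean, config$K_other_sd) +
      config$stress_K_other_shift * (group == "stress") -
      config$svo_coupling * svo_z, 0), 1.5)
  beta <- rtrunc_norm(n, config$beta_mean, config$beta_sd, 0.2, 30)
  mvc <- stats::runif(n, 60, 140)
  if (config$model$k_scheme == "shared") K_other <- K_self
  sub_seeds <- sample.int(.Machine$integer.max, 3L * n)

  agents <- data.frame(
    participant_id = ids, group = group,
    model = model_name(config$model),
    K_self = K_self, K_other = K_other,
    beta_self = beta, beta_other = beta,
    svo_angle = svo, mvc = mvc, stringsAsFactors = FALSE
  )
  choices <- vector("list", n)
  stress <- if (stress_series) vector("list", n) else NULL
  for (i in seq_len(n)) {
    ag <- agent_params(ids[i], group[i], config$model,
                       K_self = K_self[i], K_other = K_other[i],
                       beta_self = beta[i], beta_other = beta[i],
                       svo_angle = svo[i], mvc = mvc[i])
    des <- generate_design(config$design, ids[i],
                           seed = sub_seeds[3 * i - 2])
    choices[[i]] <- simulate_agent_choices(
      ag, des, miss_rate = config$miss_rate, skill = config$skill,
      seed = sub_seeds[3 * i - 1], include_force = include_force)
    if (stress_series) {
      ss <- simulate_stress_series(ag, config, seed = sub_seeds[3 * i])
      stress[[i]] <- rbind(
        data.frame(participant_id = ids[i], series_type = "perceived_stress",
                   time_min = ss$perceived_stress$times,
                   value = ss$perceived_stress$values),
        data.frame(participant_id = ids[i], series_type = "cortisol",
                   time_min = ss$cortisol$times,
                   value = ss$cortisol$values)
      )
    }
  }
  structure(
    list(agents = agents,
         choices = do.call(rbind, choices),
         stress = if (stress_series) do.call(rbind, stress) else NULL,
         config = config, seed = seed),
    class = "population_sim"
  )
}

#' @export
print.population_sim <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$agents), "participants (",
      sum(x$agents$group == "control"), "control,",
      sum(x$agents$group == "stress"), "stress ),",
      nrow(x$choices), "trials\n")
  cat("Generating model:", x$agents$model[1], " seed:", x$seed, "\n")
  invisible(x)
}

# Timepoints (minutes relative to stress-induction onset) at which
# perceived stress was rated and saliva was sampled.
RATING_TIMES_MIN <- c(-42, 0, 11, 38, 51, 64, 94, 119)
CORTISOL_TIMES_MIN <- c(-42, 0, 38, 64, 94, 119)

#' Simulate perceived-stress and cortisol series for one participant
#'
#' Perceived stress is rated at 8 timepoints (minutes -42, 0, 11, 38, 51,
#' 64, 94, 119 relative to stress-induction onset) on a 1--7 scale;
#' cortisol is sampled at the 6 of those timepoints with saliva samples
#' (-42, 0, 38, 64, 94, 119). Trajectories are piecewise linear: flat at
#' baseline until induction onset, rising to a peak mid-session, then
#' decaying back; the stress group gets the full configured peak amplitude,
#' the control group a small fraction of it. Values are clipped to the
#' valid range (ratings to [1,7], cortisol to >= 0).
#'
#' @param agent An [agent_params()] (its \code{group} selects amplitude).
#' @param config A [population_config()] (trajectory parameters), or a
#'   list with the same trajectory fields.
#' @param seed Integer seed.
#' @param peak_time_min Minute of the trajectory peak.
#' @return List of two [stress_series()] objects: \code{perceived_stress}
#'   and \code{cortisol}.
#' @export
simulate_stress_series <- function(agent, config = population_config(),
                                   seed = 1L, peak_time_min = 51) {
  rng <- local_rng(seed)
  on.exit(rng())
  amp_frac <- if (agent$group == "stress") 1 else config$control_peak_frac
  traj <- function(times, baseline, peak) {
    amp <- peak * amp_frac
    ifelse(times <= 0, baseline,
           ifelse(times <= peak_time_min,
                  baseline + amp * times / peak_time_min,
                  baseline + amp *
                    pmax(0, 1 - (times - peak_time_min) /
                           (max(times) - peak_time_min))))
  }
  ratings <- traj(RATING_TIMES_MIN, config$stress_baseline_rating,
                  config$stress_peak_rating) +
    stats::rnorm(length(RATING_TIMES_MIN), 0, config$rating_noise_sd)
  cort <- traj(CORTISOL_TIMES_MIN, config$cortisol_baseline,
               config$cortisol_peak) +
    stats::rnorm(length(CORTISOL_TIMES_MIN), 0, config$cortisol_noise_sd)
  list(
    perceived_stress = stress_series(agent$participant_id,
                                     "perceived_stress",
                                     RATING_TIMES_MIN,
                                     pmin(pmax(ratings, 1), 7)),
    cortisol = stress_series(agent$participant_id, "cortisol",
                             CORTISOL_TIMES_MIN, pmax(cort, 0))
  )
}

#' Write or read simulated choice records as long-format CSV
#'
#' @param choices Choice-record data.frame.
#' @param path File path.
#' @export
write_choices_csv <- function(choices, path) {
  utils::write.csv(choices, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_choices_csv
#' @export
read_choices_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write ground-truth agents as JSON
#'
#' @param agents Agents data.frame from [simulate_population()].
#' @param path File path.
#' @export
write_agents_json <- function(agents, path) {
  jsonlite::write_json(agents, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_agents_json
#' @export
read_agents_json <- function(path) {
  jsonlite::fromJSON(path)
}
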