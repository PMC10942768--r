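#' Type-I-error calibration study for the inferential pipeline
#'
#' Repeatedly simulates null populations (no stress effect on K_other)
#' and records, per replicate, whether (a) the Group x Recipient x Effort
#' type-III Wald test of the mixed-effects choice regression and (b) the
#' SVO x perceived-stress interaction of the moderation analysis reject
#' at the nominal level. Under the null both rejection rates should sit
#' near \code{alpha}.
#'
#' The default configuration is a scaled-down factorial (3 reward x 3
#' effort levels, 2 repetitions, 2 runs of 18 trials; 20 participants per
#' group) so that hundreds of mixed-model fits stay cheap; the logistic
#' fits use \code{nAGQ = 0} for the same reason (see the methods
#' vignette).
#'
#' @param n_replicates Number of replicate null populations.
#' @param config A null [population_config()]
#'   (\code{stress_K_other_shift = 0}); the default is the scaled-down
#'   design above.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @param nAGQ Integrator order for the logistic fits.
#' @return List of class \code{calibration_study}: logical vectors
#'   \code{reject_choice} and \code{reject_moderation}, the two empirical
#'   rates, and exact (Clopper-Pearson) 95\% confidence intervals.
#' @export
calibration_study <- function(n_replicates = 200L, config = NULL,
                              alpha = 0.05, seed = 1L, nAGQ = 0L) {
  if (is.null(config))
    config <- population_config(
      n_control = 20L, n_stress = 20L,
      stress_K_other_shift = 0, miss_rate = 0,
      design = design_config(reward_levels = c(2L, 6L, 10L),
                             effort_levels = c(1L, 3L, 5L),
                             repetitions_per_cell = 2L, n_runs = 2L))
  if (config$stress_K_other_shift != 0)
    stop("calibration requires a null config ",
         "(stress_K_other_shift = 0)")
  rng <- local_rng(seed)
  on.exit(rng())
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  rej_choice <- rej_mod <- rep(NA, n_replicates)
  for (r in seq_len(n_replicates)) {
    pop <- simulate_population(config, seed = rep_seeds[r],
                               stress_series = TRUE,
                               include_force = FALSE)
    ch <- merge(pop$choices,
                pop$agents[, c("participant_id", "group")])
    p_choice <- tryCatch({
      reg <- suppressWarnings(suppressMessages(
        choice_regression(ch, nAGQ = nAGQ)))
      wald_p(reg, "Group:Recipient:Effort")
    }, error = function(e) NA_real_)
    rej_choice[r] <- !is.na(p_choice) && p_choice < alpha
    summ <- behaviour_summary(pop$choices)
    auc <- summarise_stress(pop$stress)
    auc <- auc[auc$series_type == "perceived_stress", ]
    dat <- merge(merge(summ, auc, by = "participant_id"),
                 pop$agents[, c("participant_id", "svo_angle")])
    mod <- moderation_simple_slopes(dat$prop_prosocial, dat$z_auc,
                                    dat$svo_angle)
    rej_mod[r] <- mod$interaction[["p"]] < alpha
  }
  ci <- function(k) as.numeric(
    stats::binom.test(k, n_replicates)$conf.int)
  structure(
    list(reject_choice = rej_choice, reject_moderation = rej_mod,
         rate_choice = mean(rej_choice),
         rate_moderation = mean(rej_mod),
         ci_choice = ci(sum(rej_choice)),
         ci_moderation = ci(sum(rej_mod)),
         alpha = alpha, n_replicates = n_replicates),
    class = "calibration_study"
  )
}

#' @export
print.calibration_study <- function(x, ...) {
  cat(sprintf(
    "Null calibration over %d replicates (nominal alpha = %.2f):\n",
    x$n_replicates, x$alpha))
  cat(sprintf("  choice three-way Wald: %.3f  [%.3f, %.3f]\n",
              x$rate_choice, x$ci_choice[1], x$ci_choice[2]))
  cat(sprintf("  SVO x stress OLS:      %.3f  [%.3f, %.3f]\n",
              x$rate_moderation, x$ci_moderation[1],
              x$ci_moderation[2]))
  invisible(x)
}
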