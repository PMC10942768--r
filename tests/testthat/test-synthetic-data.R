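test_that("dominant agents choose deterministically", {
  d <- generate_design(participant_id = "p1", seed = 7)
  never_discount <- default_agent(K_self = 0, K_other = 0, beta = 1e3,
                                  model = effort_model("parabolic",
                                                       "shared", "shared"))
  ch <- simulate_agent_choices(never_discount, d, miss_rate = 0, seed = 1,
                               include_force = FALSE)
  expect_true(all(ch$decision == "work"))  # SV_work >= 2 > 1 everywhere
  heavy <- default_agent(K_self = 1.5, K_other = 1.5, beta = 1e3,
                         model = effort_model("parabolic", "shared",
                                              "shared"))
  ch2 <- simulate_agent_choices(heavy, d, miss_rate = 0, seed = 1,
                                include_force = FALSE)
  hi_effort <- ch2$effort_level >= 3
  expect_true(all(ch2$decision[hi_effort] == "rest"))
  # at K = 1.5, rest wins exactly when R - 1.5 E^2 < 1
  should_work <- ch2$reward_credits - 1.5 * ch2$effort_level^2 > 1
  expect_equal(ch2$decision == "work", should_work)
})

test_that("Monte-Carlo work rate matches the analytic mean probability", {
  agent <- default_agent(K_self = 0.25, K_other = 0.45, beta = 3)
  d <- generate_design(participant_id = "p1", seed = 21)
  K <- ifelse(d$recipient == "self", agent$K_self, agent$K_other)
  p <- choice_probability(3, subjective_value("parabolic",
                                              d$reward_credits,
                                              d$effort_level, K))
  n_rep <- 200
  rates <- vapply(seq_len(n_rep), function(r) {
    ch <- simulate_agent_choices(agent, d, miss_rate = 0, seed = 1000 + r,
                                 include_force = FALSE)
    mean(ch$decision == "work")
  }, numeric(1))
  se <- sd(rates) / sqrt(n_rep)
  expect_lt(abs(mean(rates) - mean(p)), 3 * se + 1e-12)
})

test_that("choice records respect the credit rules", {
  agent <- default_agent(beta = 2)
  d <- generate_design(participant_id = "p1", seed = 5)
  ch <- simulate_agent_choices(agent, d, miss_rate = 0.05, seed = 2,
                               include_force = TRUE, skill = 0.9)
  expect_true(all(ch$credits_earned[ch$decision == "rest"] == 1L))
  expect_true(all(ch$credits_earned[ch$decision == "missed"] == 0L))
  worked <- ch$decision == "work"
  expect_equal(ch$credits_earned[worked & ch$success],
               ch$reward_credits[worked & ch$success])
  expect_true(all(ch$credits_earned[worked & !ch$success] == 0L))
  expect_true(all(ch$force_auc_norm[worked] > 0))
  # reproducibility
  ch2 <- simulate_agent_choices(agent, d, miss_rate = 0.05, seed = 2,
                                include_force = TRUE, skill = 0.9)
  expect_identical(ch, ch2)
})

test_that("force traces succeed iff held above threshold for 1 s", {
  t <- seq(0, 3, by = 0.02)
  hold_all <- data.frame(time = t, force = rep(1.1 * 50, length(t)))
  expect_true(trace_success(hold_all, 50))
  below <- data.frame(time = t, force = rep(0.9 * 50, length(t)))
  expect_false(trace_success(below, 50))
  # above threshold but never for a contiguous second
  blips <- data.frame(time = t, force = ifelse(t %% 1 < 0.5, 60, 10))
  expect_false(trace_success(blips, 50))
  tr <- simulate_force_trace(50, mvc = 100, skill = 1, seed = 3)
  expect_true(tr$success)
  expect_equal(tr$threshold, 50)
  tr0 <- simulate_force_trace(70, mvc = 100, skill = 0, seed = 3)
  expect_false(tr0$success)
})

test_that("simulated success rate tracks the skill parameter", {
  set.seed(99)
  succ <- vapply(1:400, function(i)
    simulate_force_trace(50, 100, skill = 0.98)$success, logical(1))
  se <- sqrt(0.98 * 0.02 / 400)
  expect_lt(abs(mean(succ) - 0.98), 3 * se + 1e-12)
})

test_that("stress series have the study's sampling schedule", {
  agent <- default_agent(group = "stress")
  ss <- simulate_stress_series(agent, population_config(), seed = 4)
  expect_length(ss$cortisol$times, 6L)
  expect_length(ss$perceived_stress$times, 8L)
  expect_equal(ss$cortisol$times, c(-42, 0, 38, 64, 94, 119))
  expect_equal(ss$perceived_stress$times,
               c(-42, 0, 11, 38, 51, 64, 94, 119))
  expect_true(all(ss$perceived_stress$values >= 1 &
                    ss$perceived_stress$values <= 7))
  expect_true(all(ss$cortisol$values >= 0))
})

test_that("zero-amplitude zero-noise series are flat with AUC = b x 161", {
  cfg <- population_config(stress_peak_rating = 0, cortisol_peak = 0,
                           rating_noise_sd = 0, cortisol_noise_sd = 0,
                           stress_baseline_rating = 2,
                           cortisol_baseline = 5)
  agent <- default_agent(group = "stress")
  ss <- simulate_stress_series(agent, cfg, seed = 1)
  expect_equal(unique(ss$perceived_stress$values), 2)
  expect_equal(unique(ss$cortisol$values), 5)
  expect_equal(auc_ground(ss$perceived_stress), 2 * 161)
  expect_equal(auc_ground(ss$cortisol), 5 * 161)
})

test_that("stress group shows larger cortisol AUC than controls", {
  cfg <- population_config()
  aucs <- vapply(1:100, function(i) {
    grp <- if (i <= 50) "stress" else "control"
    ag <- default_agent(sprintf("s%03d", i), group = grp)
    auc_ground(simulate_stress_series(ag, cfg, seed = 500 + i)$cortisol)
  }, numeric(1))
  expect_gt(mean(aucs[1:50]), mean(aucs[51:100]))
})

test_that("population simulation honours sizes, shifts and ground truth", {
  cfg <- population_config(n_control = 8, n_stress = 9)
  pop <- simulate_population(cfg, seed = 3, stress_series = TRUE,
                             include_force = FALSE)
  expect_equal(sum(pop$agents$group == "control"), 8L)
  expect_equal(sum(pop$agents$group == "stress"), 9L)
  expect_equal(nrow(pop$choices), 17L * 150L)
  # ground truth recorded losslessly and within bounds
  expect_true(all(pop$agents$K_self >= 0 & pop$agents$K_self <= 1.5))
  expect_true(all(pop$agents$K_other >= 0 & pop$agents$K_other <= 1.5))
  expect_true(all(c("K_self", "K_other", "beta_self", "svo_angle") %in%
                    names(pop$agents)))
  # stress table has both series for every participant
  expect_setequal(unique(pop$stress$series_type),
                  c("perceived_stress", "cortisol"))
  expect_equal(nrow(pop$stress), 17L * (8L + 6L))
  # reproducible
  pop2 <- simulate_population(cfg, seed = 3, stress_series = TRUE,
                              include_force = FALSE)
  expect_identical(pop$choices, pop2$choices)
})

test_that("the stress shift on K_other lowers other-trial work rates", {
  base <- population_config(n_control = 20, n_stress = 20,
                            K_self_sd = 0.05, K_other_sd = 0.05,
                            beta_sd = 0, svo_coupling = 0,
                            stress_K_other_shift = 0.3, miss_rate = 0)
  pop <- simulate_population(base, seed = 11, stress_series = FALSE,
                             include_force = FALSE)
  ch <- merge(pop$choices, pop$agents[, c("participant_id", "group")])
  other <- ch[ch$recipient == "other", ]
  rate <- tapply(other$decision == "work", other$group, mean)
  expect_gt(rate[["control"]], rate[["stress"]])
})

test_that("a null configuration produces no group difference", {
  cfg <- population_config(n_control = 30, n_stress = 30,
                           stress_K_other_shift = 0, miss_rate = 0)
  props <- unlist(lapply(1:5, function(r) {
    pop <- simulate_population(cfg, seed = 100 + r,
                               stress_series = FALSE,
                               include_force = FALSE)
    summ <- behaviour_summary(pop$choices)
    summ <- merge(summ, pop$agents[, c("participant_id", "group")])
    tapply(summ$prop_prosocial, summ$group, mean, na.rm = TRUE)
  }))
  diff_means <- mean(props[names(props) == "stress"]) -
    mean(props[names(props) == "control"])
  expect_lt(abs(diff_means), 0.05)
})

test_that("simulated cohorts round-trip through CSV and JSON", {
  cfg <- population_config(n_control = 2, n_stress = 2)
  pop <- simulate_population(cfg, seed = 8, include_force = FALSE)
  cpath <- tempfile(fileext = ".csv")
  write_choices_csv(pop$choices, cpath)
  back <- read_choices_csv(cpath)
  expect_equal(back$decision, pop$choices$decision)
  expect_equal(back$reward_credits, pop$choices$reward_credits)
  jpath <- tempfile(fileext = ".json")
  write_agents_json(pop$agents, jpath)
  ag <- read_agents_json(jpath)
  expect_equal(ag$K_other, pop$agents$K_other)
  spath <- tempfile(fileext = ".csv")
  write_stress_csv(pop$stress, spath)
  expect_equal(read_stress_csv(spath)$value, pop$stress$value)
})
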