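test_that("the likelihood matches closed forms and the product oracle", {
  ch <- sim_choices(seed = 31)
  m <- effort_model("parabolic", "separate", "shared")
  n <- sum(ch$decision != "missed")
  # beta = 0: every probability is one half
  expect_equal(
    negative_log_likelihood(m, c(K_self = 0.3, K_other = 0.8,
                                 beta_self = 0, beta_other = 0), ch),
    n * log(2))
  # single-trial closed form: Delta SV = ln 3 in favour of the choice
  one <- data.frame(participant_id = "p1", recipient = "self",
                    reward_credits = 3, effort_level = 1,
                    decision = "work")
  K_star <- 2 - log(3)  # parabolic: SV = 3 - K, want SV - 1 = ln 3
  expect_equal(
    negative_log_likelihood(m, c(K_self = K_star, K_other = K_star,
                                 beta_self = 1, beta_other = 1), one),
    -log(0.75))
  # brute-force product oracle over random parameter draws
  set.seed(77)
  small <- ch[sample(nrow(ch), 30), ]
  for (form in c("linear", "hyperbolic", "parabolic")) {
    mf <- effort_model(form, "separate", "separate")
    for (i in 1:7) {
      p <- c(K_self = runif(1, 0, 1.5), K_other = runif(1, 0, 1.5),
             beta_self = runif(1, 0, 10), beta_other = runif(1, 0, 10))
      expect_equal(
        negative_log_likelihood(mf, p, small),
        nll_product_oracle(form, p[1], p[2], p[3], p[4], small),
        tolerance = 1e-9)
    }
  }
})

test_that("the likelihood is order-invariant and excludes missed trials", {
  ch <- sim_choices(seed = 32, miss_rate = 0.05)
  m <- effort_model("hyperbolic", "shared", "shared")
  p <- c(K = 0.4, beta = 3)
  set.seed(1)
  perm <- ch[sample(nrow(ch)), ]
  expect_equal(negative_log_likelihood(m, p, ch),
               negative_log_likelihood(m, p, perm))
  expect_equal(negative_log_likelihood(m, p, ch),
               negative_log_likelihood(m, p,
                                       ch[ch$decision != "missed", ]))
  all_missed <- transform(ch, decision = "missed")
  expect_error(negative_log_likelihood(m, p, all_missed), "missed")
})

test_that("BIC follows k ln n - 2 logL", {
  expect_equal(bic_score(3, 150, -80), 175.032, tolerance = 1e-3)
  expect_equal(bic_score(1, 1, 0), 0)
  expect_lt(bic_score(2, 100, -50), bic_score(4, 100, -50))
  expect_error(bic_score(3, 0, -10), "n_obs")
})

test_that("fitting is deterministic, bounded and beats the truth's NLL", {
  agent <- default_agent(K_self = 0.2, K_other = 0.5, beta = 5)
  ch <- sim_choices(seed = 33, agent = agent)
  m <- agent$model
  f1 <- fit_effort_model(ch, m, n_restarts = 8, seed = 9)
  f2 <- fit_effort_model(ch, m, n_restarts = 8, seed = 9)
  expect_identical(f1[names(f1) != "choices"], f2[names(f2) != "choices"])
  expect_true(all(f1$par[c("K_self", "K_other")] >= 0))
  expect_true(all(f1$par[c("K_self", "K_other")] <= 1.5))
  # fitted optimum is at least as good as the generating parameters
  nll_true <- negative_log_likelihood(m, c(K_self = 0.2, K_other = 0.5,
                                           beta_self = 5, beta_other = 5),
                                      ch)
  expect_lte(-f1$log_likelihood, nll_true + 1e-8)
  expect_equal(f1$bic,
               bic_score(3, f1$n_trials_used, f1$log_likelihood))
  expect_equal(f1$n_trials_used, sum(ch$decision != "missed"))
})

test_that("an agent that always works fits K at the lower bound", {
  d <- generate_design(participant_id = "p1", seed = 41)
  ch <- transform(d, decision = "work")
  f <- fit_effort_model(ch, effort_model("parabolic", "shared", "shared"),
                        n_restarts = 6, seed = 2)
  expect_lt(f$par[["K"]], 0.02)
})

test_that("recipient asymmetry in K is recovered in direction", {
  hits <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    agent <- default_agent(K_self = 0.2, K_other = 0.5, beta = 5)
    ch <- sim_choices(seed = 600 + s, agent = agent)
    f <- fit_effort_model(ch, agent$model, n_restarts = 4,
                          seed = 700 + s)
    if (f$par[["K_other"]] > f$par[["K_self"]]) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("separate-K fits never lose to nested shared-K fits", {
  for (s in 1:5) {
    ch <- sim_choices(seed = 50 + s,
                      agent = default_agent(K_self = 0.3, K_other = 0.4,
                                            beta = 4))
    for (form in c("linear", "hyperbolic", "parabolic")) {
      shared <- fit_effort_model(ch, effort_model(form, "shared",
                                                  "shared"),
                                 n_restarts = 6, seed = s)
      sep <- fit_effort_model(ch, effort_model(form, "separate",
                                               "shared"),
                              n_restarts = 6, seed = s)
      expect_lte(-sep$log_likelihood, -shared$log_likelihood + 1e-6)
    }
  }
})

test_that("effort_fit methods are coherent", {
  agent <- default_agent()
  ch <- sim_choices(seed = 61, agent = agent)
  f <- fit_effort_model(ch, n_restarts = 6, seed = 3)
  expect_s3_class(f, "effort_fit")
  expect_named(coef(f), c("K_self", "K_other", "beta"))
  expect_length(coef(f, full = TRUE), 4L)
  ll <- logLik(f)
  expect_equal(as.numeric(ll), f$log_likelihood)
  expect_equal(attr(ll, "df"), 3L)
  expect_equal(BIC(ll), f$bic)
  p <- predict(f)
  expect_length(p, f$n_trials_used)
  expect_true(all(p > 0 & p <= 1))
  expect_true(any(p > 0.01 & p < 0.99))
  expect_equal(residuals(f), f$choices$work - p)
  sims <- simulate(f, nsim = 3, seed = 4)
  expect_length(sims, 3L)
  expect_true(all(sims[[1]]$decision %in% c("work", "rest")))
  expect_output(print(f), "parabolic:K2:B1")
  expect_output(summary(f), "Work rate self")
})

test_that("family fits are complete and the comparison ranks by BIC", {
  pop <- simulate_population(
    population_config(n_control = 3, n_stress = 3),
    seed = 13, stress_series = FALSE, include_force = FALSE)
  fam <- fit_model_family(pop$choices, n_restarts = 3, seed = 5)
  expect_equal(nrow(fam), 6L * 12L)
  cmp <- compare_models(fam)
  expect_s3_class(cmp, "effort_model_comparison")
  expect_equal(cmp$ranking$rank, 1:12)
  expect_true(all(diff(cmp$ranking$total_bic) >= 0))
  expect_equal(cmp$ranking$total_bic[1],
               min(tapply(fam$bic, fam$model, sum)))
  # missing cells are an error naming the gap
  expect_error(compare_models(fam[-1, ]), "incomplete")
})

test_that("model-comparison ties break toward fewer parameters", {
  fits <- data.frame(
    participant_id = "p1",
    model = c("parabolic:K2:B1", "parabolic:K2:B2"),
    n_par = c(3L, 4L), bic = c(100, 100))
  cmp <- compare_models(fits)
  expect_equal(model_name(cmp$winner), "parabolic:K2:B1")
})

test_that("sv_regressor signs the chosen-minus-unchosen difference", {
  # indifference case: parabolic K = 0.36 makes a 10-credit level-5 offer
  # worth exactly the rest option
  ch <- data.frame(participant_id = "p1", run = 1, trial_index = 1:3,
                   recipient = c("self", "self", "other"),
                   reward_credits = c(10, 2, 6),
                   effort_level = c(5, 1, 2),
                   decision = c("work", "rest", "missed"))
  f <- structure(
    list(model = effort_model("parabolic", "shared", "shared"),
         params = c(K_self = 0.36, K_other = 0.36, beta_self = 5,
                    beta_other = 5),
         participant_id = "p1", choices = ch),
    class = "effort_fit")
  reg <- sv_regressor(f, ch)
  expect_equal(nrow(reg), 2L)          # missed trial excluded
  expect_equal(reg$sv_diff[1], 0.0)    # 10 - 0.36*25 = 1 = rest
  expect_equal(reg$sv_diff[2], 1 - (2 - 0.36))  # rest chosen
  expect_equal(nrow(attr(reg, "missed")), 1L)
  bad <- transform(ch, participant_id = "p2")
  expect_error(sv_regressor(f, bad), "different participant")
})

test_that("rest-chosen zero-K regressor equals one minus reward", {
  ch <- data.frame(participant_id = "p1", recipient = "self",
                   reward_credits = 2, effort_level = 1,
                   decision = "rest")
  f <- structure(
    list(model = effort_model("parabolic", "shared", "shared"),
         params = c(K_self = 0, K_other = 0, beta_self = 1,
                    beta_other = 1),
         participant_id = "p1", choices = ch),
    class = "effort_fit")
  expect_equal(sv_regressor(f, ch)$sv_diff, -1.0)
})
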