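# Shared fixtures: small deterministic designs and agents used across
# test files. Everything is generated in code; no stored data.

default_agent <- function(id = "p1", group = "control", K_self = 0.2,
                          K_other = 0.5, beta = 5,
                          model = effort_model("parabolic", "separate",
                                               "shared")) {
  agent_params(id, group, model, K_self = K_self, K_other = K_other,
               beta_self = beta, beta_other = beta)
}

sim_choices <- function(seed = 1, agent = default_agent(),
                        miss_rate = 0, include_force = FALSE) {
  d <- generate_design(participant_id = agent$participant_id,
                       seed = seed)
  simulate_agent_choices(agent, d, miss_rate = miss_rate, seed = seed + 1,
                         include_force = include_force)
}

# Independent brute-force oracle for the likelihood: per-trial product of
# probabilities computed with plain arithmetic, no shared code path with
# negative_log_likelihood().
nll_product_oracle <- function(form, K_self, K_other, beta_self,
                               beta_other, choices) {
  prob_log <- 0
  for (i in seq_len(nrow(choices))) {
    if (choices$decision[i] == "missed") next
    K <- if (choices$recipient[i] == "self") K_self else K_other
    b <- if (choices$recipient[i] == "self") beta_self else beta_other
    R <- choices$reward_credits[i]; E <- choices$effort_level[i]
    sv <- switch(form,
                 linear = R - K * E,
                 hyperbolic = R / (1 + K * E),
                 parabolic = R - K * E^2)
    p_work <- 1 / (1 + exp(-b * (sv - 1)))
    p <- if (choices$decision[i] == "work") p_work else 1 - p_work
    prob_log <- prob_log + log(max(p, 1e-12))
  }
  -prob_log
}

# Fine-grid trapezoid quadrature of the piecewise-linear interpolant of
# (t, v): an independent oracle for the closed-form AUC.
quadrature_oracle <- function(t, v, n_grid = 200001) {
  grid <- sort(unique(c(seq(min(t), max(t), length.out = n_grid), t)))
  y <- approx(t, v, xout = grid)$y
  sum((y[-length(y)] + y[-1]) / 2 * diff(grid))
}
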