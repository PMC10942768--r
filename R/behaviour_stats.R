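#' Proportion of prosocial work choices
#'
#' Other-benefitting work choices divided by all work choices, across all
#' reward and effort levels. Rest and missed trials do not enter either
#' count, so the measure separates prosocial allocation of effort from any
#' general decline in willingness to work.
#'
#' @param choices Choice records for one participant.
#' @return Proportion in [0, 1], or \code{NA} (with a warning) if the
#'   participant made no work choices at all.
#' @export
proportion_prosocial <- function(choices) {
  work <- choices[choices$decision == "work", , drop = FALSE]
  if (nrow(work) == 0L) {
    warning("no work choices; proportion prosocial undefined")
    return(NA_real_)
  }
  sum(work$recipient == "other") / nrow(work)
}

#' Squeeze success rate
#'
#' Percent of work choices on which the required force level was reached.
#'
#' @param choices Choice records for one participant.
#' @return Percent in [0, 100].
#' @export
success_rate <- function(choices) {
  work <- choices[choices$decision == "work", , drop = FALSE]
  if (nrow(work) == 0L) stop("no work choices; success rate undefined")
  100 * mean(work$success)
}

#' Normalised force area under the curve
#'
#' Trapezoidal area of force/MVC over the force window — the cumulated
#' effort actually exerted on a trial, normalised to the participant's
#' strength.
#'
#' @param trace Data.frame with \code{time} (seconds) and \code{force}.
#' @param mvc Participant's maximum voluntary contraction, > 0.
#' @return Area in (fraction of MVC) x seconds.
#' @export
force_auc <- function(trace, mvc) {
  if (mvc <= 0) stop("mvc must be positive")
  y <- trace$force / mvc
  t <- trace$time
  sum((y[-length(y)] + y[-1]) / 2 * diff(t))
}

#' Per-participant behavioural summary table
#'
#' @param choices Stacked choice records with \code{participant_id}.
#' @return Data.frame: participant_id, prop_prosocial, n_work_self,
#'   n_work_other, success_rate, mean_force_auc_norm.
#' @export
behaviour_summary <- function(choices) {
  ids <- unique(choices$participant_id)
  do.call(rbind, lapply(ids, function(id) {
    ch <- choices[choices$participant_id == id, ]
    work <- ch[ch$decision == "work", ]
    data.frame(
      participant_id = id,
      prop_prosocial = if (nrow(work)) suppressWarnings(
        proportion_prosocial(ch)) else NA_real_,
      n_work_self = sum(work$recipient == "self"),
      n_work_other = sum(work$recipient == "other"),
      success_rate = if (nrow(work)) success_rate(ch) else NA_real_,
      mean_force_auc_norm = if (nrow(work))
        mean(work$force_auc_norm, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE)
  }))
}

#' Mixed-effects regression of trial-level work/rest choices
#'
#' Fits the study-style mixed-effects logistic regression: work (1) vs.
#' rest (0) on Group, Recipient, Effort and Reward with all interactions
#' up to three-way as fixed effects, and a random intercept plus a random
#' Recipient slope per participant. Effort and Reward enter as categorical
#' factors; all factors use sum-to-zero contrasts so the type-III Wald
#' chi-square tests (via \code{car::Anova}) are meaningful. Missed trials
#' are dropped. The same machinery fits a gaussian model of the force
#' outcome when \code{outcome = "force"}.
#'
#' @param choices Stacked choice records with \code{participant_id} and a
#'   \code{group} column (or supply \code{groups}).
#' @param groups Optional data.frame (participant_id, group) to merge in.
#' @param outcome \code{"choice"} (logistic on work/rest) or
#'   \code{"force"} (linear on \code{force_auc_norm}, work trials only).
#' @param max_order Highest interaction order among the four fixed
#'   effects (default 3, the study's parsimonious model).
#' @param nAGQ Integrator order for the logistic fit; 1 is the Laplace
#'   default, 0 is faster and used for large calibration studies.
#' @return List of class \code{choice_regression}: \code{fit} (the merMod
#'   object), \code{wald} (type-III chi-square table), \code{coef},
#'   \code{vcov}, \code{singular} flag.
#' @export
choice_regression <- function(choices, groups = NULL,
                              outcome = c("choice", "force"),
                              max_order = 3L, nAGQ = 1L) {
  outcome <- match.arg(outcome)
  dat <- choices[choices$decision != "missed", , drop = FALSE]
  if (!is.null(groups))
    dat <- merge(dat, groups[, c("participant_id", "group")],
                 by = "participant_id")
  need <- c("participant_id", "group", "recipient", "effort_level",
            "reward_credits", "decision")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("regression data missing columns: ",
         paste(miss, collapse = ", "))
  if (length(unique(dat$participant_id)) < 2L)
    stop("insufficient grouping: need >= 2 participants for random ",
         "effects")
  dat$Group <- factor(dat$group)
  dat$Recipient <- factor(dat$recipient)
  dat$Effort <- factor(dat$effort_level)
  dat$Reward <- factor(dat$reward_credits)
  for (f in c("Group", "Recipient", "Effort", "Reward"))
    stats::contrasts(dat[[f]]) <- stats::contr.sum(nlevels(dat[[f]]))
  fx <- sprintf("(Group + Recipient + Effort + Reward)^%d", max_order)
  if (outcome == "choice") {
    dat$work <- as.integer(dat$decision == "work")
    fml <- stats::as.formula(paste("work ~", fx,
                                   "+ (1 + Recipient | participant_id)"))
    fit <- lme4::glmer(fml, data = dat, family = stats::binomial(),
                       nAGQ = nAGQ,
                       control = lme4::glmerControl(
                         optimizer = "bobyqa",
                         calc.derivs = FALSE))
  } else {
    dat <- dat[dat$decision == "work" & !is.na(dat$force_auc_norm), ]
    fml <- stats::as.formula(paste("force_auc_norm ~", fx,
                                   "+ (1 + Recipient | participant_id)"))
    fit <- lme4::lmer(fml, data = dat,
                      control = lme4::lmerControl(optimizer = "bobyqa",
                                                  calc.derivs = FALSE))
  }
  singular <- lme4::isSingular(fit)
  conv_msgs <- fit@optinfo$conv$lme4$messages
  wald <- car::Anova(fit, type = 3)
  structure(
    list(fit = fit, wald = wald,
         coef = lme4::fixef(fit),
         vcov = as.matrix(stats::vcov(fit)),
         singular = singular,
         convergence_messages = conv_msgs,
         data = dat, outcome = outcome),
    class = "choice_regression"
  )
}

#' @export
print.choice_regression <- function(x, ...) {
  cat("Mixed-effects", if (x$outcome == "choice") "logistic" else
    "linear", "regression,", length(unique(x$data$participant_id)),
    "participants,", nrow(x$data), "trials\n")
  if (x$singular) cat("NOTE: fit is singular\n")
  if (length(x$convergence_messages))
    cat("NOTE:", paste(x$convergence_messages, collapse = "; "), "\n")
  cat("\nType-III Wald chi-square tests:\n")
  print(x$wald)
  invisible(x)
}

#' Wald p-value for one term of a choice regression
#'
#' @param reg A [choice_regression()] result.
#' @param term Row name in the Wald table, e.g.
#'   \code{"Group:Recipient:Effort"}.
#' @return The p-value.
#' @export
wald_p <- function(reg, term) {
  w <- reg$wald
  if (!term %in% rownames(w))
    stop("term '", term, "' not in the model; available: ",
         paste(rownames(w), collapse = ", "))
  w[term, "Pr(>Chisq)"]
}

#' Moderation analysis with simple-slopes probing
#'
#' Ordinary least squares of \code{y} on \code{x}, the moderator \code{m}
#' and their product, followed by simple slopes of \code{x} evaluated at
#' the moderator's sample mean minus and plus one sample SD. The slope at
#' probe \eqn{m_0} is \eqn{b_x + b_{xm} m_0}; its standard error comes
#' from the linear-combination quadratic form of the coefficient
#' covariance, with two-sided p-values from the t distribution on the
#' residual degrees of freedom.
#'
#' Typical use: \code{y} = proportion of prosocial choices, \code{x} =
#' z-scored perceived-stress AUC, \code{m} = SVO angle in degrees.
#'
#' @param y Outcome vector.
#' @param x Focal predictor.
#' @param m Moderator.
#' @param probes Moderator values at which to evaluate the simple slope;
#'   default \code{mean(m) - sd(m)} and \code{mean(m) + sd(m)}.
#' @return Object of class \code{moderation_result}: \code{coef},
#'   \code{vcov}, \code{interaction} (estimate, se, p for the product
#'   term), \code{slopes} data.frame (probe, estimate, se, t, df, p).
#' @export
moderation_simple_slopes <- function(y, x, m, probes = NULL) {
  keep <- stats::complete.cases(y, x, m)
  y <- y[keep]; x <- x[keep]; m <- m[keep]
  if (is.null(probes))
    probes <- c(mean(m) - stats::sd(m), mean(m) + stats::sd(m))
  fit <- stats::lm(y ~ x * m)
  if (fit$rank < 4L)
    stop("rank-deficient moderation model; predictors are collinear")
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  df <- fit$df.residual
  ct <- summary(fit)$coefficients
  slopes <- do.call(rbind, lapply(probes, function(m0) {
    cvec <- c(0, 1, 0, m0)  # intercept, x, m, x:m
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- if (se > 0) est / se else Inf
    data.frame(probe = m0, estimate = est, se = se, t = tval, df = df,
               p = if (se > 0) 2 * stats::pt(-abs(tval), df) else 0)
  }))
  structure(
    list(coef = b, vcov = V, fit = fit,
         interaction = c(estimate = ct["x:m", 1], se = ct["x:m", 2],
                         p = ct["x:m", 4]),
         slopes = slopes, probes = probes,
         m_mean = mean(m), m_sd = stats::sd(m), n = length(y)),
    class = "moderation_result"
  )
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf(
    "Moderation (n = %d): interaction B = %.3f, SE = %.3f, p = %.4g\n",
    x$n, x$interaction["estimate"], x$interaction["se"],
    x$interaction["p"]))
  cat(sprintf("Moderator mean = %.2f, SD = %.2f\n", x$m_mean, x$m_sd))
  cat("Simple slopes at the probes:\n")
  print(transform(x$slopes, probe = round(probe, 2),
                  estimate = round(estimate, 3), se = round(se, 3),
                  t = round(t, 2), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Recipient-by-group contrasts at each effort level
#'
#' Follow-up to the three-way Group x Recipient x Effort interaction:
#' tests the Group x Recipient interaction within each effort level, on
#' the fixed-effect (logit) scale at the factor average of Reward, with
#' Bonferroni correction over the effort levels.
#'
#' @param reg A [choice_regression()] result (choice outcome).
#' @return Data.frame: effort_level, estimate (interaction contrast on
#'   the logit scale), se, z, p, p_bonferroni.
#' @export
group_recipient_by_effort <- function(reg) {
  b <- reg$coef; V <- reg$vcov
  dat <- reg$data
  efforts <- levels(dat$Effort)
  out <- do.call(rbind, lapply(efforts, function(e) {
    # contrast: (stress - control) x (self - other) at this effort,
    # averaged over reward levels; build via the design-matrix rows of a
    # reference grid
    grid <- expand.grid(Group = levels(dat$Group),
                        Recipient = levels(dat$Recipient),
                        Effort = e, Reward = levels(dat$Reward),
                        work = 0)
    for (f in c("Group", "Recipient", "Effort", "Reward")) {
      grid[[f]] <- factor(grid[[f]], levels = levels(dat[[f]]))
      stats::contrasts(grid[[f]]) <-
        stats::contrasts(dat[[f]])
    }
    M <- stats::model.matrix(stats::delete.response(
      stats::terms(lme4::nobars(stats::formula(reg$fit)))), grid)
    w <- with(grid,
              ifelse(Group == levels(dat$Group)[1], -1, 1) *
                ifelse(Recipient == levels(dat$Recipient)[1], -1, 1))
    cvec <- colSums(M * w) / (nlevels(dat$Reward) * 1)
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    z <- est / se
    data.frame(effort_level = e, estimate = est, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  }))
  out$p_bonferroni <- pmin(1, out$p * length(efforts))
  rownames(out) <- NULL
  out
}
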