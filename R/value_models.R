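#' Effort-discounted subjective value of a work offer
#'
#' Computes the subjective value (SV), in credits, of an offer of
#' \code{reward} credits at integer effort level \code{effort_level}
#' (0 = rest, 1--5 = 30--70\% of maximum voluntary contraction), under one
#' of three discount functional forms:
#' \describe{
#'   \item{linear}{\eqn{SV = R - K E}}
#'   \item{hyperbolic}{\eqn{SV = R / (1 + K E)}}
#'   \item{parabolic}{\eqn{SV = R - K E^2}}
#' }
#' Effort enters as the integer level, not as a fraction of MVC: under the
#' conventional discount-rate bound \eqn{K \in [0, 1.5]} only level coding
#' gives behaviourally meaningful indifference points (see the methods
#' vignette).
#'
#' @param form One of \code{"linear"}, \code{"hyperbolic"}, \code{"parabolic"}.
#' @param reward Reward in credits (numeric vector, >= 1).
#' @param effort_level Integer effort level(s), 0--5. Vectorised with
#'   \code{reward}.
#' @param K Discount-rate parameter, >= 0.
#' @return Numeric vector of subjective values in credits.
#' @examples
#' subjective_value("parabolic", reward = 10, effort_level = 5, K = 0.36)
#' subjective_value("hyperbolic", reward = 6, effort_level = 2, K = 0.5)
#' @export
subjective_value <- function(form = c("linear", "hyperbolic", "parabolic"),
                             reward, effort_level, K) {
  form <- match.arg(form)
  if (any(K < 0)) stop("discount parameter K must be non-negative")
  if (any(effort_level < 0)) stop("effort_level must be non-negative")
  if (any(reward < 1)) stop("reward must be at least 1 credit")
  switch(form,
    linear     = reward - K * effort_level,
    hyperbolic = reward / (1 + K * effort_level),
    parabolic  = reward - K * effort_level^2
  )
}

#' Subjective value of the rest option
#'
#' The rest option is fixed at one credit for no effort; at effort level 0
#' no discount applies under any functional form, so its SV is 1 credit.
#'
#' @return 1.0
#' @export
rest_value <- function() 1.0

#' Softmax probability of choosing the work offer
#'
#' Binary softmax (logistic) choice rule:
#' \eqn{P(work) = 1 / (1 + e^{-\beta (SV_{work} - SV_{rest})})}.
#' Overflow-safe; at \code{beta = 0} the rule is indifferent (P = 0.5).
#'
#' @param beta Softmax inverse-temperature, >= 0. Higher values make choice
#'   more deterministic in the SV difference.
#' @param sv_work Subjective value of the work offer.
#' @param sv_rest Subjective value of the rest offer (default 1 credit).
#' @return Probability of choosing work, in (0, 1) for finite inputs.
#' @examples
#' choice_probability(1, sv_work = 1 + log(3), sv_rest = 1) # 0.75
#' @export
choice_probability <- function(beta, sv_work, sv_rest = rest_value()) {
  if (any(beta < 0)) stop("beta must be non-negative")
  stats::plogis(beta * (sv_work - sv_rest))
}

#' Specify one candidate effort-discounting choice model
#'
#' A model is one cell of the 3 x 2 x 2 family: discount form (linear,
#' hyperbolic, parabolic) crossed with a shared or recipient-specific
#' discount parameter K and a shared or recipient-specific softmax
#' temperature beta.
#'
#' @param form Discount functional form.
#' @param k_scheme \code{"shared"} (one K) or \code{"separate"}
#'   (K_self, K_other).
#' @param beta_scheme \code{"shared"} (one beta) or \code{"separate"}
#'   (beta_self, beta_other).
#' @return An object of class \code{effort_model}.
#' @seealso [enumerate_models()], [fit_effort_model()]
#' @export
effort_model <- function(form = c("linear", "hyperbolic", "parabolic"),
                         k_scheme = c("shared", "separate"),
                         beta_scheme = c("shared", "separate")) {
  form <- match.arg(form)
  k_scheme <- match.arg(k_scheme)
  beta_scheme <- match.arg(beta_scheme)
  structure(
    list(form = form, k_scheme = k_scheme, beta_scheme = beta_scheme),
    class = "effort_model"
  )
}

#' @export
print.effort_model <- function(x, ...) {
  cat("Effort-discounting choice model:", model_name(x), "\n")
  cat("  discount form :", x$form, "\n")
  cat("  K scheme      :", x$k_scheme,
      if (x$k_scheme == "separate") "(K_self, K_other)" else "(one K)", "\n")
  cat("  beta scheme   :", x$beta_scheme,
      if (x$beta_scheme == "separate") "(beta_self, beta_other)" else
        "(one beta)", "\n")
  cat("  free parameters:", n_params(x), "\n")
  invisible(x)
}

#' Number of free parameters of a model spec
#'
#' @param model An \code{effort_model}.
#' @return Integer: (1 or 2 for K) + (1 or 2 for beta).
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "effort_model"))
  (if (model$k_scheme == "separate") 2L else 1L) +
    (if (model$beta_scheme == "separate") 2L else 1L)
}

#' Short canonical name of a model spec
#'
#' Names follow the pattern \code{"<form>:K<1|2>:B<1|2>"}, e.g. the
#' recipient-specific parabolic model with one temperature is
#' \code{"parabolic:K2:B1"}.
#'
#' @param model An \code{effort_model}.
#' @return A character scalar.
#' @export
model_name <- function(model) {
  stopifnot(inherits(model, "effort_model"))
  paste0(model$form,
         ":K", if (model$k_scheme == "separate") 2L else 1L,
         ":B", if (model$beta_scheme == "separate") 2L else 1L)
}

#' Parse a canonical model name back into a spec
#'
#' @param name Name as produced by [model_name()].
#' @return An \code{effort_model}.
#' @export
parse_model_name <- function(name) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L ||
      !parts[2] %in% c("K1", "K2") || !parts[3] %in% c("B1", "B2"))
    stop("not a valid model name: ", name)
  effort_model(
    form = parts[1],
    k_scheme = if (parts[2] == "K2") "separate" else "shared",
    beta_scheme = if (parts[3] == "B2") "separate" else "shared"
  )
}

#' Enumerate the full twelve-model family
#'
#' The full cross of 3 discount forms x \{shared, separate\} K x
#' \{shared, separate\} beta.
#'
#' @return A list of 12 distinct \code{effort_model} objects, named by
#'   [model_name()].
#' @export
enumerate_models <- function() {
  grid <- expand.grid(
    form = c("linear", "hyperbolic", "parabolic"),
    k_scheme = c("shared", "separate"),
    beta_scheme = c("shared", "separate"),
    stringsAsFactors = FALSE
  )
  models <- lapply(seq_len(nrow(grid)), function(i)
    effort_model(grid$form[i], grid$k_scheme[i], grid$beta_scheme[i]))
  names(models) <- vapply(models, model_name, character(1))
  models
}
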