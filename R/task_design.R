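#' Design configuration for the work/rest effort task
#'
#' The default configuration reproduces the task structure: 5 reward levels
#' (2, 4, 6, 8, 10 credits) x 5 effort levels (30--70\% MVC, coded 1--5) x
#' 3 repetitions x 2 recipients (self, other) = 150 trials, split into 6
#' runs of 25. The rest option (1 credit, effort level 0) is implicit on
#' every trial and is not a row in the schedule.
#'
#' @param reward_levels Integer reward levels in credits.
#' @param effort_levels Integer effort levels (1--5).
#' @param repetitions_per_cell Presentations of each
#'   (recipient, reward, effort) cell.
#' @param recipients Recipient conditions.
#' @param n_runs Number of runs; total trials must divide evenly into runs.
#' @param max_consecutive_same_recipient Pseudorandomisation constraint: a
#'   shuffle is rejected if more than this many consecutive trials share a
#'   recipient.
#' @return A list of class \code{design_config}.
#' @export
design_config <- function(reward_levels = c(2L, 4L, 6L, 8L, 10L),
                          effort_levels = 1:5,
                          repetitions_per_cell = 3L,
                          recipients = c("self", "other"),
                          n_runs = 6L,
                          max_consecutive_same_recipient = 4L) {
  n_trials <- length(reward_levels) * length(effort_levels) *
    repetitions_per_cell * length(recipients)
  if (n_trials %% n_runs != 0L)
    stop("inconsistent design: ", n_trials, " trials (",
         length(reward_levels), " rewards x ", length(effort_levels),
         " efforts x ", repetitions_per_cell, " repetitions x ",
         length(recipients), " recipients) do not divide into ",
         n_runs, " runs")
  structure(
    list(reward_levels = as.integer(reward_levels),
         effort_levels = as.integer(effort_levels),
         repetitions_per_cell = as.integer(repetitions_per_cell),
         recipients = as.character(recipients),
         n_runs = as.integer(n_runs),
         trials_per_run = as.integer(n_trials / n_runs),
         max_consecutive_same_recipient =
           as.integer(max_consecutive_same_recipient)),
    class = "design_config"
  )
}

#' Map an effort level to percent of maximum voluntary contraction
#'
#' Level 0 encodes rest (no squeeze); levels 1--5 map to 30, 40, 50, 60,
#' 70\% of the participant's MVC (pct = 20 + 10 * level).
#'
#' @param level Integer vector with values in 0--5.
#' @return Percent of MVC.
#' @examples
#' effort_level_to_pct(2) # 40
#' @export
effort_level_to_pct <- function(level) {
  if (any(is.na(level)) || any(level != as.integer(level)) ||
      any(level < 0L) || any(level > 5L))
    stop("effort level must be an integer in 0..5")
  ifelse(level == 0L, 0, 20 + 10 * level)
}

#' Generate a pseudorandomised factorial trial schedule
#'
#' Builds the fully crossed (recipient x reward x effort) cell set with the
#' configured repetitions, then applies a seeded uniform shuffle, re-drawn
#' until no more than \code{max_consecutive_same_recipient} consecutive
#' trials share a recipient, and splits the sequence into runs.
#'
#' @param config A [design_config()].
#' @param participant_id Identifier written into every row.
#' @param seed Integer seed; the schedule is deterministic given
#'   (config, seed).
#' @return A data.frame with columns \code{participant_id}, \code{run},
#'   \code{trial_index} (within run), \code{recipient},
#'   \code{reward_credits}, \code{effort_level}, \code{effort_pct_mvc}.
#' @examples
#' d <- generate_design(design_config(), participant_id = "p01", seed = 1)
#' nrow(d) # 150
#' @export
generate_design <- function(config = design_config(),
                            participant_id = "sim", seed = 1L) {
  stopifnot(inherits(config, "design_config"))
  cells <- expand.grid(
    recipient = config$recipients,
    reward_credits = config$reward_levels,
    effort_level = config$effort_levels,
    rep = seq_len(config$repetitions_per_cell),
    stringsAsFactors = FALSE
  )
  n <- nrow(cells)
  rng <- local_rng(seed)
  on.exit(rng())
  max_run_len <- config$max_consecutive_same_recipient
  # draw the recipient sequence under the streak constraint (sequential
  # urn sampling; rare dead-ends are retried), then shuffle each
  # recipient's cells into its slots
  rec_seq <- NULL
  for (attempt in 1:1000) {
    remaining <- table(cells$recipient)
    seq_try <- character(n)
    last <- ""; streak <- 0L; ok <- TRUE
    for (t in seq_len(n)) {
      allowed <- names(remaining)[remaining > 0L]
      if (streak >= max_run_len) allowed <- setdiff(allowed, last)
      if (!length(allowed)) { ok <- FALSE; break }
      pick <- if (length(allowed) == 1L) allowed else
        sample(allowed, 1L, prob = remaining[allowed])
      seq_try[t] <- pick
      remaining[pick] <- remaining[pick] - 1L
      if (pick == last) streak <- streak + 1L
      else { last <- pick; streak <- 1L }
    }
    if (ok) { rec_seq <- seq_try; break }
  }
  if (is.null(rec_seq))
    stop("could not satisfy the consecutive-recipient constraint; ",
         "relax max_consecutive_same_recipient")
  ord <- integer(n)
  for (r in unique(cells$recipient)) {
    idx <- which(cells$recipient == r)
    ord[rec_seq == r] <- if (length(idx) == 1L) idx else sample(idx)
  }
  out <- cells[ord, c("recipient", "reward_credits", "effort_level")]
  rownames(out) <- NULL
  out$participant_id <- participant_id
  out$run <- rep(seq_len(config$n_runs), each = config$trials_per_run)
  out$trial_index <- rep(seq_len(config$trials_per_run), config$n_runs)
  out$effort_pct_mvc <- effort_level_to_pct(out$effort_level)
  out[, c("participant_id", "run", "trial_index", "recipient",
          "reward_credits", "effort_level", "effort_pct_mvc")]
}

# Seed the RNG for a scoped computation and return a restore function,
# so exported generators are deterministic without clobbering the
# caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write or read a trial schedule as long-format CSV
#'
#' @param design Data.frame from [generate_design()] (or several stacked).
#' @param path File path.
#' @return \code{read_design_csv} returns the schedule data.frame.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
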