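#' Staircase configuration
#'
#' The adaptive-track design used in the discrimination experiment: paired
#' 3-down-1-up staircases with a 3 dB step, each terminating at the lesser
#' of 70 trials or 12 reversals.
#'
#' @param step_db step size in dB.
#' @param max_trials maximum trials per staircase.
#' @param max_reversals maximum reversals per staircase.
#' @param n_staircases staircases per condition-by-pedestal cell per
#'   repetition.
#' @param start_offset_db starting target level relative to the generating
#'   observer's analytic threshold, dB.
#' @return a list of class \code{staircase_config}.
#' @export
staircase_config <- function(step_db = 3, max_trials = 70, max_reversals = 12,
                             n_staircases = 2, start_offset_db = 20) {
  if (step_db <= 0) stop("step_db must be positive")
  if (max_trials < 1 || max_reversals < 1) {
    stop("max_trials and max_reversals must be at least 1")
  }
  structure(list(step_db = step_db, max_trials = max_trials,
                 max_reversals = max_reversals, n_staircases = n_staircases,
                 start_offset_db = start_offset_db),
            class = "staircase_config")
}

#' Probability correct in the 2AFC task
#'
#' Decision model linking the combination model's response to percent
#' correct: the observer compares the two intervals' responses, each
#' perturbed by late additive Gaussian noise of standard deviation
#' \code{sigma40}, and picks the larger, so
#' \deqn{P(correct) = \Phi\!\left(\frac{\Delta resp}{\sigma_{40}\sqrt 2}\right).}
#' At \eqn{\Delta resp = \sigma_{40}} this gives about 76 percent correct,
#' so the response-increment threshold criterion and the 75-percent-correct
#' psychometric threshold agree to within a percentage point.
#'
#' @param delta_resp response difference, signal minus standard interval.
#' @param params a \code{\link{model_params}} object (uses \code{sigma40}).
#' @return probability of a correct response; vectorised.
#' @export
prob_correct_2afc <- function(delta_resp, params) {
  stats::pnorm(delta_resp / (params$sigma40 * sqrt(2)))
}

# target level (percent) at which the simulated observer reaches p_target
# correct; solved through the threshold machinery with the equivalent
# response-increment criterion
observer_level_at <- function(condition, pedestal, params, p_target,
                              model = "gain_control") {
  crit <- sqrt(2) * params$sigma40 * stats::qnorm(p_target)
  increment_threshold(condition, pedestal, params, model, sigma = crit)
}

#' Simulate one adaptive staircase
#'
#' Runs a single 3-down-1-up track for one condition-by-pedestal cell,
#' driven by the stochastic observer of \code{\link{prob_correct_2afc}}.
#' The target level falls by \code{cfg$step_db} after every third
#' consecutive correct response and rises by the same step after each
#' error; a reversal is a change in track direction; the track stops at the
#' lesser of \code{max_trials} trials or \code{max_reversals} reversals.
#' Levels are clipped to at most 100 percent modulation; clipped trials are
#' retained and flagged in the log.
#'
#' @param condition psychophysical condition label.
#' @param pedestal pedestal depth, percent.
#' @param params generating observer's \code{\link{model_params}}.
#' @param cfg a \code{\link{staircase_config}}.
#' @param model combination rule driving the observer.
#' @param observer optional function mapping a target depth (percent) to
#'   the probability of a correct response; by default the stochastic
#'   model observer of \code{\link{prob_correct_2afc}}.
#' @param start_db starting target level in dB; default is
#'   \code{cfg$start_offset_db} above the observer's analytic threshold.
#' @param seed optional integer seed (set before the first trial).
#' @param quiet suppress the clipping warning (clip count is always in the
#'   returned log's \code{clipped} column).
#' @return data.frame of trial records: \code{condition},
#'   \code{pedestal_pct}, \code{target_pct}, \code{target_db},
#'   \code{correct}, \code{reversal}, \code{clipped}, \code{trial}.
#' @export
run_staircase <- function(condition, pedestal, params, cfg = staircase_config(),
                          model = "gain_control", observer = NULL,
                          start_db = NULL, seed = NULL, quiet = FALSE) {
  condition <- match.arg(condition, .PSY_CONDITIONS)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(observer)) {
    observer <- function(dm) {
      prob_correct_2afc(.delta_resp(condition, pedestal, dm, params, model),
                        params)
    }
  }
  if (is.null(start_db)) {
    thr <- increment_threshold(condition, pedestal, params, model)
    start_db <- depth_to_db(thr) + cfg$start_offset_db
  }
  max_db <- depth_to_db(100)

  n_max <- cfg$max_trials
  level_db <- numeric(n_max); correct <- logical(n_max)
  reversal <- logical(n_max); clipped <- logical(n_max)
  lev <- start_db
  n_correct_run <- 0L
  n_reversals <- 0L
  last_dir <- 0L  # -1 down, +1 up
  t <- 0L
  while (t < n_max && n_reversals < cfg$max_reversals) {
    t <- t + 1L
    clip <- lev > max_db
    lev_t <- if (clip) max_db else lev
    level_db[t] <- lev_t; clipped[t] <- clip
    dm <- db_to_depth(lev_t)
    pc <- observer(dm)
    corr <- stats::runif(1) < pc
    correct[t] <- corr
    if (corr) {
      n_correct_run <- n_correct_run + 1L
      if (n_correct_run == 3L) {
        dir <- -1L
        if (last_dir == 1L) { n_reversals <- n_reversals + 1L
                              reversal[t] <- TRUE }
        lev <- lev - cfg$step_db
        last_dir <- dir
        n_correct_run <- 0L
      }
    } else {
      dir <- 1L
      if (last_dir == -1L) { n_reversals <- n_reversals + 1L
                             reversal[t] <- TRUE }
      lev <- lev + cfg$step_db
      last_dir <- dir
      n_correct_run <- 0L
    }
  }
  idx <- seq_len(t)
  if (!quiet && any(clipped[idx])) {
    warning(sum(clipped[idx]), " trial(s) clipped at 100% modulation")
  }
  data.frame(condition = condition, pedestal_pct = pedestal,
             target_pct = db_to_depth(level_db[idx]),
             target_db = level_db[idx], correct = correct[idx],
             reversal = reversal[idx], clipped = clipped[idx],
             trial = idx, stringsAsFactors = FALSE)
}

#' Probit fit of pooled 2AFC trial data
#'
#' Pools trials across repetitions and staircases, tabulates percent
#' correct at each visited target level (in dB, i.e. a cumulative
#' log-Gaussian in linear depth) and fits the guessing-floored psychometric
#' function \eqn{P(x) = 0.5 + 0.5\,\Phi((x-\mu)/s)} by maximum binomial
#' likelihood. The threshold is the 75-percent-correct point, which for
#' this parameterisation is \eqn{\mu} itself.
#'
#' @param trials data.frame of trial records (needs \code{target_db} and
#'   \code{correct}).
#' @return list of class \code{psychometric_fit}: \code{mu}, \code{sd}
#'   (both dB), \code{threshold_db}, \code{threshold_pct}, \code{n_trials},
#'   \code{n_levels}, \code{loglik}, \code{converged}.
#' @export
pool_fit_probit <- function(trials) {
  if (nrow(trials) < 2) stop("need at least two trials to fit")
  agg <- stats::aggregate(correct ~ target_db, data = trials,
                          FUN = function(z) c(k = sum(z), n = length(z)))
  x <- agg$target_db
  k <- agg$correct[, "k"]; n <- agg$correct[, "n"]
  if (length(x) < 2) {
    stop("non-identifiable psychometric data: fewer than two target levels")
  }
  if (sum(k) == sum(n) || sum(k) == 0) {
    stop("non-identifiable psychometric data: responses all ",
         if (sum(k) == 0) "incorrect" else "correct",
         " across ", sum(n), " trials at ", length(x), " levels")
  }
  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    p <- 0.5 + 0.5 * stats::pnorm((x - mu) / s)
    p <- pmin(pmax(p, 0.5 + 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  # moment-style start: level range midpoint weighted by accuracy
  pc <- k / n
  mu0 <- stats::weighted.mean(x, w = n * (0.25 - (pc - 0.75)^2 + 0.05))
  fit <- stats::optim(c(mu0, log(6)), nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  mu <- fit$par[1]; s <- exp(fit$par[2])
  structure(list(mu = mu, sd = s, threshold_db = mu,
                 threshold_pct = db_to_depth(mu),
                 n_trials = sum(n), n_levels = length(x),
                 loglik = -fit$value, converged = fit$convergence == 0),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Probit psychometric fit: threshold75 = %.2f dB (%.3g%%), sd = %.2f dB, %d trials at %d levels\n",
    x$threshold_db, x$threshold_pct, x$sd, x$n_trials, x$n_levels))
  invisible(x)
}

# deterministic substream seed derivation, kept inside 32-bit integer range
.substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647L)
}

#' Simulate the full discrimination experiment
#'
#' Runs the complete adaptive-staircase design for a synthetic observer
#' defined by \code{true_params}: every condition crossed with every
#' pedestal depth, a pair of staircases per cell, repeated \code{n_reps}
#' times per synthetic participant. Detection trials (pedestal 0) from the
#' monaural, dichotic and half-binaural conditions — identical stimuli —
#' are pooled into a single psychometric fit. Thresholds are the
#' 75-percent points of probit fits to trials pooled across repetitions,
#' averaged in dB across participants.
#'
#' @param true_params generating \code{\link{model_params}}.
#' @param cfg a \code{\link{staircase_config}}.
#' @param n_reps repetitions of the experiment per participant.
#' @param n_participants number of synthetic participants.
#' @param seed integer seed; every staircase draws from a deterministic
#'   substream so the whole dataset is reproducible.
#' @param model combination rule driving the observer.
#' @param pedestals pedestal grid, percent.
#' @param conditions condition labels to run.
#' @param keep_trials if TRUE, attach the full trial log as attribute
#'   \code{"trials"}.
#' @return a \code{dipper_dataset}: data.frame with columns
#'   \code{condition}, \code{pedestal_pct}, \code{threshold_db},
#'   \code{n_trials}, \code{pooled}; attributes \code{n_participants},
#'   \code{seed}.
#' @export
simulate_experiment <- function(true_params, cfg = staircase_config(),
                                n_reps = 3, n_participants = 1, seed = 1,
                                model = "gain_control",
                                pedestals = c(0, 1, 2, 4, 8, 16, 32, 64),
                                conditions = psy_conditions(),
                                keep_trials = FALSE) {
  cells <- expand.grid(condition = conditions, pedestal = pedestals,
                       stringsAsFactors = FALSE)
  idx <- 0L
  all_trials <- vector("list",
    n_participants * nrow(cells) * n_reps * cfg$n_staircases)
  ti <- 0L
  per_part <- vector("list", n_participants)
  for (part in seq_len(n_participants)) {
    trials_part <- vector("list", nrow(cells) * n_reps * cfg$n_staircases)
    tj <- 0L
    for (ci in seq_len(nrow(cells))) {
      for (rep_i in seq_len(n_reps)) {
        for (sc in seq_len(cfg$n_staircases)) {
          idx <- idx + 1L
          tr <- run_staircase(cells$condition[ci], cells$pedestal[ci],
                              true_params, cfg, model = model,
                              seed = .substream_seed(seed, idx), quiet = TRUE)
          tr$repetition <- rep_i
          tr$staircase_id <- sc
          tr$participant <- part
          tj <- tj + 1L; trials_part[[tj]] <- tr
          ti <- ti + 1L; all_trials[[ti]] <- tr
        }
      }
    }
    per_part[[part]] <- do.call(rbind, trials_part[seq_len(tj)])
  }

  pool_set <- intersect(c("MON", "DICH", "HALF_BIN"), conditions)
  thr_rows <- lapply(seq_len(n_participants), function(part) {
    tp <- per_part[[part]]
    rows <- lapply(seq_len(nrow(cells)), function(ci) {
      cond <- cells$condition[ci]; ped <- cells$pedestal[ci]
      pooled <- ped == 0 && cond %in% pool_set && length(pool_set) > 1
      sub <- if (pooled) {
        tp[tp$pedestal_pct == 0 & tp$condition %in% pool_set, ]
      } else {
        tp[tp$condition == cond & tp$pedestal_pct == ped, ]
      }
      fit <- pool_fit_probit(sub)
      data.frame(participant = part, condition = cond, pedestal_pct = ped,
                 threshold_db = fit$threshold_db, n_trials = fit$n_trials,
                 pooled = pooled, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  thr <- do.call(rbind, thr_rows)
  out <- stats::aggregate(threshold_db ~ condition + pedestal_pct + pooled,
                          data = thr, FUN = mean)
  ntr <- stats::aggregate(n_trials ~ condition + pedestal_pct,
                          data = thr, FUN = sum)
  out <- merge(out, ntr, by = c("condition", "pedestal_pct"))
  out <- out[order(out$condition, out$pedestal_pct),
             c("condition", "pedestal_pct", "threshold_db", "n_trials",
               "pooled")]
  rownames(out) <- NULL
  class(out) <- c("dipper_dataset", "data.frame")
  attr(out, "n_participants") <- n_participants
  attr(out, "seed") <- seed
  if (keep_trials) {
    attr(out, "trials") <- do.call(rbind, all_trials[seq_len(ti)])
  }
  out
}

#' @export
print.dipper_dataset <- function(x, ...) {
  cat(sprintf(
    "Dipper dataset: %d thresholds (%d condition(s) x %d pedestal(s)), %d synthetic participant(s)\n",
    nrow(x), length(unique(x$condition)), length(unique(x$pedestal_pct)),
    attr(x, "n_participants") %||% NA_integer_))
  print.data.frame(x, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
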