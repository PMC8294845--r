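#' Behavioral-model parameters
#'
#' Parameters of the shifted-lognormal reaction-time model with additive
#' condition offsets used by [generate_behavior()]. The conflict effect is the
#' expected incongruent-minus-congruent RT difference in milliseconds; because
#' it enters additively, the configured value is recovered exactly in
#' expectation.
#'
#' @param rt_shift non-decision shift of the RT distribution, ms.
#' @param rt_mu,rt_sigma log-scale mean and sd of the lognormal RT component;
#'   `rt_shift + exp(rt_mu + rt_sigma^2/2)` is the mean congruent RT.
#' @param conflict_rt_ms additive RT cost of incongruent trials, ms (may be
#'   zero or negative).
#' @param error_rate_congruent,error_rate_incongruent per-trial error
#'   probabilities by congruency.
#' @param miss_rate probability that no response is recorded (RT missing).
#' @param oddball_hit_rate,oddball_fa_rate hit and false-alarm probabilities
#'   used for the volume-oddball (go/no-go) task instead of the error rates.
#' @return a named list of class `behavior_params`.
#' @export
behavior_params <- function(rt_shift = 200, rt_mu = log(250), rt_sigma = 0.35,
                            conflict_rt_ms = 30,
                            error_rate_congruent = 0.05,
                            error_rate_incongruent = 0.10,
                            miss_rate = 0.01,
                            oddball_hit_rate = 0.85,
                            oddball_fa_rate = 0.05) {
  .check_scalar(rt_shift, "rt_shift", lower = 0)
  .check_scalar(rt_sigma, "rt_sigma", lower = 0)
  for (p in c(error_rate_congruent, error_rate_incongruent, miss_rate,
              oddball_hit_rate, oddball_fa_rate))
    .check_scalar(p, "probability", lower = 0, upper = 1)
  structure(list(rt_shift = rt_shift, rt_mu = rt_mu, rt_sigma = rt_sigma,
                 conflict_rt_ms = conflict_rt_ms,
                 error_rate_congruent = error_rate_congruent,
                 error_rate_incongruent = error_rate_incongruent,
                 miss_rate = miss_rate,
                 oddball_hit_rate = oddball_hit_rate,
                 oddball_fa_rate = oddball_fa_rate),
            class = "behavior_params")
}

#' Generate trial-level behavior for a design
#'
#' Draws reaction times from a shifted lognormal with an additive congruency
#' offset, so the expected incongruent-minus-congruent difference equals
#' `params$conflict_rt_ms` exactly. Errors are Bernoulli draws at the
#' per-congruency rates; missed trials have no response and no RT. For the
#' volume-oddball task the response rule is go/no-go: oddball trials are hits
#' with probability `oddball_hit_rate`, standards are false alarms with
#' probability `oddball_fa_rate`, and correctness follows the
#' hit/correct-rejection rule.
#'
#' @param design a `DesignTable` from [generate_design()].
#' @param task task id (defines the correctness rule).
#' @param params a [behavior_params()] list.
#' @param seed integer seed.
#' @return a `BehavioralTable` data.frame: the design columns plus `rt_ms`,
#'   `response`, `correct`.
#' @export
#' @examples
#' d <- generate_design("content_discrimination_1", 400, seed = 1)
#' b <- generate_behavior(d, "content_discrimination_1", behavior_params(), seed = 2)
#' mean(b$rt_ms[b$congruency == "incongruent"], na.rm = TRUE) -
#'   mean(b$rt_ms[b$congruency == "congruent"], na.rm = TRUE)
generate_behavior <- function(design, task, params = behavior_params(), seed = 1) {
  task <- match.arg(task, task_ids())
  if (nrow(design) == 0) stop("design is empty", call. = FALSE)
  stopifnot(inherits(params, "behavior_params"))
  set.seed(seed)
  n <- nrow(design)

  incong <- design$congruency == "incongruent"
  rt <- params$rt_shift + rlnorm(n, params$rt_mu, params$rt_sigma) +
    ifelse(incong, params$conflict_rt_ms, 0)

  if (task == "volume_oddball") {
    responded <- ifelse(design$oddball,
                        runif(n) < params$oddball_hit_rate,
                        runif(n) < params$oddball_fa_rate)
    response <- ifelse(responded, "go", NA_character_)
    correct <- responded == design$oddball # hit or correct rejection
    rt[!responded] <- NA_real_
  } else {
    target <- switch(task,
      content_discrimination_1 = ,
      content_discrimination_2 = design$sound_content,
      location_discrimination = design$sound_location,
      vertical_rdm = ,
      horizontal_rdm = design$dot_direction)
    err_p <- ifelse(incong, params$error_rate_incongruent,
                    params$error_rate_congruent)
    erred <- runif(n) < err_p
    missed <- runif(n) < params$miss_rate
    alt <- vapply(target, function(tg) switch(tg,
      left = "right", right = "left", up = "down", down = "up"), character(1))
    response <- ifelse(missed, NA_character_, ifelse(erred, alt, target))
    correct <- !missed & !erred
    rt[missed] <- NA_real_
  }

  out <- design
  out$rt_ms <- rt
  out$response <- response
  out$correct <- correct
  out
}
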