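#' Task identifiers understood by the generators
#' @return character vector of task ids.
#' @export
task_ids <- function() {
  c("content_discrimination_1", "content_discrimination_2",
    "location_discrimination", "volume_oddball",
    "vertical_rdm", "horizontal_rdm")
}

#' Per-session trial counts of the emulated study designs
#'
#' Full-session trial counts per task: the first content discrimination task
#' and the vertical RDM ran 12 blocks of 100 trials (1200 per session); the
#' second content discrimination and the location discrimination tasks ran 6
#' blocks of 100; the volume-oddball task ran two runs of 5 blocks of 100
#' (1000 in total); the horizontal RDM ran 10 blocks of 60.
#'
#' @param task optional task id; if omitted the full named vector is
#'   returned.
#' @return integer count(s).
#' @export
#' @examples
#' session_trials("content_discrimination_1")  # 1200
session_trials <- function(task = NULL) {
  counts <- c(content_discrimination_1 = 1200L,
              content_discrimination_2 = 600L,
              location_discrimination = 600L,
              volume_oddball = 1000L,
              vertical_rdm = 1200L,
              horizontal_rdm = 600L)
  if (is.null(task)) return(counts)
  unname(counts[match.arg(task, task_ids())])
}

.balanced_tasks <- function() {
  c("content_discrimination_1", "content_discrimination_2",
    "location_discrimination", "vertical_rdm", "horizontal_rdm")
}

#' Generate a trial design for one simulated session
#'
#' Builds the per-trial factor table of one session of an auditory-conflict
#' experiment. Every trial carries a spoken-word content ("left"/"right") and
#' a speaker location (left/right); a trial is congruent exactly when content
#' and location agree, so balanced designs contain 50% congruent trials. For
#' the discrimination and random-dot-motion (RDM) tasks the four
#' content-by-location cells are exactly balanced (`n_trials` must be
#' divisible by 4) and trial order is randomized. For the volume-oddball task
#' content and location are drawn uniformly per trial and each trial is
#' independently an oddball (lower playback volume) with probability 1/8.
#'
#' @param task one of [task_ids()].
#' @param n_trials number of trials (>= 0; divisible by 4 for balanced tasks).
#' @param seed integer seed; the same `(task, n_trials, seed)` always yields
#'   the same table.
#' @param n_blocks number of blocks the session is divided into.
#' @param coherence dot-motion coherence (RDM tasks only).
#' @return a `DesignTable` data.frame with columns `trial`, `block`,
#'   `sound_content`, `sound_location`, `congruency`, `oddball`,
#'   `oddball_volume`, `dot_direction`, `coherence`.
#' @export
#' @examples
#' d <- generate_design("content_discrimination_1", 1200, seed = 1)
#' table(d$congruency)  # 600 congruent, 600 incongruent
generate_design <- function(task, n_trials, seed, n_blocks = NULL,
                            coherence = 0.3) {
  task <- match.arg(task, task_ids())
  .check_scalar(n_trials, "n_trials", lower = 0)
  if (n_trials != round(n_trials)) stop("n_trials must be an integer count")
  if (is.null(n_blocks)) {
    n_blocks <- switch(task,
      content_discrimination_1 = 12, vertical_rdm = 12,
      volume_oddball = 10, horizontal_rdm = 10, 6)
  }

  cols <- c("trial", "block", "sound_content", "sound_location", "congruency",
            "oddball", "oddball_volume", "dot_direction", "coherence")
  if (n_trials == 0) {
    out <- data.frame(trial = integer(), block = integer(),
                      sound_content = character(), sound_location = character(),
                      congruency = character(), oddball = logical(),
                      oddball_volume = numeric(), dot_direction = character(),
                      coherence = numeric(), stringsAsFactors = FALSE)
    return(out[, cols])
  }

  set.seed(seed)
  sides <- c("left", "right")

  if (task %in% .balanced_tasks()) {
    if (n_trials %% 4 != 0)
      stop("n_trials must be divisible by 4 for balanced designs", call. = FALSE)
    cells <- expand.grid(sound_content = sides, sound_location = sides,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    idx <- rep(seq_len(4), each = n_trials / 4)
    idx <- sample(idx) # randomized order
    content <- cells$sound_content[idx]
    location <- cells$sound_location[idx]
    oddball <- rep(FALSE, n_trials)
    volume <- rep(1, n_trials)
  } else { # volume_oddball: independent uniform draws
    content <- sample(sides, n_trials, replace = TRUE)
    location <- sample(sides, n_trials, replace = TRUE)
    oddball <- runif(n_trials) < 1 / 8
    volume <- ifelse(oddball, 0.7, 1)
  }

  dot <- if (task == "horizontal_rdm") {
    sample(sides, n_trials, replace = TRUE)
  } else if (task == "vertical_rdm") {
    sample(c("up", "down"), n_trials, replace = TRUE)
  } else {
    rep(NA_character_, n_trials)
  }

  data.frame(
    trial = seq_len(n_trials),
    block = as.integer(ceiling(seq_len(n_trials) / ceiling(n_trials / n_blocks))),
    sound_content = content,
    sound_location = location,
    congruency = ifelse(content == location, "congruent", "incongruent"),
    oddball = oddball,
    oddball_volume = volume,
    dot_direction = dot,
    coherence = if (grepl("rdm", task)) coherence else NA_real_,
    stringsAsFactors = FALSE
  )
}
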