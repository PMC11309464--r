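# Trial schedules for the two neurocognitive ERP tasks: a 3-choice vigilance
# task (3CVT, sustained attention) and a standard image recognition task (SIR,
# yes/no visual recognition memory).

new_task_design <- function(task, trials) {
  trials$onset_s <- round(trials$onset_s, 6)
  structure(list(task = task, trials = trials), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> %s: %d trials (%.1f min)\n", x$task,
              nrow(x$trials), max(x$trials$onset_s) / 60))
  print(table(x$trials$phase, x$trials$trial_type))
  invisible(x)
}

n_design_trials <- function(design) nrow(design$trials)

# Pseudorandom order with no run of more than max_run identical types.
# A plain shuffle of a 70% majority type almost always contains long runs, so
# the order is built constructively: the minority stimuli are shuffled as
# separators and the majority stimuli are dealt into the gaps between them,
# at most max_run per gap, which bounds majority runs by construction; the
# run-length check then guards the (rare) minority runs.
constrained_order <- function(types, max_run = 8, max_tries = 100) {
  lv <- levels(factor(types))
  types <- as.character(types)
  tab <- sort(table(types), decreasing = TRUE)
  major <- names(tab)[1]
  others <- types[types != major]
  n_major <- sum(types == major)
  n_slots <- length(others) + 1
  if (n_major > max_run * n_slots) {
    stopf("run-length constraint infeasible for this trial mix")
  }
  for (i in seq_len(max_tries)) {
    sep <- if (length(others)) sample(others) else character(0)
    slot_of <- sample(rep(seq_len(n_slots), each = max_run), n_major)
    counts <- tabulate(slot_of, n_slots)
    out <- unlist(lapply(seq_len(n_slots), function(s) {
      c(rep(major, counts[s]), if (s <= length(sep)) sep[s])
    }), use.names = FALSE)
    if (max(rle(out)$lengths) <= max_run) return(factor(out, levels = lv))
  }
  stopf("could not satisfy run-length constraint after %d tries", max_tries)
}

#' 3-choice vigilance task (3CVT) trial schedule
#'
#' 376 trials: 264 frequent targets (70%), 55 infrequent nontargets (15%) and
#' 57 distractors (15%), presented for 400 ms each in a pseudorandom order with
#' no run of more than 8 identical stimulus types. The stimulus onset asynchrony
#' (SOA) is drawn uniformly per quartile of the trial sequence: 1.5-3 s in the
#' first quartile, 3-6 s in the second, and 6-10 s in the third and fourth,
#' emulating the increasing inter-stimulus intervals of the vigilance paradigm.
#'
#' @param seed integer seed for the pseudorandom order and the SOA draws.
#' @return a `task_design` with 376 trials.
#' @export
#' @examples
#' d <- make_3cvt_design(seed = 1)
#' table(d$trials$trial_type)
make_3cvt_design <- function(seed = 1L) {
  with_seed(derive_seed(seed, "3cvt"), {
    types <- factor(c(rep("target", 264), rep("nontarget", 55), rep("distractor", 57)),
                    levels = c("target", "nontarget", "distractor"))
    ord <- constrained_order(types, max_run = 8)
    n <- length(ord)
    quartile <- rep(1:4, each = n / 4)
    soa_lo <- c(1.5, 3, 6, 6)[quartile]
    soa_hi <- c(3, 6, 10, 10)[quartile]
    soa <- stats::runif(n, soa_lo, soa_hi)
    onset <- 2 + cumsum(c(0, soa[-n]))
    trials <- data.frame(
      trial = seq_len(n), trial_type = ord, phase = "test",
      onset_s = onset, duration_s = 0.4, soa_s = soa, quartile = quartile,
      stringsAsFactors = FALSE
    )
    new_task_design("cvt", trials)
  })
}

#' Standard image recognition (SIR) task trial schedule
#'
#' Encoding phase: two identical back-to-back blocks of the 20 target images,
#' fixed 3 s onset-to-onset interval, 1.5 s on screen. Testing block: 100
#' trials (the 20 targets interspersed with 80 novel images, shuffled), 3 s
#' interval, 400 ms on screen.
#'
#' @param seed integer seed for the testing-block shuffle.
#' @return a `task_design` with 140 trials (40 encoding + 100 testing).
#' @export
make_sir_design <- function(seed = 1L) {
  with_seed(derive_seed(seed, "sir"), {
    enc <- data.frame(
      trial_type = rep("target", 40), phase = "encoding",
      onset_s = 2 + 3 * (0:39), duration_s = 1.5, soa_s = 3,
      stringsAsFactors = FALSE
    )
    test_types <- sample(c(rep("target", 20), rep("novel", 80)))
    test_start <- max(enc$onset_s) + 3 + 5  # pause before the testing block
    test <- data.frame(
      trial_type = test_types, phase = "test",
      onset_s = test_start + 3 * (0:99), duration_s = 0.4, soa_s = 3,
      stringsAsFactors = FALSE
    )
    trials <- rbind(enc, test)
    trials$trial <- seq_len(nrow(trials))
    trials$quartile <- NA_integer_
    new_task_design("sir", trials[, c("trial", "trial_type", "phase", "onset_s",
                                      "duration_s", "soa_s", "quartile")])
  })
}

#' Reduced custom ERP trial schedule
#'
#' Builds an abbreviated schedule with the trial-type mix of a named task but a
#' caller-chosen trial count and SOA range. Intended for simulation studies and
#' calibration runs where the full-length task would be unnecessarily long; the
#' full schedules are [make_3cvt_design()] and [make_sir_design()].
#'
#' @param task `"cvt"` or `"sir"` (SIR here means the testing block only).
#' @param n_trials total number of trials.
#' @param soa_range SOA range in seconds, drawn uniformly.
#' @param seed integer seed.
#' @return a `task_design`.
#' @export
make_erp_design <- function(task = c("cvt", "sir"), n_trials = 60,
                            soa_range = c(1.5, 3), seed = 1L) {
  task <- match.arg(task)
  with_seed(derive_seed(seed, "custom", task, n_trials), {
    props <- if (task == "cvt") {
      c(target = 0.70, nontarget = 0.15, distractor = 0.15)
    } else {
      c(target = 0.20, novel = 0.80)
    }
    counts <- round(props * n_trials)
    counts[1] <- n_trials - sum(counts[-1])
    types <- factor(rep(names(counts), counts), levels = names(counts))
    ord <- constrained_order(types, max_run = 8)
    soa <- stats::runif(n_trials, soa_range[1], soa_range[2])
    trials <- data.frame(
      trial = seq_len(n_trials), trial_type = as.character(ord), phase = "test",
      onset_s = 2 + cumsum(c(0, soa[-n_trials])), duration_s = 0.4,
      soa_s = soa, quartile = NA_integer_, stringsAsFactors = FALSE
    )
    new_task_design(task, trials)
  })
}
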