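# 2-back / left-right task engine: trial content, non-parametric scoring, and
# the adaptive difficulty staircase.

NBACK_LETTERS <- c("C", "F", "J", "N", "Q", "S", "V", "X")
TRIAL_MS <- 20000          # fixed total trial duration
ITEM_FIXED_MS <- 750       # fixation (250 ms) + letter (500 ms)
INTERVAL_RANGE_MS <- c(19, 2583)

#' Number of items that fit in one 20-second trial
#'
#' Each item occupies a 250 ms fixation, a 500 ms letter, and a blank interval,
#' so a trial of fixed 20 s duration holds `floor(20000 / (750 + interval_ms))`
#' items; faster trials contain more letters (6 at the slowest interval, 26 at
#' the fastest).
#'
#' @param interval_ms Blank interval duration in milliseconds, in [19, 2583].
#' @return Integer vector of item counts.
#' @examples
#' items_per_trial(c(2583, 19, 159, 1750))
#' @export
items_per_trial <- function(interval_ms) {
  check_number(interval_ms, "interval_ms", INTERVAL_RANGE_MS[1], INTERVAL_RANGE_MS[2])
  as.integer(floor(TRIAL_MS / (ITEM_FIXED_MS + interval_ms)))
}

#' Non-parametric signal detection statistic A
#'
#' Estimates the area under the proper receiver operating characteristic
#' curve from a single (hit rate, false-alarm rate) point, as the average of
#' the minimum-area and maximum-area proper ROC curves through that point.
#' `A` equals 0.5 at chance (H = F) and 1 at perfect performance (H = 1,
#' F = 0), and unlike d' it is finite at the edges of the unit square without
#' any continuity correction. Below-chance inputs (H < F) are mapped by
#' symmetry to `1 - A(F, H)`.
#'
#' @param hit_rate,fa_rate Hit and false-alarm rates in [0, 1]; recycled to a
#'   common length.
#' @return Numeric vector of A values in [0, 1].
#' @examples
#' compute_A(1, 0)        # perfect
#' compute_A(0.3, 0.3)    # chance
#' compute_A(0.9, 0.1)
#' @export
compute_A <- function(hit_rate, fa_rate) {
  check_number(hit_rate, "hit_rate", 0, 1)
  check_number(fa_rate, "fa_rate", 0, 1)
  n <- max(length(hit_rate), length(fa_rate))
  h <- rep_len(hit_rate, n)
  f <- rep_len(fa_rate, n)
  flip <- h < f
  hh <- ifelse(flip, f, h)
  ff <- ifelse(flip, h, f)
  a <- ifelse(
    hh == ff, 0.5,
    ifelse(ff <= 0.5 & hh >= 0.5,
           3 / 4 + (hh - ff) / 4 - ff * (1 - hh),
           ifelse(hh < 0.5,
                  3 / 4 + (hh - ff) / 4 - ff / (4 * hh),
                  3 / 4 + (hh - ff) / 4 - (1 - hh) / (4 * (1 - ff)))))
  ifelse(flip, 1 - a, a)
}

# Stochastic rounding: floor(x) + Bernoulli(frac(x)). Deterministic whenever x
# is integral, and unbiased otherwise, so target/lure fractions average to
# their nominal rates across sequences of any length.
round_stochastic <- function(x) {
  base <- floor(x)
  as.integer(base + (runif(length(x)) < (x - base)))
}

#' Generate a 2-back letter sequence
#'
#' Builds one trial's letter stream from the eight-consonant alphabet. The
#' first two letters are burn-in (no response expected). On average 25% of the
#' remaining letters are targets (equal to the letter two positions back) and
#' 12.5% of letters are lures (equal to the letter one or three positions back
#' but not two back); all other letters match none of the three preceding
#' positions. Fractional expected counts are resolved by stochastic rounding
#' so the average fractions are exact.
#'
#' @param n_items Number of letters, between 6 and 26.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `position`, `letter`, `label`
#'   (`"burn-in"`, `"target"`, `"lure"`, `"nontarget"`).
#' @examples
#' generate_letter_sequence(12, seed = 1)
#' @export
generate_letter_sequence <- function(n_items, seed = NULL) {
  check_number(n_items, "n_items", 6, 26)
  n_items <- as.integer(n_items)
  with_seed_(seed, {
    for (attempt in 1:100) {
      seq_try <- try_letter_sequence(n_items)
      if (!is.null(seq_try)) return(seq_try)
    }
    stopf("pb_generation_error",
          "could not place targets/lures for n_items = %d after 100 attempts.",
          n_items)
  })
}

try_letter_sequence <- function(n_items) {
  n_targets <- round_stochastic(0.25 * (n_items - 2))
  n_lures <- round_stochastic(0.125 * n_items)
  eligible <- seq(3, n_items)
  if (n_targets + n_lures > length(eligible)) return(NULL)
  pos <- sample(eligible, n_targets + n_lures)
  target_pos <- pos[seq_len(n_targets)]
  lure_pos <- setdiff(pos, target_pos)

  letters_out <- character(n_items)
  labels <- rep("nontarget", n_items)
  labels[1:2] <- "burn-in"
  labels[target_pos] <- "target"
  labels[lure_pos] <- "lure"
  letters_out[1:2] <- sample(NBACK_LETTERS, 2, replace = TRUE)

  for (i in seq(3, n_items)) {
    back1 <- letters_out[i - 1]
    back2 <- letters_out[i - 2]
    back3 <- if (i >= 4) letters_out[i - 3] else NA_character_
    letters_out[i] <- switch(
      labels[i],
      target = back2,
      lure = {
        cand <- setdiff(stats::na.omit(c(back1, back3)), back2)
        if (!length(cand)) return(NULL)
        if (length(cand) == 1) cand else sample(cand, 1)
      },
      nontarget = {
        cand <- setdiff(NBACK_LETTERS, stats::na.omit(c(back1, back2, back3)))
        sample(cand, 1)
      })
  }
  tibble(position = seq_len(n_items), letter = letters_out, label = labels)
}

#' Audit the labels of a letter sequence
#'
#' Independently recomputes each position's label from the letters alone
#' (target = matches 2-back; lure = matches 1- or 3-back but not 2-back;
#' first two positions burn-in) and compares with the stored labels.
#'
#' @param sequence A tibble as returned by [generate_letter_sequence()].
#' @return `TRUE` invisibly if all labels check out; otherwise an error.
#' @export
validate_letter_sequence <- function(sequence) {
  check_columns(sequence, c("position", "letter", "label"), "sequence")
  l <- sequence$letter
  n <- length(l)
  expected <- vapply(seq_len(n), function(i) {
    if (i <= 2) return("burn-in")
    if (l[i] == l[i - 2]) return("target")
    if (l[i] == l[i - 1] || (i >= 4 && l[i] == l[i - 3])) return("lure")
    "nontarget"
  }, character(1))
  if (!identical(expected, sequence$label)) {
    stopf("pb_validation_error", "sequence labels disagree with letter content.")
  }
  invisible(TRUE)
}

#' Score one trial's responses with the A statistic
#'
#' Responses are `"same"` / `"different"` per letter (the first two burn-in
#' letters are ignored); a missing response is treated as not-"same", i.e. a
#' miss on a target and no false alarm elsewhere. A hit is "same" on a target;
#' a false alarm is "same" on a lure or nontarget.
#'
#' @param sequence A tibble from [generate_letter_sequence()].
#' @param responses Character vector, one entry per letter (`"same"`,
#'   `"different"`, or `NA`), of length `nrow(sequence)`.
#' @return A one-row tibble with counts (`hits`, `misses`, `false_alarms`,
#'   `correct_rejections`), rates `H` and `F`, the statistic `A`, and a
#'   `below_chance` flag (TRUE when H < F).
#' @export
score_trial <- function(sequence, responses) {
  check_columns(sequence, c("position", "letter", "label"), "sequence")
  n <- nrow(sequence)
  if (length(responses) != n) {
    stopf("pb_validation_error",
          "expected %d responses (one per letter), got %d.", n, length(responses))
  }
  active <- sequence$label != "burn-in"
  is_same <- !is.na(responses) & responses == "same"
  is_target <- sequence$label == "target"
  hits <- sum(active & is_target & is_same)
  misses <- sum(active & is_target & !is_same)
  fas <- sum(active & !is_target & is_same)
  crs <- sum(active & !is_target & !is_same)
  H <- if (hits + misses > 0) hits / (hits + misses) else NA_real_
  F <- if (fas + crs > 0) fas / (fas + crs) else NA_real_
  A <- if (is.na(H) || is.na(F)) NA_real_ else compute_A(H, F)
  tibble(hits = hits, misses = misses, false_alarms = fas,
         correct_rejections = crs, H = H, F = F, A = A,
         below_chance = !is.na(H) && !is.na(F) && H < F)
}

#' Run the 18-trial staircase difficulty calibration
#'
#' Adjusts the blank interval between letters to hold 2-back performance
#' inside the 0.75 < A < 0.85 band. Starting from 2583 ms, the interval is
#' decreased after two consecutive trials with A above 0.85 and increased
#' after two consecutive trials with A below 0.75 (the streak counter resets
#' after each adjustment so a single fast pair is not counted twice), and is
#' always clamped to [19, 2583] ms. Step sizes are multiplicative because the
#' achievable range spans two orders of magnitude.
#'
#' @param respond Observer contract: `function(interval_ms, sequence)`
#'   returning one response (`"same"`/`"different"`/`NA`) per letter. See
#'   [logistic_observer()] for a ready-made simulated observer.
#' @param seed Optional integer seed controlling sequence generation and the
#'   observer's randomness.
#' @param n_trials Number of staircase trials (default 18).
#' @param start_ms Starting blank interval (default 2583 ms).
#' @param step_down,step_up Multiplicative factors applied to the interval on
#'   a decrease / increase (defaults 0.75 and 4/3).
#' @param band Performance band `c(lower, upper)` (default `c(0.75, 0.85)`).
#' @return A list of class `pb_staircase` with `history` (a tibble with one
#'   row per trial: `trial_idx`, `interval_ms`, `n_items`, `A`) and
#'   `final_interval_ms`.
#' @export
run_staircase <- function(respond, seed = NULL, n_trials = 18,
                          start_ms = 2583, step_down = 0.75, step_up = 4 / 3,
                          band = c(0.75, 0.85)) {
  stopifnot(is.function(respond), n_trials >= 1, step_down < 1, step_up > 1)
  with_seed_(seed, {
    interval <- start_ms
    up_streak <- 0L
    down_streak <- 0L
    hist <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      n <- items_per_trial(interval)
      seq_t <- generate_letter_sequence(n)
      resp <- respond(interval, seq_t)
      if (length(resp) != n) {
        stopf("pb_observer_error",
              "observer returned %d responses for %d letters.", length(resp), n)
      }
      sc <- score_trial(seq_t, resp)
      hist[[t]] <- tibble(trial_idx = t, interval_ms = interval,
                          n_items = n, A = sc$A)
      if (!is.na(sc$A) && sc$A > band[2]) {
        down_streak <- down_streak + 1L
        up_streak <- 0L
      } else if (!is.na(sc$A) && sc$A < band[1]) {
        up_streak <- up_streak + 1L
        down_streak <- 0L
      } else {
        up_streak <- 0L
        down_streak <- 0L
      }
      if (down_streak >= 2L) {
        interval <- max(INTERVAL_RANGE_MS[1], round(interval * step_down))
        down_streak <- 0L
      } else if (up_streak >= 2L) {
        interval <- min(INTERVAL_RANGE_MS[2], round(interval * step_up))
        up_streak <- 0L
      }
    }
    history <- dplyr::bind_rows(hist)
    structure(list(history = history,
                   final_interval_ms = history$interval_ms[n_trials]),
              class = "pb_staircase")
  })
}

#' Simulated 2-back observer with interval-dependent accuracy
#'
#' Returns an observer function for [run_staircase()]. The per-letter
#' probability of a correct response follows a logistic function of the blank
#' interval: near-ceiling at long intervals (slow presentation) and chance at
#' very short ones, `p = 0.5 + (0.5 - lapse) * plogis((interval - midpoint) /
#' scale)`. Incorrect responses flip "same"/"different".
#'
#' @param midpoint_ms Interval at which accuracy is halfway between chance and
#'   ceiling (default 579 ms, a typical calibrated task speed).
#' @param scale_ms Logistic slope scale in ms (default 150).
#' @param lapse Asymptotic lapse rate (default 0.02).
#' @return `function(interval_ms, sequence)` producing responses.
#' @export
logistic_observer <- function(midpoint_ms = 579, scale_ms = 150, lapse = 0.02) {
  function(interval_ms, sequence) {
    p <- 0.5 + (0.5 - lapse) * plogis((interval_ms - midpoint_ms) / scale_ms)
    correct <- runif(nrow(sequence)) < p
    truth <- ifelse(sequence$label == "target", "same", "different")
    ifelse(correct, truth, ifelse(truth == "same", "different", "same"))
  }
}

#' @export
print.pb_staircase <- function(x, ...) {
  cat("2-back staircase calibration: ", nrow(x$history), " trials, final interval ",
      x$final_interval_ms, " ms (", items_per_trial(x$final_interval_ms),
      " letters/trial)\n", sep = "")
  invisible(x)
}
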