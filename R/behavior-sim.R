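#' Training protocols
#'
#' `protocol_rat()` emulates daily touchscreen sessions: a fixed number of
#' non-correction trials per session, correction trials after every error
#' (the same trial is re-presented until answered correctly; correction
#' trials are logged but excluded from all performance computations), and a
#' learning criterion of more than 80% correct in each of two consecutive
#' sessions. `protocol_human()` emulates a continuous trial stream in
#' 12-trial pseudo-randomized blocks (each pair shown 3 times, the target
#' on the left exactly 6 times per block) with a running-mean criterion:
#' training completes as soon as the mean of the last 20 trials exceeds 80%.
#'
#' @param session_trials Non-correction trials per rat session. The printed
#'   protocol caps sessions at 60 minutes rather than a trial count; 100
#'   trials per session is used as a realistic default.
#' @param max_sessions Session cap for rats (absence of criterion is a valid
#'   outcome, not an error).
#' @param criterion_accuracy Accuracy the criterion rule compares against
#'   (strictly greater than).
#' @param max_correction Safety cap on consecutive correction trials for a
#'   single error (a deterministic wrong policy would otherwise loop
#'   forever).
#' @param block_length,per_pair_per_block,left_targets_per_block Human block
#'   structure.
#' @param criterion_window Number of most recent trials in the human
#'   running mean.
#' @param max_trials Trial cap for humans.
#' @return An object of class `protocol`.
#' @name protocols
NULL

#' @rdname protocols
#' @export
protocol_rat <- function(session_trials = 100, max_sessions = 40,
                         criterion_accuracy = 0.8, max_correction = 25) {
  structure(list(species = "rat", session_trials = session_trials,
                 max_sessions = max_sessions,
                 criterion_accuracy = criterion_accuracy,
                 criterion_sessions = 2,
                 correction_trials = TRUE,
                 max_correction = max_correction,
                 block_length = 12),
            class = "protocol")
}

#' @rdname protocols
#' @export
protocol_human <- function(block_length = 12, per_pair_per_block = 3,
                           left_targets_per_block = 6,
                           criterion_window = 20, criterion_accuracy = 0.8,
                           max_trials = 600) {
  structure(list(species = "human", block_length = block_length,
                 per_pair_per_block = per_pair_per_block,
                 left_targets_per_block = left_targets_per_block,
                 criterion_window = criterion_window,
                 criterion_accuracy = criterion_accuracy,
                 max_trials = max_trials,
                 correction_trials = FALSE),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol>", x$species, "\n")
  invisible(x)
}

#' Stimulus pairs of a task
#'
#' All pairwise target-by-distractor combinations of the four base stimuli
#' under a task mapping ("mixed pairs": 2 targets x 2 distractors = 4
#' pairs).
#'
#' @param task A `task_mapping`.
#' @return A named list of pairs; each pair is a list with `positive`,
#'   `negative` (`stim_config`s) and `pair_id`.
#' @export
base_pairs <- function(task) {
  cls <- split_by_class(task)
  out <- list()
  for (p in cls$target) for (n in cls$distractor) {
    pr <- list(positive = p, negative = n,
               pair_id = paste(p$id, n$id, sep = "|"))
    out[[pr$pair_id]] <- pr
  }
  out
}

#' Schedule one pseudo-randomized block
#'
#' Builds a block in which every pair appears equally often and the target
#' appears on the left side in exactly half the trials, with pair order and
#' side assignment randomized independently.
#'
#' @param pairs List of pairs (as from [base_pairs()]).
#' @param seed Integer seed, or an internal RNG stream.
#' @param block_length Trials per block.
#' @return A data frame with columns `pair_id` and `target_side`.
#' @export
schedule_block <- function(pairs, seed = 1L, block_length = 12) {
  n_pairs <- length(pairs)
  if (block_length %% n_pairs != 0)
    stop("block length must be divisible by the number of pairs",
         call. = FALSE)
  if (block_length %% 2 != 0)
    stop("block length must be even to balance target sides", call. = FALSE)
  rng <- if (is.environment(seed)) seed else rng_new(seed)
  per_pair <- block_length / n_pairs
  ids <- names(pairs)
  pair_seq <- rng_sample(rng, rep(ids, per_pair))
  side_seq <- rng_sample(rng, rep(c("left", "right"), block_length / 2))
  data.frame(pair_id = pair_seq, target_side = side_seq,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Decision strategies. A strategy is a constructor returning a template
# object; simulate_subject() instantiates per-subject mutable state.

#' Decision strategies for simulated subjects
#'
#' Each simulated subject sees two images side by side and must choose one.
#' \describe{
#'   \item{`strategy_random()`}{chooses a side uniformly at random.}
#'   \item{`strategy_oracle()`}{always chooses the side showing the target
#'     (a subject with perfect knowledge of the rule), up to lapses.}
#'   \item{`strategy_linear_template()`}{scores each image by its inner
#'     product with a weight template and picks the higher score. With
#'     `learning_rate > 0` the template is an exponentially weighted running
#'     average of the feedback signal (target image minus distractor image)
#'     observed on each trial, optionally restricted to a region `mask`
#'     (e.g. the upper half of the canvas). The template therefore converges
#'     to the class-mean difference image: a perfect linear template for any
#'     linearly separable mapping, and exactly zero in expectation for the
#'     XOR/symmetry mapping, whose class means collide in pixel space — so
#'     this agent provably cannot exceed chance there on average. Choices
#'     are probit-noisy: the normalized template score (a correlation-like
#'     quantity in \[-1, 1\]) is compared against Gaussian decision noise of
#'     scale `decision_noise`, so accuracy rises gradually as the template
#'     estimate sharpens rather than stepping to the asymptote on the first
#'     session.}
#'   \item{`strategy_pixel_similarity()`}{keeps running averages of the
#'     target and distractor images identified through feedback and picks
#'     the side whose image is closer (pixel distance) to the target
#'     average than to the distractor average.}
#' }
#' A lapse is a trial on which the subject guesses a side uniformly at
#' random regardless of strategy, with probability `lapse_rate`.
#'
#' @param lapse_rate Probability of a lapse trial, in `[0, 1)`.
#' @param learning_rate Exponential averaging rate of the template update,
#'   per trial (0 freezes the template).
#' @param decision_noise Standard deviation of the Gaussian noise added to
#'   the normalized template score before the choice (0 = deterministic
#'   argmax).
#' @param encoding_noise Standard deviation (in pixel-intensity units) of
#'   the internal noise corrupting each stored feedback sample. The single
#'   glimpse is a very unreliable estimate of the class difference; reliable
#'   performance emerges only as samples are averaged, which is what spreads
#'   acquisition over many sessions rather than a single one.
#' @param template Optional initial weight matrix (canvas-sized); defaults
#'   to zeros.
#' @param mask Optional 0/1 matrix restricting which pixels the agent reads
#'   and updates.
#' @return An object of class `strategy`.
#' @name strategies
NULL

new_strategy <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "strategy")
}

#' @rdname strategies
#' @export
strategy_random <- function(lapse_rate = 0) {
  new_strategy("random", lapse_rate = lapse_rate)
}

#' @rdname strategies
#' @export
strategy_oracle <- function(lapse_rate = 0) {
  new_strategy("oracle", lapse_rate = lapse_rate)
}

#' @rdname strategies
#' @export
strategy_linear_template <- function(learning_rate = 0.0005,
                                     lapse_rate = 0.05,
                                     decision_noise = 0.25,
                                     encoding_noise = 60,
                                     template = NULL, mask = NULL) {
  stopifnot(lapse_rate >= 0, lapse_rate < 1, learning_rate >= 0,
            decision_noise >= 0, encoding_noise >= 0)
  new_strategy("linear_template", lapse_rate = lapse_rate,
               learning_rate = learning_rate, decision_noise = decision_noise,
               encoding_noise = encoding_noise,
               template = template, mask = mask)
}

#' @rdname strategies
#' @export
strategy_pixel_similarity <- function(lapse_rate = 0.05) {
  new_strategy("pixel_similarity", lapse_rate = lapse_rate)
}

#' @export
print.strategy <- function(x, ...) {
  cat("<strategy>", x$kind, "| lapse rate", x$lapse_rate, "\n")
  invisible(x)
}

# Per-subject mutable strategy state.
strategy_state <- function(strategy, canvas_dim) {
  st <- new.env(parent = emptyenv())
  st$kind <- strategy$kind
  st$lapse <- strategy$lapse_rate
  if (strategy$kind == "linear_template") {
    st$lr <- strategy$learning_rate
    st$noise <- strategy$decision_noise
    st$enc_noise <- strategy$encoding_noise
    st$w <- if (is.null(strategy$template))
      matrix(0, canvas_dim[1], canvas_dim[2]) else strategy$template
    st$mask <- if (is.null(strategy$mask))
      matrix(1, canvas_dim[1], canvas_dim[2]) else strategy$mask
  }
  if (strategy$kind == "pixel_similarity") {
    st$t_sum <- matrix(0, canvas_dim[1], canvas_dim[2]); st$t_n <- 0
    st$d_sum <- matrix(0, canvas_dim[1], canvas_dim[2]); st$d_n <- 0
  }
  st
}

# Choose a side. u1, u2 are pre-drawn uniforms (lapse gate; tie-break /
# random choice).
strategy_choose <- function(st, img_left, img_right, target_side, u1, u2) {
  if (u1 < st$lapse) return(if (u2 < 0.5) "left" else "right")
  if (st$kind == "random") return(if (u2 < 0.5) "left" else "right")
  if (st$kind == "oracle") return(target_side)
  if (st$kind == "linear_template") {
    dimg <- st$mask * (img_left - img_right)
    d <- sum(st$w * dimg)
    wn <- sqrt(sum(st$w^2)); dn <- sqrt(sum(dimg^2))
    if (wn == 0 || dn == 0) return(if (u2 < 0.5) "left" else "right")
    z <- d / (wn * dn)   # normalized score, in [-1, 1]
    if (st$noise > 0) z <- z + stats::qnorm(u2) * st$noise
    if (z == 0) return(if (u2 < 0.5) "left" else "right")
    return(if (z > 0) "left" else "right")
  }
  if (st$kind == "pixel_similarity") {
    if (st$t_n == 0 || st$d_n == 0) return(if (u2 < 0.5) "left" else "right")
    tbar <- st$t_sum / st$t_n; dbar <- st$d_sum / st$d_n
    score <- function(img) mean((img - dbar)^2) - mean((img - tbar)^2)
    sl <- score(img_left); sr <- score(img_right)
    if (sl == sr) return(if (u2 < 0.5) "left" else "right")
    return(if (sl > sr) "left" else "right")
  }
  stop("unknown strategy kind")
}

strategy_update <- function(st, img_chosen, img_other, correct, rng = NULL) {
  if (st$kind == "linear_template" && st$lr > 0) {
    signal <- if (correct) img_chosen - img_other else img_other - img_chosen
    if (st$enc_noise > 0 && !is.null(rng))
      signal <- signal + with_rng(rng, stats::rnorm(length(signal),
                                                    sd = st$enc_noise))
    st$w <- (1 - st$lr) * st$w + st$lr * st$mask * signal
  }
  if (st$kind == "pixel_similarity") {
    tgt <- if (correct) img_chosen else img_other
    dis <- if (correct) img_other else img_chosen
    st$t_sum <- st$t_sum + tgt; st$t_n <- st$t_n + 1
    st$d_sum <- st$d_sum + dis; st$d_n <- st$d_n + 1
  }
  invisible(st)
}

# Buffered uniform draws from an RNG stream (keeps the per-trial overhead of
# swapping RNG state negligible).
unif_buffer <- function(rng, chunk = 2048L) {
  b <- new.env(parent = emptyenv())
  b$rng <- rng; b$chunk <- chunk
  b$buf <- rng_runif(rng, chunk); b$pos <- 0L
  b
}
next_unif <- function(b) {
  b$pos <- b$pos + 1L
  if (b$pos > length(b$buf)) {
    b$buf <- rng_runif(b$rng, b$chunk); b$pos <- 1L
  }
  b$buf[b$pos]
}

#' Simulate one subject
#'
#' Generates a full trial log for one simulated subject under a decision
#' strategy, a task mapping and a species protocol. Rat subjects run in
#' sessions with correction trials (after an error the same trial is
#' re-presented, flagged `correction_trial = TRUE`, until answered
#' correctly) and stop at the two-consecutive-sessions criterion or the
#' session cap. Human subjects run a blocked trial stream and stop when the
#' running mean of the last `criterion_window` trials exceeds the criterion,
#' or at the trial cap. Reaching the cap without criterion is a valid
#' outcome, flagged in the attributes, not an error.
#'
#' @param strategy A `strategy`.
#' @param task A `task_mapping`.
#' @param protocol A `protocol`.
#' @param seed Integer seed; all subject-level randomness derives from it.
#' @param pairs Pairs to present; defaults to all mixed pairs of the task.
#' @param geometry A `stim_geometry`.
#' @param subject Subject id stored in the log.
#' @param stage Stage label stored in the log.
#' @param state Optional pre-existing strategy state (continues learning
#'   across staged phases).
#' @param max_sessions Optional override of the protocol session cap.
#' @return A data frame of trial records (`subject`, `session`, `trial`,
#'   `pair_id`, `target_side`, `chosen_side`, `correct`, `correction_trial`,
#'   `stage`) with attributes `criterion_reached`, `criterion_point`, and
#'   `state` (the final strategy state).
#' @export
simulate_subject <- function(strategy, task, protocol, seed,
                             pairs = base_pairs(task),
                             geometry = stim_geometry(),
                             subject = "s1", stage = "mixed",
                             state = NULL, max_sessions = NULL) {
  rng <- rng_new(seed)
  cfg_list <- list()
  for (pr in pairs) {
    cfg_list[[pr$positive$id]] <- pr$positive
    cfg_list[[pr$negative$id]] <- pr$negative
  }
  images <- lapply(cfg_list, function(cf)
    render_stimulus(cf, geometry)$pixels * 1.0)
  st <- if (is.null(state)) strategy_state(strategy, dim(images[[1]]))
  else state
  ub <- unif_buffer(rng)
  # block length must be divisible by the pair count (and even, to balance
  # sides); widen the protocol block to the smallest compatible length.
  block_len <- protocol$block_length
  n_pairs <- length(pairs)
  if (block_len %% n_pairs != 0)
    block_len <- n_pairs * max(1, ceiling(block_len / n_pairs))
  if (block_len %% 2 != 0) block_len <- block_len * 2

  rec <- new.env(parent = emptyenv())
  rec$rows <- list(); rec$i <- 0L
  push <- function(session, trial, pair_id, target_side, chosen, correct,
                   correction) {
    rec$i <- rec$i + 1L
    rec$rows[[rec$i]] <- list(session, trial, pair_id, target_side, chosen,
                              correct, correction)
  }

  # On a correction trial the same arrangement is re-presented; the subject
  # shifts away from the side it was just punished for (lose-shift), which
  # in a two-alternative task ends the correction run on the first repeat.
  # Learning updates are applied on regular trials only, so the learning
  # stream is one feedback sample per scheduled trial.
  run_trial <- function(pair_id, target_side, session, trial, correction,
                        last_choice = NULL) {
    pr <- pairs[[pair_id]]
    pos_img <- images[[pr$positive$id]]
    neg_img <- images[[pr$negative$id]]
    img_left <- if (target_side == "left") pos_img else neg_img
    img_right <- if (target_side == "left") neg_img else pos_img
    chosen <- if (correction && !is.null(last_choice)) {
      if (last_choice == "left") "right" else "left"
    } else {
      strategy_choose(st, img_left, img_right, target_side,
                      next_unif(ub), next_unif(ub))
    }
    correct <- chosen == target_side
    if (!correction) {
      img_chosen <- if (chosen == "left") img_left else img_right
      img_other <- if (chosen == "left") img_right else img_left
      strategy_update(st, img_chosen, img_other, correct, rng)
    }
    push(session, trial, pair_id, target_side, chosen, correct, correction)
    list(correct = correct, chosen = chosen)
  }

  criterion_reached <- FALSE
  criterion_point <- NA_integer_

  if (protocol$species == "rat") {
    cap <- if (is.null(max_sessions)) protocol$max_sessions else max_sessions
    session_acc <- numeric(0)
    trial_counter <- 0L
    for (s in seq_len(cap)) {
      sched <- schedule_session(pairs, rng, protocol$session_trials,
                                block_len)
      n_correct <- 0L
      for (t in seq_len(nrow(sched))) {
        trial_counter <- trial_counter + 1L
        r <- run_trial(sched$pair_id[t], sched$target_side[t], s,
                       trial_counter, FALSE)
        if (r$correct) n_correct <- n_correct + 1L
        reps <- 0L
        while (!r$correct && protocol$correction_trials &&
               reps < protocol$max_correction) {
          reps <- reps + 1L
          trial_counter <- trial_counter + 1L
          r <- run_trial(sched$pair_id[t], sched$target_side[t], s,
                         trial_counter, TRUE, last_choice = r$chosen)
        }
      }
      session_acc <- c(session_acc, n_correct / nrow(sched))
      if (s >= 2 &&
          session_acc[s - 1] > protocol$criterion_accuracy &&
          session_acc[s] > protocol$criterion_accuracy) {
        criterion_reached <- TRUE
        criterion_point <- s
        break
      }
    }
  } else {
    window <- protocol$criterion_window
    recent <- integer(0)
    trial_counter <- 0L
    done <- FALSE
    while (!done && trial_counter < protocol$max_trials) {
      sched <- schedule_block(pairs, rng, block_len)
      for (t in seq_len(nrow(sched))) {
        trial_counter <- trial_counter + 1L
        r <- run_trial(sched$pair_id[t], sched$target_side[t], 1L,
                       trial_counter, FALSE)
        recent <- c(recent, as.integer(r$correct))
        if (length(recent) > window)
          recent <- recent[(length(recent) - window + 1):length(recent)]
        if (length(recent) == window &&
            mean(recent) > protocol$criterion_accuracy) {
          criterion_reached <- TRUE
          criterion_point <- trial_counter
          done <- TRUE
          break
        }
        if (trial_counter >= protocol$max_trials) { done <- TRUE; break }
      }
    }
  }

  rows <- rec$rows[seq_len(rec$i)]
  log <- data.frame(
    subject = subject,
    session = vapply(rows, `[[`, 0L, 1),
    trial = vapply(rows, `[[`, 0L, 2),
    pair_id = vapply(rows, `[[`, "", 3),
    target_side = vapply(rows, `[[`, "", 4),
    chosen_side = vapply(rows, `[[`, "", 5),
    correct = vapply(rows, `[[`, TRUE, 6),
    correction_trial = vapply(rows, `[[`, TRUE, 7),
    stage = stage,
    stringsAsFactors = FALSE
  )
  attr(log, "criterion_reached") <- criterion_reached
  attr(log, "criterion_point") <- criterion_point
  attr(log, "state") <- st
  log
}

# A rat session schedule: whole pseudo-randomized blocks, truncated to the
# session length (the human block scheduler reused with rat session sizes).
schedule_session <- function(pairs, rng, session_trials, block_length = 12) {
  n_blocks <- ceiling(session_trials / block_length)
  sched <- do.call(rbind, lapply(seq_len(n_blocks), function(i)
    schedule_block(pairs, rng, block_length)))
  sched[seq_len(session_trials), , drop = FALSE]
}

#' Simulate a cohort of subjects
#'
#' @param n_subjects Number of subjects.
#' @param strategy,task,protocol,pairs,geometry,stage As in
#'   [simulate_subject()].
#' @param base_seed Cohort seed; subject i uses `base_seed + i`.
#' @return A list of per-subject trial logs (see [simulate_subject()]).
#' @export
simulate_cohort <- function(n_subjects, strategy, task, protocol,
                            base_seed = 1L, pairs = base_pairs(task),
                            geometry = stim_geometry(), stage = "mixed") {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i)
    simulate_subject(strategy, task, protocol, seed = base_seed + i,
                     pairs = pairs, geometry = geometry,
                     subject = sprintf("s%02d", i), stage = stage))
}

#' Simulate a staged (two-pair introduction) subject
#'
#' Emulates the staged design: the subject is first trained on a single
#' initial pair to criterion; a second pair is then introduced (both pairs
#' intermixed); finally all pairwise combinations are presented. The two
#' stage pairs are chosen so that the initial pair has the same target under
#' the linear and the nonlinear mapping while the second pair's targets
#' conflict between the two mappings. Learning state carries across stages.
#'
#' @param strategy,task,protocol,seed,geometry,subject As in
#'   [simulate_subject()].
#' @param stage_caps Session caps for the three stages (rat protocol).
#' @return A single trial log with a `stage` column
#'   (`initial_pair`, `second_pair`, `mixed`) and per-stage criterion
#'   attributes.
#' @export
simulate_staged_subject <- function(strategy, task, protocol, seed,
                                    geometry = stim_geometry(),
                                    subject = "s1",
                                    stage_caps = c(20, 15, 15)) {
  all_pairs <- base_pairs(task)
  # initial pair: top-top vs top-bottom (same target under both mappings);
  # second pair: bottom-bottom vs bottom-top (targets conflict).
  p1 <- if (task$task_id == "linear") "Ltop_Rtop|Ltop_Rbottom"
  else "Ltop_Rtop|Ltop_Rbottom"
  p2 <- if (task$task_id == "linear") "Lbottom_Rtop|Lbottom_Rbottom"
  else "Lbottom_Rbottom|Lbottom_Rtop"
  stopifnot(p1 %in% names(all_pairs), p2 %in% names(all_pairs))
  st <- NULL
  logs <- list()
  crit <- list()
  stage_pairs <- list(initial_pair = all_pairs[p1],
                      second_pair = all_pairs[c(p1, p2)],
                      mixed = all_pairs)
  for (i in seq_along(stage_pairs)) {
    sg <- names(stage_pairs)[i]
    log <- simulate_subject(strategy, task, protocol,
                            seed = derive_seed(seed, sg),
                            pairs = stage_pairs[[i]], geometry = geometry,
                            subject = subject, stage = sg, state = st,
                            max_sessions = stage_caps[i])
    st <- attr(log, "state")
    crit[[sg]] <- list(reached = attr(log, "criterion_reached"),
                       point = attr(log, "criterion_point"))
    logs[[sg]] <- log
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  attr(out, "stage_criteria") <- crit
  attr(out, "old_pair") <- p1
  attr(out, "new_pair") <- p2
  out
}

#' Locate the criterion point in a trial log
#'
#' Applies the protocol's criterion rule to a recorded (or simulated) trial
#' log. Correction trials are excluded. For the human rule the running mean
#' of the last `criterion_window` non-correction trials is evaluated after
#' every trial (undefined before the window has filled); for the rat rule,
#' the first session whose accuracy and whose predecessor's accuracy both
#' exceed the criterion is returned.
#'
#' @param records A trial-record data frame.
#' @param protocol A `protocol`.
#' @return A list with `reached` (logical) and `point` (trial index for
#'   humans, session index for rats; `NA` when the criterion was never
#'   met).
#' @export
apply_criterion <- function(records, protocol) {
  rec <- records[!records$correction_trial, , drop = FALSE]
  if (nrow(rec) == 0) return(list(reached = FALSE, point = NA_integer_))
  if (protocol$species == "human") {
    w <- protocol$criterion_window
    ok <- as.integer(rec$correct)
    if (length(ok) >= w) {
      cs <- cumsum(ok)
      run_mean <- (cs[w:length(ok)] - c(0, cs)[seq_len(length(ok) - w + 1)]) / w
      hit <- which(run_mean > protocol$criterion_accuracy)
      if (length(hit) > 0)
        return(list(reached = TRUE, point = hit[1] + w - 1L))
    }
    list(reached = FALSE, point = NA_integer_)
  } else {
    acc <- session_accuracy(records)
    if (nrow(acc) >= 2) {
      both <- acc$accuracy[-1] > protocol$criterion_accuracy &
        acc$accuracy[-nrow(acc)] > protocol$criterion_accuracy
      hit <- which(both)
      if (length(hit) > 0)
        return(list(reached = TRUE, point = acc$session[hit[1] + 1]))
    }
    list(reached = FALSE, point = NA_integer_)
  }
}

#' Per-session accuracy (correction trials excluded)
#'
#' @param records A trial-record data frame.
#' @return A data frame with `session`, `n_trials`, `accuracy`.
#' @export
session_accuracy <- function(records) {
  rec <- records[!records$correction_trial, , drop = FALSE]
  sessions <- sort(unique(rec$session))
  data.frame(
    session = sessions,
    n_trials = vapply(sessions, function(s) sum(rec$session == s), 0L),
    accuracy = vapply(sessions, function(s)
      mean(rec$correct[rec$session == s]), 0)
  )
}

#' Read or write trial logs as CSV
#'
#' The CSV trial-log format doubles as the ingestion format for real data:
#' columns `subject`, `session`, `trial`, `pair_id`, `target_side`,
#' `chosen_side`, `correct`, `correction_trial`, `stage`.
#'
#' @param logs A trial-record data frame or list of them.
#' @param path File path.
#' @return `read_trial_log()` returns a data frame.
#' @export
write_trial_log <- function(logs, path) {
  if (is.list(logs) && !is.data.frame(logs)) logs <- do.call(rbind, logs)
  utils::write.csv(logs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "session", "trial", "pair_id", "target_side",
              "chosen_side", "correct", "correction_trial")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("trial log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$correct <- as.logical(df$correct)
  df$correction_trial <- as.logical(df$correction_trial)
  df
}
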