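#' Template models over stimulus regions
#'
#' A template model predicts discrimination performance on a stimulus pair
#' from one region of the canvas: the full canvas (`"full"`), the upper half
#' (`"upper_field"`) or the lower half (`"lower_field"`). The top/bottom
#' boundary defaults to the horizontal midline (`split = 0.5`,
#' configurable). A subject relying only on a region cannot discriminate
#' a pair whose two stimuli are identical within it.
#'
#' @param kind `"full"`, `"upper_field"` or `"lower_field"`.
#' @param geometry A `stim_geometry`.
#' @param split Fraction of the canvas height assigned to the upper field.
#' @return An object of class `template_model` with a 0/1 region `mask`.
#' @export
template_model <- function(kind = c("full", "upper_field", "lower_field"),
                           geometry = stim_geometry(), split = 0.5) {
  kind <- match.arg(kind)
  nr <- geometry$nrow; nc <- geometry$ncol
  mask <- matrix(0, nr, nc)
  boundary <- round(nr * split)
  if (kind == "full") mask[,] <- 1
  if (kind == "upper_field") mask[seq_len(boundary), ] <- 1
  if (kind == "lower_field") mask[(boundary + 1):nr, ] <- 1
  structure(list(kind = kind, mask = mask, geometry = geometry,
                 split = split),
            class = "template_model")
}

#' @export
print.template_model <- function(x, ...) {
  cat("<template_model>", x$kind, "\n")
  invisible(x)
}

#' Template-model prediction for one stimulus pair
#'
#' Binary mode (default): predicted performance is 0.5 (chance) when the two
#' rendered stimuli are identical within the model's region, and 1.0
#' otherwise. Graded mode maps the normalized in-region pixel difference d
#' (relative to `d_max`, the largest in-region difference across the pair
#' set under study) to `0.5 + 0.5 * d / d_max`, so informativeness scales
#' with how much of the region distinguishes the pair.
#'
#' @param model A `template_model`.
#' @param pair A pair (list with `positive` and `negative` `stim_config`s).
#' @param geometry A `stim_geometry` (must match the model's).
#' @param mode `"binary"` or `"graded"`.
#' @param d_max Normalization constant for graded mode.
#' @return A single predicted performance in \[0.5, 1\].
#' @export
template_prediction <- function(model, pair, geometry = model$geometry,
                                mode = c("binary", "graded"), d_max = NULL) {
  mode <- match.arg(mode)
  if (!identical(geometry$nrow, model$geometry$nrow) ||
      !identical(geometry$ncol, model$geometry$ncol))
    stop("pair geometry does not match the template model's", call. = FALSE)
  d <- region_difference(model, pair, geometry)
  if (mode == "binary") return(if (d == 0) 0.5 else 1.0)
  if (is.null(d_max) || d_max == 0) d_max <- max(d, .Machine$double.eps)
  0.5 + 0.5 * min(d / d_max, 1)
}

# In-region mean squared pixel difference between the two pair members.
region_difference <- function(model, pair, geometry) {
  a <- render_stimulus(pair$positive, geometry)$pixels
  b <- render_stimulus(pair$negative, geometry)$pixels
  sum(model$mask * (a - b)^2) / sum(model$mask)
}

#' Template predictions for a whole pair set
#'
#' @param model A `template_model`.
#' @param pairs Data frame of pairs as produced by
#'   [build_manipulated_pairs()] (`$pairs`), or a list of pair objects.
#' @param geometry A `stim_geometry`.
#' @param mode `"binary"` or `"graded"` (graded normalizes by the largest
#'   in-region difference across the set).
#' @param drop_identical Drop pairs whose members are identical stimuli.
#' @return A data frame with `pair_id` and `prediction`.
#' @export
template_predictions <- function(model, pairs, geometry = model$geometry,
                                 mode = c("binary", "graded"),
                                 drop_identical = TRUE) {
  mode <- match.arg(mode)
  plist <- as_pair_list(pairs)
  if (drop_identical)
    plist <- Filter(function(p) !config_equal(p$positive, p$negative), plist)
  d <- vapply(plist, region_difference, 0, model = model, geometry = geometry)
  pred <- if (mode == "binary") ifelse(d == 0, 0.5, 1.0)
  else 0.5 + 0.5 * d / max(d, .Machine$double.eps)
  data.frame(pair_id = vapply(plist, `[[`, "", "pair_id"),
             prediction = pred, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Accept either a pairs data frame (positive/negative id columns) or a list
# of pair objects.
as_pair_list <- function(pairs) {
  if (is.data.frame(pairs)) {
    lapply(seq_len(nrow(pairs)), function(i) {
      list(positive = config_from_id(pairs$positive[i]),
           negative = config_from_id(pairs$negative[i]),
           pair_id = pairs$pair_id[i])
    })
  } else pairs
}

config_from_id <- function(id) {
  m <- regmatches(id, regexec("^L(top|bottom|both|none)_R(top|bottom|both|none)$", id))[[1]]
  if (length(m) != 3) stop("not a stimulus id: ", id, call. = FALSE)
  stim_config(m[2], m[3])
}

#' Correlation between template predictions and observed performance
#'
#' Pearson correlation across matched pair ids with a two-sided p-value
#' (t approximation), plus an optional seeded permutation p-value.
#'
#' @param predictions Data frame with `pair_id`, `prediction`.
#' @param observed Data frame with `pair_id`, `accuracy`.
#' @param n_permutations If > 0, also compute a permutation p-value by
#'   shuffling the observed accuracies.
#' @param seed Seed for the permutations.
#' @return A list with `r`, `p`, `n`, `zero_variance` (flag), and
#'   optionally `p_permutation`.
#' @export
prediction_performance_correlation <- function(predictions, observed,
                                               n_permutations = 0,
                                               seed = 1L) {
  merged <- merge(predictions, observed, by = "pair_id")
  if (nrow(merged) < 3)
    stop("need at least 3 matched pairs", call. = FALSE)
  x <- merged$prediction; y <- merged$accuracy
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(merged),
                zero_variance = TRUE))
  ct <- stats::cor.test(x, y)
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = nrow(merged),
              zero_variance = FALSE)
  if (n_permutations > 0) {
    rng <- rng_new(seed)
    r_obs <- abs(out$r)
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      yp <- rng_sample(rng, y)
      if (abs(stats::cor(x, yp)) >= r_obs) exceed <- exceed + 1L
    }
    out$p_permutation <- (exceed + 1) / (n_permutations + 1)
  }
  out
}

#' Per-pair performance with exact binomial confidence intervals
#'
#' Counts successes per stimulus pair over a trailing window of sessions
#' (correction trials excluded) and attaches the exact Clopper-Pearson
#' interval at the requested level, plus a chance-inclusion flag: whether
#' the observed accuracy lies inside the central binomial interval around
#' chance (p = 0.5) for that trial count.
#'
#' @param records A trial-record data frame.
#' @param last_sessions Window: the final n sessions (`Inf` = all).
#' @param level Confidence level for the Clopper-Pearson interval.
#' @param chance_level Level of the central chance band.
#' @return A data frame with `pair_id`, `successes`, `trials`, `accuracy`,
#'   `ci_lower`, `ci_upper`, `chance_lower`, `chance_upper`,
#'   `within_chance`. Pairs with zero trials are reported with `NA`
#'   accuracy, not dropped.
#' @export
per_pair_performance <- function(records, last_sessions = 10, level = 0.95,
                                 chance_level = level) {
  rec <- records[!records$correction_trial, , drop = FALSE]
  sessions <- sort(unique(rec$session))
  if (is.finite(last_sessions) && length(sessions) > last_sessions)
    rec <- rec[rec$session %in% utils::tail(sessions, last_sessions), ,
               drop = FALSE]
  pair_ids <- sort(unique(records$pair_id))
  rows <- lapply(pair_ids, function(pid) {
    sub <- rec[rec$pair_id == pid, , drop = FALSE]
    n <- nrow(sub); s <- sum(sub$correct)
    if (n == 0)
      return(data.frame(pair_id = pid, successes = 0L, trials = 0L,
                        accuracy = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, chance_lower = NA_real_,
                        chance_upper = NA_real_, within_chance = NA))
    ci <- stats::binom.test(s, n, conf.level = level)$conf.int
    alpha <- 1 - chance_level
    chance <- c(stats::qbinom(alpha / 2, n, 0.5),
                stats::qbinom(1 - alpha / 2, n, 0.5)) / n
    data.frame(pair_id = pid, successes = s, trials = n, accuracy = s / n,
               ci_lower = ci[1], ci_upper = ci[2],
               chance_lower = chance[1], chance_upper = chance[2],
               within_chance = s / n >= chance[1] & s / n <= chance[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Old-pair versus new-pair transfer analysis
#'
#' For a staged run in which a second stimulus pair is introduced after
#' training on an initial pair, reports the accuracy on the old and the new
#' pair in the introduction session (with exact binomial intervals) and the
#' Pearson correlation between old- and new-pair per-session accuracies
#' across the remaining sessions of that stage. A strategy carried over
#' from the initial pair predicts above-chance old-pair and (when the new
#' pair's target conflicts with that strategy) below-chance new-pair
#' performance, and a negative across-session correlation while the
#' strategy is being unlearned and relearned.
#'
#' @param records A staged trial log (see [simulate_staged_subject()]) or
#'   any log with a `stage` column containing `"second_pair"`.
#' @param old_pair,new_pair Pair ids; default to the log's attributes.
#' @param level Confidence level for the binomial intervals.
#' @return A list with `first_session` (data frame: pair, successes, trials,
#'   accuracy, ci bounds) and `correlation` (`r`, `p`, `n_sessions`;
#'   `NA` with `zero_variance = TRUE` when either series is constant).
#' @export
transfer_analysis <- function(records, old_pair = attr(records, "old_pair"),
                              new_pair = attr(records, "new_pair"),
                              level = 0.95) {
  if (!"stage" %in% names(records) ||
      !any(records$stage == "second_pair"))
    stop("log has no 'second_pair' stage; transfer analysis needs a staged run",
         call. = FALSE)
  if (is.null(old_pair) || is.null(new_pair))
    stop("old_pair and new_pair must be given (or present as attributes)",
         call. = FALSE)
  rec <- records[records$stage == "second_pair" & !records$correction_trial, ,
                 drop = FALSE]
  sessions <- sort(unique(rec$session))
  first <- rec[rec$session == sessions[1], , drop = FALSE]
  fs <- lapply(c(old = old_pair, new = new_pair), function(pid) {
    sub <- first[first$pair_id == pid, , drop = FALSE]
    n <- nrow(sub); s <- sum(sub$correct)
    ci <- if (n > 0) stats::binom.test(s, n, conf.level = level)$conf.int
    else c(NA_real_, NA_real_)
    data.frame(pair_id = pid, successes = s, trials = n,
               accuracy = if (n > 0) s / n else NA_real_,
               ci_lower = ci[1], ci_upper = ci[2])
  })
  first_session <- do.call(rbind, fs)
  first_session <- cbind(pair = rownames(first_session), first_session)
  rownames(first_session) <- NULL

  rest <- rec[rec$session != sessions[1], , drop = FALSE]
  corr <- list(r = NA_real_, p = NA_real_, n_sessions = 0L,
               zero_variance = NA)
  if (nrow(rest) > 0) {
    per_sess <- function(pid) {
      vapply(sort(unique(rest$session)), function(s) {
        sub <- rest[rest$session == s & rest$pair_id == pid, , drop = FALSE]
        if (nrow(sub) == 0) NA_real_ else mean(sub$correct)
      }, 0)
    }
    a_old <- per_sess(old_pair); a_new <- per_sess(new_pair)
    keep <- !is.na(a_old) & !is.na(a_new)
    a_old <- a_old[keep]; a_new <- a_new[keep]
    corr$n_sessions <- sum(keep)
    if (sum(keep) >= 3) {
      if (stats::sd(a_old) == 0 || stats::sd(a_new) == 0) {
        corr$zero_variance <- TRUE
      } else {
        ct <- stats::cor.test(a_old, a_new)
        corr$r <- unname(ct$estimate); corr$p <- ct$p.value
        corr$zero_variance <- FALSE
      }
    }
  }
  list(first_session = first_session, correlation = corr)
}
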