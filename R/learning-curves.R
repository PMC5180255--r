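#' Backward learning curve
#'
#' Aligns every subject at the point where the learning criterion was
#' reached and averages performance backwards from there, so the shape of
#' acquisition is isolated from the variable number of trials/sessions
#' subjects needed. For humans the curve covers the criterion trial and the
#' 19 trials before it (window 20, unit = trial); for rats the criterion
#' session and the 8 sessions before it (window 9, unit = session). Every
#' point therefore averages the same number of subjects. Positions are
#' indexed 1 (earliest included point) through `window` (the criterion
#' point).
#'
#' Subjects that never reached criterion cannot be aligned and are excluded
#' with a warning (their count is reported in the `n_excluded` attribute).
#' As an alternative for groups that never learn, `align = "end"` aligns
#' subjects at their final session/trial instead, which is how a
#' chance-level group can still be summarized and given a (linear) fit.
#'
#' @param logs List of per-subject trial logs (see [simulate_subject()]).
#' @param protocol A `protocol` (determines the unit and criterion rule).
#' @param window Number of positions; defaults to 20 for humans and 9 for
#'   rats.
#' @param align `"criterion"` (default) or `"end"`.
#' @return An object of class `backward_curve`: data frame with `x`, `y`
#'   (mean accuracy), `se`, plus attributes `n_subjects`, `n_excluded`,
#'   `unit`.
#' @export
backward_curve <- function(logs, protocol,
                           window = if (protocol$species == "human") 20 else 9,
                           align = c("criterion", "end")) {
  align <- match.arg(align)
  if (is.data.frame(logs)) logs <- split(logs, logs$subject)
  unit <- if (protocol$species == "human") "trial" else "session"
  per_subject <- list()
  n_excluded <- 0
  for (log in logs) {
    rec <- log[!log$correction_trial, , drop = FALSE]
    series <- if (unit == "trial") as.numeric(rec$correct)
    else session_accuracy(rec)$accuracy
    if (align == "criterion") {
      cr <- apply_criterion(log, protocol)
      if (!cr$reached) { n_excluded <- n_excluded + 1; next }
      end <- cr$point
    } else {
      end <- length(series)
    }
    if (end < window) { n_excluded <- n_excluded + 1; next }
    per_subject[[length(per_subject) + 1]] <-
      series[(end - window + 1):end]
  }
  if (n_excluded > 0)
    warning(sprintf("%d subject(s) excluded from the backward curve", n_excluded),
            call. = FALSE)
  if (length(per_subject) == 0)
    stop("no subject could be aligned; backward curve is empty", call. = FALSE)
  m <- do.call(rbind, per_subject)
  n <- nrow(m)
  y <- colMeans(m)
  se <- if (n > 1) apply(m, 2, stats::sd) / sqrt(n) else rep(0, ncol(m))
  out <- data.frame(x = seq_len(window), y = y, se = se)
  attr(out, "n_subjects") <- n
  attr(out, "n_excluded") <- n_excluded
  attr(out, "unit") <- unit
  class(out) <- c("backward_curve", "data.frame")
  out
}

#' Logistic growth model prediction
#'
#' The constrained growth model fitted to backward learning curves:
#' `y = b + b * L / (1 + exp(-k * (x - x0)))`, with baseline constant `b`
#' (default 0.55), asymptote parameter `L`, learning rate `k`
#' (per trial/session) and midpoint `x0` (the half-way point between
#' baseline and asymptotic performance).
#'
#' @param x Positions (trials or sessions).
#' @param L,k,x0 Model parameters.
#' @param baseline Baseline constant `b`.
#' @return Predicted accuracies.
#' @export
logistic_growth <- function(x, L, k, x0, baseline = 0.55) {
  baseline + baseline * L / (1 + exp(-k * (x - x0)))
}

#' Default start values and bounds for the logistic fit
#'
#' Start values `(L, k, x0) = (0.5, 0.3, 10)` for humans and `(0.5, 0.3, 5)`
#' for rats; bounds `L` in \[0, 1\], `k` in \[-1, 1\], `x0` in \[0, 20\]
#' (humans) or \[0, 10\] (rats).
#'
#' @param species `"human"` or `"rat"`.
#' @return A list with `start`, `lower`, `upper` named triples.
#' @export
logistic_fit_defaults <- function(species = c("human", "rat")) {
  species <- match.arg(species)
  x0_start <- if (species == "human") 10 else 5
  x0_upper <- if (species == "human") 20 else 10
  list(start = c(L = 0.5, k = 0.3, x0 = x0_start),
       lower = c(L = 0, k = -1, x0 = 0),
       upper = c(L = 1, k = 1, x0 = x0_upper))
}

#' Fit the logistic growth model to a backward curve
#'
#' Bounded nonlinear least squares for the model
#' `y = b + b * L / (1 + exp(-k (x - x0)))`. Primary optimizer is
#' `stats::nls` with the `"port"` algorithm (bounded Gauss-Newton); if it
#' fails (e.g. on noiseless data with zero residuals, where Gauss-Newton
#' cannot establish a relative offset) the fit falls back to bounded
#' quasi-Newton minimization of the SSE (`optim`, method `"L-BFGS-B"`).
#' Non-convergence is reported via `converged = FALSE`, never silently.
#'
#' @param curve A `backward_curve` or any data frame with `x` and `y`.
#' @param start,lower,upper Named triples `(L, k, x0)`; defaults from
#'   [logistic_fit_defaults()].
#' @param baseline Baseline constant `b`.
#' @param species Used only to pick defaults when `start`/bounds are
#'   missing.
#' @return An object of class `logistic_fit`: `par` (named triple),
#'   `baseline`, `sse`, `converged`, `start`, `lower`, `upper`, `fitted`,
#'   `method`.
#' @export
fit_logistic <- function(curve, start = NULL, lower = NULL, upper = NULL,
                         baseline = 0.55, species = c("human", "rat")) {
  species <- match.arg(species)
  defs <- logistic_fit_defaults(species)
  if (is.null(start)) start <- defs$start
  if (is.null(lower)) lower <- defs$lower
  if (is.null(upper)) upper <- defs$upper
  stopifnot(all(lower <= start), all(start <= upper))
  x <- curve$x; y <- curve$y
  if (length(x) < 4)
    stop("need more points than parameters to fit the logistic model",
         call. = FALSE)
  sse_fun <- function(p)
    sum((y - logistic_growth(x, p[1], p[2], p[3], baseline))^2)

  par <- NULL; converged <- FALSE; method <- "port"
  fit <- tryCatch(
    suppressWarnings(stats::nls(y ~ logistic_growth(x, L, k, x0, baseline),
               data = data.frame(x = x, y = y),
               start = as.list(start), lower = lower, upper = upper,
               algorithm = "port",
               control = stats::nls.control(maxiter = 500, warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    par <- stats::coef(fit)
    converged <- fit$convInfo$isConv
  }
  # refine / fall back with bounded quasi-Newton on the SSE
  o_start <- if (!is.null(par)) pmin(pmax(par, lower), upper) else start
  opt <- tryCatch(
    stats::optim(o_start, sse_fun, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 10000, factr = 1e2)),
    error = function(e) NULL)
  if (!is.null(opt) && (is.null(par) || opt$value < sse_fun(par))) {
    par <- opt$par
    converged <- opt$convergence == 0
    method <- if (is.null(fit)) "L-BFGS-B" else "port+L-BFGS-B"
  }
  if (is.null(par))
    return(structure(list(par = c(L = NA, k = NA, x0 = NA),
                          baseline = baseline, sse = NA,
                          converged = FALSE, start = start,
                          lower = lower, upper = upper,
                          fitted = rep(NA_real_, length(x)),
                          method = "failed"),
                     class = "logistic_fit"))
  names(par) <- c("L", "k", "x0")
  structure(list(par = par, baseline = baseline, sse = sse_fun(par),
                 converged = converged, start = start, lower = lower,
                 upper = upper,
                 fitted = logistic_growth(x, par[1], par[2], par[3], baseline),
                 method = method),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> L = %.3f, k = %.3f, x0 = %.3f (baseline %.2f), SSE = %.3g%s\n",
    x$par["L"], x$par["k"], x$par["x0"], x$baseline, x$sse,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Fit a straight line to a backward curve
#'
#' Ordinary least squares, used where the logistic growth model is
#' inadmissible — groups that show no learning (chance-level throughout),
#' for which the constrained logistic parameters would be meaningless.
#'
#' @param curve A `backward_curve` or data frame with `x` and `y`.
#' @return An object of class `linear_fit`: `slope`, `intercept`, `sse`.
#' @export
fit_linear <- function(curve) {
  stopifnot(length(curve$x) >= 2)
  fit <- stats::lm(y ~ x, data = data.frame(x = curve$x, y = curve$y))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 sse = sum(stats::residuals(fit)^2),
                 fitted = unname(stats::fitted(fit))),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope = %.4f, intercept = %.3f, SSE = %.3g\n",
              x$slope, x$intercept, x$sse))
  invisible(x)
}

#' Fitted-model report over a set of backward curves
#'
#' Fits the logistic growth model to each named curve and reports the
#' parameter triple and SSE; curves declared non-learning (flagged in
#' `linear_for`, e.g. a group in which no subject reached criterion) get
#' the linear fit instead.
#'
#' @param curves Named list of `backward_curve`s.
#' @param species Named character vector (or single value) giving the
#'   species per curve (sets fit defaults).
#' @param baseline Baseline constant for the logistic model.
#' @param linear_for Character vector of curve names to fit linearly.
#' @return A data frame with one row per curve: `curve`, `model`, `L`, `k`,
#'   `x0`, `slope`, `intercept`, `sse`, `converged`.
#' @export
model_selection_report <- function(curves, species = "human",
                                   baseline = 0.55, linear_for = character(0)) {
  if (length(curves) == 0)
    return(data.frame(curve = character(0), model = character(0),
                      L = numeric(0), k = numeric(0), x0 = numeric(0),
                      slope = numeric(0), intercept = numeric(0),
                      sse = numeric(0), converged = logical(0)))
  if (length(species) == 1) species <- stats::setNames(
    rep(species, length(curves)), names(curves))
  rows <- lapply(names(curves), function(nm) {
    if (nm %in% linear_for) {
      f <- fit_linear(curves[[nm]])
      data.frame(curve = nm, model = "linear", L = NA, k = NA, x0 = NA,
                 slope = f$slope, intercept = f$intercept, sse = f$sse,
                 converged = TRUE)
    } else {
      f <- fit_logistic(curves[[nm]], baseline = baseline,
                        species = species[[nm]])
      data.frame(curve = nm, model = "logistic", L = f$par["L"],
                 k = f$par["k"], x0 = f$par["x0"], slope = NA,
                 intercept = NA, sse = f$sse, converged = f$converged)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort's backward-curve data from known logistic parameters
#'
#' Generates per-subject binomial accuracy series whose success
#' probability follows the logistic growth model on positions `1..n_points`
#' and returns the subject-averaged curve. With `trials_per_point = 1` each
#' position is one Bernoulli trial per subject (a human-style trial curve);
#' with larger values each position is a session of that many trials (a
#' rat-style session curve). Used for parameter-recovery validation of the
#' fitting pipeline.
#'
#' @param L,k,x0,baseline Generating parameters.
#' @param n_subjects Subjects per cohort.
#' @param n_points Positions per subject (trials or sessions).
#' @param trials_per_point Trials behind each per-subject position.
#' @param seed Integer seed.
#' @param noiseless If `TRUE`, returns the exact model curve (no sampling).
#' @return A data frame with `x`, `y` (and `se`), usable by
#'   [fit_logistic()].
#' @export
simulate_logistic_cohort <- function(L, k, x0, baseline = 0.55,
                                     n_subjects = 30, n_points = 60,
                                     trials_per_point = 1,
                                     seed = 1L, noiseless = FALSE) {
  x <- seq_len(n_points)
  p <- logistic_growth(x, L, k, x0, baseline)
  p <- pmin(pmax(p, 0), 1)
  if (noiseless)
    return(data.frame(x = x, y = p, se = 0))
  rng <- rng_new(seed)
  draws <- with_rng(rng, matrix(
    stats::rbinom(n_subjects * n_points, trials_per_point,
                  rep(p, each = n_subjects)) / trials_per_point,
    nrow = n_subjects))
  y <- colMeans(draws)
  se <- apply(draws, 2, stats::sd) / sqrt(n_subjects)
  data.frame(x = x, y = y, se = se)
}
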