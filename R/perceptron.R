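#' Build a labeled dataset for the linear readout
#'
#' @param features Numeric matrix, one row per example (raw pixels or V1
#'   response values).
#' @param labels Vector of class labels coded +1 (target) / -1 (distractor),
#'   or a character vector of `"target"`/`"distractor"`.
#' @param ids Optional example ids.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, ids = NULL) {
  features <- as.matrix(features)
  if (is.character(labels))
    labels <- ifelse(labels == "target", 1L, -1L)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels),
            all(labels %in% c(-1L, 1L)))
  if (length(unique(labels)) < 2)
    stop("dataset must contain both classes", call. = FALSE)
  if (is.null(ids)) ids <- paste0("ex", seq_len(nrow(features)))
  structure(list(features = features, labels = labels, ids = ids),
            class = "labeled_dataset")
}

#' Assemble the readout dataset for a task over the base stimuli
#'
#' @param task A `task_mapping`.
#' @param feature_space `"pixels"` for raw rendered pixels or `"v1"` for
#'   model responses.
#' @param geometry A `stim_geometry`.
#' @param spec,params Filter bank spec and stage parameters (V1 space only).
#' @return A `labeled_dataset` over the 4 base stimuli.
#' @export
task_dataset <- function(task, feature_space = c("pixels", "v1"),
                         geometry = stim_geometry(),
                         spec = filterbank_spec(), params = v1_params()) {
  feature_space <- match.arg(feature_space)
  configs <- make_base_set()
  images <- lapply(configs, render_stimulus, geometry = geometry)
  feats <- if (feature_space == "pixels") {
    t(vapply(images, function(im) as.vector(im$pixels * 1.0),
             numeric(length(images[[1]]$pixels))))
  } else {
    rm_ <- v1_response_matrix(images, spec, params)
    t(vapply(rm_$responses, function(r) r$values,
             numeric(length(rm_$responses[[1]]$values))))
  }
  labeled_dataset(feats, vapply(configs, task$class_of, ""),
                  ids = names(configs))
}

#' Train a classic perceptron
#'
#' Rosenblatt's perceptron with unit learning rate and a bias term. Weights
#' start at zero. An example is misclassified when `sign(w . x + b) != y`,
#' with the tie at exactly zero activation predicting the distractor (-1);
#' misclassified examples are added to (targets) or subtracted from
#' (distractors) the weights. Training stops early on the first epoch with
#' zero updates (convergence: the data are linearly separable and the final
#' weights classify every example correctly). Accuracy over the full
#' dataset is recorded after every epoch.
#'
#' @param data A `labeled_dataset`.
#' @param max_epochs Maximum number of passes over the data.
#' @param shuffle If `TRUE`, the presentation order is reshuffled each epoch
#'   using `seed`; if `FALSE` (default) examples are presented in dataset
#'   order. The converged/not-converged outcome does not depend on order.
#' @param seed Integer seed for the shuffled order.
#' @param init Optional initial weight vector (length = features + 1, bias
#'   last); defaults to zeros.
#' @return An object of class `perceptron_fit`: `weights` (bias last),
#'   `epoch_history` (per-epoch training accuracy), `converged`,
#'   `epochs_run`.
#' @export
perceptron_train <- function(data, max_epochs = 20, shuffle = FALSE,
                             seed = 1L, init = NULL) {
  stopifnot(inherits(data, "labeled_dataset"), max_epochs >= 1)
  X <- data$features
  y <- data$labels
  n <- nrow(X); p <- ncol(X)
  w <- if (is.null(init)) numeric(p + 1) else { stopifnot(length(init) == p + 1); init }
  predict_all <- function(w) {
    act <- as.vector(X %*% w[seq_len(p)]) + w[p + 1]
    ifelse(act > 0, 1L, -1L)   # tie at 0 -> distractor
  }
  rng <- if (shuffle) rng_new(seed) else NULL
  history <- numeric(0)
  converged <- FALSE
  epochs_run <- 0L
  for (ep in seq_len(max_epochs)) {
    ord <- if (shuffle) rng_sample(rng, n) else seq_len(n)
    updates <- 0L
    for (i in ord) {
      act <- sum(X[i, ] * w[seq_len(p)]) + w[p + 1]
      pred <- if (act > 0) 1L else -1L
      if (pred != y[i]) {
        w[seq_len(p)] <- w[seq_len(p)] + y[i] * X[i, ]
        w[p + 1] <- w[p + 1] + y[i]
        updates <- updates + 1L
      }
    }
    epochs_run <- ep
    history <- c(history, mean(predict_all(w) == y))
    if (updates == 0L) { converged <- TRUE; break }
  }
  structure(list(weights = w, epoch_history = history,
                 converged = converged, epochs_run = epochs_run,
                 ids = data$ids),
            class = "perceptron_fit")
}

#' @export
print.perceptron_fit <- function(x, ...) {
  cat(sprintf("<perceptron_fit> %s after %d epoch(s); final accuracy %.2f\n",
              if (x$converged) "converged" else "did not converge",
              x$epochs_run, utils::tail(x$epoch_history, 1)))
  invisible(x)
}

#' Predict with a trained perceptron
#'
#' @param object A `perceptron_fit`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Vector of +1/-1 predictions.
#' @export
predict.perceptron_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- length(object$weights) - 1
  act <- as.vector(newdata %*% object$weights[seq_len(p)]) + object$weights[p + 1]
  ifelse(act > 0, 1L, -1L)
}

#' Linear-separability certificate
#'
#' Decides the separability status of a labeled dataset:
#' \itemize{
#'   \item `"non-separable-by-mean-collision"` when the class mean feature
#'     vectors are exactly equal — a sufficient condition for
#'     non-separability, since any separating hyperplane would have to put
#'     the common mean strictly on both of its sides.
#'   \item `"separable"` when a perceptron run converges (its zero-error
#'     epoch is the certificate).
#'   \item `"unknown"` otherwise.
#' }
#'
#' @param data A `labeled_dataset`.
#' @param max_epochs Epoch budget for the perceptron probe.
#' @return A string: `"separable"`, `"non-separable-by-mean-collision"`, or
#'   `"unknown"`.
#' @export
separability_certificate <- function(data, max_epochs = 1000) {
  X <- data$features; y <- data$labels
  mu_t <- colMeans(X[y == 1L, , drop = FALSE])
  mu_d <- colMeans(X[y == -1L, , drop = FALSE])
  if (identical(all.equal(mu_t, mu_d, tolerance = 0), TRUE) ||
      max(abs(mu_t - mu_d)) == 0)
    return("non-separable-by-mean-collision")
  fit <- perceptron_train(data, max_epochs = max_epochs)
  if (fit$converged) "separable" else "unknown"
}
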