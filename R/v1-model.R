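#' Gabor filter bank specification
#'
#' Defines the filters of the V1-like encoder: oriented Gabor patches over a
#' grid of orientations and spatial frequencies, in quadrature-free ON/OFF
#' cosine phase pairs (0 and 180 degrees). The default bank uses 16
#' orientations uniformly spanning 0-180 degrees (a grid closed under the
#' reflection theta -> 180 - theta, so mirror-symmetric stimuli produce
#' mirror-equivariant response maps), 6 spatial frequencies log-spaced over
#' 0.1-0.6 cycles/degree, and 31 x 31 pixel filters at the default
#' 2 px/degree rendering scale. The filter is deliberately narrower than the
#' central arm (17.06 degrees = 34 px) so that no single unit pools both
#' lateral arm regions: the encoding is local with respect to the arm
#' layout, as in a retinotopic V1 population.
#'
#' @param orientations Filter orientations in degrees.
#' @param spatial_frequencies Carrier frequencies in cycles/degree.
#' @param filter_size Odd kernel side length in pixels.
#' @param phases Carrier phase offsets in degrees.
#' @param pixels_per_degree Scale used to convert cycles/degree to
#'   cycles/pixel; match the rendering geometry.
#' @param aspect Gaussian envelope aspect ratio (gamma).
#' @param bandwidth Spatial-frequency bandwidth in octaves (sets the
#'   envelope width relative to the carrier wavelength).
#' @return An object of class `filterbank_spec`.
#' @export
filterbank_spec <- function(orientations = seq(0, 180, length.out = 17)[-17],
                            spatial_frequencies = exp(seq(log(0.1), log(0.6),
                                                          length.out = 6)),
                            filter_size = 31,
                            phases = c(0, 180),
                            pixels_per_degree = 2,
                            aspect = 0.5,
                            bandwidth = 1) {
  stopifnot(length(orientations) >= 2, length(spatial_frequencies) >= 2,
            filter_size %% 2 == 1, filter_size >= 3,
            pixels_per_degree > 0, aspect > 0, bandwidth > 0)
  structure(list(orientations = orientations,
                 spatial_frequencies = spatial_frequencies,
                 filter_size = filter_size,
                 phases = phases,
                 pixels_per_degree = pixels_per_degree,
                 aspect = aspect,
                 bandwidth = bandwidth),
            class = "filterbank_spec")
}

#' @export
print.filterbank_spec <- function(x, ...) {
  cat(sprintf(
    "<filterbank_spec> %d orientations x %d frequencies x %d phases, %d x %d px\n",
    length(x$orientations), length(x$spatial_frequencies), length(x$phases),
    x$filter_size, x$filter_size))
  invisible(x)
}

# One zero-mean Gabor kernel. theta/psi in degrees, f in cycles/pixel.
gabor_kernel <- function(size, theta, f, psi, aspect, bandwidth) {
  half <- (size - 1) / 2
  xs <- matrix(rep(-half:half, each = size), nrow = size)   # column coord
  ys <- matrix(rep(-half:half, times = size), nrow = size)  # row coord
  th <- theta * pi / 180
  xr <- xs * cos(th) + ys * sin(th)
  yr <- -xs * sin(th) + ys * cos(th)
  lambda <- 1 / f
  # envelope width from the octave bandwidth (standard Gabor relation)
  sigma <- lambda / pi * sqrt(log(2) / 2) * (2^bandwidth + 1) / (2^bandwidth - 1)
  g <- exp(-(xr^2 + (aspect * yr)^2) / (2 * sigma^2)) *
    cos(2 * pi * f * xr + psi * pi / 180)
  g - mean(g)
}

#' Materialize a filter bank
#'
#' @param spec A `filterbank_spec`.
#' @return A list of kernels (matrices) with a metadata data frame attached
#'   as attribute `"info"`.
#' @export
build_filterbank <- function(spec) {
  grid <- expand.grid(phase = spec$phases,
                      frequency = spec$spatial_frequencies,
                      orientation = spec$orientations)
  kernels <- lapply(seq_len(nrow(grid)), function(i) {
    gabor_kernel(spec$filter_size, grid$orientation[i],
                 grid$frequency[i] / spec$pixels_per_degree,
                 grid$phase[i], spec$aspect, spec$bandwidth)
  })
  attr(kernels, "info") <- grid
  kernels
}

#' V1 stage parameters
#'
#' Parameters for the nonlinear stages around the Gabor convolution: local
#' divisive normalization of the input, response thresholding and
#' saturation, and local divisive normalization of the output.
#'
#' @param input_norm_neighborhood,output_norm_neighborhood Odd side length
#'   (pixels) of the square pooling neighborhood used for divisive
#'   normalization.
#' @param norm_stabilizer Small positive constant added to the pooled norm
#'   (prevents division by zero).
#' @param activation_threshold Responses below this value are floored to it.
#' @param saturation_ceiling Responses above this value are clipped to it.
#' @param stride Spatial subsampling step applied to the response maps
#'   before flattening.
#' @return An object of class `v1_params`.
#' @export
v1_params <- function(input_norm_neighborhood = 3,
                      output_norm_neighborhood = 3,
                      norm_stabilizer = 1e-4,
                      activation_threshold = 0,
                      saturation_ceiling = 1,
                      stride = 4) {
  stopifnot(norm_stabilizer > 0,
            activation_threshold < saturation_ceiling,
            input_norm_neighborhood %% 2 == 1,
            output_norm_neighborhood %% 2 == 1,
            stride >= 1)
  structure(list(input_norm_neighborhood = input_norm_neighborhood,
                 output_norm_neighborhood = output_norm_neighborhood,
                 norm_stabilizer = norm_stabilizer,
                 activation_threshold = activation_threshold,
                 saturation_ceiling = saturation_ceiling,
                 stride = stride),
            class = "v1_params")
}

# 2-D "valid" cross-correlation via FFT. Returns a
# (nrow(x)-k+1) x (ncol(x)-k+1) map.
conv2_valid <- function(x, kernel) {
  k <- nrow(kernel)
  nr <- nrow(x) + k - 1
  nc <- ncol(x) + k - 1
  xp <- matrix(0, nr, nc); xp[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  kp <- matrix(0, nr, nc)
  # correlation = convolution with the flipped kernel
  kp[seq_len(k), seq_len(k)] <- kernel[k:1, k:1]
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / (nr * nc)
  full[k:nrow(x), k:ncol(x), drop = FALSE]
}

# Same, but with the kernel FFT precomputed for padded size nr x nc.
conv2_valid_f <- function(xf, kf, k, nr, nc, out_r, out_c) {
  full <- Re(stats::fft(xf * kf, inverse = TRUE)) / (nr * nc)
  full[k:(out_r + k - 1), k:(out_c + k - 1), drop = FALSE]
}

# Local divisive normalization: x / (eps + L2 norm of the w x w neighborhood).
# Computed with a box filter on x^2 ("same" size, zero padding at borders).
# Because the pooled L2 norm always dominates |x|, the output is bounded by
# 1 in magnitude.
divisive_normalize <- function(x, w, eps) {
  half <- (w - 1) / 2
  box <- matrix(1, w, w)
  nr <- nrow(x) + w - 1; nc <- ncol(x) + w - 1
  xp <- matrix(0, nr, nc)
  xp[half + seq_len(nrow(x)), half + seq_len(ncol(x))] <- x^2
  bp <- matrix(0, nr, nc); bp[seq_len(w), seq_len(w)] <- box
  pooled <- Re(stats::fft(stats::fft(xp) * stats::fft(bp), inverse = TRUE)) / (nr * nc)
  pooled <- pooled[w:(nrow(x) + w - 1), w:(ncol(x) + w - 1), drop = FALSE]
  pooled[pooled < 0] <- 0  # FFT round-off
  x / (eps + sqrt(pooled))
}

# Mirror-symmetric subsample grid along one axis of length n with step s.
stride_grid <- function(n, s) {
  if (s <= 1) return(seq_len(n))
  offset <- ((n - 1) %% s) %/% 2
  seq(offset + 1, n, by = s)
}

#' Encode a stimulus image with the V1-like model
#'
#' Pipeline, in fixed order: (1) local divisive normalization of the input
#' image; (2) convolution with every Gabor filter of the bank (valid region
#' only, so border artifacts never enter the code); (3) output
#' nonlinearities — thresholding (floor) and response saturation (clip);
#' (4) local divisive normalization of each response map; then spatial
#' subsampling by `params$stride` and flattening. Deterministic given
#' (image, spec, params).
#'
#' @param img A `stim_image` or a numeric matrix.
#' @param spec A `filterbank_spec`.
#' @param params A `v1_params`.
#' @param bank Optional pre-built filter bank (from [build_filterbank()]).
#' @param stages Character vector of enabled stages, for ablation studies;
#'   any subset of `c("input_norm", "threshold", "saturate", "output_norm")`.
#'   Convolution always runs.
#' @return An object of class `v1_response`: list with `values` (numeric
#'   vector), `map_dim`, `n_filters`, `image_id`.
#' @export
v1_encode <- function(img, spec = filterbank_spec(), params = v1_params(),
                      bank = NULL,
                      stages = c("input_norm", "threshold", "saturate",
                                 "output_norm")) {
  x <- if (inherits(img, "stim_image")) img$pixels else img
  image_id <- if (inherits(img, "stim_image")) img$config$id else "image"
  if (nrow(x) < spec$filter_size || ncol(x) < spec$filter_size)
    stop("image is smaller than the filter size", call. = FALSE)
  if (is.null(bank)) bank <- build_filterbank(spec)
  x <- x * 1.0
  if ("input_norm" %in% stages)
    x <- divisive_normalize(x, params$input_norm_neighborhood,
                            params$norm_stabilizer)
  k <- spec$filter_size
  out_r <- nrow(x) - k + 1; out_c <- ncol(x) - k + 1
  nr <- nrow(x) + k - 1; nc <- ncol(x) + k - 1
  xp <- matrix(0, nr, nc); xp[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  xf <- stats::fft(xp)
  rows <- stride_grid(out_r, params$stride)
  cols <- stride_grid(out_c, params$stride)
  values <- vector("list", length(bank))
  for (i in seq_along(bank)) {
    kp <- matrix(0, nr, nc)
    kp[seq_len(k), seq_len(k)] <- bank[[i]][k:1, k:1]
    m <- conv2_valid_f(xf, stats::fft(kp), k, nr, nc, out_r, out_c)
    if ("threshold" %in% stages)
      m[m < params$activation_threshold] <- params$activation_threshold
    if ("saturate" %in% stages)
      m[m > params$saturation_ceiling] <- params$saturation_ceiling
    if ("output_norm" %in% stages)
      m <- divisive_normalize(m, params$output_norm_neighborhood,
                              params$norm_stabilizer)
    values[[i]] <- as.vector(m[rows, cols, drop = FALSE])
  }
  structure(list(values = unlist(values, use.names = FALSE),
                 map_dim = c(length(rows), length(cols)),
                 n_filters = length(bank),
                 image_id = image_id),
            class = "v1_response")
}

#' @export
print.v1_response <- function(x, ...) {
  cat(sprintf("<v1_response> %s: %d filters x %d x %d positions (%d values)\n",
              x$image_id, x$n_filters, x$map_dim[1], x$map_dim[2],
              length(x$values)))
  invisible(x)
}

#' Correlation-based model distance
#'
#' One minus the Pearson correlation between two model response vectors;
#' lies in \[0, 2\].
#'
#' @param r_i,r_j `v1_response` objects or plain numeric vectors of equal
#'   length.
#' @return A single number in \[0, 2\].
#' @export
model_distance <- function(r_i, r_j) {
  vi <- if (inherits(r_i, "v1_response")) r_i$values else r_i
  vj <- if (inherits(r_j, "v1_response")) r_j$values else r_j
  if (length(vi) != length(vj))
    stop("response vectors must have equal length", call. = FALSE)
  if (stats::sd(vi) == 0 || stats::sd(vj) == 0)
    stop("model distance is undefined for a zero-variance response vector",
         call. = FALSE)
  1 - stats::cor(vi, vj)
}

#' Responses and pairwise model distances for a stimulus set
#'
#' @param images Named list of `stim_image`s.
#' @param spec A `filterbank_spec`.
#' @param params A `v1_params`.
#' @return A list with `responses` (list of `v1_response`) and `distances`
#'   (symmetric matrix with zero diagonal, dimnames = stimulus ids).
#' @export
v1_response_matrix <- function(images, spec = filterbank_spec(),
                               params = v1_params()) {
  stopifnot(length(images) >= 2)
  bank <- build_filterbank(spec)
  ids <- names(images)
  if (is.null(ids)) ids <- paste0("stim", seq_along(images))
  responses <- vector("list", length(images))
  for (i in seq_along(images)) {
    responses[[i]] <- tryCatch(
      v1_encode(images[[i]], spec, params, bank = bank),
      error = function(e) stop(sprintf("encoding '%s' failed: %s",
                                       ids[i], conditionMessage(e)),
                               call. = FALSE))
  }
  names(responses) <- ids
  n <- length(images)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- model_distance(responses[[i]], responses[[j]])
  }
  list(responses = responses, distances = d)
}

#' Model-based within/between class distance summary
#'
#' Convenience wrapper computing [class_distance_summary()] under the model
#' metric from a precomputed distance matrix.
#'
#' @param task A `task_mapping`.
#' @param distances Symmetric distance matrix over the 4 base stimuli with
#'   ids as dimnames.
#' @return A list with `within` and `between` means.
#' @export
class_distance_from_matrix <- function(task, distances) {
  configs <- make_base_set()
  ids <- names(configs)
  stopifnot(all(ids %in% rownames(distances)))
  cls <- vapply(configs, task$class_of, "")
  within <- c(); between <- c()
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    d <- distances[ids[i], ids[j]]
    if (cls[i] == cls[j]) within <- c(within, d) else between <- c(between, d)
  }
  list(within = mean(within), between = mean(between))
}
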