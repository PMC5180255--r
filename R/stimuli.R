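#' Stimulus configurations
#'
#' A stimulus is a central vertical arm plus one optional horizontal arm
#' slot near the top and one near the bottom on each side. `stim_config()`
#' describes a stimulus symbolically by the occupancy of its left and right
#' horizontal-arm slots; the central arm is always present.
#'
#' @param left,right Occupancy of the left/right horizontal arm:
#'   `"top"`, `"bottom"`, `"both"` or `"none"`.
#' @return An object of class `stim_config` with fields `left`, `right`
#'   and an `id` string.
#' @examples
#' stim_config("top", "bottom")
#' @export
stim_config <- function(left, right) {
  occ <- c("top", "bottom", "both", "none")
  left <- match.arg(left, occ)
  right <- match.arg(right, occ)
  structure(
    list(left = left, right = right, central = TRUE,
         id = paste0("L", left, "_R", right)),
    class = "stim_config"
  )
}

#' @export
print.stim_config <- function(x, ...) {
  cat("<stim_config> left arm:", x$left, "| right arm:", x$right,
      "| central arm: present\n")
  invisible(x)
}

#' @export
format.stim_config <- function(x, ...) x$id

#' Test whether two configurations are identical
#'
#' @param a,b `stim_config` objects.
#' @return Logical scalar.
#' @export
config_equal <- function(a, b) {
  identical(a$left, b$left) && identical(a$right, b$right)
}

#' Is a configuration a base stimulus?
#'
#' Base stimuli carry exactly one horizontal arm per side (top or bottom,
#' never both or none).
#'
#' @param config A `stim_config`.
#' @return Logical scalar.
#' @export
is_base_config <- function(config) {
  config$left %in% c("top", "bottom") && config$right %in% c("top", "bottom")
}

#' The four base stimuli
#'
#' Every combination of top/bottom occupancy of the left and right arm.
#' Two of the four (left equal to right) are mirror-symmetric about the
#' vertical midline.
#'
#' @return A list of 4 `stim_config` objects, named by id.
#' @export
make_base_set <- function() {
  cfgs <- list(
    stim_config("top", "top"),
    stim_config("top", "bottom"),
    stim_config("bottom", "top"),
    stim_config("bottom", "bottom")
  )
  names(cfgs) <- vapply(cfgs, function(x) x$id, "")
  cfgs
}

#' Stimulus geometry
#'
#' Physical layout of the stimulus in visual degrees together with the
#' degree-to-pixel scale. Defaults follow the study display: the stimulus
#' spans 61.92 degrees horizontally and 69.98 degrees vertically and the
#' central arm is 17.06 degrees wide. Horizontal arms are as thick as the
#' central arm is wide, run from the central arm's edge to the lateral
#' canvas edge, and sit flush with the top/bottom canvas edge
#' (`arm_vertical_offset = 0`).
#'
#' @param total_width,total_height Canvas extent in visual degrees.
#' @param central_arm_width Width of the central vertical arm (degrees).
#' @param pixels_per_degree Rendering scale (pixels per visual degree).
#' @param horizontal_arm_thickness Thickness of the horizontal arms
#'   (degrees); defaults to the central arm width.
#' @param arm_vertical_offset Distance of a horizontal arm from the nearest
#'   (top or bottom) canvas edge, in degrees.
#' @return An object of class `stim_geometry`.
#' @export
stim_geometry <- function(total_width = 61.92,
                          total_height = 69.98,
                          central_arm_width = 17.06,
                          pixels_per_degree = 2,
                          horizontal_arm_thickness = central_arm_width,
                          arm_vertical_offset = 0) {
  stopifnot(pixels_per_degree > 0, total_width > 0, total_height > 0)
  if (central_arm_width >= total_width)
    stop("central arm must be narrower than the canvas", call. = FALSE)
  if (2 * arm_vertical_offset + 2 * horizontal_arm_thickness > total_height)
    stop("horizontal arms do not fit on the canvas", call. = FALSE)
  g <- list(
    total_width = total_width,
    total_height = total_height,
    central_arm_width = central_arm_width,
    pixels_per_degree = pixels_per_degree,
    horizontal_arm_thickness = horizontal_arm_thickness,
    arm_vertical_offset = arm_vertical_offset
  )
  g$ncol <- round(total_width * pixels_per_degree)
  g$nrow <- round(total_height * pixels_per_degree)
  structure(g, class = "stim_geometry")
}

#' @export
print.stim_geometry <- function(x, ...) {
  cat(sprintf(
    "<stim_geometry> %.2f x %.2f deg at %g px/deg -> %d x %d px (rows x cols)\n",
    x$total_width, x$total_height, x$pixels_per_degree, x$nrow, x$ncol))
  invisible(x)
}

# Pixel column/row ranges of the arm regions, computed symmetrically about
# the canvas midlines so that equal left/right occupancy yields an exactly
# mirror-symmetric raster. Coordinates are row-major, origin at the top-left,
# 1-based (R convention); row 1 is the top of the stimulus.
arm_regions <- function(geometry) {
  g <- geometry
  ppd <- g$pixels_per_degree
  hw <- round(g$central_arm_width * ppd / 2)   # central arm half-width, px
  cmid <- g$ncol / 2
  central_cols <- (floor(cmid) - hw + 1):(ceiling(cmid) + hw)
  central_cols <- central_cols[central_cols >= 1 & central_cols <= g$ncol]
  left_cols <- seq_len(min(central_cols) - 1)
  right_cols <- if (max(central_cols) < g$ncol)
    (max(central_cols) + 1):g$ncol else integer(0)
  th <- round(g$horizontal_arm_thickness * ppd)
  off <- round(g$arm_vertical_offset * ppd)
  top_rows <- (off + 1):(off + th)
  bottom_rows <- (g$nrow - off - th + 1):(g$nrow - off)
  list(central_cols = central_cols, left_cols = left_cols,
       right_cols = right_cols, top_rows = top_rows, bottom_rows = bottom_rows)
}

#' Render a stimulus configuration to a binary image
#'
#' Deterministic rasterization: the central vertical arm spans the full
#' canvas height; each occupied horizontal-arm slot is drawn from the
#' central arm's edge to the lateral canvas edge. White (foreground) pixels
#' are 1, black pixels are 0.
#'
#' @param config A `stim_config`.
#' @param geometry A `stim_geometry`.
#' @return An object of class `stim_image`: a list with `pixels` (an
#'   `nrow x ncol` 0/1 matrix), `config` and `geometry`.
#' @export
render_stimulus <- function(config, geometry = stim_geometry()) {
  stopifnot(inherits(config, "stim_config"), inherits(geometry, "stim_geometry"))
  reg <- arm_regions(geometry)
  if (length(reg$left_cols) == 0 || length(reg$right_cols) == 0)
    stop("central arm leaves no room for horizontal arms", call. = FALSE)
  px <- matrix(0L, nrow = geometry$nrow, ncol = geometry$ncol)
  px[, reg$central_cols] <- 1L
  draw <- function(rows, cols) px[rows, cols] <<- 1L
  if (config$left %in% c("top", "both")) draw(reg$top_rows, reg$left_cols)
  if (config$left %in% c("bottom", "both")) draw(reg$bottom_rows, reg$left_cols)
  if (config$right %in% c("top", "both")) draw(reg$top_rows, reg$right_cols)
  if (config$right %in% c("bottom", "both")) draw(reg$bottom_rows, reg$right_cols)
  structure(list(pixels = px, config = config, geometry = geometry),
            class = "stim_image")
}

#' @export
print.stim_image <- function(x, ...) {
  cat(sprintf("<stim_image> %s, %d x %d px, foreground fraction %.3f\n",
              x$config$id, nrow(x$pixels), ncol(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' Normalized pixel-wise distance between two binary images
#'
#' The squared pixel-wise difference summed over the canvas and divided by
#' the total pixel count n, i.e. the squared Euclidean distance normalized
#' by the maximal possible difference in an n-dimensional unit hypercube.
#' Lies in \[0, 1\] for binary images and is symmetric in its arguments.
#'
#' @param img_i,img_j `stim_image` objects (or plain matrices) with
#'   identical dimensions.
#' @return A single number in \[0, 1\].
#' @export
pixel_distance <- function(img_i, img_j) {
  pi_ <- if (inherits(img_i, "stim_image")) img_i$pixels else img_i
  pj_ <- if (inherits(img_j, "stim_image")) img_j$pixels else img_j
  if (!all(dim(pi_) == dim(pj_)))
    stop("images must have identical dimensions", call. = FALSE)
  sum((pi_ - pj_)^2) / length(pi_)
}

#' Task mappings: linear and nonlinear (symmetry / XOR)
#'
#' The linear task assigns base stimuli to the target class when the right
#' arm sits near the top: a single local cue carries the category. The
#' nonlinear task assigns the two mirror-symmetric stimuli (left arm height
#' equal to right arm height) to the target class: the category is the
#' XOR-like agreement of the two arm heights and no single pixel is
#' informative.
#'
#' @param task_id `"linear"` or `"nonlinear"`.
#' @return An object of class `task_mapping` with a `class_of(config)`
#'   function returning `"target"` or `"distractor"`.
#' @export
task_mapping <- function(task_id = c("linear", "nonlinear")) {
  task_id <- match.arg(task_id)
  class_of <- if (task_id == "linear") {
    function(config) if (config$right == "top") "target" else "distractor"
  } else {
    function(config) if (config$left == config$right) "target" else "distractor"
  }
  structure(list(task_id = task_id, class_of = class_of),
            class = "task_mapping")
}

#' @export
print.task_mapping <- function(x, ...) {
  cat("<task_mapping>", x$task_id, "\n")
  invisible(x)
}

#' Split the base set into target and distractor configurations
#'
#' @param task A `task_mapping`.
#' @param configs A list of `stim_config`s; defaults to the base set.
#' @return A list with elements `target` and `distractor`.
#' @export
split_by_class <- function(task, configs = make_base_set()) {
  cls <- vapply(configs, task$class_of, "")
  list(target = configs[cls == "target"],
       distractor = configs[cls == "distractor"])
}

#' Single-arm manipulations of a base stimulus
#'
#' All configurations reachable by adding or removing one horizontal arm:
#' remove the existing left arm, remove the existing right arm, add the
#' missing left slot, add the missing right slot. The central arm is never
#' edited. Each base configuration yields exactly 4 manipulated
#' configurations, none equal to the input.
#'
#' @param config A base `stim_config`.
#' @return A list of 4 `stim_config`s, named by id.
#' @export
enumerate_manipulations <- function(config) {
  if (!is_base_config(config))
    stop("manipulations are defined for base stimuli only", call. = FALSE)
  out <- list(
    stim_config("none", config$right),   # remove left arm
    stim_config("both", config$right),   # add missing left slot
    stim_config(config$left, "none"),    # remove right arm
    stim_config(config$left, "both")     # add missing right slot
  )
  names(out) <- vapply(out, function(x) x$id, "")
  out
}

# Union of manipulations over a list of base configs, deduplicated by id
# and ordered by id for reproducible matrix layouts.
union_manipulations <- function(configs) {
  all <- unlist(lapply(configs, enumerate_manipulations), recursive = FALSE)
  all <- all[!duplicated(vapply(all, function(x) x$id, ""))]
  all[order(vapply(all, function(x) x$id, ""))]
}

#' Manipulated stimulus pairs for the linear task
#'
#' Applies the single-arm add/remove manipulation to the positive and the
#' negative base stimuli of the linear task (6 unique manipulated stimuli
#' on each side), forms all pairwise positive-by-negative combinations
#' (36), and removes the pairs whose two stimuli are identical (4),
#' retaining 32 pairs.
#'
#' @param task A `task_mapping`; must be the linear task.
#' @return A list with `positives`, `negatives` (lists of `stim_config`),
#'   `pairs` (data frame with `pair_id`, `positive`, `negative`,
#'   `identical`), and counts `n_raw`, `n_removed`, `n_retained`. Retained
#'   pairs have `identical == FALSE`.
#' @export
build_manipulated_pairs <- function(task = task_mapping("linear")) {
  if (task$task_id != "linear")
    stop("manipulated pairs are defined for the linear task", call. = FALSE)
  cls <- split_by_class(task)
  pos <- union_manipulations(cls$target)
  neg <- union_manipulations(cls$distractor)
  grid <- expand.grid(p = seq_along(pos), n = seq_along(neg))
  pid <- vapply(pos, function(x) x$id, "")
  nid <- vapply(neg, function(x) x$id, "")
  pairs <- data.frame(
    pair_id = paste(pid[grid$p], nid[grid$n], sep = "|"),
    positive = pid[grid$p],
    negative = nid[grid$n],
    row = grid$p,
    col = grid$n,
    identical = pid[grid$p] == nid[grid$n],
    stringsAsFactors = FALSE
  )
  list(positives = pos, negatives = neg, pairs = pairs,
       n_raw = nrow(pairs),
       n_removed = sum(pairs$identical),
       n_retained = sum(!pairs$identical))
}

#' Within- and between-class mean dissimilarity
#'
#' Averages a dissimilarity metric over all same-class stimulus pairs
#' (within) and all cross-class pairs (between) for the four base stimuli
#' under a task mapping.
#'
#' @param task A `task_mapping`.
#' @param metric A function of two `stim_image`s returning a number;
#'   defaults to [pixel_distance()].
#' @param geometry A `stim_geometry`.
#' @param images Optional pre-rendered named list of `stim_image`s (one per
#'   base config); rendered from `geometry` when omitted.
#' @return A list with `within`, `between` (means), and the underlying
#'   per-pair values.
#' @export
class_distance_summary <- function(task, metric = pixel_distance,
                                   geometry = stim_geometry(),
                                   images = NULL) {
  configs <- make_base_set()
  if (is.null(images))
    images <- lapply(configs, render_stimulus, geometry = geometry)
  cls <- vapply(configs, task$class_of, "")
  if (min(table(cls)) < 2)
    stop("each class needs at least 2 stimuli for a within-class mean",
         call. = FALSE)
  n <- length(images)
  within <- c(); between <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- metric(images[[i]], images[[j]])
      if (cls[i] == cls[j]) within <- c(within, d) else between <- c(between, d)
    }
  }
  list(within = mean(within), between = mean(between),
       within_values = within, between_values = between)
}

#' Pixel-space class-mean images
#'
#' Mean rendered image of the target class and of the distractor class. For
#' the nonlinear (symmetry) task the two class means are identical
#' pixel-for-pixel — the class-mean collision that makes the task
#' unsolvable by any linear readout. For the linear task the class means
#' differ only in the right-arm regions.
#'
#' @param task A `task_mapping`.
#' @param geometry A `stim_geometry`.
#' @return A list with matrices `target_mean`, `distractor_mean` and their
#'   difference `diff`.
#' @export
class_mean_images <- function(task, geometry = stim_geometry()) {
  cls <- split_by_class(task)
  avg <- function(cfgs) {
    mats <- lapply(cfgs, function(cf) render_stimulus(cf, geometry)$pixels)
    Reduce(`+`, mats) / length(mats)
  }
  tm <- avg(cls$target); dm <- avg(cls$distractor)
  list(target_mean = tm, distractor_mean = dm, diff = tm - dm)
}

#' Write a stimulus manifest and rendered images
#'
#' @param out_dir Output directory (created if needed).
#' @param geometry A `stim_geometry`.
#' @param configs List of `stim_config`s; defaults to the base set.
#' @return Invisibly, the manifest data frame (config id, file, class under
#'   each task).
#' @export
write_stimulus_manifest <- function(out_dir, geometry = stim_geometry(),
                                    configs = make_base_set()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lin <- task_mapping("linear"); nonlin <- task_mapping("nonlinear")
  rows <- lapply(configs, function(cf) {
    img <- render_stimulus(cf, geometry)
    f <- file.path(out_dir, paste0(cf$id, ".csv"))
    utils::write.table(img$pixels, f, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    data.frame(id = cf$id, file = basename(f),
               class_linear = if (is_base_config(cf)) lin$class_of(cf) else NA,
               class_nonlinear = if (is_base_config(cf)) nonlin$class_of(cf) else NA,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
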