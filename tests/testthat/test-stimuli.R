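test_that("base set contains the four top/bottom combinations exactly once", {
  base <- make_base_set()
  expect_length(base, 4)
  ids <- vapply(base, function(x) x$id, "")
  expect_equal(unname(sort(ids)), sort(c("Ltop_Rtop", "Ltop_Rbottom",
                                         "Lbottom_Rtop", "Lbottom_Rbottom")))
  occ <- unlist(lapply(base, function(x) c(x$left, x$right)))
  expect_true(all(occ %in% c("top", "bottom")))
  n_sym <- sum(vapply(base, function(x) x$left == x$right, TRUE))
  expect_equal(n_sym, 2)
})

test_that("task mappings split the base set into 2 targets and 2 distractors", {
  for (tk in c("linear", "nonlinear")) {
    cls <- split_by_class(task_mapping(tk))
    expect_length(cls$target, 2)
    expect_length(cls$distractor, 2)
  }
  nl <- task_mapping("nonlinear")
  expect_equal(nl$class_of(stim_config("top", "top")), "target")
  expect_equal(nl$class_of(stim_config("top", "bottom")), "distractor")
  li <- task_mapping("linear")
  expect_equal(li$class_of(stim_config("bottom", "top")), "target")
})

test_that("rendering is deterministic and binary", {
  cf <- stim_config("top", "bottom")
  a <- render_stimulus(cf, g_default)
  b <- render_stimulus(cf, g_default)
  expect_identical(a$pixels, b$pixels)
  expect_true(all(a$pixels %in% c(0L, 1L)))
  expect_equal(dim(a$pixels), c(g_default$nrow, g_default$ncol))
})

test_that("mirror symmetry about the vertical midline holds iff arms match", {
  for (cf in make_base_set()) {
    px <- render_stimulus(cf, g_default)$pixels
    is_sym <- identical(px, px[, ncol(px):1, drop = FALSE])
    expect_equal(is_sym, cf$left == cf$right, info = cf$id)
  }
})

test_that("foreground fraction is resolution-invariant within tolerance", {
  cf <- stim_config("top", "bottom")
  f1 <- mean(render_stimulus(cf, stim_geometry(pixels_per_degree = 1))$pixels)
  f4 <- mean(render_stimulus(cf, stim_geometry(pixels_per_degree = 4))$pixels)
  expect_lt(abs(f1 - f4), 0.02)
})

test_that("invalid geometry is rejected", {
  expect_error(stim_geometry(central_arm_width = 70), "narrower")
  expect_error(stim_geometry(horizontal_arm_thickness = 40), "fit")
  expect_error(render_stimulus(stim_config("top", "top"),
                               stim_geometry(central_arm_width = 61.9,
                                             total_width = 61.92,
                                             horizontal_arm_thickness = 17)),
               "no room")
})

test_that("pixel distance is the hypercube-normalized squared difference", {
  imgs <- base_images()
  expect_equal(pixel_distance(imgs[[1]], imgs[[1]]), 0)
  white <- matrix(1, 10, 8); black <- matrix(0, 10, 8)
  expect_equal(pixel_distance(white, black), 1)
  # symmetry over all rendered pairs
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(pixel_distance(imgs[[i]], imgs[[j]]),
                 pixel_distance(imgs[[j]], imgs[[i]]))
  expect_error(pixel_distance(white, matrix(0, 9, 8)), "dimensions")
})

test_that("pixel distances are stable across rendering resolutions", {
  for (pair in list(c(1, 2), c(1, 4), c(2, 3))) {
    d2 <- pixel_distance(base_images(stim_geometry(pixels_per_degree = 2))[[pair[1]]],
                         base_images(stim_geometry(pixels_per_degree = 2))[[pair[2]]])
    d4 <- pixel_distance(base_images(stim_geometry(pixels_per_degree = 4))[[pair[1]]],
                         base_images(stim_geometry(pixels_per_degree = 4))[[pair[2]]])
    expect_lt(abs(d2 - d4), 0.02)
  }
})

test_that("single-arm manipulations produce 4 new configs per base stimulus", {
  for (cf in make_base_set()) {
    man <- enumerate_manipulations(cf)
    expect_length(man, 4)
    expect_length(unique(names(man)), 4)
    for (m in man) expect_false(config_equal(m, cf))
  }
  expect_error(enumerate_manipulations(stim_config("both", "top")), "base")
})

test_that("manipulations are invertible by the opposite edit", {
  for (cf in make_base_set()) {
    for (m in enumerate_manipulations(cf)) {
      # exactly one side was edited; restoring that side's original occupancy
      # recovers the starting configuration
      side <- if (m$left != cf$left) "left" else "right"
      restored <- if (side == "left") stim_config(cf$left, m$right)
      else stim_config(m$left, cf$right)
      expect_true(config_equal(restored, cf))
    }
  }
})

test_that("manipulated pair enumeration reproduces the 6/6/36/4/32 design", {
  mp <- build_manipulated_pairs(task_mapping("linear"))
  expect_length(mp$positives, 6)
  expect_length(mp$negatives, 6)
  expect_equal(mp$n_raw, 36)
  expect_equal(mp$n_removed, 4)
  expect_equal(mp$n_retained, 32)
  kept <- mp$pairs[!mp$pairs$identical, ]
  expect_true(all(kept$positive != kept$negative))
  expect_error(build_manipulated_pairs(task_mapping("nonlinear")), "linear")
})

test_that("nonlinear class means collide exactly; linear difference sits in the right-arm region", {
  cm_nl <- class_mean_images(task_mapping("nonlinear"), g_default)
  expect_identical(max(abs(cm_nl$diff)), 0)
  cm_li <- class_mean_images(task_mapping("linear"), g_default)
  nz <- which(cm_li$diff != 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  reg <- crosslearn:::arm_regions(g_default)
  expect_true(all(nz[, 2] >= min(reg$right_cols)))
})

test_that("within/between class distance pattern dissociates the two tasks", {
  s_nl <- class_distance_summary(task_mapping("nonlinear"))
  expect_gt(s_nl$within, s_nl$between)
  s_li <- class_distance_summary(task_mapping("linear"))
  expect_lte(s_li$within, s_li$between)
  # constant metric degenerates to zero on both sides
  s0 <- class_distance_summary(task_mapping("nonlinear"),
                               metric = function(a, b) 0)
  expect_equal(s0$within, 0)
  expect_equal(s0$between, 0)
})

test_that("a class with fewer than 2 members is rejected explicitly", {
  lopsided <- structure(list(
    task_id = "linear",
    class_of = function(cf) if (cf$id == "Ltop_Rtop") "target" else "distractor"
  ), class = "task_mapping")
  expect_error(class_distance_summary(lopsided), "at least 2")
})

test_that("stimulus manifest round-trips configs, files and classes", {
  out <- withr::local_tempdir()
  manifest <- write_stimulus_manifest(out, g_coarse)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_equal(nrow(manifest), 4)
  px <- as.matrix(utils::read.csv(file.path(out, manifest$file[1]),
                                  header = FALSE))
  orig <- render_stimulus(make_base_set()[[manifest$id[1]]], g_coarse)$pixels
  expect_equal(unname(px), unname(orig), ignore_attr = TRUE)
})
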