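test_that("motion CSV round trip is lossless and structurally exact", {
  withr::with_seed(11, {
    m <- random_motion(n = 7, J = 31)
    path <- withr::local_tempfile(fileext = ".csv")
    write_motion_csv(m, path)
    lines <- readLines(path)
    expect_length(lines, 2 + 7)                    # header + fps + frames
    expect_match(lines[1], "^j00_x,j00_y,j00_z,")
    expect_match(lines[2], "^# fps=")
    m2 <- read_motion_csv(path)
    expect_identical(m2$frames, m$frames)          # bitwise round trip
    expect_equal(m2$fps, m$fps)
    # byte-identical re-write (write/read/write fixed point)
    path2 <- withr::local_tempfile(fileext = ".csv")
    write_motion_csv(m2, path2)
    expect_identical(readLines(path2), lines)
  })
})

test_that("CSV round trip is lossless across many random motions", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      m <- random_motion(n = sample(1:12, 1), J = sample(c(2, 5, 31), 1),
                         scale = 10^stats::runif(1, -3, 3))
      path <- withr::local_tempfile(fileext = ".csv")
      write_motion_csv(m, path)
      expect_identical(read_motion_csv(path)$frames, m$frames)
    }
  })
})

test_that("malformed motion files are rejected with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  # column count not divisible by 3 (94 columns)
  writeLines(c(paste(c(actionkeys:::joint_colnames(31), "extra"),
                     collapse = ","), "# fps=120"), path)
  expect_error(read_motion_csv(path), "not divisible by 3")
  # non-numeric cell, reported with row and column
  m <- motion(matrix(1, 2, 6), motion_id = "t")
  write_motion_csv(m, path)
  lines <- readLines(path)
  lines[4] <- "1,1,oops,1,1,1"
  writeLines(lines, path)
  expect_error(read_motion_csv(path), "row 2, column 3")
  # empty file
  writeLines(character(0), path)
  expect_error(read_motion_csv(path), "empty")
  # NaN never reaches disk
  bad <- motion(matrix(1, 2, 6))
  bad$frames[1, 1] <- NaN
  expect_error(write_motion_csv(bad, path), "non-finite")
  expect_error(read_motion_csv("/nonexistent/x.csv"), "no such")
})

test_that("dataset directory round trip preserves labels and ordering", {
  root <- withr::local_tempdir()
  withr::with_seed(31, {
    for (lab in c("walk", "run")) {
      dir.create(file.path(root, lab))
      for (i in seq_len(if (lab == "walk") 2 else 3))
        write_motion_csv(random_motion(n = 3, J = 5),
                         file.path(root, lab, sprintf("m%02d.csv", i)))
    }
  })
  ds <- load_dataset(root)
  expect_s3_class(ds, "motion_dataset")
  expect_identical(ds$classes, c("run", "walk"))   # sorted
  expect_length(ds$motions, 5)
  expect_identical(dataset_labels <- vapply(ds$motions, `[[`, "", "label"),
                   c(rep("run", 3), rep("walk", 2)))
  # determinism: reload gives identical structure
  ds2 <- load_dataset(root)
  expect_identical(lapply(ds2$motions, `[[`, "frames"),
                   lapply(ds$motions, `[[`, "frames"))
  expect_error(load_dataset(withr::local_tempdir()), "no class subdirectories")
})

test_that("synthetic dataset survives a write/load round trip", {
  cfg <- synth_config(n_classes = 2, motions_per_class = 3, J = 7,
                      frame_range = c(4L, 8L), seed = 5)
  ds <- generate_dataset(cfg)
  root <- withr::local_tempdir()
  write_dataset(ds, root)
  ds2 <- load_dataset(root)
  expect_identical(ds2$classes, ds$classes)
  ids <- vapply(ds$motions, `[[`, "", "motion_id")
  ids2 <- vapply(ds2$motions, `[[`, "", "motion_id")
  labs <- vapply(ds$motions, `[[`, "", "label")
  labs2 <- vapply(ds2$motions, `[[`, "", "label")
  expect_identical(labs2[match(ids, ids2)], labs)
  for (i in seq_along(ids))
    expect_identical(ds2$motions[[match(ids[i], ids2)]]$frames,
                     ds$motions[[i]]$frames)
})

test_that("keyframe index JSON round-trips losslessly and validates ranges", {
  m <- withr::with_seed(41, random_motion(n = 30, J = 5, scale = 30))
  res <- extract_keyframes(m, threshold = 25)
  path <- withr::local_tempfile(fileext = ".json")
  write_keyframe_index(res, path)
  res2 <- read_keyframe_index(path)
  expect_identical(res2$keyframes, as.integer(res$keyframes))
  expect_identical(res2$selection_order, as.integer(res$selection_order))
  expect_identical(lapply(res2$candidate_sets, as.integer),
                   lapply(res$candidate_sets, as.integer))
  expect_equal(res2$threshold, res$threshold)
  expect_equal(res2$k_initial, res$k_initial)
  expect_identical(res2$n, res$n)
  # out-of-range index rejected
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$keyframes <- c(obj$keyframes, 12L)
  obj$n <- 10L
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(read_keyframe_index(path), "outside")
})

test_that("trained model JSON round trip reproduces predictions exactly", {
  cfg <- synth_config(n_classes = 3, motions_per_class = 4, J = 7,
                      frame_range = c(6L, 10L), seed = 9)
  ds <- generate_dataset(cfg)
  nc <- net_config(input_dim = 21, hidden1 = 8, hidden2 = 6, output_dim = 3,
                   max_epochs = 3, seed = 2)
  model <- train_action_model(ds, config = nc)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(model, path)
  model2 <- read_network(path)
  expect_identical(model2$params$w, model$params$w)
  expect_identical(model2$params$class_names, model$params$class_names)
  expect_equal(model2$scaler, model$scaler)
  m <- ds$motions[[1]]
  p1 <- classify_motion(model, m)
  p2 <- classify_motion(model2, m)
  expect_identical(p1$predicted_class, p2$predicted_class)
  expect_identical(p1$prob_sums, p2$prob_sums)
})
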