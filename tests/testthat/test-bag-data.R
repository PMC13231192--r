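test_that("patient label is the OR over nodule diagnoses", {
  expect_equal(assign_patient_label(c(0, 1, 0)), 1)
  expect_equal(assign_patient_label(c(0, 0)), 0)
  expect_equal(assign_patient_label(1), 1)
  expect_error(assign_patient_label(numeric(0)), "no diagnoses")
})

write_tiny_manifest <- function(dir, conflicting = FALSE) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  set.seed(1)
  for (pid in c("A1", "B2")) {
    for (j in 1:3) {
      fn <- sprintf("images/%s_%d.png", pid, j)
      EBImage::writeImage(EBImage::Image(matrix(runif(16 * 16), 16)),
                          file.path(dir, fn), type = "png")
      lab <- if (pid == "A1") 1 else 0
      if (conflicting && pid == "A1" && j == 3) lab <- 0
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, image_path = fn, label = lab)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  file.path(dir, "manifest.csv")
}

test_that("manifest loading groups rows into bags and validates them", {
  dir <- withr::local_tempdir()
  mf <- write_tiny_manifest(dir)
  bags <- load_manifest(mf)
  expect_s3_class(bags, "mil_bags")
  expect_length(bags, 2)
  expect_equal(vapply(bags, function(b) b$patient_id, ""), c("A1", "B2"))
  expect_equal(vapply(bags, function(b) as.numeric(b$n), 1), c(3, 3))
  expect_equal(vapply(bags, function(b) b$label, 1), c(1, 0))
  expect_equal(dim(bags[[1]]$images[[1]]), c(16, 16))
  tb <- tibble::as_tibble(bags)
  expect_equal(nrow(tb), 6)
})

test_that("manifest loading errors name the offending patient or path", {
  dir <- withr::local_tempdir()
  mf <- write_tiny_manifest(dir, conflicting = TRUE)
  expect_error(load_manifest(mf), "conflicting labels.*A1")
  dir2 <- withr::local_tempdir()
  mf2 <- write_tiny_manifest(dir2)
  file.remove(file.path(dir2, "images/B2_2.png"))
  expect_error(load_manifest(mf2), "B2_2\\.png")
})

make_id_bags <- function(labels) {
  structure(lapply(seq_along(labels), function(i)
    list(patient_id = sprintf("P%03d", i), n = 1, label = labels[i])),
    class = "mil_bags")
}

test_that("patient splits have exact sizes, stratification and no leakage", {
  bags <- make_id_bags(rep(c(0, 1), each = 50))
  sp <- split_patients(bags, test_frac = 0.1, k = 5, seed = 3)
  expect_length(sp$test, 10)
  ids <- vapply(bags, function(b) b$patient_id, "")
  pool <- setdiff(ids, sp$test)
  for (f in sp$folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(sp$test, c(f$train, f$val)), 0)
    expect_length(f$val, 18)
    expect_setequal(c(f$train, f$val), pool)
  }
  # validation folds are pairwise disjoint and cover the pool
  vals <- lapply(sp$folds, `[[`, "val")
  expect_equal(sort(unlist(vals)), sort(pool))
  # stratification: each fold's validation set is half positive
  lab_of <- setNames(vapply(bags, function(b) b$label, 1), ids)
  for (v in vals) expect_equal(mean(lab_of[v]), 0.5)
})

test_that("split sizes follow round-half-up and uneven cohorts still partition", {
  bags <- make_id_bags(c(rep(1, 40), rep(0, 23)))  # 63 patients
  sp <- split_patients(bags, test_frac = 0.1, k = 5, seed = 9)
  expect_length(sp$test, 6)   # round(6.3)
  expect_equal(sum(lengths(lapply(sp$folds, `[[`, "val"))), 57)
  expect_error(split_patients(make_id_bags(c(0, 1, 0)), k = 5),
               "at least k \\+ 1")
})

test_that("splits are bitwise reproducible from the seed and survive a JSON round trip", {
  bags <- make_id_bags(sample(0:1, 37, TRUE))
  s1 <- split_patients(bags, test_frac = 0.15, k = 3, seed = 7)
  s2 <- split_patients(bags, test_frac = 0.15, k = 3, seed = 7)
  expect_identical(s1, s2)
  s3 <- split_patients(bags, test_frac = 0.15, k = 3, seed = 8)
  expect_false(identical(s1$test, s3$test))
  path <- withr::local_tempfile(fileext = ".json")
  write_split(s1, path)
  s4 <- read_split(path)
  expect_equal(s4$test, s1$test)
  for (f in 1:3) {
    expect_equal(s4$folds[[f]]$val, s1$folds[[f]]$val)
    expect_setequal(s4$folds[[f]]$train, s1$folds[[f]]$train)
  }
})

test_that("preprocessing resizes, replicates channels and standardises", {
  img <- matrix(0.485, 64, 64)
  out <- preprocess_image(img, size = 256)
  expect_equal(dim(out), c(256, 256, 3))
  expect_equal(max(abs(out[, , 1])), 0, tolerance = 1e-12)
  # one-sigma offset in channel 1
  out2 <- preprocess_image(matrix(0.485 + 0.229, 8, 8), size = 8)
  expect_equal(out2[, , 1], matrix(1, 8, 8), tolerance = 1e-12)
  expect_equal(out2[, , 2], matrix((0.714 - 0.456) / 0.224, 8, 8),
               tolerance = 1e-12)
  expect_error(preprocess_image(matrix(numeric(0), 0, 0)), "zero-dimension")
})

test_that("augmentation draws flip at rate 1/2 and right-angle rotations compose", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  # identity branch
  expect_identical(attnmil:::augment_apply(img, FALSE, 0L), img)
  # 180 degrees twice is the identity
  r180 <- attnmil:::augment_apply(img, FALSE, 2L)
  expect_equal(attnmil:::augment_apply(r180, FALSE, 2L), img)
  # flip is an involution
  expect_equal(attnmil:::augment_apply(
    attnmil:::augment_apply(img, TRUE, 0L), TRUE, 0L), img)
  # four quarter turns return the original
  expect_equal(attnmil:::augment_apply(img, FALSE, 4L), img)
  # Monte-Carlo check of the flip probability: on an asymmetric 2x2 marker,
  # a mirror reverses the clockwise reading order, and no right-angle
  # rotation can undo that, so flips are detectable under any rotation
  set.seed(123)
  marker <- array(matrix(c(1, 3, 2, 4), 2, 2), c(2, 2, 1))[, , c(1, 1, 1),
                                                           drop = FALSE]
  is_flipped <- function(out) {
    m <- out[, , 1]
    cw <- c(m[1, 1], m[1, 2], m[2, 2], m[2, 1])  # clockwise from top-left
    cw <- c(cw[which(cw == 1):4], cw[seq_len(which(cw == 1) - 1)])
    !identical(cw, c(1, 2, 4, 3))
  }
  expect_false(is_flipped(marker))
  n_flip <- sum(replicate(10000, is_flipped(augment_image(marker))))
  expect_gte(n_flip / 10000, 0.48)
  expect_lte(n_flip / 10000, 0.52)
})

test_that("collation pads with zero images and masks that sum to bag sizes", {
  bags <- tiny_cohort(n_patients = 4, seed = 21, image_size = 16)
  batch <- collate_bags(bags, image_size = 16)
  n <- vapply(bags, function(b) as.numeric(b$n), 1)
  expect_equal(dim(batch$images), c(16, 16, 3, max(n), 4))
  expect_equal(rowSums(batch$mask), n)
  for (b in 1:4) {
    pad <- which(batch$mask[b, ] == 0)
    for (j in pad) expect_true(all(batch$images[, , , j, b] == 0))
  }
  # single bag: no padding
  b1 <- collate_bags(bags[1], image_size = 16)
  expect_true(all(b1$mask == 1))
})
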