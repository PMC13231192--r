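# Patient-level bags: loading, labelling, splitting, preprocessing, batching.

#' Patient-level label from per-nodule diagnoses
#'
#' A patient is labelled malignant if any nodule was confirmed malignant
#' (the most severe diagnosis wins), mirroring the standard MIL assumption
#' that the bag label is the OR over instance labels.
#'
#' @param nodule_diagnoses non-empty binary vector (1 = malignant).
#' @return 0 or 1.
#' @export
#' @examples
#' assign_patient_label(c(0, 1, 0))  # 1
assign_patient_label <- function(nodule_diagnoses) {
  if (length(nodule_diagnoses) == 0L) stop("no diagnoses")
  stopifnot(all(nodule_diagnoses %in% c(0, 1)))
  as.numeric(any(nodule_diagnoses == 1))
}

read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (any(d[1:2] == 0L)) stop("unreadable or zero-dimension image: ", path)
  m <- EBImage::imageData(img)
  if (length(dim(m)) == 3L) m <- rowMeans(m, dims = 2L)  # to grayscale
  m
}

#' Load a cohort manifest into a list of bags
#'
#' The manifest is a UTF-8 CSV with header columns `patient_id`,
#' `image_path`, `label` and optionally `instance_label` (synthetic ground
#' truth). Image paths are resolved relative to the manifest's directory.
#' One bag is produced per distinct patient, ordered by `patient_id` with the
#' manifest row order preserved within a patient.
#'
#' @param path manifest file path.
#' @param load_images read pixel data eagerly (default `TRUE`; grayscale
#'   matrices in `[0, 1]`).
#' @return An object of class `"mil_bags"`: a list of bags, each with
#'   `patient_id`, `paths`, `n`, `label`, optional `instance_labels`, and
#'   `images` when loaded. `tibble::as_tibble()` gives a per-instance view.
#' @export
load_manifest <- function(path, load_images = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("patient_id", "image_path", "label")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  root <- dirname(normalizePath(path))
  df$patient_id <- as.character(df$patient_id)
  ids <- sort(unique(df$patient_id))
  bags <- lapply(ids, function(id) {
    rows <- df[df$patient_id == id, , drop = FALSE]
    labs <- unique(rows$label)
    if (length(labs) != 1L)
      stop("conflicting labels for patient ", id, ": ",
           paste(labs, collapse = ", "))
    paths <- file.path(root, rows$image_path)
    miss <- paths[!file.exists(paths)]
    if (length(miss) > 0L) stop("image file not found: ", miss[[1L]])
    bag <- list(patient_id = id, paths = paths, n = nrow(rows),
                label = as.numeric(labs))
    if ("instance_label" %in% names(rows)) {
      bag$instance_labels <- as.numeric(rows$instance_label)
      if (bag$label != max(bag$instance_labels))
        stop("bag label of patient ", id,
             " does not equal the OR of its instance labels")
    }
    if (load_images) bag$images <- lapply(paths, read_gray_image)
    bag
  })
  structure(bags, class = "mil_bags")
}

#' @export
as_tibble.mil_bags <- function(x, ...) {
  purrr::map_dfr(x, function(b) tibble::tibble(
    patient_id = b$patient_id,
    instance = seq_len(b$n),
    image_path = b$paths,
    label = b$label,
    instance_label = if (is.null(b$instance_labels)) NA_real_
                     else b$instance_labels))
}

#' @export
print.mil_bags <- function(x, ...) {
  n <- vapply(x, function(b) as.numeric(b$n), numeric(1))
  lab <- vapply(x, function(b) b$label, numeric(1))
  cat(sprintf("<mil_bags> %d patients (%d malignant), %d images, bag sizes %d-%d\n",
              length(x), sum(lab), sum(n), min(n), max(n)))
  invisible(x)
}

# allocate counts to strata by largest remainder so the total is exact
largest_remainder <- function(sizes, total) {
  q <- sizes * total / sum(sizes)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(q - base, sizes, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Patient-level stratified train/test and k-fold split
#'
#' Splitting is always by patient, never by image. A label-stratified test
#' set of `round(test_frac * P)` patients (ties rounded up) is held out
#' first; the remaining patients are dealt, per label and in seeded random
#' order, round-robin into `k` near-equal validation folds. Each fold's
#' training set is the pool minus its validation set, so validation sets are
#' pairwise disjoint and cover the pool.
#'
#' @param bags a `"mil_bags"` list (or tibble with `patient_id`, `label`).
#' @param test_frac fraction of patients held out for testing.
#' @param k number of cross-validation folds (>= 2).
#' @param seed integer; the split draws from its `"split"` sub-stream and is
#'   fully reproducible.
#' @return An object of class `"cohort_split"`: `test` (patient ids),
#'   `folds` (list of `list(train, val)`), `seed`, `counts`.
#' @export
split_patients <- function(bags, test_frac = 0.1, k = 5L, seed = 1L) {
  stopifnot(k >= 2L, test_frac > 0, test_frac < 1)
  if (inherits(bags, "mil_bags")) {
    ids <- vapply(bags, function(b) b$patient_id, character(1))
    labels <- vapply(bags, function(b) b$label, numeric(1))
  } else {
    df <- unique(tibble::as_tibble(bags)[, c("patient_id", "label")])
    ids <- as.character(df$patient_id); labels <- df$label
  }
  ord <- order(ids)
  ids <- ids[ord]; labels <- labels[ord]
  P <- length(ids)
  if (P < k + 1L) stop("need at least k + 1 = ", k + 1L, " patients, got ", P)
  n_test <- round_half_up(test_frac * P)
  strata <- split(ids, labels)
  test_per <- largest_remainder(lengths(strata), n_test)
  res <- with_stream(seed, "split", {
    test <- character(0)
    pool <- stats::setNames(vector("list", length(strata)), names(strata))
    for (s in seq_along(strata)) {
      sh <- sample(strata[[s]])
      test <- c(test, sh[seq_len(test_per[s])])
      pool[[s]] <- sh[-seq_len(test_per[s])]
    }
    val_folds <- replicate(k, character(0), simplify = FALSE)
    for (s in seq_along(pool)) {
      sh <- sample(pool[[s]])
      f <- rep_len(seq_len(k), length(sh))
      for (i in seq_len(k)) val_folds[[i]] <- c(val_folds[[i]], sh[f == i])
    }
    pool_all <- unlist(pool, use.names = FALSE)
    folds <- lapply(val_folds, function(v)
      list(train = sort(setdiff(pool_all, v)), val = sort(v)))
    list(test = sort(test), folds = folds)
  })
  structure(list(test = res$test, folds = res$folds, seed = as.integer(seed),
                 counts = list(patients = P, test = length(res$test),
                               fold_val = lengths(lapply(res$folds, `[[`, "val")))),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d patients: %d test, %d folds (val sizes %s); seed %d\n",
              x$counts$patients, x$counts$test, length(x$folds),
              paste(x$counts$fold_val, collapse = "/"), x$seed))
  invisible(x)
}

#' Write / read a cohort split as JSON
#'
#' The file maps every patient id to its role (`test` or `fold_<k>_val`;
#' training membership is implied) and records the seed and counts.
#'
#' @param split a [split_patients()] result.
#' @param path output file.
#' @return `path`, invisibly. `read_split()` returns the `"cohort_split"`.
#' @export
write_split <- function(split, path) {
  roles <- c(stats::setNames(rep("test", length(split$test)), split$test),
             unlist(lapply(seq_along(split$folds), function(i)
               stats::setNames(rep(sprintf("fold_%d_val", i),
                                   length(split$folds[[i]]$val)),
                               split$folds[[i]]$val))))
  jsonlite::write_json(list(seed = split$seed, k = length(split$folds),
                            counts = split$counts,
                            roles = as.list(roles[order(names(roles))])),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  roles <- unlist(j$roles)
  test <- sort(names(roles)[roles == "test"])
  pool <- sort(names(roles)[roles != "test"])
  folds <- lapply(seq_len(j$k), function(i) {
    v <- sort(names(roles)[roles == sprintf("fold_%d_val", i)])
    list(train = setdiff(pool, v), val = v)
  })
  structure(list(test = test, folds = folds, seed = as.integer(j$seed),
                 counts = j$counts), class = "cohort_split")
}

#' Preprocess a raw image for the backbone
#'
#' Resizes to `size x size` (bilinear), replicates grayscale to 3 channels,
#' and standardises each channel with the ImageNet statistics
#' `mu = (0.485, 0.456, 0.406)`, `sigma = (0.229, 0.224, 0.225)`.
#'
#' @param img numeric matrix `[H, W]` in `[0, 1]`, or array `[H, W, 3]`.
#' @param size output spatial size (default 256).
#' @return Numeric array `[size, size, 3]`.
#' @export
preprocess_image <- function(img, size = 256L) {
  d <- dim(img)
  if (is.null(d) || any(d[1:2] == 0L)) stop("unreadable or zero-dimension image")
  mu <- c(0.485, 0.456, 0.406); sigma <- c(0.229, 0.224, 0.225)
  if (length(d) == 2L) img <- array(img, c(d, 1L))
  if (dim(img)[3L] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (any(dim(img)[1:2] != size)) {
    img <- EBImage::imageData(EBImage::resize(
      EBImage::Image(img, colormode = "Color"), w = size, h = size))
    dim(img) <- c(size, size, 3L)
  }
  for (c in 1:3) img[, , c] <- (img[, , c] - mu[c]) / sigma[c]
  img
}

# deterministic geometric transform: optional horizontal flip (mirror along
# the width axis) then k quarter-turn rotations
augment_apply <- function(img, flip, k) {
  if (flip) img <- img[, dim(img)[2L]:1L, , drop = FALSE]
  k <- k %% 4L
  if (k > 0) for (i in seq_len(k))   # one quarter turn per pass
    img <- aperm(img, c(2L, 1L, 3L))[dim(img)[2L]:1L, , , drop = FALSE]
  img
}

#' Random training-time augmentation
#'
#' Horizontal flip with probability 0.5, then a rotation drawn uniformly
#' from \{0, 90, 180, 270\} degrees. Draws come from the current RNG state;
#' the evaluation path applies no augmentation.
#'
#' @param img numeric array `[H, W, C]` (square).
#' @return Transformed array of the same shape.
#' @export
augment_image <- function(img) {
  flip <- runif(1) < 0.5
  k <- sample(0:3, 1L)
  augment_apply(img, flip, k)
}

# cache the preprocessed (unaugmented) instances on each bag
preprocess_bags <- function(bags, image_size) {
  for (i in seq_along(bags)) {
    b <- bags[[i]]
    if (is.null(b$images)) b$images <- lapply(b$paths, read_gray_image)
    if (is.null(b$prep) || dim(b$prep[[1L]])[1L] != image_size)
      b$prep <- lapply(b$images, preprocess_image, size = image_size)
    bags[[i]] <- b
  }
  bags
}

# assemble the real instances of a list of bags into a flattened batch
prepare_instances <- function(bags, image_size = 64L, augment = FALSE) {
  bags <- preprocess_bags(bags, image_size)
  n <- vapply(bags, function(b) as.numeric(b$n), numeric(1))
  M <- sum(n)
  images <- array(0, c(image_size, image_size, 3L, M))
  m <- 0L
  for (b in bags) for (img in b$prep) {
    m <- m + 1L
    images[, , , m] <- if (augment) augment_image(img) else img
  }
  list(images = images, grp = rep(seq_along(bags), times = n),
       labels = vapply(bags, function(b) b$label, numeric(1)), n = n)
}

#' Collate bags into a zero-padded batch
#'
#' Pads every bag to the batch's maximum bag size with all-zero images and a
#' binary mask (1 = real instance). Row `b` of the mask sums to bag `b`'s
#' true size.
#'
#' @param bags a list of bags.
#' @param image_size preprocessing size.
#' @return List with `images` (`[size, size, 3, n_max, B]`), `mask`
#'   (`B x n_max`), `labels` (length `B`), `patient_id`.
#' @export
collate_bags <- function(bags, image_size = 64L) {
  stopifnot(length(bags) >= 1L)
  bags <- preprocess_bags(bags, image_size)
  n <- vapply(bags, function(b) as.integer(b$n), integer(1))
  n_max <- max(n); B <- length(bags)
  images <- array(0, c(image_size, image_size, 3L, n_max, B))
  mask <- matrix(0, B, n_max)
  for (b in seq_len(B)) {
    for (j in seq_len(n[b])) images[, , , j, b] <- bags[[b]]$prep[[j]]
    mask[b, seq_len(n[b])] <- 1
  }
  list(images = images, mask = mask,
       labels = vapply(bags, function(b) b$label, numeric(1)),
       patient_id = vapply(bags, function(b) b$patient_id, character(1)))
}
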