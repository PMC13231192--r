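# Synthetic speckle-textured nodule cohorts with instance-level ground
# truth. Benign instances are smooth-boundary bright ellipses; malignant
# instances add an irregular (Fourier-perturbed) boundary and punctate
# high-intensity spots (microcalcification proxies). Background texture and
# the speckle model are identical between classes, so only boundary
# irregularity and the spots are discriminative — global brightness is
# dominated by nodule size/intensity jitter shared by both classes.

#' Configuration for the synthetic bag generator
#'
#' @param n_patients number of patients (bags).
#' @param prevalence fraction of malignant patients.
#' @param bag_size_range integer pair; bag sizes are uniform on this range.
#' @param witness_rate fraction of malignant instances within a positive bag
#'   (at least one is always planted).
#' @param image_size square image side in pixels (default 64).
#' @param speckle_scale multiplicative speckle strength in `[0, 1]`; 0 turns
#'   noise off, 1 is full Rayleigh speckle.
#' @param irregularity boundary perturbation amplitude for malignant
#'   nodules, as a fraction of the nodule radius.
#' @param seed integer master seed.
#' @return A `"synth_config"` list.
#' @export
synth_config <- function(n_patients = 200L, prevalence = 0.5,
                         bag_size_range = c(3L, 12L), witness_rate = 0.3,
                         image_size = 64L, speckle_scale = 0.35,
                         irregularity = 0.35, seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, bag_size_range[1L] >= 1L,
            bag_size_range[2L] >= bag_size_range[1L],
            witness_rate > 0, witness_rate <= 1, speckle_scale >= 0)
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 bag_size_range = as.integer(bag_size_range),
                 witness_rate = witness_rate,
                 image_size = as.integer(image_size),
                 speckle_scale = speckle_scale, irregularity = irregularity,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# first-order ultrasound speckle approximation: multiplicative Rayleigh
# factor with unit mean, blended by speckle_scale and clipped to [0, 1]
apply_speckle <- function(img, scale) {
  if (scale <= 0) return(pmin(pmax(img, 0), 1))
  sigma <- sqrt(2 / pi)                       # Rayleigh with mean 1
  r <- sigma * sqrt(-2 * log(runif(length(img))))
  noisy <- img * (1 + scale * (r - 1))
  dim(noisy) <- dim(img)
  pmin(pmax(noisy, 0), 1)
}

#' Generate one synthetic nodule instance
#'
#' Both classes share the nodule/background intensity model and speckle; a
#' malignant instance differs only by an irregular boundary (radius
#' modulated by a low-order random Fourier series) and 3-8 punctate bright
#' spots inside the nodule.
#'
#' @param instance_class 0 (benign) or 1 (malignant).
#' @param config a [synth_config()]. Draws come from the current RNG state.
#' @param detail if `TRUE`, attach the noise-free layer as attribute
#'   `"clean"` and the spot centres as `"spots"`.
#' @return Numeric matrix `[size, size]` in `[0, 1]`.
#' @export
generate_instance <- function(instance_class, config, detail = FALSE) {
  stopifnot(instance_class %in% c(0, 1))
  s <- config$image_size
  cx <- s / 2 + runif(1, -s / 10, s / 10)
  cy <- s / 2 + runif(1, -s / 10, s / 10)
  a <- runif(1, s * 0.16, s * 0.31)           # semi-axes
  b <- runif(1, s * 0.16, s * 0.31)
  phi <- runif(1, 0, pi)
  bg <- runif(1, 0.12, 0.20)
  fg <- runif(1, 0.48, 0.62)
  xs <- matrix(seq_len(s), s, s) - cy         # rows
  ys <- matrix(seq_len(s), s, s, byrow = TRUE) - cx
  xr <- cos(phi) * xs + sin(phi) * ys
  yr <- -sin(phi) * xs + cos(phi) * ys
  rho <- sqrt((xr / a)^2 + (yr / b)^2)        # 1 on the smooth boundary
  if (instance_class == 1 && config$irregularity > 0) {
    theta <- atan2(yr / b, xr / a)
    mod <- 0; amp2 <- 0
    for (ord in 2:4) {
      amp <- config$irregularity * runif(1, 0.3, 1) / sqrt(ord)
      amp2 <- amp2 + amp^2
      mod <- mod + amp * cos(ord * theta + runif(1, 0, 2 * pi))
    }
    # area-preserving in expectation: E[(1 + mod)^2 / (1 + sum amp^2/2)] = 1,
    # so boundary irregularity does not change expected nodule size
    rho <- rho * sqrt(1 + amp2 / 2) / (1 + mod)
  }
  edge <- 0.08                                 # soft boundary width
  interior <- stats::plogis((1 - rho) / edge)
  img <- bg + (fg - bg) * interior
  spots <- NULL
  if (instance_class == 1) {
    n_spots <- sample(3:8, 1L)
    spots <- matrix(0, n_spots, 2L)
    xg <- matrix(seq_len(s), s, s)
    yg <- matrix(seq_len(s), s, s, byrow = TRUE)
    added <- 0
    for (sp in seq_len(n_spots)) {
      repeat {                                 # rejection-sample inside
        t0 <- runif(1, 0, 2 * pi); r0 <- sqrt(runif(1)) * 0.7
        px <- cx + r0 * (a * cos(t0) * cos(phi) - b * sin(t0) * sin(phi))
        py <- cy + r0 * (a * cos(t0) * sin(phi) + b * sin(t0) * cos(phi))
        if (px > 2 && px < s - 1 && py > 2 && py < s - 1) break
      }
      spots[sp, ] <- c(py, px)                 # (row, col)
      sig <- runif(1, 1.0, 1.6)
      # peak reaches ~1.0 over the nodule interior with negligible clipping
      g <- 0.42 * exp(-((yg - px)^2 + (xg - py)^2) / (2 * sig^2))
      img <- img + g
      added <- added + sum(g)
    }
    # brightness compensation: spread the spots' added intensity mass as a
    # uniform debit over the nodule interior so class is carried by texture
    # and boundary shape, never by global image brightness
    img <- img - interior * (added / sum(interior))
    img <- pmin(pmax(img, 0), 1)
  }
  out <- apply_speckle(img, config$speckle_scale)
  if (detail) {
    attr(out, "clean") <- pmin(pmax(img, 0), 1)
    attr(out, "spots") <- spots
  }
  out
}

#' Generate one synthetic bag
#'
#' Bag size is uniform on `bag_size_range`. A positive bag plants
#' `max(1, round(witness_rate * n))` malignant instances at seeded random
#' positions; a negative bag is all benign. Instance labels are recorded.
#'
#' @param bag_label 0 or 1.
#' @param config a [synth_config()]. Draws come from the current RNG state.
#' @param patient_id identifier stored on the bag.
#' @return A bag list (`patient_id`, `n`, `label`, `instance_labels`,
#'   `images`).
#' @export
generate_bag <- function(bag_label, config, patient_id = "P1") {
  stopifnot(bag_label %in% c(0, 1))
  n <- sample(seq(config$bag_size_range[1L], config$bag_size_range[2L]), 1L)
  inst <- numeric(n)
  if (bag_label == 1) {
    n_pos <- max(1L, as.integer(round_half_up(config$witness_rate * n)))
    inst[sample(n, n_pos)] <- 1
  }
  images <- lapply(inst, generate_instance, config = config)
  list(patient_id = patient_id, n = n, label = as.numeric(bag_label),
       instance_labels = inst, images = images)
}

#' Generate a synthetic cohort in memory
#'
#' The bag-level view of [generate_cohort()] without touching the
#' filesystem: exactly `round(prevalence * n_patients)` positive bags in a
#' seeded random arrangement, with per-instance ground truth attached.
#'
#' @param config a [synth_config()].
#' @return A `"mil_bags"` list.
#' @export
generate_bags <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  P <- config$n_patients
  n_pos <- as.integer(round_half_up(config$prevalence * P))
  labels <- c(rep(1, n_pos), rep(0, P - n_pos))
  width <- max(3L, nchar(as.character(P)))
  bags <- with_stream(config$seed, "cohort", {
    labels <- sample(labels)                   # interleave classes in id order
    lapply(seq_len(P), function(i)
      generate_bag(labels[i], config,
                   patient_id = sprintf("P%0*d", width, i)))
  })
  structure(bags, class = "mil_bags")
}

#' Generate and write a synthetic cohort
#'
#' Writes `images/<patient>_<instance>.png`, a `manifest.csv` loadable by
#' [load_manifest()] (columns `patient_id`, `image_path`, `label`,
#' `instance_label`), and a `truth.csv` with per-instance ground truth.
#' Exactly `round(prevalence * n_patients)` bags are positive. Regeneration
#' from the same config (including seed) is byte-identical.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return Invisibly, a list with `manifest` (tibble), `dir`, and `bags`
#'   (the in-memory `"mil_bags"` list, so a round trip through disk is not
#'   required for training).
#' @export
generate_cohort <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite)
    stop("output directory exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)")
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  bags <- generate_bags(config)
  rows <- list()
  for (b in bags) {
    fn <- sprintf("images/%s_%02d.png", b$patient_id, seq_len(b$n))
    for (j in seq_len(b$n))
      EBImage::writeImage(EBImage::Image(b$images[[j]]),
                          file.path(out_dir, fn[j]), type = "png")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      patient_id = b$patient_id, image_path = fn, label = b$label,
      instance_label = b$instance_labels)
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(manifest[, c("patient_id", "image_path", "instance_label")],
                   file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  for (i in seq_along(bags)) {
    bags[[i]]$paths <- file.path(out_dir, sprintf("images/%s_%02d.png",
                                                  bags[[i]]$patient_id,
                                                  seq_len(bags[[i]]$n)))
  }
  class(bags) <- "mil_bags"
  invisible(list(manifest = manifest, dir = out_dir, bags = bags))
}
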