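test_that("masked mean and max aggregation match loop oracles and exclude padding", {
  set.seed(30)
  v <- matrix(rnorm(40), 5, 8)
  mean_loop <- apply(v, 2, function(col) sum(col) / 5)
  max_loop <- apply(v, 2, function(col) { m <- -Inf; for (x in col) m <- max(m, x); m })
  expect_equal(aggregate_mean(v), mean_loop)
  expect_equal(aggregate_max(v), max_loop)
  # two-point means / maxima
  v2 <- matrix(c(1, 3), 2, 4)
  expect_equal(aggregate_mean(v2), rep(2, 4))
  expect_equal(aggregate_max(v2), rep(3, 4))
  # padding exclusion: all-negative real values with padded zero rows
  vneg <- rbind(matrix(-abs(rnorm(8)), 2, 4), 0)
  expect_equal(aggregate_max(vneg, c(1, 1, 0)),
               apply(vneg[1:2, ], 2, max))
  expect_true(all(aggregate_max(vneg, c(1, 1, 0)) < 0))
  expect_equal(aggregate_mean(rbind(v2[1, , drop = FALSE], 0), c(1, 0)),
               v2[1, ])
  expect_error(aggregate_mean(v, rep(0, 5)), "empty bag")
  expect_error(aggregate_max(v, rep(0, 5)), "empty bag")
})

test_that("classification is a stable softmax over the linear head", {
  C <- 6
  z <- rnorm(C)
  p0 <- classify(z, list(W = matrix(0, C, 2), b = c(0, 0)))
  expect_equal(p0, c(0.5, 0.5))
  # extreme logits do not overflow
  p1 <- classify(z, list(W = matrix(0, C, 2), b = c(0, 1000)))
  expect_equal(p1, c(0, 1), tolerance = 1e-12)
  expect_true(all(is.finite(p1)))
  # closed form: logits (ln 1, ln 3) -> (0.25, 0.75)
  zz <- c(1, rep(0, C - 1))
  W <- matrix(0, C, 2); W[1, ] <- c(log(1), log(3))
  expect_equal(classify(zz, list(W = W, b = c(0, 0))), c(0.25, 0.75))
})

test_that("bag loss is the mean negative log-likelihood with clamping", {
  expect_equal(bag_loss(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE), c(1, 0)), 0)
  expect_equal(bag_loss(matrix(0.5, 3, 2), c(1, 0, 1)), log(2))
  expect_equal(bag_loss(rbind(c(0.25, 0.75), c(0.5, 0.5)), c(1, 0)),
               (-log(0.75) - log(0.5)) / 2)
  # exact zero probability is clamped, never infinite
  expect_true(is.finite(bag_loss(rbind(c(1, 0)), 1)))
  expect_gt(bag_loss(rbind(c(1, 0)), 1), 20)
})

test_that("all variants produce valid probabilities and identical shared structure", {
  bags <- tiny_cohort(n_patients = 3, seed = 31, image_size = 32)
  batch <- collate_bags(bags, image_size = 32)
  shapes <- function(p) rapply(p, dim, how = "unlist")
  ref <- NULL
  for (variant in c("dual_attention", "meanpool", "maxpool")) {
    m <- tiny_model(variant, seed = 31)
    out <- forward_bag(m, batch)
    expect_equal(rowSums(out$probs), rep(1, 3), tolerance = 1e-6)
    expect_true(all(out$probs >= 0))
    # shared parts: backbone and classifier parameter shapes are identical
    sh <- list(bb = shapes(attnmil:::net_params(m$backbone)),
               clf = shapes(m$clf))
    if (is.null(ref)) ref <- sh else expect_identical(sh, ref)
  }
})

test_that("bag predictions are permutation- and padding-invariant in eval mode", {
  bags <- tiny_cohort(n_patients = 2, seed = 32, image_size = 32)
  for (variant in c("dual_attention", "meanpool", "maxpool")) {
    m <- tiny_model(variant, seed = 32)
    batch <- collate_bags(bags, image_size = 32)
    out <- forward_bag(m, batch)
    # permute instances inside bag 1
    bags_p <- bags
    n1 <- bags_p[[1]]$n
    perm <- rev(seq_len(n1))
    bags_p[[1]]$images <- bags_p[[1]]$images[perm]
    out_p <- forward_bag(m, collate_bags(bags_p, image_size = 32))
    expect_equal(out_p$probs, out$probs, tolerance = 1e-5)
    if (variant == "dual_attention")
      expect_equal(out_p$alpha[[1]][seq_len(n1)],
                   out$alpha[[1]][perm], tolerance = 1e-5)
    # padding invariance: add an artificial all-zero padded slot by batching
    # with a larger bag
    single <- forward_bag(m, collate_bags(bags[1], image_size = 32))
    both <- forward_bag(m, collate_bags(bags, image_size = 32))
    expect_equal(both$probs[1, ], single$probs[1, ], tolerance = 1e-10)
  }
})

test_that("identical bags in one batch receive identical predictions", {
  bags <- tiny_cohort(n_patients = 2, seed = 33, image_size = 32)
  bags2 <- structure(list(bags[[1]], bags[[1]], bags[[2]]), class = "mil_bags")
  m <- tiny_model("dual_attention", seed = 33)
  out <- forward_bag(m, collate_bags(bags2, image_size = 32))
  expect_equal(out$probs[1, ], out$probs[2, ], tolerance = 1e-12)
})

test_that("single-instance bags collapse all aggregators to the same embedding", {
  cfg <- synth_config(bag_size_range = c(1, 1), image_size = 32, seed = 34)
  set.seed(34)
  bag <- generate_bag(1, cfg, patient_id = "S1")
  batch <- collate_bags(structure(list(bag), class = "mil_bags"),
                        image_size = 32)
  z <- list()
  for (variant in c("dual_attention", "meanpool", "maxpool")) {
    m <- tiny_model(variant, seed = 34)   # same seed: identical backbones
    z[[variant]] <- forward_bag(m, batch)$z
  }
  # IRAM is the identity at zero-init, so v is the same pooled vector; with
  # n = 1 mean, max and the alpha = 1 attention sum all return v
  expect_equal(z$dual_attention, z$meanpool, tolerance = 1e-10)
  expect_equal(z$meanpool, z$maxpool, tolerance = 1e-10)
})

test_that("unknown variants are rejected", {
  expect_error(mil_model("medianpool"), "arg")
})

test_that("the full model gradient passes a randomized finite-difference check", {
  set.seed(35)
  m <- tiny_model("dual_attention", seed = 35)
  imgs <- array(rnorm(32 * 32 * 3 * 5), c(32, 32, 3, 5))
  grp <- c(1, 1, 2, 2, 2)
  labels <- c(1, 0)
  par <- attnmil:::mil_params(m)
  fwd <- attnmil:::mil_forward(m, imgs, grp, training = TRUE,
                               need_cache = TRUE)
  grad <- attnmil:::mil_backward(m, fwd, labels)
  lossf <- function(p) {
    mm <- attnmil:::mil_set_params(m, p)
    f <- attnmil:::mil_forward(mm, imgs, grp, training = TRUE)
    bag_loss(f$probs, labels)
  }
  eps <- 1e-5
  # sample one coordinate from every top-level component (paths are lists so
  # numeric positions and names are not coerced together)
  poke <- function(path) {
    pl <- par; gl <- grad
    for (k in path) { pl <- pl[[k]]; gl <- gl[[k]] }
    i <- sample(length(pl), 1)
    modify <- function(p, path, i, d) {
      if (length(path) == 1) { p[[path[[1]]]][i] <- p[[path[[1]]]][i] + d; p }
      else { p[[path[[1]]]] <- modify(p[[path[[1]]]], path[-1], i, d); p }
    }
    num <- (lossf(modify(par, path, i, eps)) -
              lossf(modify(par, path, i, -eps))) / (2 * eps)
    expect_equal(gl[i], num, tolerance = 1e-3)
  }
  poke(list("backbone", 1, "w"))
  poke(list("backbone", 10, "w"))
  poke(list("backbone", 2, "gamma"))
  poke(list("iram", "psi1")); poke(list("iram", "psi2"))
  poke(list("iram", "psi3")); poke(list("iram", "psi4"))
  poke(list("isam", "Wa")); poke(list("isam", "wc"))
  poke(list("clf", "W")); poke(list("clf", "b"))
})

test_that("a gradient step on a single bag strictly decreases the loss", {
  set.seed(36)
  m <- tiny_model("dual_attention", seed = 36)
  imgs <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  grp <- c(1, 1); labels <- 1
  par <- attnmil:::mil_params(m)
  fwd <- attnmil:::mil_forward(m, imgs, grp, training = TRUE,
                               need_cache = TRUE)
  l0 <- bag_loss(fwd$probs, labels)
  grad <- attnmil:::mil_backward(m, fwd, labels)
  upd <- attnmil:::sgd_step(par, grad, attnmil:::nested_zeros(par),
                            lr = 0.05, momentum = 0, weight_decay = 0)
  m2 <- attnmil:::mil_set_params(m, upd$p)
  l1 <- bag_loss(attnmil:::mil_forward(m2, imgs, grp,
                                       training = TRUE)$probs, labels)
  expect_lt(l1, l0)
})

test_that("checkpoints round-trip through disk", {
  bags <- tiny_cohort(n_patients = 6, seed = 37, image_size = 32)
  m <- tiny_model("dual_attention", seed = 37)
  fit <- structure(list(model = m, best_epoch = 0L, best_val_auroc = 0.5,
                        history = tibble::tibble(epoch = 0L),
                        fold_index = 1L, config = train_config(epochs = 1)),
                   class = "mil_fit")
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  p1 <- predict_bags(fit$model, bags, image_size = 32)
  p2 <- predict_bags(fit2$model, bags, image_size = 32)
  expect_equal(p2$malignancy_score, p1$malignancy_score)
})
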