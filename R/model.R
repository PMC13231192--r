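# Assembly of the three comparable bag classifiers (dual-attention,
# mean-pooling, max-pooling) over a shared backbone and classifier, the
# cross-entropy bag loss, and the full forward/backward passes.

#' Construct a multiple-instance bag classifier
#'
#' All three variants share the same backbone feature extractor and linear
#' softmax classifier; they differ only in how per-instance features become a
#' bag embedding:
#'
#' * `"dual_attention"` — spatial refinement of each instance map
#'   ([spatial_refine()]), global average pooling, then gated instance
#'   attention ([instance_attention()]).
#' * `"meanpool"` / `"maxpool"` — global average pooling of the *raw*
#'   backbone maps followed by element-wise mean/max over instances (both
#'   attention sub-modules are absent).
#'
#' @param variant aggregation variant.
#' @param backbone `"tinycnn"` or `"resnet34"` (see [build_backbone()]).
#' @param iram,isam option lists overriding attention defaults
#'   (`iram$c_prime`, `iram$tau`, `iram$dropout`; `isam$hidden_dim`,
#'   `isam$dropout`).
#' @param pretrained_path optional RDS file with backbone parameters.
#' @param seed optional integer; initialisation uses its `"init"` sub-stream.
#' @return An object of class `"mil_model"`.
#' @export
#' @examples
#' m <- mil_model("dual_attention", backbone = "tinycnn",
#'                iram = list(c_prime = 16, tau = 16), seed = 1)
mil_model <- function(variant = c("dual_attention", "meanpool", "maxpool"),
                      backbone = c("tinycnn", "resnet34"),
                      iram = list(), isam = list(),
                      pretrained_path = NULL, seed = NULL) {
  variant <- match.arg(variant)
  backbone <- match.arg(backbone)
  build <- function() {
    bb <- build_backbone(backbone, pretrained_path = pretrained_path)
    C <- attr(bb, "out_channels")
    ir <- is <- NULL
    if (variant == "dual_attention") {
      ir <- iram_params(C,
                        c_prime = iram$c_prime %||% 128L,
                        tau = iram$tau %||% 128,
                        dropout = iram$dropout %||% 0.25)
      is <- isam_params(C,
                        hidden_dim = isam$hidden_dim %||% 256L,
                        dropout = isam$dropout %||% 0.25)
    }
    clf <- list(W = matrix(rnorm(C * 2, sd = sqrt(1 / C)), C, 2),
                b = numeric(2))
    structure(list(variant = variant, backbone = bb, iram = ir, isam = is,
                   clf = clf, C = C, backbone_variant = backbone),
              class = "mil_model")
  }
  if (is.null(seed)) build() else with_stream(seed, "init", build())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all learnable parameters, as one nested list
mil_params <- function(model) {
  list(backbone = net_params(model$backbone),
       iram = if (is.null(model$iram)) NULL else unclass(model$iram),
       isam = if (is.null(model$isam)) NULL else unclass(model$isam),
       clf = model$clf)
}

mil_set_params <- function(model, p) {
  model$backbone <- net_set_params(model$backbone, p$backbone)
  if (!is.null(model$iram)) {
    at <- attributes(model$iram)
    model$iram <- p$iram
    attributes(model$iram) <- utils::modifyList(at, attributes(p$iram) %||% list())
    class(model$iram) <- "iram_params"
  }
  if (!is.null(model$isam)) {
    at <- attributes(model$isam)
    model$isam <- p$isam
    attributes(model$isam) <- utils::modifyList(at, attributes(p$isam) %||% list())
    class(model$isam) <- "isam_params"
  }
  model$clf <- p$clf
  model
}

#' Masked mean aggregation of instance vectors
#'
#' @param v numeric matrix `n x C`.
#' @param mask binary vector of length `n`; only `mask == 1` rows contribute.
#' @return Length-`C` vector.
#' @export
aggregate_mean <- function(v, mask = rep(1, nrow(v))) {
  keep <- which(mask > 0)
  if (length(keep) == 0L) stop("empty bag: no unmasked instances")
  colMeans(v[keep, , drop = FALSE])
}

#' Masked channel-wise max aggregation of instance vectors
#'
#' @inheritParams aggregate_mean
#' @return Length-`C` vector.
#' @export
aggregate_max <- function(v, mask = rep(1, nrow(v))) {
  keep <- which(mask > 0)
  if (length(keep) == 0L) stop("empty bag: no unmasked instances")
  apply(v[keep, , drop = FALSE], 2L, max)
}

#' Linear softmax classification of a bag embedding
#'
#' Computes `p = softmax(W' z + b)` with max-subtraction for numerical
#' stability; `p[2]` is the malignancy score.
#'
#' @param z length-`C` bag embedding.
#' @param par list with `W` (`C x 2`) and `b` (length 2).
#' @return Length-2 probability vector summing to 1.
#' @export
classify <- function(z, par) {
  stopifnot(all(is.finite(z)))
  softmax(drop(z %*% par$W) + par$b)
}

#' Mean cross-entropy bag loss
#'
#' `L = -(1/N) sum_i log p_{i, y_i}`; probabilities are clamped at 1e-12 so
#' float underflow never produces an infinite loss.
#'
#' @param probs numeric matrix `N x 2` of class probabilities (column 2 =
#'   malignant), or a list of length-2 vectors.
#' @param labels binary vector of length `N`.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' bag_loss(matrix(0.5, 2, 2), c(0, 1))  # log(2)
bag_loss <- function(probs, labels) {
  if (is.list(probs)) probs <- do.call(rbind, probs)
  stopifnot(nrow(probs) == length(labels), nrow(probs) >= 1L)
  p_true <- probs[cbind(seq_along(labels), labels + 1L)]
  -mean(log(pmax(p_true, 1e-12)))
}

# Core forward pass over the real instances of a batch of bags.
# images: [H, W, 3, M] preprocessed real instances; grp: length-M bag index
# (1..B, non-decreasing). Returns probs (B x 2), alpha (list per bag),
# z (B x C), and caches for the backward pass.
mil_forward <- function(model, images, grp, training = FALSE,
                        need_cache = FALSE) {
  B <- max(grp)
  bfr <- layer_fwd(model$backbone, images, training)
  model$backbone <- bfr$layer                   # updated BN running stats
  feats <- bfr$y
  d <- dim(feats)
  HW <- d[1L] * d[2L]; M <- d[4L]
  if (model$variant == "dual_attention") {
    ir <- iram_fwd(feats, model$iram, training = training)
    V <- pool_flat(ir$out, HW, M)               # M x C
  } else {
    ir <- NULL
    V <- pool_flat(flatten_hw(feats), HW, M)
  }
  Z <- matrix(0, B, model$C)
  alpha <- vector("list", B)
  bag_caches <- vector("list", B)
  rows_of <- split(seq_len(M), grp)
  for (b in seq_len(B)) {
    rows <- rows_of[[b]]
    Vb <- V[rows, , drop = FALSE]
    if (model$variant == "dual_attention") {
      r <- isam_fwd(Vb, model$isam, training = training)
      Z[b, ] <- r$z
      alpha[[b]] <- r$alpha
      bag_caches[[b]] <- r$cache
    } else if (model$variant == "meanpool") {
      Z[b, ] <- colMeans(Vb)
    } else {
      amax <- apply(Vb, 2L, which.max)
      Z[b, ] <- Vb[cbind(amax, seq_len(ncol(Vb)))]
      bag_caches[[b]] <- amax
    }
  }
  logits <- sweep(Z %*% model$clf$W, 2L, model$clf$b, "+")
  probs <- softmax(logits)
  out <- list(probs = probs, alpha = alpha, Z = Z, model = model)
  if (need_cache)
    out$cache <- list(bb = bfr$cache, feats_dim = d, ir = ir, V = V,
                      rows_of = rows_of, bag_caches = bag_caches, M = M,
                      HW = HW)
  out
}

# Backward pass: returns gradient structure parallel to mil_params(model)
# for the mean cross-entropy loss over the batch.
mil_backward <- function(model, fwd, labels) {
  cache <- fwd$cache
  B <- nrow(fwd$probs)
  Y <- matrix(0, B, 2); Y[cbind(seq_len(B), labels + 1L)] <- 1
  dlogits <- (fwd$probs - Y) / B
  gW <- crossprod(fwd$Z, dlogits)
  gb <- colSums(dlogits)
  dZ <- tcrossprod(dlogits, model$clf$W)        # B x C
  M <- cache$M
  dV <- matrix(0, M, model$C)
  g_isam <- NULL
  for (b in seq_len(B)) {
    rows <- cache$rows_of[[b]]
    if (model$variant == "dual_attention") {
      r <- isam_bwd(model$isam, cache$bag_caches[[b]], dZ[b, ])
      dV[rows, ] <- r$dv
      g_isam <- if (is.null(g_isam)) r$grad else
        nested_map2(g_isam, r$grad, `+`)
    } else if (model$variant == "meanpool") {
      n <- length(rows)
      dV[rows, ] <- matrix(dZ[b, ] / n, n, model$C, byrow = TRUE)
    } else {
      amax <- cache$bag_caches[[b]]
      for (cc in seq_len(model$C))
        dV[rows[amax[cc]], cc] <- dZ[b, cc]
    }
  }
  dOUT <- dV[rep(seq_len(M), each = cache$HW), , drop = FALSE] / cache$HW
  if (model$variant == "dual_attention") {
    ib <- iram_bwd(model$iram, cache$ir$cache, dOUT)
    dfeats <- ib$dfeats
    g_iram <- ib$grad
  } else {
    d <- cache$feats_dim
    dfeats <- unflatten_hw_batch(dOUT, d[1L], d[2L], M)
    g_iram <- NULL
  }
  gbb <- layer_bwd(model$backbone, cache$bb, dfeats)
  list(backbone = gbb$grad, iram = g_iram, isam = g_isam,
       clf = list(W = gW, b = gb))
}

# SGD with momentum and decoupled-by-name weight decay: decay applies to
# weight matrices (conv kernels, attention projections, classifier W), not to
# biases or batch-norm scale/shift.
.decay_names <- c("w", "psi1", "psi2", "psi3", "psi4", "Wa", "Wb", "wc", "W")

sgd_step <- function(par, grad, mom, lr, momentum, weight_decay) {
  rec <- function(p, g, m, nm) {
    if (is.numeric(p)) {
      gg <- g
      if (weight_decay > 0 && nm %in% .decay_names) gg <- gg + weight_decay * p
      m_new <- momentum * m + gg
      list(p = p - lr * m_new, m = m_new)
    } else {
      nms <- names(p)
      pm <- p; mm <- m
      for (i in seq_along(p)) {
        if (is.null(p[[i]])) next
        r <- rec(p[[i]], g[[i]], m[[i]],
                 if (!is.null(nms) && nzchar(nms[i])) nms[i] else nm)
        pm[[i]] <- r$p; mm[[i]] <- r$m
      }
      list(p = pm, m = mm)
    }
  }
  rec(par, grad, mom, "")
}

#' Predict bag-level class probabilities
#'
#' Evaluation-mode forward pass of a fitted (or freshly initialised) model
#' over a list of bags. Dropout is inactive and batch norm uses running
#' statistics, so predictions are deterministic and independent of batch
#' composition and instance order.
#'
#' @param model a [mil_model()].
#' @param bags a bag list from [load_manifest()] (images are loaded lazily).
#' @param image_size spatial size instances are preprocessed to.
#' @return A tibble with one row per bag: `patient_id`, `label`,
#'   `prob_benign`, `malignancy_score`, and (dual-attention only) a list
#'   column `alpha` of per-instance attention weights.
#' @export
predict_bags <- function(model, bags, image_size = 64L) {
  stopifnot(inherits(model, "mil_model"))
  prep <- prepare_instances(bags, image_size = image_size)
  fwd <- mil_forward(model, prep$images, prep$grp, training = FALSE)
  out <- tibble::tibble(
    patient_id = vapply(bags, function(b) b$patient_id, character(1)),
    label = vapply(bags, function(b) b$label, numeric(1)),
    prob_benign = fwd$probs[, 1L],
    malignancy_score = fwd$probs[, 2L])
  if (model$variant == "dual_attention") out$alpha <- fwd$alpha
  out
}

#' Forward one padded batch through a chosen variant
#'
#' Operates on a [collate_bags()] batch: padded slots (mask 0) are excluded
#' from the backbone and carry exactly zero attention weight, so adding
#' padding never changes predictions.
#'
#' @param model a [mil_model()].
#' @param batch a padded batch from [collate_bags()].
#' @param training logical; training mode enables dropout and batch-norm
#'   batch statistics.
#' @return List with `probs` (`B x 2` matrix), `alpha` (list of length-`n_max`
#'   weight vectors, zeros on padding; `NULL` for pooling baselines), and
#'   `z` (`B x C` bag embeddings).
#' @export
forward_bag <- function(model, batch, training = FALSE) {
  stopifnot(inherits(model, "mil_model"))
  d <- dim(batch$images)                        # H, W, 3, n_max, B
  imgs <- array(batch$images, c(d[1L], d[2L], d[3L], d[4L] * d[5L]))
  slot_real <- as.vector(t(batch$mask)) > 0     # slot j of bag b at (b-1)*n_max+j
  bag_of_slot <- rep(seq_len(d[5L]), each = d[4L])
  keep <- which(slot_real)
  imgs <- imgs[, , , keep, drop = FALSE]
  grp <- bag_of_slot[keep]
  fwd <- mil_forward(model, imgs, grp, training = training)
  alpha <- NULL
  if (model$variant == "dual_attention") {
    alpha <- vector("list", d[5L])
    for (b in seq_len(d[5L])) {
      a <- numeric(d[4L])
      a[which(batch$mask[b, ] > 0)] <- fwd$alpha[[b]]
      alpha[[b]] <- a
    }
  }
  list(probs = fwd$probs, alpha = alpha, z = fwd$Z)
}
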