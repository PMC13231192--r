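# SGD training loop: cosine warm-up + milestone decay schedule, per-epoch
# reshuffling and augmentation from named seed sub-streams, model selection
# by validation AUROC, and cross-validation orchestration.

#' Training configuration
#'
#' Defaults follow the reference protocol: SGD with momentum 0.9 and weight
#' decay 5e-4, base learning rate 1e-3 with a half-cosine warm-up from
#' `base_lr/1000` across the first epoch, decay by `gamma = 0.1` at epochs
#' 50 and 75, 100 epochs, 10 bags per batch.
#'
#' @param epochs,base_lr,momentum,weight_decay,warmup_epochs,warmup_factor,milestones,gamma,batch_bags,image_size,seed
#'   see Details; `image_size` is the preprocessing size instances are fed
#'   to the backbone at.
#' @return A `"train_config"` list.
#' @export
train_config <- function(epochs = 100L, base_lr = 1e-3, momentum = 0.9,
                         weight_decay = 5e-4, warmup_epochs = 1L,
                         warmup_factor = 1 / 1000, milestones = c(50L, 75L),
                         gamma = 0.1, batch_bags = 10L, image_size = 64L,
                         seed = 1L) {
  stopifnot(all(diff(milestones) > 0), gamma > 0, gamma < 1,
            warmup_factor > 0, warmup_factor <= 1)
  milestones <- milestones[milestones < epochs]  # unreachable ones are inert
  structure(list(epochs = as.integer(epochs), base_lr = base_lr,
                 momentum = momentum, weight_decay = weight_decay,
                 warmup_epochs = as.integer(warmup_epochs),
                 warmup_factor = warmup_factor,
                 milestones = as.integer(milestones), gamma = gamma,
                 batch_bags = as.integer(batch_bags),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a global optimisation step
#'
#' During the warm-up epoch the rate ramps from `base_lr * warmup_factor` to
#' `base_lr` along a half-cosine ease-in; afterwards
#' `lr = base_lr * gamma^(milestones passed)`.
#'
#' @param step 0-based global step index.
#' @param steps_per_epoch number of batches per epoch.
#' @param config a [train_config()].
#' @return The learning rate (scalar).
#' @export
#' @examples
#' cfg <- train_config()
#' lr_at(0, 10, cfg)    # 1e-6
#' lr_at(10, 10, cfg)   # 1e-3
lr_at <- function(step, steps_per_epoch, config) {
  stopifnot(step >= 0, steps_per_epoch >= 1)
  epoch <- step %/% steps_per_epoch
  warm_steps <- config$warmup_epochs * steps_per_epoch
  if (step < warm_steps) {
    t <- step / warm_steps
    wf <- config$warmup_factor
    return(config$base_lr * (wf + (1 - wf) * (1 - cos(pi * t)) / 2))
  }
  config$base_lr * config$gamma^sum(epoch >= config$milestones)
}

#' Train one fold
#'
#' Runs the full optimisation loop on the training bags with training-time
#' augmentation, evaluates validation AUROC after every epoch, and keeps the
#' parameters of the best epoch (ties break toward the earlier epoch). All
#' randomness (shuffling, augmentation, dropout) is drawn from per-epoch
#' sub-streams of `config$seed`, so reruns are reproducible.
#'
#' @param train_bags,val_bags disjoint `"mil_bags"` lists; the validation
#'   set must contain both classes.
#' @param config a [train_config()].
#' @param model a [mil_model()] to optimise (its initialisation seed is the
#'   caller's choice), or a variant name to build one from
#'   `config$seed`.
#' @param fold_index integer recorded on the result.
#' @param verbose print a line per epoch.
#' @return An object of class `"mil_fit"`: the best `model`, `best_epoch`,
#'   `best_val_auroc`, `history` (tibble: epoch, train_loss, val_auroc, lr)
#'   and `fold_index`.
#' @export
train_fold <- function(train_bags, val_bags, config, model = "dual_attention",
                       fold_index = NA_integer_, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_bags) == 0L) stop("empty training set")
  if (length(val_bags) == 0L) stop("empty validation set")
  tr_ids <- vapply(train_bags, function(b) b$patient_id, character(1))
  va_ids <- vapply(val_bags, function(b) b$patient_id, character(1))
  if (length(intersect(tr_ids, va_ids)) > 0L)
    stop("train and validation sets share patients")
  val_labels <- vapply(val_bags, function(b) b$label, numeric(1))
  if (length(unique(val_labels)) < 2L)
    stop("AUROC undefined for single-class validation set")
  if (is.character(model))
    model <- mil_model(model, backbone = "tinycnn",
                       iram = list(c_prime = 32L, tau = 32),
                       isam = list(hidden_dim = 64L),
                       seed = config$seed)
  train_bags <- preprocess_bags(train_bags, config$image_size)
  val_bags <- preprocess_bags(val_bags, config$image_size)
  par <- mil_params(model)
  mom <- nested_zeros(par)
  B <- length(train_bags)
  steps_per_epoch <- ceiling(B / config$batch_bags)
  step <- 0L
  best <- list(auroc = -Inf, epoch = NA_integer_, par = par,
               backbone = model$backbone)
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs) - 1L) {
    ep_loss <- 0; ep_n <- 0L
    with_stream(config$seed, sprintf("epoch%03d", epoch), {
      ord <- sample(B)
      for (i0 in seq(1L, B, by = config$batch_bags)) {
        idx <- ord[i0:min(i0 + config$batch_bags - 1L, B)]
        prep <- prepare_instances(train_bags[idx],
                                  image_size = config$image_size,
                                  augment = TRUE)
        lr <- lr_at(step, steps_per_epoch, config)
        model <- mil_set_params(model, par)
        fwd <- mil_forward(model, prep$images, prep$grp, training = TRUE,
                           need_cache = TRUE)
        model <- fwd$model                     # BN running stats advanced
        loss <- bag_loss(fwd$probs, prep$labels)
        grad <- mil_backward(model, fwd, prep$labels)
        upd <- sgd_step(par, grad, mom, lr, config$momentum,
                        config$weight_decay)
        par <- upd$p; mom <- upd$m
        ep_loss <- ep_loss + loss * length(idx); ep_n <- ep_n + length(idx)
        step <- step + 1L
      }
    })
    model <- mil_set_params(model, par)
    val_scores <- predict_bags(model, val_bags,
                               image_size = config$image_size)$malignancy_score
    v_auc <- auroc(val_scores, val_labels)
    if (v_auc > best$auroc) {                  # strict: ties keep earlier epoch
      best <- list(auroc = v_auc, epoch = epoch, par = par,
                   backbone = model$backbone)
    }
    history[[epoch + 1L]] <- tibble::tibble(
      epoch = epoch, train_loss = ep_loss / ep_n, val_auroc = v_auc,
      lr = lr_at(epoch * steps_per_epoch, steps_per_epoch, config))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val AUROC %.3f",
                      epoch, ep_loss / ep_n, v_auc))
  }
  model$backbone <- best$backbone              # running stats of best epoch
  model <- mil_set_params(model, best$par)
  structure(list(model = model, best_epoch = best$epoch,
                 best_val_auroc = best$auroc,
                 history = dplyr::bind_rows(history),
                 fold_index = fold_index, config = config),
            class = "mil_fit")
}

#' @export
print.mil_fit <- function(x, ...) {
  cat(sprintf("<mil_fit> %s/%s, %d epochs; best epoch %d (val AUROC %.3f)\n",
              x$model$variant, x$model$backbone_variant,
              nrow(x$history), x$best_epoch, x$best_val_auroc))
  invisible(x)
}

#' Run patient-level cross-validation
#'
#' Trains one model per fold on that fold's training patients, selects the
#' best epoch on the fold's validation patients, then evaluates the selected
#' model on the common held-out test patients.
#'
#' @param bags the full `"mil_bags"` cohort.
#' @param split a [split_patients()] result.
#' @param config a [train_config()].
#' @param variant model variant passed to [mil_model()].
#' @param threshold operating point on the malignancy score.
#' @param verbose print per-epoch progress.
#' @return An object of class `"mil_cv"`: `fits` (list of `"mil_fit"`),
#'   `test_metrics` (per-fold tibble), `summary` (mean ± sd tibble),
#'   `test_scores` (per-fold tibble of patient scores).
#' @export
run_cv <- function(bags, split, config, variant = "dual_attention",
                   threshold = 0.5, verbose = FALSE) {
  stopifnot(inherits(split, "cohort_split"))
  ids <- vapply(bags, function(b) b$patient_id, character(1))
  pick <- function(want) bags[match(want, ids)]
  test_bags <- preprocess_bags(pick(split$test), config$image_size)
  fits <- vector("list", length(split$folds))
  reports <- vector("list", length(split$folds))
  scores <- vector("list", length(split$folds))
  for (f in seq_along(split$folds)) {
    fold <- split$folds[[f]]
    model <- mil_model(variant, backbone = "tinycnn",
                       iram = list(c_prime = 32L, tau = 32),
                       isam = list(hidden_dim = 64L),
                       seed = substream_seed(config$seed,
                                             sprintf("fold%d", f)))
    fits[[f]] <- train_fold(pick(fold$train), pick(fold$val), config,
                            model = model, fold_index = f, verbose = verbose)
    pr <- predict_bags(fits[[f]]$model, test_bags,
                       image_size = config$image_size)
    scores[[f]] <- dplyr::mutate(pr[, c("patient_id", "label",
                                        "malignancy_score")], fold = f)
    reports[[f]] <- metrics_report(pr$malignancy_score, pr$label,
                                   threshold = threshold, fold_index = f)
  }
  test_metrics <- dplyr::bind_rows(reports)
  structure(list(fits = fits, test_metrics = test_metrics,
                 summary = summarize_folds(test_metrics),
                 test_scores = dplyr::bind_rows(scores),
                 variant = variant, threshold = threshold),
            class = "mil_cv")
}

#' @export
print.mil_cv <- function(x, ...) {
  cat(sprintf("<mil_cv> %s, %d folds; test AUROC %.3f +/- %.3f\n",
              x$variant, length(x$fits),
              x$summary$mean[x$summary$metric == "auroc"],
              x$summary$sd[x$summary$metric == "auroc"]))
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single RDS file holding the parameter set, the model
#' and training configuration fingerprint, the selected epoch and its
#' validation AUROC.
#'
#' @param fit a `"mil_fit"`.
#' @param path file path.
#' @return `path` invisibly; `load_checkpoint()` returns the `"mil_fit"`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "mil_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "mil_fit"))
  fit
}
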