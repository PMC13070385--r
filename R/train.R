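# Training engine: Poisson negative log-likelihood objective, AdamW with a
# linear warm-up (first epoch) / linear decay (remaining epochs) learning-rate
# schedule, batch size 1, multi-track and single-track modes, and the
# pretrain -> head swap -> (optionally frozen) fine-tune workflow.

#' Training configuration
#'
#' Defaults follow the published recipe: AdamW, peak learning rate 3e-5,
#' weight decay 1e-4, 10 epochs, batch size 1, linear warm-up over the first
#' epoch and linear decay to zero over the remaining epochs. (The published
#' post-hoc fine-tuning runs of the track-count sweep use a reduced learning
#' rate, 3e-7 at full scale.)
#'
#' @param learning_rate peak learning rate.
#' @param weight_decay decoupled AdamW weight decay.
#' @param epochs training epochs.
#' @param batch_size examples per optimiser step (gradients averaged).
#' @param mode one of `"pretrain"`, `"scratch"`, `"finetune"`,
#'   `"finetune_frozen"`. The optimisation is identical across modes; the
#'   mode documents intent and, for `finetune_frozen`, freezes the trunk.
#' @param track_selection `"all"` (multi-track: objective is the average
#'   Poisson NLL over all tracks) or a single track name/index (single-track
#'   mode).
#' @param seed integer; drives shuffling and any dropout draws.
#' @param gradient_clip optional global-norm clip (default none).
#' @param beta1,beta2,adam_eps AdamW moment parameters (optimizer defaults).
#' @param validate_each_epoch compute the validation Pearson after each epoch
#'   when validation data are available.
#' @param save_each_epoch write a checkpoint after every epoch (otherwise
#'   only the final one when a checkpoint directory is given).
#' @return an `s2t_train_config`.
#' @export
train_config <- function(learning_rate = 3e-5,
                         weight_decay = 1e-4,
                         epochs = 10L,
                         batch_size = 1L,
                         mode = c("scratch", "pretrain", "finetune", "finetune_frozen"),
                         track_selection = "all",
                         seed = 1L,
                         gradient_clip = NULL,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         validate_each_epoch = TRUE,
                         save_each_epoch = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_s2t("learning_rate must be > 0")
  if (!is.numeric(weight_decay) || weight_decay < 0)
    stop_s2t("weight_decay must be >= 0")
  if (!is_count(epochs)) stop_s2t("epochs must be >= 1")
  if (!is_count(batch_size)) stop_s2t("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 mode = mode, track_selection = track_selection,
                 seed = as.integer(seed), gradient_clip = gradient_clip,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 validate_each_epoch = isTRUE(validate_each_epoch),
                 save_each_epoch = isTRUE(save_each_epoch)),
            class = "s2t_train_config")
}

#' Poisson negative log-likelihood
#'
#' The mean over bins and tracks of `lambda - y * log(lambda)`, i.e. the
#' Poisson NLL up to the `log(y!)` term, which does not depend on the model
#' and is omitted from the optimisation target (set `full = TRUE` to add it
#' for likelihood reporting).
#'
#' @param predicted_rates strictly positive rates (vector or matrix).
#' @param target_counts non-negative counts, same shape.
#' @param full include the `log(y!)` constant.
#' @return a scalar.
#' @examples
#' poisson_nll(1, 0)  # 1
#' @export
poisson_nll <- function(predicted_rates, target_counts, full = FALSE) {
  if (length(predicted_rates) != length(target_counts))
    stop_s2t("rates and targets differ in length (%d vs %d)",
             length(predicted_rates), length(target_counts))
  if (any(predicted_rates <= 0))
    stop_s2t("all predicted rates must be strictly positive")
  if (any(target_counts < 0))
    stop_s2t("all target counts must be non-negative")
  ll <- predicted_rates - target_counts * log(predicted_rates)
  if (full) ll <- ll + lgamma(target_counts + 1)
  mean(ll)
}

# gradient of the mean Poisson NLL w.r.t. the rates
poisson_nll_grad <- function(predicted_rates, target_counts) {
  (1 - target_counts / predicted_rates) / length(predicted_rates)
}

#' Learning rate at a given optimiser step
#'
#' Piecewise-linear schedule: 0 at step 0, rising linearly to the peak at the
#' end of the first epoch, then decaying linearly to 0 at the final step.
#'
#' @param config an [train_config()].
#' @param step optimiser step in `0..epochs*steps_per_epoch`.
#' @param steps_per_epoch optimiser steps per epoch.
#' @param epochs total epochs (defaults to `config$epochs`).
#' @return the learning rate.
#' @export
lr_at_step <- function(config, step, steps_per_epoch, epochs = config$epochs) {
  total <- epochs * steps_per_epoch
  if (any(step < 0 | step > total))
    stop_s2t("step %s out of range [0, %d]", paste(step[step < 0 | step > total],
                                                   collapse = ","), total)
  peak <- config$learning_rate
  ifelse(step <= steps_per_epoch,
         peak * step / steps_per_epoch,
         if (total == steps_per_epoch) 0 else
           peak * (total - step) / (total - steps_per_epoch))
}

## ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  lapply(params, function(group) lapply(group, function(w)
    list(m = w * 0, v = w * 0)))
}

# one decoupled-weight-decay Adam update over the (possibly restricted)
# parameter groups named in `update_names`
adamw_step <- function(params, grads, state, lr, config, t, update_names) {
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$adam_eps
  wd <- config$weight_decay
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
  if (!is.null(config$gradient_clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(vapply(g, function(x)
      sum(x^2), numeric(1))), numeric(1))))
    if (gn > config$gradient_clip)
      grads <- lapply(grads, function(g) lapply(g, function(x)
        x * config$gradient_clip / gn))
  }
  for (nm in update_names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    for (wn in names(g)) {
      w <- params[[nm]][[wn]]
      st <- state[[nm]][[wn]]
      st$m <- b1 * st$m + (1 - b1) * g[[wn]]
      st$v <- b2 * st$v + (1 - b2) * g[[wn]]^2
      upd <- (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      params[[nm]][[wn]] <- w - lr * upd - lr * wd * w
      state[[nm]][[wn]] <- st
    }
  }
  list(params = params, state = state)
}

## ---- training loop --------------------------------------------------------

resolve_track_selection <- function(data, selection) {
  if (identical(selection, "all")) return(NULL)
  ti <- if (is.character(selection)) match(selection, data$track_names)
        else as.integer(selection)
  if (anyNA(ti) || any(ti < 1L) || any(ti > length(data$track_names)))
    stop_s2t("track_selection '%s' does not name a track in the manifest",
             paste(selection, collapse = ","))
  ti
}

#' Train a model
#'
#' Runs `epochs` passes of AdamW over the training windows of `data`
#' (shuffled each epoch with a seed derived from the global seed and the
#' epoch), with the scheduled learning rate of [lr_at_step()]. In multi-track
#' mode the objective is the average Poisson NLL over all tracks; in
#' single-track mode the model head must emit one track and the NLL of the
#' selected manifest track is used. With a frozen trunk only head parameters
#' are updated (and, when dropout is zero, trunk activations are computed
#' once per window and cached).
#'
#' @param model an `s2t_model` whose (single) head matches the selected
#'   tracks.
#' @param data an `s2t_dataset`; examples with split `train` are optimised,
#'   `validation` examples (if any) feed the per-epoch metric.
#' @param config an [train_config()].
#' @param checkpoint_dir optional directory for checkpoints.
#' @param parent provenance string recorded in the checkpoint sidecar.
#' @return a list: `model` (trained), `log` (per-step data.frame: step,
#'   epoch, lr, loss), `epoch_log` (per-epoch: epoch, mean loss, validation
#'   Pearson, wall time), `checkpoint` (path or `NULL`).
#' @export
train <- function(model, data, config = train_config(), checkpoint_dir = NULL,
                  parent = NULL) {
  ti <- resolve_track_selection(data, config$track_selection)
  n_out <- model$config$head_track_counts
  if (length(n_out) != 1L)
    stop_s2t("training expects a single-head model (found %d heads)", length(n_out))
  n_target <- if (is.null(ti)) length(data$track_names) else length(ti)
  # In single-track mode the head may either emit exactly the selected
  # track(s), or emit the full catalogue with the objective restricted to
  # the selected column (the post-hoc fine-tuning setting of the sweep).
  wide_head <- !is.null(ti) && n_out == length(data$track_names) &&
    n_out != n_target
  if (n_out != n_target && !wide_head)
    stop_s2t("model head emits %d track(s) but %d target track(s) selected",
             n_out, n_target)
  if (config$mode == "finetune_frozen") model <- set_trunk_frozen(model, TRUE)
  frozen <- isTRUE(model$frozen)

  tr_idx <- which(vapply(data$examples, `[[`, "", "split") == "train")
  if (!length(tr_idx)) stop_s2t("no training windows in the dataset")
  val <- dataset_subset(data, split = "validation",
                        tracks = if (wide_head) NULL else ti)
  has_val <- length(val$examples) > 0L && config$validate_each_epoch

  steps_per_epoch <- ceiling(length(tr_idx) / config$batch_size)
  total_steps <- steps_per_epoch * config$epochs
  state <- adamw_init(model$params)
  update_names <- if (frozen) grep("^head", names(model$params), value = TRUE)
                  else names(model$params)

  use_cache <- frozen && model$config$dropout_rate == 0
  trunk_cache <- if (use_cache) vector("list", length(data$examples)) else NULL

  log_step <- integer(total_steps); log_epoch <- integer(total_steps)
  log_lr <- numeric(total_steps); log_loss <- numeric(total_steps)
  epoch_log <- data.frame(epoch = integer(), mean_loss = numeric(),
                          validation_r = numeric(), seconds = numeric())
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    set.seed(derive_seed(config$seed, "shuffle", epoch))
    order_idx <- sample(tr_idx)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
    ep_losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      step <- step + 1L
      lr <- lr_at_step(config, step, steps_per_epoch)
      grads <- NULL
      loss_b <- 0
      for (ei in batches[[b]]) {
        ex <- data$examples[[ei]]
        y <- if (is.null(ti)) ex$y else ex$y[, ti, drop = FALSE]
        if (use_cache) {
          if (is.null(trunk_cache[[ei]])) {
            fw <- model_forward(model, ex$x, training = FALSE)
            trunk_cache[[ei]] <- fw$cache$head_input
          }
          H <- trunk_cache[[ei]]             # channels x bins
          hp <- model$params$head1
          z <- hp$W %*% H + hp$b             # tracks x bins
          lam <- softplus(z)
          sel <- if (wide_head) lam[ti, , drop = FALSE] else lam
          loss <- poisson_nll(sel, t(y))
          dsel <- poisson_nll_grad(sel, t(y))
          dlam <- if (wide_head) {
            dd <- matrix(0, nrow(lam), ncol(lam)); dd[ti, ] <- dsel; dd
          } else dsel
          dz <- dlam * sigmoid(z)
          g <- list(head1 = list(W = tcrossprod(dz, H), b = rowSums(dz)))
        } else {
          fw <- model_forward(model, ex$x, training = TRUE)
          lam <- fw$heads[[1]]
          sel <- if (wide_head) lam[, ti, drop = FALSE] else lam
          loss <- poisson_nll(sel, y)
          dsel <- poisson_nll_grad(sel, y)
          dlam <- if (wide_head) {
            dd <- matrix(0, nrow(lam), ncol(lam)); dd[, ti] <- dsel; dd
          } else dsel
          g <- model_backward(model, fw$cache, list(dlam), head_only = frozen)
        }
        loss_b <- loss_b + loss / length(batches[[b]])
        if (is.null(grads)) {
          grads <- lapply(g, function(gr) lapply(gr, function(x)
            x / length(batches[[b]])))
        } else {
          for (nm in names(g)) for (wn in names(g[[nm]]))
            grads[[nm]][[wn]] <- grads[[nm]][[wn]] +
              g[[nm]][[wn]] / length(batches[[b]])
        }
      }
      upd <- adamw_step(model$params, grads, state, lr, config, step, update_names)
      model$params <- upd$params
      state <- upd$state
      ep_losses[b] <- loss_b
      log_step[step] <- step; log_epoch[step] <- epoch
      log_lr[step] <- lr; log_loss[step] <- loss_b
    }
    val_r <- NA_real_
    if (has_val) {
      rep <- evaluate(model, val, split_label = "validation")
      val_r <- if (wide_head) mean(rep$per_track_r[ti]) else rep$mean_r
    }
    epoch_log <- rbind(epoch_log, data.frame(
      epoch = epoch, mean_loss = mean(ep_losses), validation_r = val_r,
      seconds = proc.time()[["elapsed"]] - t0))
    if (!is.null(checkpoint_dir) &&
        (config$save_each_epoch || epoch == config$epochs)) {
      save_checkpoint(model, file.path(checkpoint_dir, sprintf("epoch%02d", epoch)),
                      seed = config$seed, epoch = epoch, parent = parent)
    }
  }
  ckpt <- if (is.null(checkpoint_dir)) NULL else
    file.path(checkpoint_dir, sprintf("epoch%02d", config$epochs))
  list(model = model,
       log = data.frame(step = log_step, epoch = log_epoch, lr = log_lr,
                        loss = log_loss),
       epoch_log = epoch_log,
       checkpoint = ckpt)
}

#' Fine-tune from a checkpoint
#'
#' Loads the pretrained checkpoint, deletes its head(s), attaches a freshly
#' initialised head with `n_tracks` outputs, optionally freezes the trunk
#' (`mode = "finetune_frozen"`), and trains on `data`. The returned
#' checkpoint records the parent checkpoint for provenance.
#'
#' @param checkpoint directory of a pretrained checkpoint, or an `s2t_model`.
#' @param data an `s2t_dataset` for the new task(s).
#' @param n_tracks number of tracks of the new head.
#' @param config an [train_config()] with mode `finetune` or
#'   `finetune_frozen`.
#' @param checkpoint_dir optional output checkpoint directory.
#' @return as [train()].
#' @export
finetune <- function(checkpoint, data, n_tracks,
                     config = train_config(mode = "finetune"),
                     checkpoint_dir = NULL) {
  if (!config$mode %in% c("finetune", "finetune_frozen"))
    stop_s2t("finetune() requires mode 'finetune' or 'finetune_frozen'")
  parent <- NULL
  model <- if (is.character(checkpoint)) {
    parent <- normalizePath(checkpoint)
    load_checkpoint(checkpoint)
  } else checkpoint
  model <- replace_head(model, n_tracks, seed = derive_seed(config$seed, "head"))
  if (config$mode == "finetune_frozen") model <- set_trunk_frozen(model, TRUE)
  train(model, data, config, checkpoint_dir = checkpoint_dir, parent = parent)
}

#' Grid search over learning rate and weight decay
#'
#' One full training run per (learning rate, weight decay) cell per dataset;
#' the best setting maximises the mean validation Pearson over datasets,
#' with ties broken towards the smaller learning rate, then the smaller
#' weight decay. Duplicate grid values are deduplicated with a warning.
#'
#' @param model_factory function(seed) returning a fresh `s2t_model`.
#' @param datasets named list of `s2t_dataset`s (each needs validation
#'   windows).
#' @param lr_grid,wd_grid numeric grids (the published grids are
#'   `c(1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 3e-4)` and `c(1e-4, 3e-4, 1e-3)`).
#' @param config base [train_config()]; its learning rate / weight decay are
#'   overridden cell by cell.
#' @return list with `table` (data.frame: dataset, learning_rate,
#'   weight_decay, validation_r) and `best` (row with the winning setting).
#' @export
grid_search <- function(model_factory, datasets, lr_grid, wd_grid,
                        config = train_config()) {
  if (!length(lr_grid) || !length(wd_grid))
    stop_s2t("grids must be non-empty")
  if (anyDuplicated(lr_grid) || anyDuplicated(wd_grid)) {
    warning("duplicate grid values removed", call. = FALSE)
    lr_grid <- unique(lr_grid); wd_grid <- unique(wd_grid)
  }
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("dataset%d", seq_along(datasets))
  rows <- list()
  for (lr in lr_grid) for (wd in wd_grid) for (dn in names(datasets)) {
    cfg <- config
    cfg$learning_rate <- lr; cfg$weight_decay <- wd
    fit <- train(model_factory(cfg$seed), datasets[[dn]], cfg)
    vr <- tail(stats::na.omit(fit$epoch_log$validation_r), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      dataset = dn, learning_rate = lr, weight_decay = wd,
      validation_r = if (length(vr)) vr else NA_real_)
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(validation_r ~ learning_rate + weight_decay, tab, mean)
  agg <- agg[order(-agg$validation_r, agg$learning_rate, agg$weight_decay), ]
  list(table = tab, best = agg[1L, ])
}
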