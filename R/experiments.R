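# Scripted, seeded experiment designs: architecture comparison,
# pretrain-versus-scratch-versus-freeze transfer, and the track-count
# tradeoff sweep with post-hoc single-track fine-tuning. All arms of a
# comparison share seeds and data order, so differences are attributable to
# the manipulated factor alone.

#' The five standard architecture variants
#'
#' Baseline, the two single ablations (attention-block linear layer, final
#' pointwise convolution), the double ablation ("simplified"), and the
#' 5-attention-block simplified variant.
#'
#' @param base an [model_config()] to modify.
#' @return a named list of `s2t_model_config`s.
#' @export
architecture_variants <- function(base) {
  modify <- function(...) {
    o <- list(...)
    cfg <- unclass(base)
    cfg[names(o)] <- o
    do.call(model_config, cfg)
  }
  list(
    baseline = modify(),
    no_linear = modify(include_attention_linear = FALSE),
    no_pointwise = modify(include_final_pointwise = FALSE),
    no_linear_no_pointwise = modify(include_attention_linear = FALSE,
                                    include_final_pointwise = FALSE),
    five_blocks_simplified = modify(include_attention_linear = FALSE,
                                    include_final_pointwise = FALSE,
                                    n_attention_blocks = 5L)
  )
}

#' Architecture comparison
#'
#' Trains each variant on the same dataset with identical seeds (hence
#' identical shuffling) and records the per-epoch validation Pearson
#' alongside the variant's parameter count.
#'
#' @param variants named list of `s2t_model_config`s (e.g.
#'   [architecture_variants()]); names must be unique.
#' @param data an `s2t_dataset` with train and validation windows.
#' @param config an [train_config()].
#' @return list with `curves` (data.frame: variant, epoch, validation_r,
#'   mean_loss) and `params` (data.frame: variant, trainable_count).
#' @export
run_architecture_comparison <- function(variants, data, config = train_config()) {
  if (is.null(names(variants)) || anyDuplicated(names(variants)))
    stop_s2t("variants must be a uniquely named list")
  curves <- list(); params <- list()
  for (vn in names(variants)) {
    model <- build_model(variants[[vn]], seed = config$seed)
    fit <- train(model, data, config)
    curves[[vn]] <- data.frame(variant = vn, fit$epoch_log)
    params[[vn]] <- data.frame(
      variant = vn,
      trainable_count = count_parameters(model)$trainable_count)
  }
  list(curves = do.call(rbind, c(curves, make.row.names = FALSE)),
       params = do.call(rbind, c(params, make.row.names = FALSE)))
}

#' Pretrain-versus-scratch-versus-freeze transfer experiment
#'
#' Pretrains once on the reference multi-task corpus (or reuses a supplied
#' checkpoint), then for each seed and each requested mode trains on a single
#' held-out-species task and evaluates the held-out Pearson:
#' `pretrain` (fine-tune the full pretrained model), `no_pretrain` (train
#' from scratch), `pretrain_freeze` (fine-tune the head only),
#' `no_pretrain_freeze` (random trunk, head only; the control).
#'
#' @param world an `s2t_world` (or directory) from [generate_world()].
#' @param species which nonreference species to fine-tune on.
#' @param task task id (defaults to the species' first task).
#' @param modes subset of the four modes.
#' @param seeds integer vector of replicate seeds.
#' @param model_config_fn function(n_tracks) returning the architecture to
#'   use (default: the simplified toy architecture with the world geometry).
#' @param pretrain_config,arm_config [train_config()]s for the pretraining
#'   run and the per-arm runs.
#' @param pretrain_checkpoint optional existing checkpoint directory to
#'   reuse (required pretrained weights are otherwise trained in place).
#' @param eval_split split evaluated for the reported metric.
#' @return list with `results` (data.frame: mode, seed, r), `summary`
#'   (per-mode mean/median r and the percentage improvement of pretraining
#'   over scratch), and `pretrain_checkpoint`.
#' @export
run_transfer_experiment <- function(world, species = NULL, task = NULL,
                                    modes = c("pretrain", "no_pretrain",
                                              "pretrain_freeze", "no_pretrain_freeze"),
                                    seeds = 1:5,
                                    model_config_fn = NULL,
                                    pretrain_config = NULL,
                                    arm_config = NULL,
                                    pretrain_checkpoint = NULL,
                                    eval_split = "test") {
  if (is.character(world)) world <- load_world(world)
  wc <- world$config
  species <- species %||% wc$species[1]
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(model_config_fn))
    model_config_fn <- function(n_tracks)
      toy_model_config(n_tracks = n_tracks,
                       input_length = wc$input_length,
                       crop_length = wc$crop_length, bin_size = wc$bin_size,
                       include_attention_linear = FALSE,
                       include_final_pointwise = FALSE)
  pretrain_config <- pretrain_config %||%
    train_config(learning_rate = 1e-2, epochs = 10L, mode = "pretrain",
                 seed = 1L, validate_each_epoch = FALSE)
  arm_config <- arm_config %||%
    train_config(learning_rate = 3e-3, epochs = 10L,
                 validate_each_epoch = FALSE)

  needs_pre <- any(modes %in% c("pretrain", "pretrain_freeze"))
  if (needs_pre && is.null(pretrain_checkpoint)) {
    ref_data <- world_dataset(world, "ref")
    pre_model <- build_model(model_config_fn(length(ref_data$track_names)),
                             seed = pretrain_config$seed)
    ckdir <- file.path(tempdir(), sprintf("s2t_pretrain_%s",
                                          derive_seed(pretrain_config$seed, "ck")))
    fit <- train(pre_model, ref_data, pretrain_config, checkpoint_dir = ckdir)
    pretrain_checkpoint <- fit$checkpoint
  } else if (needs_pre && !dir.exists(pretrain_checkpoint)) {
    stop_s2t("pretrained checkpoint %s not found", pretrain_checkpoint)
  }

  sp_tasks <- names(world$tasks)[vapply(world$tasks, `[[`, "", "species") == species]
  task <- task %||% sp_tasks[1]
  sp_data <- world_dataset(world, species, tasks = task)

  rows <- list()
  for (sd in seeds) for (mode in modes) {
    cfg <- arm_config
    cfg$seed <- derive_seed(sd, "arm")
    fit <- switch(mode,
      pretrain = {
        cfg$mode <- "finetune"
        finetune(pretrain_checkpoint, sp_data, n_tracks = 1L, config = cfg)
      },
      pretrain_freeze = {
        cfg$mode <- "finetune_frozen"
        finetune(pretrain_checkpoint, sp_data, n_tracks = 1L, config = cfg)
      },
      no_pretrain = {
        cfg$mode <- "scratch"
        m <- build_model(model_config_fn(1L), seed = derive_seed(sd, "init"))
        train(m, sp_data, cfg)
      },
      no_pretrain_freeze = {
        cfg$mode <- "scratch"
        m <- build_model(model_config_fn(1L), seed = derive_seed(sd, "init"))
        m <- set_trunk_frozen(m, TRUE)
        train(m, sp_data, cfg)
      })
    r <- evaluate(fit$model, sp_data, split_label = eval_split)$mean_r
    rows[[length(rows) + 1L]] <- data.frame(mode = mode, seed = sd, r = r)
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(r ~ mode, results,
                              function(v) c(mean = mean(v), median = stats::median(v)))
  summary <- data.frame(mode = summary$mode,
                        mean_r = summary$r[, "mean"],
                        median_r = summary$r[, "median"])
  if (all(c("pretrain", "no_pretrain") %in% modes)) {
    rp <- summary$mean_r[summary$mode == "pretrain"]
    rs <- summary$mean_r[summary$mode == "no_pretrain"]
    summary$improvement_pct <- NA_real_
    summary$improvement_pct[summary$mode == "pretrain"] <- 100 * (rp - rs) / rs
  }
  out <- list(results = results, summary = summary,
              task = task, species = species,
              pretrain_checkpoint = pretrain_checkpoint)
  attr(out, "provenance") <- list(
    world = world$dir, world_config_md5 = object_md5(unclass(world$config)),
    arm_config_md5 = object_md5(unclass(arm_config)),
    seeds = seeds,
    pretrain_checkpoint = pretrain_checkpoint)
  out
}

#' Track-count tradeoff sweep
#'
#' For each requested number of additional tracks and each replicate:
#' sample that many additional reference tasks uniformly at random (seeded
#' per replicate), train a multi-track model from a fresh random
#' initialisation on {track of interest} + sample, record the test Pearson
#' on the track of interest and the mean over all trained tracks; then
#' fine-tune for the configured number of epochs on the single track of
#' interest and record the post-fine-tune Pearson.
#'
#' @param world an `s2t_world` (or directory).
#' @param track_of_interest a reference task id.
#' @param additional_counts integer vector of additional-track counts.
#' @param replicates replicates per count (fresh random init each).
#' @param train_cfg,finetune_cfg [train_config()]s for the multi-track runs
#'   and for the post-hoc single-track fine-tuning (the published recipe
#'   reduces the fine-tuning learning rate by two orders of magnitude).
#' @param model_config_fn function(n_tracks) returning the architecture.
#' @param train_subsample optional number of training windows to keep
#'   (seed-deterministic subsample, mirroring the published corpus
#'   subsampling).
#' @param eval_split evaluated split.
#' @return data.frame with one row per (count, replicate):
#'   `n_additional`, `replicate`, `r_interest_pre`, `r_mean_pre`,
#'   `r_interest_post`, plus the sampled track ids (comma-separated).
#' @export
run_tradeoff_sweep <- function(world, track_of_interest = NULL,
                               additional_counts = c(1L, 4L, 16L),
                               replicates = 2L,
                               train_cfg = NULL, finetune_cfg = NULL,
                               model_config_fn = NULL,
                               train_subsample = NULL,
                               eval_split = "test") {
  if (is.character(world)) world <- load_world(world)
  wc <- world$config
  ref_tasks <- names(world$tasks)[vapply(world$tasks, `[[`, "", "species") == "ref"]
  track_of_interest <- track_of_interest %||% ref_tasks[1]
  stopifnot(track_of_interest %in% ref_tasks)
  pool <- setdiff(ref_tasks, track_of_interest)
  if (max(additional_counts) > length(pool))
    stop_s2t("requested %d additional tracks but only %d are available",
             max(additional_counts), length(pool))
  if (is.null(model_config_fn))
    model_config_fn <- function(n_tracks)
      toy_model_config(n_tracks = n_tracks,
                       input_length = wc$input_length,
                       crop_length = wc$crop_length, bin_size = wc$bin_size,
                       include_attention_linear = FALSE,
                       include_final_pointwise = FALSE)
  train_cfg <- train_cfg %||% train_config(learning_rate = 1e-2, epochs = 10L,
                                           validate_each_epoch = FALSE)
  finetune_cfg <- finetune_cfg %||%
    train_config(learning_rate = 1e-4, epochs = 10L, mode = "finetune",
                 validate_each_epoch = FALSE)

  rows <- list()
  for (nc in additional_counts) for (rep_i in seq_len(replicates)) {
    set.seed(derive_seed(train_cfg$seed, "tracksample", nc, rep_i))
    extra <- sort(sample(pool, nc))
    ids <- c(track_of_interest, extra)
    data_multi <- world_dataset(world, "ref", tasks = ids,
                                subsample = train_subsample,
                                seed = derive_seed(train_cfg$seed, "sub", nc, rep_i))
    cfg <- train_cfg
    cfg$seed <- derive_seed(train_cfg$seed, "rep", nc, rep_i)
    m <- build_model(model_config_fn(length(ids)), seed = cfg$seed)
    fit <- train(m, data_multi, cfg)
    ev <- evaluate(fit$model, data_multi, split_label = eval_split)
    r_interest_pre <- unname(ev$per_track_r[track_of_interest])
    r_mean_pre <- ev$mean_r
    # post-hoc fine-tune: continue training the same model with the
    # objective restricted to the track of interest (single-track mode)
    fcfg <- finetune_cfg
    fcfg$seed <- derive_seed(train_cfg$seed, "ft", nc, rep_i)
    fcfg$track_selection <- track_of_interest
    ftfit <- train(fit$model, data_multi, fcfg)
    ev2 <- evaluate(ftfit$model, data_multi, split_label = eval_split)
    rows[[length(rows) + 1L]] <- data.frame(
      n_additional = nc, replicate = rep_i,
      r_interest_pre = r_interest_pre, r_mean_pre = r_mean_pre,
      r_interest_post = unname(ev2$per_track_r[track_of_interest]),
      r_mean_post = ev2$mean_r,
      sampled_tracks = paste(extra, collapse = ","))
  }
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- list(
    world = world$dir, world_config_md5 = object_md5(unclass(world$config)),
    train_config_md5 = object_md5(unclass(train_cfg)),
    finetune_config_md5 = object_md5(unclass(finetune_cfg)),
    track_of_interest = track_of_interest,
    train_subsample = train_subsample)
  out
}
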