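# Loss analytics, schedule exactness, determinism, freezing, track modes,
# fine-tuning workflow and the hyperparameter grid search.

test_that("Poisson NLL matches its closed-form values", {
  expect_equal(poisson_nll(1, 0), 1)
  expect_equal(poisson_nll(1, 1), 1)  # 1 - 1 * log(1)
  expect_equal(poisson_nll(c(2, 3), c(1, 0)),
               mean(c(2 - log(2), 3)))
  expect_equal(poisson_nll(2, 3, full = TRUE),
               2 - 3 * log(2) + lgamma(4))
  expect_error(poisson_nll(c(1, -1), c(0, 0)), "strictly positive")
  expect_error(poisson_nll(1, -2), "non-negative")
  expect_error(poisson_nll(c(1, 2), 1), "length")
})

test_that("the NLL in lambda is minimised at lambda = y", {
  for (y in c(1, 4, 7.5)) {
    lam <- seq(0.2, 15, by = 0.01)
    vals <- vapply(lam, function(l) poisson_nll(l, y), numeric(1))
    expect_equal(lam[which.min(vals)], y, tolerance = 0.011)
  }
})

test_that("the schedule is linear warm-up then linear decay", {
  cfg <- train_config()  # peak 3e-5, 10 epochs
  spe <- 50
  expect_equal(lr_at_step(cfg, 0, spe), 0)
  expect_equal(lr_at_step(cfg, spe, spe), 3e-5)
  expect_equal(lr_at_step(cfg, 10 * spe, spe), 0)
  expect_equal(lr_at_step(cfg, 25, spe), 3e-5 / 2)           # mid warm-up
  expect_equal(lr_at_step(cfg, spe + 4.5 * spe, spe), 3e-5 / 2)  # mid decay
  expect_error(lr_at_step(cfg, 501, spe), "out of range")
  expect_error(lr_at_step(cfg, -1, spe), "out of range")
})

test_that("the logged learning-rate trace equals the closed form pointwise", {
  cfg <- tiny_cfg(head_track_counts = 1L)
  d <- model_dist_dataset(tiny_cfg(head_track_counts = 1L),
                          n_train = 4, n_val = 0)
  tc <- train_config(learning_rate = 1e-3, epochs = 3, seed = 1,
                     validate_each_epoch = FALSE)
  fit <- train(build_model(cfg, 1), d, tc)
  spe <- 4
  expect_equal(fit$log$lr, lr_at_step(tc, seq_len(3 * spe), spe))
  expect_equal(nrow(fit$log), 3 * spe)
})

test_that("a single-intercept rate model recovers the Poisson mean", {
  # one-parameter model lambda = softplus(theta) against constant counts 4,
  # optimised with the engine's AdamW at constant learning rate
  theta <- 0
  cfg <- train_config(learning_rate = 0.05, weight_decay = 0)
  params <- list(intercept = list(theta = theta))
  state <- seq2track:::adamw_init(params)
  y <- rep(4, 64)
  for (t in 1:400) {
    lam <- softplus(rep(params$intercept$theta, 64))
    dlam <- seq2track:::poisson_nll_grad(lam, y)
    dtheta <- sum(dlam * seq2track:::sigmoid(rep(params$intercept$theta, 64)))
    upd <- seq2track:::adamw_step(params, list(intercept = list(theta = dtheta)),
                                  state, 0.05, cfg, t, "intercept")
    params <- upd$params; state <- upd$state
  }
  expect_equal(softplus(params$intercept$theta), 4, tolerance = 1e-2)
})

test_that("training is bit-deterministic given the seed", {
  cfg <- tiny_cfg(head_track_counts = 1L)
  d <- model_dist_dataset(cfg, n_train = 5, n_val = 2)
  tc <- train_config(learning_rate = 1e-3, epochs = 2, seed = 11)
  f1 <- train(build_model(cfg, 1), d, tc)
  f2 <- train(build_model(cfg, 1), d, tc)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("frozen fine-tuning leaves every non-head weight bit-identical", {
  cfg <- tiny_cfg(head_track_counts = 3L)
  pre <- build_model(cfg, seed = 2)
  ckdir <- file.path(tempdir(), "freeze_ck")
  save_checkpoint(pre, ckdir)
  d <- model_dist_dataset(tiny_cfg(head_track_counts = 1L),
                          n_train = 5, n_val = 0)
  fit <- finetune(ckdir, d, n_tracks = 1L,
                  config = train_config(learning_rate = 1e-3, epochs = 2,
                                        mode = "finetune_frozen", seed = 3,
                                        validate_each_epoch = FALSE))
  trunk_names <- seq2track:::trunk_param_names(pre)
  expect_identical(fit$model$params[trunk_names], pre$params[trunk_names])
  expect_identical(trunk_checksum(fit$model), trunk_checksum(pre))
  # the head did move
  init_head <- replace_head(pre, 1L,
                            seed = derive_seed(3, "head"))$params$head1
  expect_false(identical(fit$model$params$head1, init_head))
})

test_that("full fine-tuning updates the trunk and records provenance", {
  cfg <- tiny_cfg(head_track_counts = 2L)
  pre <- build_model(cfg, seed = 2)
  ckdir <- file.path(tempdir(), "full_ck")
  save_checkpoint(pre, ckdir)
  d <- model_dist_dataset(tiny_cfg(head_track_counts = 1L),
                          n_train = 4, n_val = 0)
  out <- file.path(tempdir(), "ft_out")
  fit <- finetune(ckdir, d, n_tracks = 1L,
                  config = train_config(learning_rate = 1e-3, epochs = 2,
                                        mode = "finetune", seed = 3,
                                        validate_each_epoch = FALSE),
                  checkpoint_dir = out)
  expect_false(identical(trunk_checksum(fit$model), trunk_checksum(pre)))
  meta <- jsonlite::read_json(file.path(fit$checkpoint, "meta.json"))
  expect_match(meta$parent, "full_ck")
  expect_equal(nrow(fit$epoch_log), 2L)
})

test_that("single-track and multi-track modes agree on a one-track manifest", {
  cfg <- tiny_cfg(head_track_counts = 1L)
  d <- model_dist_dataset(cfg, n_train = 5, n_val = 0)
  tc_all <- train_config(learning_rate = 1e-3, epochs = 2, seed = 5,
                         track_selection = "all", validate_each_epoch = FALSE)
  tc_one <- train_config(learning_rate = 1e-3, epochs = 2, seed = 5,
                         track_selection = "t1", validate_each_epoch = FALSE)
  f_all <- train(build_model(cfg, 1), d, tc_all)
  f_one <- train(build_model(cfg, 1), d, tc_one)
  expect_identical(f_all$log$loss, f_one$log$loss)
})

test_that("single-track mode restricts the objective of a wide head", {
  cfg <- tiny_cfg(head_track_counts = 2L)
  d <- model_dist_dataset(cfg, n_train = 4, n_val = 0)
  tc <- train_config(learning_rate = 1e-3, epochs = 1, seed = 5,
                     track_selection = "t2", validate_each_epoch = FALSE)
  fit <- train(build_model(cfg, 1), d, tc)
  expect_equal(nrow(fit$log), 4L)
  expect_error(train(build_model(cfg, 1), d,
                     train_config(track_selection = "nope")),
               "does not name a track")
})

test_that("track mismatches are rejected before any optimisation step", {
  cfg <- tiny_cfg(head_track_counts = 3L)
  d <- model_dist_dataset(tiny_cfg(head_track_counts = 2L),
                          n_train = 3, n_val = 0)
  expect_error(train(build_model(cfg, 1), d, train_config()),
               "head emits 3")
})

test_that("loss decreases across epochs on realisable data", {
  cfg <- tiny_cfg(head_track_counts = 1L)
  ok <- vapply(1:5, function(sd) {
    d <- model_dist_dataset(cfg, n_train = 6, n_val = 0, seed = sd)
    fit <- train(build_model(cfg, sd), d,
                 train_config(learning_rate = 3e-3, epochs = 4, seed = sd,
                              validate_each_epoch = FALSE))
    el <- fit$epoch_log$mean_loss
    el[length(el)] < el[1]
  }, logical(1))
  expect_gte(sum(ok), 4)
})

test_that("grid search records every cell and picks the best mean metric", {
  cfg <- tiny_cfg(head_track_counts = 1L)
  d <- model_dist_dataset(cfg, n_train = 4, n_val = 2)
  factory <- function(seed) build_model(cfg, seed)
  gs <- grid_search(factory, list(a = d), lr_grid = c(1e-3, 1e-2),
                    wd_grid = c(1e-4, 1e-3),
                    config = train_config(epochs = 1, seed = 1))
  expect_equal(nrow(gs$table), 4L)
  agg <- stats::aggregate(validation_r ~ learning_rate + weight_decay,
                          gs$table, mean)
  expect_equal(gs$best$validation_r, max(agg$validation_r))
  expect_warning(grid_search(factory, list(a = d), c(1e-3, 1e-3), 1e-4,
                             config = train_config(epochs = 1, seed = 1)),
                 "duplicate")
  expect_error(grid_search(factory, list(a = d), numeric(0), 1e-4),
               "non-empty")
})
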