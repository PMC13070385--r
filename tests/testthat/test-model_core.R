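# Architecture construction, output geometry, parameter accounting, head
# replacement and freezing.

test_that("output geometry holds across a grid of configurations", {
  grids <- list(
    list(input = 32L, crop = 16L, bin = 4L, nconv = 2L),
    list(input = 64L, crop = 32L, bin = 8L, nconv = 3L),
    list(input = 64L, crop = 64L, bin = 8L, nconv = 3L),  # crop == input
    list(input = 128L, crop = 64L, bin = 4L, nconv = 2L)
  )
  for (g in grids) {
    for (tracks in c(1L, 3L)) {
      cfg <- tiny_cfg(input_length = g$input, crop_length = g$crop,
                      bin_size = g$bin, n_conv_blocks = g$nconv,
                      head_track_counts = tracks)
      m <- build_model(cfg, seed = 1)
      out <- forward(m, rand_onehot(g$input, seed = 2))
      expect_length(out, 1L)
      expect_equal(dim(out[[1]]), c(g$crop %/% g$bin, tracks))
      expect_true(all(out[[1]] >= 0))
    }
  }
})

test_that("the full-scale geometry yields 896 output bins per track", {
  cfg <- model_config()  # 196608 / 114688 / 128
  expect_identical(cfg$crop_length %/% cfg$bin_size, 896L)
  expect_identical(cfg$input_length %/% cfg$bin_size, 1536L)
})

test_that("multiple heads each get their own grid", {
  cfg <- tiny_cfg(head_track_counts = c(3L, 2L))
  m <- build_model(cfg, seed = 1)
  out <- forward(m, rand_onehot(32, seed = 1))
  expect_length(out, 2L)
  expect_equal(ncol(out[[1]]), 3L)
  expect_equal(ncol(out[[2]]), 2L)
})

test_that("invalid configurations fail naming the violated invariant", {
  expect_error(model_config(input_length = 100L, bin_size = 128L),
               "multiple of bin_size")
  expect_error(tiny_cfg(crop_length = 64L), "exceeds input_length")
  expect_error(tiny_cfg(n_conv_blocks = 3L), "pooling factor")
  expect_error(tiny_cfg(head_track_counts = 0L), "track count")
  expect_error(tiny_cfg(channels = 10L, n_heads = 4L), "divisible")
  expect_error(tiny_cfg(positional_scheme = "enformer_basis",
                        channels = 8L, n_heads = 2L), "divisible by 6")
})

test_that("initialisation and forward are deterministic given the seed", {
  cfg <- tiny_cfg()
  m1 <- build_model(cfg, seed = 7)
  m2 <- build_model(cfg, seed = 7)
  m3 <- build_model(cfg, seed = 8)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  x <- rand_onehot(32, seed = 3)
  expect_identical(forward(m1, x), forward(m2, x))
})

test_that("a dense layer of 4 inputs and 2 outputs has 10 parameters", {
  set.seed(1)
  layer <- seq2track:::init_linear(4L, 2L)
  expect_identical(as.integer(seq2track:::param_count(layer)), 10L)
})

test_that("ablations remove exactly the analytically expected parameters", {
  C <- 12L; natt <- 2L
  base <- tiny_cfg(n_attention_blocks = natt, channels = C)
  nolin <- tiny_cfg(n_attention_blocks = natt, channels = C,
                    include_attention_linear = FALSE)
  nopw <- tiny_cfg(n_attention_blocks = natt, channels = C,
                   include_final_pointwise = FALSE)
  n_base <- count_parameters(build_model(base, 1))$trainable_count
  n_nolin <- count_parameters(build_model(nolin, 1))$trainable_count
  n_nopw <- count_parameters(build_model(nopw, 1))$trainable_count
  # post-attention projection: C x C weights + C biases, per block
  expect_equal(n_base - n_nolin, natt * (C * C + C))
  # final pointwise: BN (2C) + width-1 conv C -> 2C (2C^2 + 2C),
  # and the head then reads C instead of 2C features
  tracks <- base$head_track_counts[1]
  expect_equal(n_base - n_nopw, (2 * C) + (2 * C * C + 2 * C) + C * tracks)
})

test_that("trainable counts fall monotonically along the published ablations", {
  mk <- function(...) count_parameters(build_model(tiny_cfg(
    n_attention_blocks = 3L, ...), 1))$trainable_count
  n_base <- mk()
  n_nolin <- mk(include_attention_linear = FALSE)
  n_simpl <- mk(include_attention_linear = FALSE, include_final_pointwise = FALSE)
  n_fewer <- count_parameters(build_model(tiny_cfg(
    n_attention_blocks = 1L, include_attention_linear = FALSE,
    include_final_pointwise = FALSE), 1))$trainable_count
  expect_true(n_base > n_nolin)
  expect_true(n_nolin > n_simpl)
  expect_true(n_simpl > n_fewer)
})

test_that("per-component counts sum to the trainable count", {
  m <- build_model(tiny_cfg(), 1)
  ps <- count_parameters(m)
  expect_equal(ps$trainable_count, sum(unlist(ps$per_component_counts)))
  frozen <- set_trunk_frozen(m, TRUE)
  ps_tr <- count_parameters(frozen, trainable_only = TRUE)
  expect_equal(ps_tr$trainable_count, ps$per_component_counts$heads)
})

test_that("replace_head leaves every trunk weight bit-identical", {
  m <- build_model(tiny_cfg(head_track_counts = 5L), seed = 2)
  before <- trunk_checksum(m)
  m2 <- replace_head(m, n_tracks = 11L, seed = 9)
  expect_identical(trunk_checksum(m2), before)
  expect_equal(m2$config$head_track_counts, 11L)
  out <- forward(m2, rand_onehot(32, 1))
  expect_equal(ncol(out[[1]]), 11L)
  m3 <- replace_head(m, n_tracks = 11L, seed = 9)
  expect_identical(m2$params$head1, m3$params$head1)
  expect_error(replace_head(m, 0L), "positive")
})

test_that("degenerate all-N input yields finite non-negative rates", {
  m <- build_model(tiny_cfg(), 1)
  out <- forward(m, matrix(0, 32, 4))
  expect_true(all(is.finite(out[[1]])))
  expect_true(all(out[[1]] >= 0))
})

test_that("wrong input length reports expected versus received", {
  m <- build_model(tiny_cfg(), 1)
  expect_error(forward(m, rand_onehot(16)), "expected 32 rows, received 16")
})

test_that("predicted rates stay non-negative over 1000 random inputs", {
  m <- build_model(tiny_cfg(), 3)
  ok <- vapply(seq_len(1000), function(i)
    all(forward(m, rand_onehot(32, seed = i))[[1]] >= 0), logical(1))
  expect_true(all(ok))
})

test_that("checkpoints round-trip bit-exactly with provenance", {
  m <- build_model(tiny_cfg(positional_scheme = "enformer_basis"), seed = 4)
  d <- file.path(tempdir(), "ckpt_roundtrip")
  save_checkpoint(m, d, seed = 4, epoch = 3, parent = "origin")
  m2 <- load_checkpoint(d)
  expect_identical(m2$params, m$params)
  expect_identical(unclass(m2$config), unclass(m$config))
  meta <- jsonlite::read_json(file.path(d, "meta.json"))
  expect_equal(meta$epoch, 3)
  expect_equal(meta$parent, "origin")
})
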