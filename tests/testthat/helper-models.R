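# Shared fixtures: miniature architectures, random one-hot inputs, datasets
# drawn from a model's own predictive distribution, and a lazily generated
# synthetic world reused across test files.

tiny_cfg <- function(...) {
  args <- list(
    input_length = 32L, bin_size = 4L, crop_length = 16L, n_conv_blocks = 2L,
    n_attention_blocks = 1L, n_heads = 2L, key_size = 3L, channels = 12L,
    head_track_counts = 2L, dropout_rate = 0,
    positional_scheme = "simple_relative_bias"
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

rand_onehot <- function(L, seed = 1) {
  set.seed(seed)
  x <- matrix(0, L, 4L)
  x[cbind(seq_len(L), sample(4L, L, replace = TRUE))] <- 1
  x
}

rand_seq <- function(L, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# in-memory dataset whose targets are Poisson draws from a reference model's
# own predictions (so the data are realisable by the architecture)
model_dist_dataset <- function(cfg, n_train = 6, n_val = 2, n_test = 0, seed = 1) {
  ref <- build_model(cfg, seed = seed + 999)
  nb <- cfg$crop_length %/% cfg$bin_size
  nt <- cfg$head_track_counts[1]
  mk <- function(n, split, off) {
    lapply(seq_len(n), function(i) {
      x <- rand_onehot(cfg$input_length, seed = seed + off + i)
      lam <- forward(ref, x)[[1]]
      set.seed(seed + off + i)
      y <- matrix(rpois(nb * nt, lam), nb, nt)
      colnames(y) <- sprintf("t%d", seq_len(nt))
      list(x = x, y = y, id = sprintf("%s%d", split, i), split = split,
           window = list(chrom = "chr", start = 0L, end = cfg$input_length))
    })
  }
  structure(list(
    examples = c(mk(n_train, "train", 0), mk(n_val, "validation", 100),
                 mk(n_test, "test", 200)),
    track_names = sprintf("t%d", seq_len(nt)),
    n_bins = nb,
    manifest = list(geometry = list(input_length = cfg$input_length,
                                    crop_length = cfg$crop_length,
                                    bin_size = cfg$bin_size))
  ), class = "s2t_dataset")
}

# one shared tiny world per test session (generation takes ~30 s)
.test_world_env <- new.env(parent = emptyenv())
get_test_world <- function() {
  if (is.null(.test_world_env$world)) {
    dir <- file.path(tempdir(), "s2t_test_world")
    .test_world_env$world <- generate_world(world_config("tiny", seed = 1), dir)
  }
  .test_world_env$world
}
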