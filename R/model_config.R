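#' Architecture configuration
#'
#' Describes an Enformer-derived trunk (convolutional stem + tower, a stack of
#' self-attention blocks) together with the ablation switches studied here and
#' one or more linear output heads. The defaults reproduce the published
#' full-scale architecture restricted to the 5313-track human head, which is
#' the configuration used for pretraining.
#'
#' The sequence is downsampled two-fold by the stem and by each tower stage,
#' so the total pooling factor is `2^n_conv_blocks` and must equal `bin_size`:
#' the trunk emits one feature vector per `bin_size` bp. Predictions are made
#' for the centred `crop_length` bp only, i.e. `crop_length / bin_size` bins.
#'
#' @param input_length receptive field in bp (default 196608).
#' @param bin_size output resolution in bp (default 128).
#' @param crop_length centred span, in bp, for which predictions are emitted
#'   (default 114688, i.e. 896 bins).
#' @param n_conv_blocks number of two-fold-pooling convolutional blocks
#'   (stem counts as the first; default 7, so the pooling factor is 128).
#' @param n_attention_blocks number of self-attention blocks (default 11;
#'   the reduced variant uses 5).
#' @param n_heads attention heads (default 8).
#' @param key_size per-head query/key width (default 64). The per-head value
#'   width is `channels / n_heads`.
#' @param channels trunk width after the tower (default 1536; the stem runs at
#'   `channels / 2`).
#' @param include_attention_linear keep the linear output projection that
#'   follows multi-head attention in every block (`TRUE` = baseline;
#'   `FALSE` = the "no linear" ablation).
#' @param include_final_pointwise keep the final width-1 convolution that
#'   doubles the channel width before the heads (`TRUE` = baseline;
#'   `FALSE` = the "no pointwise" ablation).
#' @param head_track_counts integer vector, one entry per output head, giving
#'   the number of tracks each head predicts (default 5313).
#' @param dropout_rate dropout probability applied at the standard sites
#'   (post-attention, feed-forward, final pointwise). Desk-scale presets use 0.
#' @param positional_scheme `"enformer_basis"` for the published fixed basis of
#'   relative-position features (exponential, central-mask and gamma families,
#'   projected per head), or `"simple_relative_bias"` for a learned per-head
#'   bias over relative distances (cheaper; intended for small configurations).
#' @return an object of class `s2t_model_config`.
#' @seealso [build_model()], [toy_model_config()]
#' @export
model_config <- function(input_length = 196608L,
                         bin_size = 128L,
                         crop_length = 114688L,
                         n_conv_blocks = 7L,
                         n_attention_blocks = 11L,
                         n_heads = 8L,
                         key_size = 64L,
                         channels = 1536L,
                         include_attention_linear = TRUE,
                         include_final_pointwise = TRUE,
                         head_track_counts = 5313L,
                         dropout_rate = 0.4,
                         positional_scheme = c("enformer_basis", "simple_relative_bias")) {
  positional_scheme <- match.arg(positional_scheme)
  cfg <- structure(list(
    input_length = as.integer(input_length),
    bin_size = as.integer(bin_size),
    crop_length = as.integer(crop_length),
    n_conv_blocks = as.integer(n_conv_blocks),
    n_attention_blocks = as.integer(n_attention_blocks),
    n_heads = as.integer(n_heads),
    key_size = as.integer(key_size),
    channels = as.integer(channels),
    include_attention_linear = isTRUE(include_attention_linear),
    include_final_pointwise = isTRUE(include_final_pointwise),
    head_track_counts = as.integer(head_track_counts),
    dropout_rate = as.numeric(dropout_rate),
    positional_scheme = positional_scheme
  ), class = "s2t_model_config")
  validate_model_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks the structural invariants of [model_config()] and fails with a
#' message naming the violated one.
#'
#' @param cfg an `s2t_model_config`.
#' @return `cfg`, invisibly.
#' @export
validate_model_config <- function(cfg) {
  with(cfg, {
    if (!is_count(input_length) || !is_count(bin_size) || !is_count(crop_length))
      stop_s2t("input_length, bin_size and crop_length must be positive integers")
    if (input_length %% bin_size != 0L)
      stop_s2t("invalid config: input_length (%d) is not a multiple of bin_size (%d)",
               input_length, bin_size)
    if (crop_length %% bin_size != 0L)
      stop_s2t("invalid config: crop_length (%d) is not a multiple of bin_size (%d)",
               crop_length, bin_size)
    if (crop_length > input_length)
      stop_s2t("invalid config: crop_length (%d) exceeds input_length (%d)",
               crop_length, input_length)
    if ((input_length - crop_length) %% (2L * bin_size) != 0L)
      stop_s2t("invalid config: (input_length - crop_length) must be an even number of bins")
    if (!is_count(n_conv_blocks, 1L))
      stop_s2t("invalid config: n_conv_blocks must be >= 1")
    if (2^n_conv_blocks != bin_size)
      stop_s2t(paste0("invalid config: total pooling factor 2^n_conv_blocks (%d) ",
                      "does not equal bin_size (%d)"), 2^n_conv_blocks, bin_size)
    if (!is_count(n_attention_blocks, 1L))
      stop_s2t("invalid config: n_attention_blocks must be >= 1")
    if (channels %% 2L != 0L)
      stop_s2t("invalid config: channels must be even (stem runs at channels/2)")
    if (channels %% n_heads != 0L)
      stop_s2t("invalid config: channels (%d) must be divisible by n_heads (%d)",
               channels, n_heads)
    if (length(head_track_counts) < 1L || any(head_track_counts < 1L))
      stop_s2t("invalid config: every head track count must be >= 1")
    if (dropout_rate < 0 || dropout_rate >= 1)
      stop_s2t("invalid config: dropout_rate must be in [0, 1)")
    if (positional_scheme == "enformer_basis" && (channels / n_heads) %% 6 != 0)
      stop_s2t(paste0("invalid config: the relative-position feature size ",
                      "channels/n_heads (%d) must be divisible by 6 for ",
                      "positional_scheme = 'enformer_basis'"), channels / n_heads)
  })
  invisible(cfg)
}

#' Small-scale architecture presets
#'
#' A convenience wrapper around [model_config()] with defaults sized for
#' desk-scale experimentation on one CPU: 4096-bp windows, 128-bp bins
#' (so the same 7 pooling stages as the full model), a narrow trunk and a
#' learned relative-position bias.
#'
#' @param n_tracks tracks for the single output head.
#' @param channels trunk width (default 48; motif discovery at desk scale
#'   benefits from a comfortably over-complete stem).
#' @param n_attention_blocks attention depth (default 2).
#' @param input_length,crop_length,bin_size window geometry.
#' @param ... further overrides passed to [model_config()].
#' @return an `s2t_model_config`.
#' @export
toy_model_config <- function(n_tracks = 1L,
                             channels = 48L,
                             n_attention_blocks = 2L,
                             input_length = 4096L,
                             crop_length = 2048L,
                             bin_size = 128L,
                             ...) {
  args <- list(
    input_length = input_length, crop_length = crop_length, bin_size = bin_size,
    n_conv_blocks = as.integer(round(log2(bin_size))),
    n_attention_blocks = n_attention_blocks,
    n_heads = 4L, key_size = 8L, channels = channels,
    head_track_counts = n_tracks, dropout_rate = 0,
    positional_scheme = "simple_relative_bias"
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(model_config, args)
}

# number of output bins implied by a config
config_n_bins <- function(cfg) cfg$crop_length %/% cfg$bin_size

# sequence length at the attention blocks
config_attn_length <- function(cfg) cfg$input_length %/% cfg$bin_size

# channel width feeding the heads
config_head_input <- function(cfg)
  if (cfg$include_final_pointwise) 2L * cfg$channels else cfg$channels

# widths of the 6-stage tower (exponentially spaced, rounded to 128-divisible
# multiples at full scale, to n_heads-divisible multiples at toy scale)
config_tower_filters <- function(cfg) {
  n <- cfg$n_conv_blocks - 1L
  if (n == 0L) return(integer(0))
  half <- cfg$channels %/% 2L
  div <- if (cfg$channels %% 128L == 0L) 128L else cfg$n_heads
  if (n == 1L) return(cfg$channels)
  base <- exp(log(cfg$channels / half) / (n - 1L))
  f <- as.integer(round(half * base^(seq_len(n) - 1L) / div) * div)
  f[n] <- cfg$channels
  pmax(f, div)
}
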