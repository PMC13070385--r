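# Model assembly and the full forward/backward passes.
#
# A model is a plain list: config (s2t_model_config), params (flat named list
# of numeric arrays), static (fixed tensors: relative-position features and
# index matrices) and frozen (trunk freeze flag). Parameter names encode the
# component ("stem.", "tower<i>.", "att<j>.", "pointwise.", "head<k>."), which
# is what count_parameters() and the freezing logic key on.

#' Build a model from a configuration
#'
#' Instantiates the Enformer-derived architecture described by `config`:
#' a convolutional stem, an exponentially widening convolutional tower (each
#' stage pooling two-fold via learned softmax pooling), `n_attention_blocks`
#' self-attention blocks with relative positional information, optionally the
#' final width-1 convolution, and one softplus-linear head per entry of
#' `head_track_counts`. Weight initialisation follows the PyTorch defaults
#' (Kaiming-uniform for dense/convolution weights) and is fully determined by
#' `seed`.
#'
#' @param config an [model_config()] object.
#' @param seed integer; determines every random draw of the initialisation.
#' @return an object of class `s2t_model`.
#' @examples
#' m <- build_model(toy_model_config(n_tracks = 2), seed = 1)
#' count_parameters(m)$trainable_count
#' @export
build_model <- function(config, seed = 1L) {
  validate_model_config(config)
  set.seed(as.integer(seed))
  cfg <- config
  half <- cfg$channels %/% 2L
  C <- cfg$channels
  h <- cfg$n_heads; dk <- cfg$key_size; F_ <- C %/% h
  Latt <- config_attn_length(cfg)
  p <- list()

  # stem: conv(4 -> C/2, width 15), residual BN-GELU-conv(1), softmax pool
  p[["stem.conv"]] <- init_linear(15L * 4L, half)
  p[["stem.res.bn"]] <- list(gamma = rep(1, half), beta = rep(0, half))
  p[["stem.res.conv"]] <- init_linear(half, half)
  p[["stem.pool"]] <- list(W = diag(2, half))

  filters <- config_tower_filters(cfg)
  prev <- half
  for (i in seq_along(filters)) {
    f <- filters[i]
    p[[sprintf("tower%d.bn1", i)]] <- list(gamma = rep(1, prev), beta = rep(0, prev))
    p[[sprintf("tower%d.conv1", i)]] <- init_linear(5L * prev, f)
    p[[sprintf("tower%d.res.bn", i)]] <- list(gamma = rep(1, f), beta = rep(0, f))
    p[[sprintf("tower%d.res.conv", i)]] <- init_linear(f, f)
    p[[sprintf("tower%d.pool", i)]] <- list(W = diag(2, f))
    prev <- f
  }

  basis <- cfg$positional_scheme == "enformer_basis"
  for (j in seq_len(cfg$n_attention_blocks)) {
    nm <- function(s) sprintf("att%d.%s", j, s)
    p[[nm("ln1")]] <- list(gamma = rep(1, C), beta = rep(0, C))
    att <- list(
      Wq = init_linear(C, h * dk, bias = FALSE)$W,
      Wk = init_linear(C, h * dk, bias = FALSE)$W,
      Wv = init_linear(C, C, bias = FALSE)$W
    )
    if (cfg$include_attention_linear) {
      ol <- init_linear(C, C)
      att$Wo <- ol$W; att$bo <- ol$b
    }
    att$rw <- matrix(rnorm(h * dk, sd = 0.1), h, dk)
    if (basis) {
      att$rr <- matrix(rnorm(h * dk, sd = 0.1), h, dk)
      att$Wr <- init_linear(F_, h * dk, bias = FALSE)$W
    } else {
      att$relbias <- matrix(0, 2L * Latt - 1L, h)
    }
    p[[nm("mha")]] <- att
    p[[nm("ln2")]] <- list(gamma = rep(1, C), beta = rep(0, C))
    p[[nm("ffn1")]] <- init_linear(C, 2L * C)
    p[[nm("ffn2")]] <- init_linear(2L * C, C)
  }

  if (cfg$include_final_pointwise) {
    p[["pointwise.bn"]] <- list(gamma = rep(1, C), beta = rep(0, C))
    p[["pointwise.conv"]] <- init_linear(C, 2L * C)
  }

  D <- config_head_input(cfg)
  for (k in seq_along(cfg$head_track_counts)) {
    p[[sprintf("head%d", k)]] <- init_linear(D, cfg$head_track_counts[k])
  }

  static <- list(idxd = rel_index_matrix(Latt))
  if (basis) static$R <- positional_features(Latt, F_)

  structure(list(config = cfg, params = p, static = static, frozen = FALSE),
            class = "s2t_model")
}

#' @export
print.s2t_model <- function(x, ...) {
  cfg <- x$config
  ps <- count_parameters(x)
  cat(sprintf(
    "s2t_model: input %d bp, %d bins x %s tracks | conv blocks %d, attention blocks %d, channels %d\n",
    cfg$input_length, config_n_bins(cfg),
    paste(cfg$head_track_counts, collapse = "+"),
    cfg$n_conv_blocks, cfg$n_attention_blocks, cfg$channels))
  cat(sprintf("  ablations: attention linear %s, final pointwise %s | trunk %s\n",
              cfg$include_attention_linear, cfg$include_final_pointwise,
              if (x$frozen) "FROZEN" else "trainable"))
  cat(sprintf("  parameters: %s (%s)\n",
              format(ps$trainable_count, big.mark = ","),
              paste(sprintf("%s %s", names(ps$per_component_counts),
                            format(unlist(ps$per_component_counts), big.mark = ",", trim = TRUE)),
                    collapse = ", ")))
  invisible(x)
}

param_component <- function(nm) {
  ifelse(grepl("^stem", nm), "stem",
  ifelse(grepl("^tower", nm), "conv_tower",
  ifelse(grepl("^att", nm), "attention_blocks",
  ifelse(grepl("^pointwise", nm), "pointwise", "heads"))))
}

#' Count model parameters per component
#'
#' @param model an `s2t_model`.
#' @param trainable_only if `TRUE` and the trunk is frozen, only head
#'   parameters are counted.
#' @return a list with `trainable_count` and `per_component_counts`
#'   (stem, conv_tower, attention_blocks, pointwise, heads).
#' @examples
#' m <- build_model(toy_model_config(), seed = 1)
#' count_parameters(m)$per_component_counts
#' @export
count_parameters <- function(model, trainable_only = FALSE) {
  nms <- names(model$params)
  keep <- rep(TRUE, length(nms))
  if (trainable_only && isTRUE(model$frozen)) keep <- grepl("^head", nms)
  comp <- param_component(nms)
  sizes <- vapply(model$params, param_count, numeric(1))
  out <- setNames(numeric(5), c("stem", "conv_tower", "attention_blocks",
                                "pointwise", "heads"))
  for (cc in names(out)) out[cc] <- sum(sizes[keep & comp == cc])
  list(trainable_count = sum(out), per_component_counts = as.list(out))
}

#' Replace all output heads with one freshly initialised head
#'
#' Implements the head-swap step of fine-tuning: every existing head is
#' removed and a single new head with `n_tracks` outputs is attached; no
#' trunk weight is touched (their values are bit-identical before and after).
#'
#' @param model an `s2t_model`.
#' @param n_tracks number of tracks the new head predicts.
#' @param seed determines the new head's initialisation.
#' @return the modified model.
#' @export
replace_head <- function(model, n_tracks, seed = 1L) {
  if (!is_count(n_tracks)) stop_s2t("n_tracks must be a positive integer")
  set.seed(as.integer(seed))
  nms <- names(model$params)
  model$params[grepl("^head", nms)] <- NULL
  D <- config_head_input(model$config)
  model$params[["head1"]] <- init_linear(D, as.integer(n_tracks))
  model$config$head_track_counts <- as.integer(n_tracks)
  model
}

#' Freeze or unfreeze the trunk
#'
#' When frozen, training updates only head parameters; every other weight is
#' left bit-identical after any number of optimisation steps.
#'
#' @param model an `s2t_model`.
#' @param frozen logical.
#' @return the modified model.
#' @export
set_trunk_frozen <- function(model, frozen = TRUE) {
  model$frozen <- isTRUE(frozen)
  model
}

trunk_param_names <- function(model) {
  nms <- names(model$params)
  nms[!grepl("^head", nms)]
}

#' Checksum of the trunk weights
#'
#' An md5 digest of the binary serialization of all non-head parameters;
#' used to prove head-swap isolation and freeze invariance.
#'
#' @param model an `s2t_model`.
#' @return a character md5 string.
#' @export
trunk_checksum <- function(model) {
  object_md5(model$params[trunk_param_names(model)])
}

## ---- forward / backward ---------------------------------------------------

validate_onehot <- function(x, cfg) {
  if (!is.matrix(x) || ncol(x) != 4L)
    stop_s2t("input must be a one-hot matrix with 4 columns, received %s",
             paste(dim(x), collapse = "x"))
  if (nrow(x) != cfg$input_length)
    stop_s2t("input length mismatch: expected %d rows, received %d",
             cfg$input_length, nrow(x))
}

#' Run the model forward
#'
#' Maps a one-hot encoded sequence of `input_length` bp to one non-negative
#' prediction grid of shape `(crop_length / bin_size, n_tracks)` per head.
#'
#' @param model an `s2t_model`.
#' @param x one-hot matrix (`input_length` x 4), or a list of such matrices.
#' @param training if `TRUE`, dropout is active (drawing from the current RNG
#'   stream); evaluation mode is deterministic.
#' @return a list with one matrix per head (or a list of such lists for list
#'   input).
#' @export
forward <- function(model, x, training = FALSE) {
  if (is.list(x)) return(lapply(x, function(xi) forward(model, xi, training)))
  validate_onehot(x, model$config)
  model_forward(model, x, training)$heads
}

model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  p <- model$params
  cache <- list()
  drop <- cfg$dropout_rate
  x <- t(x)  # channel-major internally: 4 x L

  # stem
  st <- conv1d_fw(x, p$stem.conv$W, p$stem.conv$b, 15L); cache$stem_conv <- st$cache
  rb <- batchnorm_fw(st$out, p$stem.res.bn$gamma, p$stem.res.bn$beta)
  cache$stem_res_bn <- rb$cache
  rg <- gelu_fw(rb$out); cache$stem_res_gelu <- rg$cache
  rc <- conv1d_fw(rg$out, p$stem.res.conv$W, p$stem.res.conv$b, 1L)
  cache$stem_res_conv <- rc$cache
  h1 <- st$out + rc$out
  pl <- attnpool_fw(h1, p$stem.pool$W); cache$stem_pool <- pl$cache
  h <- pl$out

  # tower
  nt <- cfg$n_conv_blocks - 1L
  cache$tower <- vector("list", nt)
  for (i in seq_len(nt)) {
    tc <- list()
    b1 <- batchnorm_fw(h, p[[sprintf("tower%d.bn1", i)]]$gamma,
                       p[[sprintf("tower%d.bn1", i)]]$beta); tc$bn1 <- b1$cache
    g1 <- gelu_fw(b1$out); tc$gelu1 <- g1$cache
    c1 <- conv1d_fw(g1$out, p[[sprintf("tower%d.conv1", i)]]$W,
                    p[[sprintf("tower%d.conv1", i)]]$b, 5L); tc$conv1 <- c1$cache
    b2 <- batchnorm_fw(c1$out, p[[sprintf("tower%d.res.bn", i)]]$gamma,
                       p[[sprintf("tower%d.res.bn", i)]]$beta); tc$bn2 <- b2$cache
    g2 <- gelu_fw(b2$out); tc$gelu2 <- g2$cache
    c2 <- conv1d_fw(g2$out, p[[sprintf("tower%d.res.conv", i)]]$W,
                    p[[sprintf("tower%d.res.conv", i)]]$b, 1L); tc$conv2 <- c2$cache
    s <- c1$out + c2$out
    pl <- attnpool_fw(s, p[[sprintf("tower%d.pool", i)]]$W); tc$pool <- pl$cache
    h <- pl$out
    cache$tower[[i]] <- tc
  }

  # attention blocks
  na <- cfg$n_attention_blocks
  cache$att <- vector("list", na)
  for (j in seq_len(na)) {
    ac <- list()
    mp <- p[[sprintf("att%d.mha", j)]]
    l1 <- layernorm_fw(h, p[[sprintf("att%d.ln1", j)]]$gamma,
                       p[[sprintf("att%d.ln1", j)]]$beta); ac$ln1 <- l1$cache
    mh <- mha_fw(l1$out, mp, cfg, model$static); ac$mha <- mh$cache
    d1 <- dropout_fw(mh$out, drop, training); ac$drop1 <- d1$cache
    h <- h + d1$out
    l2 <- layernorm_fw(h, p[[sprintf("att%d.ln2", j)]]$gamma,
                       p[[sprintf("att%d.ln2", j)]]$beta); ac$ln2 <- l2$cache
    f1 <- linear_fw(l2$out, p[[sprintf("att%d.ffn1", j)]]$W,
                    p[[sprintf("att%d.ffn1", j)]]$b); ac$ffn1 <- f1$cache
    d2 <- dropout_fw(f1$out, drop, training); ac$drop2 <- d2$cache
    r1 <- relu_fw(d2$out); ac$relu <- r1$cache
    f2 <- linear_fw(r1$out, p[[sprintf("att%d.ffn2", j)]]$W,
                    p[[sprintf("att%d.ffn2", j)]]$b); ac$ffn2 <- f2$cache
    d3 <- dropout_fw(f2$out, drop, training); ac$drop3 <- d3$cache
    h <- h + d3$out
    cache$att[[j]] <- ac
  }

  # centre crop at bin resolution
  Latt <- ncol(h)
  nb <- config_n_bins(cfg)
  off <- (Latt - nb) %/% 2L
  cache$crop <- list(Latt = Latt, nb = nb, off = off)
  h <- h[, (off + 1L):(off + nb), drop = FALSE]

  if (cfg$include_final_pointwise) {
    pb <- batchnorm_fw(h, p$pointwise.bn$gamma, p$pointwise.bn$beta)
    cache$pw_bn <- pb$cache
    pg <- gelu_fw(pb$out); cache$pw_gelu1 <- pg$cache
    pc <- linear_fw(pg$out, p$pointwise.conv$W, p$pointwise.conv$b)
    cache$pw_conv <- pc$cache
    pd <- dropout_fw(pc$out, drop, training); cache$pw_drop <- pd$cache
    pg2 <- gelu_fw(pd$out); cache$pw_gelu2 <- pg2$cache
    h <- pg2$out
  }
  cache$head_input <- h

  heads <- list()
  cache$head_pre <- list()
  for (k in seq_along(cfg$head_track_counts)) {
    hp <- p[[sprintf("head%d", k)]]
    z <- linear_fw(h, hp$W, hp$b)
    sp <- softplus_fw(z$out)
    cache$head_pre[[k]] <- list(lin = z$cache, act = sp$cache)
    heads[[k]] <- t(sp$out)  # public orientation: bins x tracks
  }
  list(heads = heads, cache = cache)
}

# Backward pass: dheads is a list of gradients in the public (bins x tracks)
# orientation, one per head (NULL entries allowed). Returns a flat named
# list of gradients mirroring model$params. When head_only = TRUE (frozen
# trunk) only head gradients are computed.
model_backward <- function(model, cache, dheads, head_only = FALSE) {
  cfg <- model$config
  p <- model$params
  g <- list()
  H <- cache$head_input
  dH <- matrix(0, nrow(H), ncol(H))
  for (k in seq_along(cfg$head_track_counts)) {
    if (is.null(dheads[[k]])) next
    hp <- p[[sprintf("head%d", k)]]
    dz <- softplus_bw(cache$head_pre[[k]]$act, t(dheads[[k]]))
    lb <- linear_bw(cache$head_pre[[k]]$lin, hp$W, dz)
    g[[sprintf("head%d", k)]] <- lb$grads
    dH <- dH + lb$dx
  }
  if (head_only) return(g)

  if (cfg$include_final_pointwise) {
    dpd <- gelu_bw(cache$pw_gelu2, dH)
    dpc <- dropout_bw(cache$pw_drop, dpd)
    lb <- linear_bw(cache$pw_conv, p$pointwise.conv$W, dpc)
    g$pointwise.conv <- lb$grads
    dpg <- gelu_bw(cache$pw_gelu1, lb$dx)
    bb <- batchnorm_bw(cache$pw_bn, p$pointwise.bn$gamma, dpg)
    g$pointwise.bn <- bb$grads
    dH <- bb$dx
  }

  # un-crop
  cr <- cache$crop
  dh <- matrix(0, nrow(dH), cr$Latt)
  dh[, (cr$off + 1L):(cr$off + cr$nb)] <- dH

  for (j in rev(seq_len(cfg$n_attention_blocks))) {
    ac <- cache$att[[j]]
    # feed-forward sublayer
    df2o <- dropout_bw(ac$drop3, dh)
    lb2 <- linear_bw(ac$ffn2, p[[sprintf("att%d.ffn2", j)]]$W, df2o)
    g[[sprintf("att%d.ffn2", j)]] <- lb2$grads
    dr <- relu_bw(ac$relu, lb2$dx)
    dr <- dropout_bw(ac$drop2, dr)
    lb1 <- linear_bw(ac$ffn1, p[[sprintf("att%d.ffn1", j)]]$W, dr)
    g[[sprintf("att%d.ffn1", j)]] <- lb1$grads
    ln2 <- layernorm_bw(ac$ln2, p[[sprintf("att%d.ln2", j)]]$gamma, lb1$dx)
    g[[sprintf("att%d.ln2", j)]] <- ln2$grads
    dh <- dh + ln2$dx
    # attention sublayer
    dmo <- dropout_bw(ac$drop1, dh)
    mb <- mha_bw(ac$mha, p[[sprintf("att%d.mha", j)]], cfg, model$static, dmo)
    g[[sprintf("att%d.mha", j)]] <- mb$grads
    ln1 <- layernorm_bw(ac$ln1, p[[sprintf("att%d.ln1", j)]]$gamma, mb$dx)
    g[[sprintf("att%d.ln1", j)]] <- ln1$grads
    dh <- dh + ln1$dx
  }

  for (i in rev(seq_len(cfg$n_conv_blocks - 1L))) {
    tc <- cache$tower[[i]]
    pb <- attnpool_bw(tc$pool, p[[sprintf("tower%d.pool", i)]]$W, dh)
    g[[sprintf("tower%d.pool", i)]] <- pb$grads
    ds <- pb$dx
    cb2 <- conv1d_bw(tc$conv2, p[[sprintf("tower%d.res.conv", i)]]$W, ds)
    g[[sprintf("tower%d.res.conv", i)]] <- cb2$grads
    dg2 <- gelu_bw(tc$gelu2, cb2$dx)
    bb2 <- batchnorm_bw(tc$bn2, p[[sprintf("tower%d.res.bn", i)]]$gamma, dg2)
    g[[sprintf("tower%d.res.bn", i)]] <- bb2$grads
    dc1 <- ds + bb2$dx
    cb1 <- conv1d_bw(tc$conv1, p[[sprintf("tower%d.conv1", i)]]$W, dc1)
    g[[sprintf("tower%d.conv1", i)]] <- cb1$grads
    dg1 <- gelu_bw(tc$gelu1, cb1$dx)
    bb1 <- batchnorm_bw(tc$bn1, p[[sprintf("tower%d.bn1", i)]]$gamma, dg1)
    g[[sprintf("tower%d.bn1", i)]] <- bb1$grads
    dh <- bb1$dx
  }

  pb <- attnpool_bw(cache$stem_pool, p$stem.pool$W, dh)
  g$stem.pool <- pb$grads
  dh1 <- pb$dx
  cb <- conv1d_bw(cache$stem_res_conv, p$stem.res.conv$W, dh1)
  g$stem.res.conv <- cb$grads
  dgl <- gelu_bw(cache$stem_res_gelu, cb$dx)
  bb <- batchnorm_bw(cache$stem_res_bn, p$stem.res.bn$gamma, dgl)
  g$stem.res.bn <- bb$grads
  dst <- dh1 + bb$dx
  sb <- conv1d_bw(cache$stem_conv, p$stem.conv$W, dst)
  g$stem.conv <- sb$grads
  g
}

## ---- checkpoints ----------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the weights (RDS container) plus a JSON sidecar recording the
#' configuration, seed, epoch, trunk checksum and parent checkpoint, so that
#' `load_checkpoint(save_checkpoint(m, d))` is bit-exact and provenance is
#' traceable across pretrain/fine-tune lineages.
#'
#' @param model an `s2t_model`.
#' @param dir directory to create/write into.
#' @param seed,epoch,parent optional provenance fields.
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir, seed = NULL, epoch = NULL, parent = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  meta <- list(
    config = unclass(model$config),
    seed = seed, epoch = epoch, parent = parent,
    frozen = model$frozen,
    trunk_checksum = trunk_checksum(model)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir directory written by [save_checkpoint()].
#' @return an `s2t_model` with the stored weights.
#' @export
load_checkpoint <- function(dir) {
  wf <- file.path(dir, "weights.rds"); mf <- file.path(dir, "meta.json")
  if (!file.exists(wf) || !file.exists(mf))
    stop_s2t("not a checkpoint directory: %s", dir)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cfgl <- meta$config
  cfg <- model_config(
    input_length = cfgl$input_length, bin_size = cfgl$bin_size,
    crop_length = cfgl$crop_length, n_conv_blocks = cfgl$n_conv_blocks,
    n_attention_blocks = cfgl$n_attention_blocks, n_heads = cfgl$n_heads,
    key_size = cfgl$key_size, channels = cfgl$channels,
    include_attention_linear = cfgl$include_attention_linear,
    include_final_pointwise = cfgl$include_final_pointwise,
    head_track_counts = cfgl$head_track_counts,
    dropout_rate = cfgl$dropout_rate,
    positional_scheme = cfgl$positional_scheme
  )
  params <- readRDS(wf)
  static <- list(idxd = rel_index_matrix(config_attn_length(cfg)))
  if (cfg$positional_scheme == "enformer_basis")
    static$R <- positional_features(config_attn_length(cfg), cfg$channels %/% cfg$n_heads)
  model <- structure(list(config = cfg, params = params, static = static,
                          frozen = isTRUE(meta$frozen)), class = "s2t_model")
  chk <- trunk_checksum(model)
  if (!identical(chk, meta$trunk_checksum))
    stop_s2t("checkpoint %s is corrupt: trunk checksum mismatch", dir)
  model
}
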