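# Data pipeline: sequence and coverage in, one-hot windows with binned count
# labels out. Coordinates are 0-based half-open throughout (BED/bedGraph
# convention); FASTA headers are taken up to the first whitespace.

ONEHOT_CODE <- local({
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("a")] <- 1L
  v[utf8ToInt("C")] <- 2L; v[utf8ToInt("c")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("g")] <- 3L
  v[utf8ToInt("T")] <- 4L; v[utf8ToInt("t")] <- 4L
  v[utf8ToInt("N")] <- 0L; v[utf8ToInt("n")] <- 0L
  v
})

#' One-hot encode a DNA sequence
#'
#' `A -> (1,0,0,0)`, `C -> (0,1,0,0)`, `G -> (0,0,1,0)`, `T -> (0,0,0,1)`,
#' `N -> (0,0,0,0)`; case-insensitive.
#'
#' @param sequence a single DNA string over `A,C,G,T,N` (either case).
#' @return a `nchar(sequence) x 4` binary matrix.
#' @examples
#' one_hot_encode("ACGTN")
#' @export
one_hot_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  m <- matrix(0, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  if (n == 0L) return(m)
  codes <- ONEHOT_CODE[as.integer(charToRaw(sequence))]
  bad <- which(is.na(codes))
  if (length(bad))
    stop_s2t("invalid character '%s' at offset %d (alphabet is A,C,G,T,N)",
             substr(sequence, bad[1], bad[1]), bad[1])
  nz <- codes > 0L
  m[cbind(which(nz), codes[nz])] <- 1
  m
}

#' Decode a one-hot matrix back to sequence
#'
#' Inverse of [one_hot_encode()]: all-zero rows decode to `N`.
#'
#' @param m an L x 4 one-hot matrix.
#' @return an uppercase DNA string.
#' @export
decode_one_hot <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  if (nrow(m) == 0L) return("")
  idx <- max.col(m, ties.method = "first")
  idx[rowSums(m) == 0] <- 5L
  paste(c("A", "C", "G", "T", "N")[idx], collapse = "")
}

#' Aggregate per-base signal into fixed-width bins
#'
#' Each output value is the sum of its bin's per-base values (the convention
#' used to build 128-bp coverage labels).
#'
#' @param per_base_values non-negative numeric vector whose length is a
#'   multiple of `bin_size`.
#' @param bin_size bin width in bases.
#' @param stat `"sum"` (default) or `"mean"`.
#' @return numeric vector of length `length(per_base_values) / bin_size`.
#' @examples
#' bin_signal(c(1, 2, 3, 4), 2)  # 3, 7
#' @export
bin_signal <- function(per_base_values, bin_size, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  n <- length(per_base_values)
  if (n %% bin_size != 0L)
    stop_s2t(paste0("signal length %d is not a multiple of bin_size %d; ",
                    "pad or trim the vector to a whole number of bins"),
             n, bin_size)
  out <- colSums(matrix(per_base_values, nrow = bin_size))
  if (stat == "mean") out <- out / bin_size
  out
}

#' Extract the centred crop of a per-base vector or matrix
#'
#' @param values numeric vector, or matrix with one row per base/bin position.
#' @param crop_length length (in the same positional units as `values`) to
#'   retain, centred.
#' @return the centred slice, same type as `values`.
#' @export
crop_center <- function(values, crop_length) {
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (crop_length > n)
    stop_s2t("crop_length %d exceeds available length %d", crop_length, n)
  if ((n - crop_length) %% 2L != 0L)
    stop_s2t("length %d minus crop_length %d must be even for a centred crop",
             n, crop_length)
  off <- (n - crop_length) %/% 2L
  if (is.matrix(values)) values[(off + 1L):(off + crop_length), , drop = FALSE]
  else values[(off + 1L):(off + crop_length)]
}

## ---- readers / writers ----------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Names are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Intervals are 0-based half-open; positions not covered by any interval
#' have value 0.
#'
#' @param path bedGraph file.
#' @return a named [S4Vectors::RleList]-like per-chromosome run-length
#'   representation of per-base values.
#' @export
read_coverage <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::coverage(gr, weight = "score")
}

#' Write per-bin values as a bedGraph track
#'
#' Each bin of width `bin_size` starting at 0 is written as one interval
#' whose per-base value is `values / bin_size`, so that summing per-base
#' signal over a bin recovers the original value exactly.
#'
#' @param values numeric vector of per-bin values for one chromosome.
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage_bins <- function(values, chrom, bin_size, path) {
  n <- length(values)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = (seq_len(n) - 1L) * bin_size + 1L,
                              width = bin_size),
    score = values / bin_size
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# per-base numeric vector for a 0-based half-open window of one chromosome
coverage_vector <- function(cov, chrom, start, end) {
  if (!chrom %in% names(cov)) return(numeric(end - start))
  rle <- cov[[chrom]]
  n <- length(rle)
  out <- numeric(end - start)
  lo <- max(start, 0L); hi <- min(end, n)
  if (hi > lo)
    out[(lo - start + 1L):(hi - start)] <-
      as.numeric(S4Vectors::window(rle, lo + 1L, hi))
  out
}

## ---- windows and manifests ------------------------------------------------

#' Tile fixed-length windows along chromosomes
#'
#' Windows have length `input_length` and are placed so that their centred
#' `crop_length` spans tile the chromosome contiguously (stride =
#' `crop_length`); windows extending past a chromosome end are dropped.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param input_length,crop_length window geometry in bp.
#' @return a data.frame with columns `chrom`, `start`, `end`, `id`
#'   (0-based half-open coordinates).
#' @export
tile_windows <- function(chrom_lengths, input_length, crop_length) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, by = crop_length, length.out =
                    max(0L, (len - input_length) %/% crop_length + 1L))
    starts <- starts[starts + input_length <= len]
    if (!length(starts)) return(NULL)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(starts + input_length),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer())
  df$id <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  df
}

#' Build a training dataset from genome and coverage tracks
#'
#' For each window: the one-hot encoded `input_length`-bp sequence and a
#' `(crop_length / bin_size) x n_tracks` matrix of binned counts over the
#' centred crop. Windows that do not fit their chromosome are skipped with a
#' warning reporting the count. An optional seed-deterministic subsample of
#' the (training) windows is supported.
#'
#' @param genome named character vector of chromosome sequences.
#' @param tracks named list of coverage objects from [read_coverage()] (or a
#'   named list of per-chromosome numeric vectors).
#' @param windows data.frame as from [tile_windows()], optionally with a
#'   `split` column (`train`/`validation`/`test`).
#' @param config an [model_config()] (only the geometry fields are used).
#' @param subsample optional number of `train` windows to retain.
#' @param seed seed for the subsampling draw.
#' @return an `s2t_dataset`: list with `examples` (each `x`, `y`, `id`,
#'   `split`, `window`), `track_names`, `n_bins` and `manifest`.
#' @export
make_examples <- function(genome, tracks, windows, config,
                          subsample = NULL, seed = 1L) {
  cfg <- config
  nb <- config_n_bins(cfg)
  off <- (cfg$input_length - cfg$crop_length) %/% 2L
  track_names <- names(tracks)
  if (is.null(track_names) || any(track_names == ""))
    stop_s2t("tracks must be a named list")
  if (is.null(windows$split)) windows$split <- "train"
  bad_split <- setdiff(unique(windows$split), c("train", "validation", "test"))
  if (length(bad_split))
    stop_s2t("unknown split label(s): %s", paste(bad_split, collapse = ", "))

  fits <- windows$start >= 0L &
    windows$end <= nchar(genome)[match(windows$chrom, names(genome))] &
    (windows$end - windows$start) == cfg$input_length
  fits[is.na(fits)] <- FALSE
  if (any(!fits))
    warning(sprintf("%d window(s) skipped (off chromosome end or wrong length)",
                    sum(!fits)), call. = FALSE)
  windows <- windows[fits, , drop = FALSE]

  if (!is.null(subsample)) {
    tr <- which(windows$split == "train")
    if (subsample < length(tr)) {
      set.seed(derive_seed(seed, "subsample"))
      drop_idx <- setdiff(tr, sort(sample(tr, subsample)))
      if (length(drop_idx)) windows <- windows[-drop_idx, , drop = FALSE]
    }
  }

  examples <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    s <- substr(genome[[w$chrom]], w$start + 1L, w$end)
    x <- one_hot_encode(s)
    y <- matrix(0, nb, length(tracks), dimnames = list(NULL, track_names))
    cs <- w$start + off; ce <- cs + cfg$crop_length
    for (t in seq_along(tracks)) {
      tr <- tracks[[t]]
      v <- if (is.list(tr) && !methods::is(tr, "RleList")) {
        vv <- tr[[w$chrom]]
        if (is.null(vv)) numeric(cfg$crop_length)
        else vv[(cs + 1L):ce]
      } else coverage_vector(tr, w$chrom, cs, ce)
      y[, t] <- bin_signal(v, cfg$bin_size)
    }
    examples[[i]] <- list(x = x, y = y, id = w$id, split = w$split,
                          window = list(chrom = w$chrom, start = w$start,
                                        end = w$end))
  }
  manifest <- list(
    records = windows[, c("id", "chrom", "start", "end", "split")],
    track_names = track_names,
    geometry = list(input_length = cfg$input_length,
                    crop_length = cfg$crop_length, bin_size = cfg$bin_size),
    provenance = list(subsample = subsample, seed = seed,
                      n_windows = nrow(windows))
  )
  structure(list(examples = examples, track_names = track_names,
                 n_bins = nb, manifest = manifest),
            class = "s2t_dataset")
}

#' @export
print.s2t_dataset <- function(x, ...) {
  sp <- table(factor(vapply(x$examples, `[[`, "", "split"),
                     levels = c("train", "validation", "test")))
  cat(sprintf("s2t_dataset: %d windows (%s) x %d tracks, %d bins/window\n",
              length(x$examples),
              paste(sprintf("%s %d", names(sp), sp), collapse = ", "),
              length(x$track_names), x$n_bins))
  invisible(x)
}

# subset a dataset by split label and/or track columns
dataset_subset <- function(data, split = NULL, tracks = NULL) {
  ex <- data$examples
  if (!is.null(split))
    ex <- ex[vapply(ex, `[[`, "", "split") %in% split]
  if (!is.null(tracks)) {
    ti <- if (is.character(tracks)) match(tracks, data$track_names) else tracks
    if (anyNA(ti)) stop_s2t("unknown track(s): %s",
                            paste(tracks[is.na(ti)], collapse = ", "))
    ex <- lapply(ex, function(e) { e$y <- e$y[, ti, drop = FALSE]; e })
    data$track_names <- data$track_names[ti]
  }
  data$examples <- ex
  data
}

#' Write / read a dataset manifest
#'
#' The manifest (window records, split labels, track catalogue, geometry and
#' provenance) is stored as JSON next to a binary label container holding the
#' one-hot inputs and label matrices; `read_manifest(write_manifest(d))`
#' round-trips exactly.
#'
#' @param data an `s2t_dataset`.
#' @param path directory to write to.
#' @return `path` (for `write_manifest`) or the dataset (for `read_manifest`).
#' @export
write_manifest <- function(data, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data$manifest$track_names <- data$track_names
  if (is.null(data$manifest$geometry))
    stop_s2t("dataset manifest lacks geometry; cannot serialise")
  jsonlite::write_json(data$manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  saveRDS(data$examples, file.path(path, "labels.rds"))
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_s2t("no manifest.json under %s", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  examples <- readRDS(file.path(path, "labels.rds"))
  structure(list(examples = examples,
                 track_names = manifest$track_names,
                 n_bins = manifest$geometry$crop_length %/% manifest$geometry$bin_size,
                 manifest = manifest),
            class = "s2t_dataset")
}
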