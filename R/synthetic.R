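# Synthetic benchmark: desk-scale "genomes" with planted position-weight-
# matrix motifs driving Poisson-distributed binned coverage, organised as a
# large pretraining task corpus on a reference species plus small task sets
# on related species that share part of the motif vocabulary (and carry
# planted exact-duplicate segments, emitted as PSL, so the homology split is
# exercisable end to end).

#' Synthetic world configuration
#'
#' Defines the study conditions of the benchmark: window geometry, motif
#' vocabulary, task counts, cross-species sharing and genome composition.
#' The `"desk"` preset is the default experimental condition (40 pretraining
#' tasks, 300 reference training windows); `"tiny"` is a reduced condition
#' sized for fast end-to-end runs on one CPU.
#'
#' @param preset `"desk"` or `"tiny"`.
#' @param ... overrides of individual fields.
#' @return an `s2t_world_config` list with fields:
#'   `input_length`, `crop_length`, `bin_size` (window geometry);
#'   `n_motifs`, `motif_length` (PWM vocabulary of the reference species);
#'   `n_pretrain_tasks`, `n_finetune_tasks` (tracks per species);
#'   `species` (nonreference species names), `sharing_fraction` (fraction of
#'   the reference motif vocabulary each species shares), `gc` (named GC
#'   content per species, reference first);
#'   `ref_windows`, `species_windows` (train/validation/test window counts);
#'   `occ_rate_per_kb` (motif occurrences per kb), `baseline_rate` (expected
#'   counts per bin away from motifs), `weight_scale` (typical motif effect
#'   on the log rate), `motifs_per_task`, `bandwidth` (Gaussian kernel sd in
#'   bp); `dup_n`, `dup_length` (planted homologous segments); `seed`.
#' @export
world_config <- function(preset = c("desk", "tiny"), ...) {
  preset <- match.arg(preset)
  base <- list(
    input_length = 4096L, crop_length = 2048L, bin_size = 128L,
    n_motifs = 12L, motif_length = 10L, motif_concentration = 0.1,
    n_pretrain_tasks = 40L, n_finetune_tasks = 3L,
    species = c("speciesA", "speciesB"),
    sharing_fraction = 0.75,
    gc = c(ref = 0.41, speciesA = 0.46, speciesB = 0.52),
    ref_windows = c(train = 300L, validation = 30L, test = 30L),
    species_windows = c(train = 60L, validation = 12L, test = 20L),
    occ_rate_per_kb = 16, baseline_rate = 1.2, weight_scale = 3.5,
    motifs_per_task = 4L, bandwidth = 192,
    dup_n = 16L, dup_length = 2048L,
    seed = 1L
  )
  if (preset == "tiny") {
    base$input_length <- 2048L; base$crop_length <- 1024L
    base$n_motifs <- 8L; base$motif_length <- 8L
    base$n_pretrain_tasks <- 24L; base$n_finetune_tasks <- 2L
    base$species <- "speciesA"
    base$gc <- c(ref = 0.41, speciesA = 0.46)
    base$ref_windows <- c(train = 256L, validation = 16L, test = 16L)
    base$species_windows <- c(train = 32L, validation = 6L, test = 14L)
    base$dup_n <- 10L; base$dup_length <- 1024L
    base$bandwidth <- 160
  }
  over <- list(...)
  base[names(over)] <- over
  w <- structure(base, class = "s2t_world_config")
  if (w$sharing_fraction < 0 || w$sharing_fraction > 1)
    stop_s2t("sharing_fraction must be in [0, 1]")
  stopifnot(all(w$species %in% names(w$gc)))
  w
}

#' Sample a motif vocabulary
#'
#' `M` position weight matrices of length `L`, each row drawn from a
#' Dirichlet with the given concentration (small values give sharp,
#' informative motifs).
#'
#' @param M number of motifs.
#' @param L motif length (>= 4).
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration per row (default 0.3).
#' @return a list of `L x 4` row-stochastic matrices named `motif01`, ...
#' @export
sample_motifs <- function(M, L, seed = 1L, concentration = 0.3) {
  stopifnot(M >= 1L, L >= 4L)
  set.seed(as.integer(seed))
  out <- lapply(seq_len(M), function(i) {
    g <- matrix(rgamma(L * 4L, shape = concentration), L, 4L)
    pwm <- g / rowSums(g)
    colnames(pwm) <- c("A", "C", "G", "T")
    pwm
  })
  names(out) <- sprintf("motif%02d", seq_len(M))
  out
}

#' Sample a genome with planted motif occurrences
#'
#' Background bases are i.i.d. with the requested GC content; motif
#' instances (drawn from their PWMs) are planted at approximately
#' Poisson-distributed, non-overlapping positions.
#'
#' @param length genome length in bp.
#' @param gc GC content of the background.
#' @param motifs named list of PWMs (may be empty).
#' @param occ_rate_per_kb expected motif occurrences per kb (0 disables
#'   planting).
#' @param seed RNG seed.
#' @return list with `sequence` (character string) and `occurrences`
#'   (data.frame: `start` 0-based, `motif`).
#' @export
sample_genome <- function(length, gc, motifs, occ_rate_per_kb = 0, seed = 1L) {
  set.seed(as.integer(seed))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(probs), length, replace = TRUE, prob = probs)
  occ <- data.frame(start = integer(), motif = character(),
                    stringsAsFactors = FALSE)
  if (occ_rate_per_kb > 0 && base::length(motifs) > 0) {
    Lm <- nrow(motifs[[1]])
    n_occ <- rpois(1L, length * occ_rate_per_kb / 1000)
    if (n_occ > 0) {
      pos <- sort(sample.int(length - Lm + 1L, min(n_occ, length %/% (2L * Lm)),
                             replace = FALSE) - 1L)
      # enforce non-overlap
      keep <- c(TRUE, diff(pos) >= Lm)
      pos <- pos[keep]
      ids <- sample(names(motifs), base::length(pos), replace = TRUE)
      for (k in seq_along(pos)) {
        pwm <- motifs[[ids[k]]]
        inst <- vapply(seq_len(Lm), function(r)
          sample(colnames(pwm), 1L, prob = pwm[r, ]), character(1))
        bases[(pos[k] + 1L):(pos[k] + Lm)] <- inst
      }
      occ <- data.frame(start = pos, motif = ids, stringsAsFactors = FALSE)
    }
  }
  list(sequence = paste(bases, collapse = ""), occurrences = occ)
}

#' Per-bin Poisson rates for one task
#'
#' `lambda(bin) = softplus(log(baseline) + sum_occ w(motif) *
#' exp(-d^2 / (2 bandwidth^2)))` with `d` the distance from the bin centre
#' to the occurrence centre; strictly positive by construction.
#'
#' @param occurrences data.frame (`start`, `motif`), 0-based.
#' @param task a task spec: list with `weights` (named by motif), `baseline`,
#'   `bandwidth`, and the motif length `motif_length`.
#' @param n_bins number of bins.
#' @param bin_size bin width in bp.
#' @return numeric vector of length `n_bins`.
#' @export
task_rates <- function(occurrences, task, n_bins, bin_size) {
  s <- rep(log(task$baseline), n_bins)
  if (nrow(occurrences)) {
    w <- task$weights[occurrences$motif]
    w[is.na(w)] <- 0
    rel <- which(w != 0)
    if (length(rel)) {
      centers <- (seq_len(n_bins) - 0.5) * bin_size
      oc <- occurrences$start[rel] + task$motif_length / 2
      bw <- task$bandwidth
      for (k in seq_along(rel)) {
        s <- s + w[rel[k]] * exp(-0.5 * ((centers - oc[k]) / bw)^2)
      }
    }
  }
  softplus(s)
}

#' Draw Poisson counts for a rate vector
#'
#' @param lambda strictly positive rates.
#' @param seed RNG seed.
#' @return integer counts, deterministic given the seed.
#' @export
sample_counts <- function(lambda, seed = 1L) {
  if (any(lambda <= 0)) stop_s2t("all rates must be > 0")
  set.seed(as.integer(seed))
  rpois(length(lambda), lambda)
}

# sample a task spec over a motif id set
sample_task <- function(id, species, motif_ids, world, seed) {
  set.seed(seed)
  k <- min(world$motifs_per_task, length(motif_ids))
  chosen <- sample(motif_ids, k)
  weights <- setNames(
    exp(rnorm(k, mean = log(world$weight_scale), sd = 0.25)), chosen)
  list(id = id, species = species, weights = as.list(weights),
       baseline = exp(rnorm(1L, mean = log(world$baseline_rate), sd = 0.3)),
       bandwidth = world$bandwidth, motif_length = world$motif_length)
}

# genome length so that n windows tile at stride = crop
world_genome_length <- function(world, n_windows) {
  (n_windows + 1L) * world$crop_length
}

#' Generate the full synthetic world on disk
#'
#' Writes, under `dir`: per-species FASTA genomes, per-task bedGraph
#' coverage, motif-occurrence BED files, reference train/validation BED
#' interval sets, PSL mappings of the planted duplicate segments, per-species
#' split-assignment TSVs and JSON descriptions of the world, motifs and
#' tasks. Everything is deterministic given `world$seed`.
#'
#' Species genomes share `sharing_fraction` of the reference motif
#' vocabulary (with freshly drawn task weights) plus species-specific
#' motifs and a shifted GC content, so cross-species transfer is beneficial
#' but not trivial.
#'
#' @param world an [world_config()].
#' @param dir output directory.
#' @return (invisibly) an `s2t_world` list with the in-memory genomes,
#'   motifs, tasks, occurrence tables, PSL mappings, split tables and
#'   `dir`.
#' @export
generate_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  seed <- world$seed
  M <- world$n_motifs

  # motif vocabulary: reference pool + species-specific additions
  pool <- sample_motifs(M, world$motif_length, seed = derive_seed(seed, "motifs"),
                        concentration = world$motif_concentration)
  n_shared <- round(world$sharing_fraction * M)
  motif_sets <- list(ref = names(pool))
  all_motifs <- pool
  for (sp in world$species) {
    set.seed(derive_seed(seed, "shared", sp))
    shared <- if (n_shared > 0) sort(sample(names(pool), n_shared)) else character()
    n_spec <- M - n_shared
    spec <- list()
    if (n_spec > 0) {
      spec <- sample_motifs(n_spec, world$motif_length,
                            seed = derive_seed(seed, "specific", sp),
                            concentration = world$motif_concentration)
      names(spec) <- sprintf("%s_motif%02d", sp, seq_len(n_spec))
      all_motifs <- c(all_motifs, spec)
    }
    motif_sets[[sp]] <- c(shared, names(spec))
  }

  # genomes
  species_all <- c("ref", world$species)
  n_win <- list(ref = world$ref_windows)
  for (sp in world$species) n_win[[sp]] <- world$species_windows
  genomes <- list(); occurrences <- list(); chrom <- list()
  for (sp in species_all) {
    len <- world_genome_length(world, sum(n_win[[sp]]))
    g <- sample_genome(len, world$gc[[sp]], all_motifs[motif_sets[[sp]]],
                       world$occ_rate_per_kb,
                       seed = derive_seed(seed, "genome", sp))
    genomes[[sp]] <- g$sequence
    occurrences[[sp]] <- g$occurrences
    chrom[[sp]] <- sprintf("%s_chr1", sp)
  }

  # reference split intervals (contiguous, over the crop tiling)
  nr <- n_win$ref
  off <- (world$input_length - world$crop_length) %/% 2L
  ref_len <- nchar(genomes$ref)
  bound <- cumsum(c(0L, nr)) * world$crop_length + off
  ref_sets <- list(
    train = data.frame(chrom = chrom$ref, start = bound[1], end = bound[2]),
    validation = data.frame(chrom = chrom$ref, start = bound[2], end = bound[3]),
    test = data.frame(chrom = chrom$ref, start = bound[3], end = bound[4])
  )

  # planted duplicate segments reference -> species, recorded as PSL
  psl <- list()
  for (sp in world$species) {
    set.seed(derive_seed(seed, "dup", sp))
    splen <- nchar(genomes[[sp]])
    dl <- world$dup_length
    taken <- IRanges::IRanges()
    rows <- list()
    for (d in seq_len(world$dup_n)) {
      src <- off + sample.int(bound[3] - off - dl, 1L) - 1L  # within train+validation span
      for (try in 1:20) {
        tgt <- sample.int(splen - dl, 1L) - 1L
        cand <- IRanges::IRanges(tgt + 1L, tgt + dl)
        if (!length(IRanges::findOverlaps(cand, taken))) break
        tgt <- NA_integer_
      }
      if (is.na(tgt)) next
      taken <- c(taken, IRanges::IRanges(tgt + 1L, tgt + dl))
      # copy sequence
      seg <- substr(genomes$ref, src + 1L, src + dl)
      genomes[[sp]] <- paste0(substr(genomes[[sp]], 1L, tgt),
                              seg,
                              substr(genomes[[sp]], tgt + dl + 1L, splen))
      # drop species occurrences inside the overwritten span,
      # import reference occurrences fully inside the source span
      oc <- occurrences[[sp]]
      Lm <- world$motif_length
      oc <- oc[oc$start + Lm <= tgt | oc$start >= tgt + dl, , drop = FALSE]
      rin <- occurrences$ref
      rin <- rin[rin$start >= src & rin$start + Lm <= src + dl, , drop = FALSE]
      if (nrow(rin)) {
        rin$start <- rin$start - src + tgt
        oc <- rbind(oc, rin)
      }
      occurrences[[sp]] <- oc[order(oc$start), , drop = FALSE]
      rows[[length(rows) + 1L]] <- list(
        matches = dl, strand = "+",
        qName = chrom[[sp]], qSize = splen, qStart = tgt, qEnd = tgt + dl,
        tName = chrom$ref, tSize = ref_len, tStart = src, tEnd = src + dl,
        block_sizes = dl, q_starts = tgt, t_starts = src)
    }
    df <- data.frame(
      matches = vapply(rows, `[[`, numeric(1), "matches"),
      strand = vapply(rows, `[[`, character(1), "strand"),
      qName = vapply(rows, `[[`, character(1), "qName"),
      qSize = vapply(rows, `[[`, numeric(1), "qSize"),
      qStart = vapply(rows, `[[`, numeric(1), "qStart"),
      qEnd = vapply(rows, `[[`, numeric(1), "qEnd"),
      tName = vapply(rows, `[[`, character(1), "tName"),
      tSize = vapply(rows, `[[`, numeric(1), "tSize"),
      tStart = vapply(rows, `[[`, numeric(1), "tStart"),
      tEnd = vapply(rows, `[[`, numeric(1), "tEnd"),
      stringsAsFactors = FALSE)
    df$block_sizes <- lapply(rows, `[[`, "block_sizes")
    df$q_starts <- lapply(rows, `[[`, "q_starts")
    df$t_starts <- lapply(rows, `[[`, "t_starts")
    psl[[sp]] <- df
  }

  # tasks
  tasks <- list()
  for (t in seq_len(world$n_pretrain_tasks)) {
    id <- sprintf("ref_task%03d", t)
    tasks[[id]] <- sample_task(id, "ref", motif_sets$ref, world,
                               derive_seed(seed, "task", id))
  }
  for (sp in world$species) for (t in seq_len(world$n_finetune_tasks)) {
    id <- sprintf("%s_task%02d", sp, t)
    tasks[[id]] <- sample_task(id, sp, motif_sets[[sp]], world,
                               derive_seed(seed, "task", id))
  }

  # coverage tracks (genome-wide bins, Poisson counts)
  counts <- list()
  for (id in names(tasks)) {
    tk <- tasks[[id]]
    sp <- tk$species
    nbg <- nchar(genomes[[sp]]) %/% world$bin_size
    lam <- task_rates(occurrences[[sp]],
                      list(weights = unlist(tk$weights), baseline = tk$baseline,
                           bandwidth = tk$bandwidth, motif_length = tk$motif_length),
                      nbg, world$bin_size)
    counts[[id]] <- sample_counts(lam, seed = derive_seed(seed, "counts", id))
  }

  # windows and split labels
  windows <- list(); assignments <- list()
  for (sp in species_all) {
    cl <- setNames(nchar(genomes[[sp]]), chrom[[sp]])
    w <- tile_windows(cl, world$input_length, world$crop_length)
    w <- w[seq_len(min(nrow(w), sum(n_win[[sp]]))), , drop = FALSE]
    if (sp == "ref") {
      w$split <- rep(c("train", "validation", "test"), times = nr)[seq_len(nrow(w))]
    } else {
      pol <- split_policy(
        zero_ratios = c(train = unname(n_win[[sp]]["train"]),
                        validation = unname(n_win[[sp]]["validation"]),
                        test = unname(n_win[[sp]]["test"])) / sum(n_win[[sp]]),
        seed = derive_seed(seed, "zero", sp))
      asg <- assign_regions(w, psl[[sp]], ref_sets$train, ref_sets$validation, pol)
      assignments[[sp]] <- asg
      w$split <- asg$label
    }
    windows[[sp]] <- w
  }

  # ---- write everything ----
  for (sp in species_all) {
    write_fasta(setNames(genomes[[sp]], chrom[[sp]]),
                file.path(dir, sprintf("%s.fa", sp)))
    oc <- occurrences[[sp]]
    if (nrow(oc)) {
      gr <- GenomicRanges::GRanges(chrom[[sp]],
              IRanges::IRanges(oc$start + 1L, oc$start + world$motif_length),
              name = oc$motif)
      rtracklayer::export(gr, file.path(dir, sprintf("%s_occurrences.bed", sp)),
                          format = "bed")
    }
    write.table(windows[[sp]], file.path(dir, sprintf("%s_windows.tsv", sp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (lab in c("train", "validation")) {
    d <- ref_sets[[lab]]
    gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
    rtracklayer::export(gr, file.path(dir, sprintf("ref_%s.bed", lab)),
                        format = "bed")
  }
  for (sp in world$species) {
    write_psl(psl[[sp]], file.path(dir, sprintf("%s.psl", sp)))
    write_assignments(assignments[[sp]],
                      file.path(dir, sprintf("%s_split.tsv", sp)))
  }
  for (id in names(tasks)) {
    sp <- tasks[[id]]$species
    write_coverage_bins(counts[[id]], chrom[[sp]], world$bin_size,
                        file.path(dir, "tracks", sprintf("%s.bedGraph", id)))
  }
  jsonlite::write_json(unclass(world), file.path(dir, "world.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(all_motifs, function(m) unname(as.data.frame(m))),
                       file.path(dir, "motifs.json"), digits = NA)
  jsonlite::write_json(tasks, file.path(dir, "tasks.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(structure(list(
    dir = dir, config = world, motifs = all_motifs, motif_sets = motif_sets,
    genomes = genomes, chrom = chrom, occurrences = occurrences,
    tasks = tasks, counts = counts, windows = windows,
    assignments = assignments, psl = psl, ref_sets = ref_sets
  ), class = "s2t_world"))
}

#' Build an `s2t_dataset` for one species of a generated world
#'
#' Reads the species genome (FASTA) and the requested coverage tracks
#' (bedGraph) back through the standard data pipeline and windows them with
#' the world's geometry and split labels.
#'
#' @param w an `s2t_world` from [generate_world()] (or a directory path).
#' @param species `"ref"` or one of the world's species names.
#' @param tasks optional character vector of task ids (default: all tasks of
#'   that species).
#' @param subsample optional seed-deterministic subsample of the training
#'   windows (passed to [make_examples()]).
#' @param seed seed for the subsampling draw.
#' @return an `s2t_dataset`.
#' @export
world_dataset <- function(w, species = "ref", tasks = NULL,
                          subsample = NULL, seed = 1L) {
  if (is.character(w)) w <- load_world(w)
  wc <- w$config
  ids <- names(w$tasks)[vapply(w$tasks, `[[`, "", "species") == species]
  if (!is.null(tasks)) {
    if (!all(tasks %in% ids)) stop_s2t("unknown task id(s) for species %s", species)
    ids <- tasks
  }
  genome <- setNames(w$genomes[[species]], w$chrom[[species]])
  tracks <- lapply(ids, function(id)
    read_coverage(file.path(w$dir, "tracks", sprintf("%s.bedGraph", id))))
  names(tracks) <- ids
  cfg <- toy_model_config(n_tracks = length(ids),
                          input_length = wc$input_length,
                          crop_length = wc$crop_length, bin_size = wc$bin_size)
  make_examples(genome, tracks, w$windows[[species]], cfg,
                subsample = subsample, seed = seed)
}

#' Reload a generated world from disk
#'
#' @param dir directory written by [generate_world()].
#' @return an `s2t_world` (sufficient for [world_dataset()] and the
#'   experiment drivers).
#' @export
load_world <- function(dir) {
  wc <- jsonlite::read_json(file.path(dir, "world.json"), simplifyVector = TRUE)
  wc$ref_windows <- unlist(wc$ref_windows)
  wc$species_windows <- unlist(wc$species_windows)
  wc$gc <- unlist(wc$gc)
  class(wc) <- "s2t_world_config"
  tasks <- jsonlite::read_json(file.path(dir, "tasks.json"), simplifyVector = FALSE)
  species_all <- c("ref", wc$species)
  genomes <- list(); chrom <- list(); windows <- list(); assignments <- list()
  for (sp in species_all) {
    fa <- read_fasta(file.path(dir, sprintf("%s.fa", sp)))
    genomes[[sp]] <- unname(fa[1]); chrom[[sp]] <- names(fa)[1]
    windows[[sp]] <- read.table(file.path(dir, sprintf("%s_windows.tsv", sp)),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  for (sp in wc$species) {
    f <- file.path(dir, sprintf("%s_split.tsv", sp))
    if (file.exists(f))
      assignments[[sp]] <- read.table(f, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
  }
  tasks <- lapply(tasks, function(t) { t$weights <- lapply(t$weights, as.numeric); t })
  structure(list(dir = dir, config = wc, genomes = genomes, chrom = chrom,
                 tasks = tasks, windows = windows, assignments = assignments),
            class = "s2t_world")
}
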