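# Homology-aware splitting: nonhuman windows are assigned to train /
# validation / test by how many of their bases map (via PSL alignments)
# into the reference training versus validation sets, and residual homology
# to the reference training set is quantified for leakage-binned evaluation.
# All coordinates are 0-based half-open, as in the PSL and BED formats.

PSL_COLS <- c("matches", "misMatches", "repMatches", "nCount",
              "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
              "strand", "qName", "qSize", "qStart", "qEnd",
              "tName", "tSize", "tStart", "tEnd",
              "blockCount", "blockSizes", "qStarts", "tStarts")

#' Parse a PSL alignment file
#'
#' Reads the 21-column tab-separated PSL format (as emitted by BLAT/pslMap),
#' with or without the textual psLayout header. Only forward-strand ("+")
#' alignments are supported, which is what the bundled synthetic mapper
#' emits. Malformed lines are rejected with their line number.
#'
#' @param path PSL file.
#' @return a data.frame with one row per alignment: the standard summary
#'   columns plus list-columns `block_sizes`, `q_starts`, `t_starts`
#'   (integer vectors per alignment).
#' @export
parse_psl <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(psLayout|match\\t|\\s*match\\s|-{5,}|\\s*$)", lines)
  # the canonical header also contains an unindented continuation line
  keep <- keep & !grepl("^\\s+(match|Q\\s)", lines)
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(qName = character(), stringsAsFactors = FALSE))
  rows <- vector("list", length(idx))
  for (r in seq_along(idx)) {
    ln <- idx[r]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L)
      stop_s2t("PSL parse error at line %d: expected 21 tab-separated columns, found %d",
               ln, length(f))
    numi <- c(1:8, 11:13, 15:18)
    vals <- suppressWarnings(as.numeric(f[numi]))
    if (anyNA(vals) || any(vals < 0))
      stop_s2t("PSL parse error at line %d: non-numeric or negative coordinate field",
               ln)
    if (!f[9] %in% c("+", "-"))
      stop_s2t("PSL parse error at line %d: bad strand '%s'", ln, f[9])
    if (f[9] == "-")
      stop_s2t("PSL line %d: negative-strand alignments are not supported", ln)
    qs <- as.integer(f[12]); qe <- as.integer(f[13])
    ts <- as.integer(f[16]); te <- as.integer(f[17])
    if (qs >= qe || ts >= te)
      stop_s2t("PSL parse error at line %d: start must be < end", ln)
    bs <- as.integer(strsplit(f[19], ",")[[1]])
    qb <- as.integer(strsplit(f[20], ",")[[1]])
    tb <- as.integer(strsplit(f[21], ",")[[1]])
    if (length(bs) != as.integer(f[18]) || length(qb) != length(bs) ||
        length(tb) != length(bs))
      stop_s2t("PSL parse error at line %d: block lists disagree with blockCount", ln)
    rows[[r]] <- list(matches = as.integer(f[1]), strand = f[9],
                      qName = f[10], qSize = as.integer(f[11]),
                      qStart = qs, qEnd = qe,
                      tName = f[14], tSize = as.integer(f[15]),
                      tStart = ts, tEnd = te,
                      block_sizes = bs, q_starts = qb, t_starts = tb)
  }
  df <- data.frame(
    matches = vapply(rows, `[[`, integer(1), "matches"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    qName = vapply(rows, `[[`, character(1), "qName"),
    qSize = vapply(rows, `[[`, integer(1), "qSize"),
    qStart = vapply(rows, `[[`, integer(1), "qStart"),
    qEnd = vapply(rows, `[[`, integer(1), "qEnd"),
    tName = vapply(rows, `[[`, character(1), "tName"),
    tSize = vapply(rows, `[[`, integer(1), "tSize"),
    tStart = vapply(rows, `[[`, integer(1), "tStart"),
    tEnd = vapply(rows, `[[`, integer(1), "tEnd"),
    stringsAsFactors = FALSE
  )
  df$block_sizes <- lapply(rows, `[[`, "block_sizes")
  df$q_starts <- lapply(rows, `[[`, "q_starts")
  df$t_starts <- lapply(rows, `[[`, "t_starts")
  df
}

#' Write alignments as PSL
#'
#' @param psl a data.frame in the layout returned by [parse_psl()].
#' @param path output file.
#' @param header write the psLayout header lines.
#' @return `path`, invisibly.
#' @export
write_psl <- function(psl, path, header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(c("psLayout version 3", "",
                 paste("match\tmis- \trep. \tN's\tQ gap\tQ gap\tT gap\tT gap",
                       "\tstrand\tQ        \tQ   \tQ    \tQ  \tT        \tT   ",
                       "\tT    \tT  \tblock\tblockSizes \tqStarts\t tStarts", sep = ""),
                 paste(rep("-", 100), collapse = "")), con)
  }
  for (i in seq_len(nrow(psl))) {
    r <- psl[i, ]
    bs <- r$block_sizes[[1]]; qs <- r$q_starts[[1]]; ts <- r$t_starts[[1]]
    writeLines(paste(
      r$matches, 0, 0, 0, 0, 0, 0, 0, r$strand,
      r$qName, r$qSize, r$qStart, r$qEnd,
      r$tName, r$tSize, r$tStart, r$tEnd,
      length(bs),
      paste0(paste(bs, collapse = ","), ","),
      paste0(paste(qs, collapse = ","), ","),
      paste0(paste(ts, collapse = ","), ","),
      sep = "\t"), con)
  }
  invisible(path)
}

# block-level mapping table: one row per aligned block
psl_blocks <- function(psl) {
  if (!nrow(psl)) return(data.frame(qName = character(), qStart = integer(),
                                    qEnd = integer(), tName = character(),
                                    tStart = integer(), tEnd = integer()))
  out <- lapply(seq_len(nrow(psl)), function(i) {
    bs <- psl$block_sizes[[i]]
    data.frame(qName = psl$qName[i],
               qStart = psl$q_starts[[i]], qEnd = psl$q_starts[[i]] + bs,
               tName = psl$tName[i],
               tStart = psl$t_starts[[i]], tEnd = psl$t_starts[[i]] + bs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# reference interval set as a per-chromosome reduced IRangesList
as_reference_set <- function(ref) {
  if (methods::is(ref, "GRanges")) {
    spl <- split(IRanges::ranges(ref), as.character(GenomicRanges::seqnames(ref)))
    return(lapply(as.list(spl), IRanges::reduce))
  }
  stopifnot(is.data.frame(ref))
  lapply(split(ref, ref$chrom), function(d)
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end)))
}

#' Window bases mapping into a reference interval set
#'
#' Counts the number of bases of `window` whose mapped position (through the
#' aligned blocks of `mappings`) falls inside `reference_set`, counting each
#' window base once even if several alignments cover it (union semantics).
#'
#' @param window list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open, in query/nonreference coordinates).
#' @param mappings alignments from [parse_psl()] (query = the window's
#'   genome, target = the reference genome).
#' @param reference_set reference intervals: a data.frame with
#'   `chrom`/`start`/`end` (0-based half-open) or a `GRanges`.
#' @return integer number of bases.
#' @export
overlap_bp <- function(window, mappings, reference_set) {
  refs <- as_reference_set(reference_set)
  bl <- psl_blocks(mappings)
  bl <- bl[bl$qName == window$chrom &
           bl$qEnd > window$start & bl$qStart < window$end, , drop = FALSE]
  if (!nrow(bl)) return(0L)
  covered <- IRanges::IRanges()
  for (i in seq_len(nrow(bl))) {
    ref <- refs[[bl$tName[i]]]
    if (is.null(ref)) next
    qs <- max(bl$qStart[i], window$start)
    qe <- min(bl$qEnd[i], window$end)
    if (qs >= qe) next
    shift <- bl$tStart[i] - bl$qStart[i]
    timg <- IRanges::IRanges(start = qs + shift + 1L, end = qe + shift)
    hit <- IRanges::intersect(timg, ref)
    if (length(hit))
      covered <- c(covered, IRanges::shift(hit, -shift))
  }
  sum(IRanges::width(IRanges::reduce(covered)))
}

#' Split policy for homology-based assignment
#'
#' @param tie where equal nonzero train/validation overlaps go
#'   (default `"validation"`, conservative against leakage into train).
#' @param zero_ratios how windows with no mapped overlap at all are split,
#'   as a named train/validation/test probability vector.
#' @param seed seed for the zero-overlap assignment (combined with the
#'   window id, so the label is independent of call order).
#' @return a policy list.
#' @export
split_policy <- function(tie = c("validation", "train"),
                         zero_ratios = c(train = 0.8, validation = 0.1, test = 0.1),
                         seed = 1L) {
  tie <- match.arg(tie)
  if (abs(sum(zero_ratios) - 1) > 1e-8)
    stop_s2t("zero_ratios must sum to 1")
  list(tie = tie, zero_ratios = zero_ratios, seed = as.integer(seed))
}

#' Assign one window to train/validation/test by mapped overlap
#'
#' The rule: a region with more mapped overlap with the reference training
#' set than with the reference validation set is assigned to train, and vice
#' versa. Equal nonzero overlaps follow the policy tie rule; windows with no
#' overlap at all are assigned by a seeded draw from the policy ratios.
#'
#' @param window list/one-row data.frame with `chrom`, `start`, `end`, and
#'   optionally `id`.
#' @param mappings alignments from [parse_psl()].
#' @param train_set,validation_set reference interval sets (see
#'   [overlap_bp()]).
#' @param policy a [split_policy()].
#' @return a one-row data.frame: `id`, `label`, `overlap_train`,
#'   `overlap_validation`, `homology_proportion`.
#' @export
assign_region <- function(window, mappings, train_set, validation_set,
                          policy = split_policy()) {
  ot <- overlap_bp(window, mappings, train_set)
  ov <- overlap_bp(window, mappings, validation_set)
  wlen <- window$end - window$start
  id <- window$id %||% sprintf("%s:%d-%d", window$chrom, window$start, window$end)
  label <- if (ot > ov) "train"
    else if (ov > ot) "validation"
    else if (ot > 0L) policy$tie
    else {
      set.seed(derive_seed(policy$seed, "zero-overlap", id))
      sample(names(policy$zero_ratios), 1L, prob = policy$zero_ratios)
    }
  data.frame(id = id, label = label,
             overlap_train = ot, overlap_validation = ov,
             homology_proportion = ot / wlen,
             stringsAsFactors = FALSE)
}

#' Assign many windows at once
#'
#' @param windows data.frame with `chrom`, `start`, `end`, `id`.
#' @param mappings,train_set,validation_set,policy see [assign_region()].
#' @return a data.frame of per-window assignments.
#' @export
assign_regions <- function(windows, mappings, train_set, validation_set,
                           policy = split_policy()) {
  out <- lapply(seq_len(nrow(windows)), function(i)
    assign_region(windows[i, ], mappings, train_set, validation_set, policy))
  do.call(rbind, out)
}

#' Group test windows into homology bins
#'
#' @param assignments data.frame from [assign_regions()] (only rows with
#'   `label == "test"` are binned unless `label_filter` says otherwise).
#' @param bin_edges strictly increasing numeric edges spanning `[0, 1]`;
#'   bins are left-closed, with the last bin closed on both sides.
#' @param label_filter which labels to bin (default `"test"`).
#' @return a list with `bins` (list of window-id character vectors) and
#'   `counts` (integer vector, one per bin).
#' @export
homology_bins <- function(assignments, bin_edges = c(0, 0.1, 0.5, 1),
                          label_filter = "test") {
  if (any(diff(bin_edges) <= 0))
    stop_s2t("bin_edges must be strictly increasing")
  if (bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 1)
    stop_s2t("bin_edges must span [0, 1]")
  a <- assignments[assignments$label %in% label_filter, , drop = FALSE]
  cutf <- cut(a$homology_proportion, breaks = bin_edges,
              right = FALSE, include.lowest = TRUE)
  # make the last bin closed at 1
  cutf[a$homology_proportion == 1] <- levels(cutf)[length(levels(cutf))]
  bins <- split(a$id, cutf)
  list(bins = bins, counts = vapply(bins, length, integer(1)))
}

#' Write split assignments as TSV
#'
#' @param assignments data.frame from [assign_regions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
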