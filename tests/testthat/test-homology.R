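# PSL parsing, mapped-overlap computation (against a per-base brute-force
# oracle), the majority-overlap assignment rule, and homology binning.

psl_line <- function(qName, qStart, qEnd, tName, tStart, tEnd,
                     blocks = NULL) {
  if (is.null(blocks))
    blocks <- list(sizes = qEnd - qStart, q = qStart, t = tStart)
  paste(qEnd - qStart, 0, 0, 0, 0, 0, 0, 0, "+",
        qName, 100000, qStart, qEnd, tName, 100000, tStart, tEnd,
        length(blocks$sizes),
        paste0(paste(blocks$sizes, collapse = ","), ","),
        paste0(paste(blocks$q, collapse = ","), ","),
        paste0(paste(blocks$t, collapse = ","), ","),
        sep = "\t")
}

test_that("parse_psl reads plain and headered files", {
  f <- tempfile(fileext = ".psl")
  writeLines(c(psl_line("q1", 0, 300, "hg", 1000, 1300),
               psl_line("q1", 500, 600, "hg", 5000, 5100),
               psl_line("q2", 10, 40, "hg", 0, 30)), f)
  psl <- parse_psl(f)
  expect_equal(nrow(psl), 3L)
  expect_equal(psl$qStart, c(0L, 500L, 10L))
  fh <- tempfile(fileext = ".psl")
  writeLines(c("psLayout version 3", "",
               "match\tmis-\trep.\tN's", paste(rep("-", 80), collapse = ""),
               psl_line("q1", 0, 300, "hg", 1000, 1300)), fh)
  expect_equal(nrow(parse_psl(fh)), 1L)
})

test_that("parse_psl round-trips through write_psl", {
  f <- tempfile(fileext = ".psl")
  writeLines(c(psl_line("q1", 0, 300, "hg", 1000, 1300),
               psl_line("q2", 10, 40, "hg", 0, 30)), f)
  psl <- parse_psl(f)
  f2 <- tempfile(fileext = ".psl")
  write_psl(psl, f2)
  psl2 <- parse_psl(f2)
  expect_equal(psl2$qStart, psl$qStart)
  expect_equal(psl2$tEnd, psl$tEnd)
  expect_identical(psl2$block_sizes, psl$block_sizes)
})

test_that("malformed PSL lines are rejected with their line number", {
  f <- tempfile(fileext = ".psl")
  writeLines(c(psl_line("q1", 0, 300, "hg", 1000, 1300),
               "only\tthree\tcolumns"), f)
  expect_error(parse_psl(f), "line 2.*21")
  f2 <- tempfile(fileext = ".psl")
  writeLines(psl_line("q1", -5, 300, "hg", 1000, 1305), f2)
  expect_error(parse_psl(f2), "negative")
  f3 <- tempfile(fileext = ".psl")
  ln <- strsplit(psl_line("q1", 0, 300, "hg", 1000, 1300), "\t")[[1]]
  ln[9] <- "-"
  writeLines(paste(ln, collapse = "\t"), f3)
  expect_error(parse_psl(f3), "negative-strand")
})

ref_df <- function(...) {
  d <- data.frame(...)
  names(d) <- c("chrom", "start", "end")
  d
}

test_that("overlap_bp counts mapped bases with union semantics", {
  f <- tempfile(fileext = ".psl")
  writeLines(psl_line("q1", 0, 300, "hg", 1000, 1300), f)
  psl <- parse_psl(f)
  train <- ref_df("hg", 1000, 2000)
  w <- list(chrom = "q1", start = 0L, end = 1000L)
  expect_equal(overlap_bp(w, psl, train), 300L)
  # two alignments covering the same 100 query bases count once
  f2 <- tempfile(fileext = ".psl")
  writeLines(c(psl_line("q1", 100, 200, "hg", 1000, 1100),
               psl_line("q1", 100, 200, "hg", 3000, 3100)), f2)
  psl2 <- parse_psl(f2)
  train2 <- ref_df("hg", 0, 5000)
  expect_equal(overlap_bp(w, psl2, train2), 100L)
  expect_equal(overlap_bp(w, psl2[0, ], train2), 0L)
  # partial intersection with the reference interval
  expect_equal(overlap_bp(w, psl, ref_df("hg", 1200, 2000)), 100L)
})

# brute-force oracle: walk every base of the window, map it through every
# block, and mark it covered if any image lands in the reference set
overlap_oracle <- function(window, psl, refs) {
  blocks <- seq2track:::psl_blocks(psl)
  covered <- rep(FALSE, window$end - window$start)
  for (p in seq(window$start, window$end - 1L)) {
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      if (b$qName != window$chrom || p < b$qStart || p >= b$qEnd) next
      tp <- b$tStart + (p - b$qStart)
      hit <- any(refs$chrom == b$tName & tp >= refs$start & tp < refs$end)
      if (hit) covered[p - window$start + 1L] <- TRUE
    }
  }
  sum(covered)
}

test_that("overlap_bp equals the per-base brute-force oracle on random instances", {
  # (the acceptance suite runs the full 200-instance version)
  set.seed(99)
  for (i in seq_len(60)) {
    n_map <- sample(0:4, 1)
    lines <- character(0)
    if (n_map > 0) {
      for (j in seq_len(n_map)) {
        qs <- sample(0:80, 1); len <- sample(5:40, 1)
        ts <- sample(0:150, 1)
        lines <- c(lines, psl_line("q1", qs, qs + len, "hg", ts, ts + len))
      }
    }
    f <- tempfile(fileext = ".psl")
    writeLines(lines, f)
    psl <- parse_psl(f)
    refs <- ref_df("hg", sort(sample(0:100, 2))[1], sort(sample(100:220, 2))[2])
    w <- list(chrom = "q1", start = sample(0:30, 1), end = sample(60:120, 1))
    expect_equal(overlap_bp(w, psl, refs), overlap_oracle(w, psl, refs))
  }
})

test_that("assign_region applies the majority-overlap rule", {
  f <- tempfile(fileext = ".psl")
  writeLines(c(psl_line("q1", 0, 300, "hg", 1000, 1300),    # into train
               psl_line("q1", 400, 500, "hg", 9000, 9100)), f) # into validation
  psl <- parse_psl(f)
  train <- ref_df("hg", 0, 5000)
  val <- ref_df("hg", 8000, 10000)
  w <- list(chrom = "q1", start = 0L, end = 1000L, id = "w1")
  a <- assign_region(w, psl, train, val)
  expect_equal(a$label, "train")
  expect_equal(a$overlap_train, 300L)
  expect_equal(a$overlap_validation, 100L)
  expect_equal(a$homology_proportion, 0.3)
  # vice versa: validation outweighs (or train overlap is zero)
  a2 <- assign_region(w, psl, ref_df("hg", 99000, 99500), val)
  expect_equal(a2$label, "validation")
  expect_equal(a2$overlap_train, 0L)
})

test_that("ties and zero-overlap windows follow the policy deterministically", {
  f <- tempfile(fileext = ".psl")
  writeLines(c(psl_line("q1", 0, 100, "hg", 1000, 1100),
               psl_line("q1", 200, 300, "hg", 9000, 9100)), f)
  psl <- parse_psl(f)
  train <- ref_df("hg", 0, 5000); val <- ref_df("hg", 8000, 10000)
  w <- list(chrom = "q1", start = 0L, end = 1000L, id = "w1")
  expect_equal(assign_region(w, psl, train, val)$label, "validation")  # tie
  expect_equal(assign_region(w, psl, train, val,
                             split_policy(tie = "train"))$label, "train")
  # no overlap at all: seeded ratio assignment, stable across calls and
  # under permutation of the mapping rows
  w0 <- list(chrom = "qZ", start = 0L, end = 1000L, id = "zero1")
  pol <- split_policy(seed = 7)
  l1 <- assign_region(w0, psl, train, val, pol)$label
  l2 <- assign_region(w0, psl[2:1, ], train, val, pol)$label
  expect_identical(l1, l2)
  labels <- vapply(sprintf("z%02d", 1:40), function(id)
    assign_region(list(chrom = "qZ", start = 0L, end = 1000L, id = id),
                  psl, train, val, pol)$label, "")
  expect_identical(labels,
                   vapply(sprintf("z%02d", 1:40), function(id)
                     assign_region(list(chrom = "qZ", start = 0L, end = 1000L,
                                        id = id), psl, train, val, pol)$label, ""))
  expect_true(all(c("train") %in% labels))  # dominant ratio class present
})

test_that("homology bins partition test windows by proportion", {
  a <- data.frame(id = c("a", "b", "c"), label = "test",
                  overlap_train = 0L, overlap_validation = 0L,
                  homology_proportion = c(0.0, 0.05, 0.5))
  hb <- homology_bins(a, bin_edges = c(0, 0.1, 1.0))
  expect_equal(unname(hb$counts), c(2L, 1L))
  hb2 <- homology_bins(data.frame(id = letters[1:4], label = "test",
                                  homology_proportion = rep(0, 4)),
                       bin_edges = c(0, 0.5, 1))
  expect_equal(unname(hb2$counts), c(4L, 0L))
  hb3 <- homology_bins(a, bin_edges = c(0, 1))
  expect_equal(unname(hb3$counts), 3L)
  expect_error(homology_bins(a, bin_edges = c(0, 0.5, 0.4, 1)), "increasing")
  expect_error(homology_bins(a, bin_edges = c(0.2, 1)), "span")
})
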