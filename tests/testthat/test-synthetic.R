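# Generator statistics, world construction, cross-species structure and the
# leakage audit.

test_that("motif sampling is deterministic with row-stochastic PWMs", {
  m1 <- sample_motifs(5, 8, seed = 3)
  m2 <- sample_motifs(5, 8, seed = 3)
  expect_identical(m1, m2)
  for (p in m1) expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-12)
  single <- sample_motifs(1, 4, seed = 1)
  expect_length(single, 1L)
  expect_equal(dim(single[[1]]), c(4L, 4L))
})

test_that("background GC content matches the requested composition", {
  g <- sample_genome(1e5, gc = 0.5, motifs = list(), seed = 2)
  x <- one_hot_encode(g$sequence)
  gc_obs <- mean(x[, "C"] + x[, "G"])
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(gc_obs - 0.5), 3 * se)
  expect_equal(nrow(g$occurrences), 0L)
})

test_that("genomes are seed-deterministic and planted instances match PWMs", {
  motifs <- sample_motifs(3, 8, seed = 1, concentration = 0.1)
  g1 <- sample_genome(2e4, 0.45, motifs, occ_rate_per_kb = 8, seed = 5)
  g2 <- sample_genome(2e4, 0.45, motifs, occ_rate_per_kb = 8, seed = 5)
  expect_identical(g1, g2)
  expect_gt(nrow(g1$occurrences), 50)
  # instances carry far more PWM log-likelihood than background positions
  llr <- function(pwm, s) {
    x <- one_hot_encode(s)
    sum(log(pmax(rowSums(x * pwm), 1e-9))) - nrow(pwm) * log(0.25)
  }
  at_occ <- vapply(seq_len(min(50, nrow(g1$occurrences))), function(i) {
    o <- g1$occurrences[i, ]
    llr(motifs[[o$motif]], substr(g1$sequence, o$start + 1, o$start + 8))
  }, numeric(1))
  set.seed(1)
  at_bg <- vapply(sample(2e4 - 8, 50), function(p)
    llr(motifs[[1]], substr(g1$sequence, p + 1, p + 8)), numeric(1))
  expect_gt(mean(at_occ), mean(at_bg) + 5)
})

test_that("task rates respond to occurrences as the kernel model dictates", {
  task <- list(weights = c(motif01 = 2), baseline = 1.5, bandwidth = 100,
               motif_length = 8)
  none <- task_rates(data.frame(start = integer(), motif = character()),
                     task, 10, 128)
  expect_equal(none, rep(softplus(log(1.5)), 10))
  one <- task_rates(data.frame(start = 500, motif = "motif01"), task, 10, 128)
  expect_equal(which.max(one), 4L)  # occurrence centre 504 sits in bin 4
  expect_true(all(one >= none - 1e-12))
  flat <- task_rates(data.frame(start = 500, motif = "motif01"),
                     list(weights = c(motif01 = 0), baseline = 1.5,
                          bandwidth = 100, motif_length = 8), 10, 128)
  expect_equal(flat, none)
  # unknown motifs carry zero weight
  other <- task_rates(data.frame(start = 500, motif = "motifXX"), task, 10, 128)
  expect_equal(other, none)
})

test_that("sampled counts match their rates in distribution", {
  lam <- rep(4, 1e4)
  cts <- sample_counts(lam, seed = 9)
  expect_identical(cts, sample_counts(lam, seed = 9))
  expect_lt(abs(mean(cts) - 4), 3 * sqrt(4 / 1e4))
  expect_true(all(sample_counts(rep(1e-8, 100), seed = 1) == 0))
  expect_error(sample_counts(c(1, 0), 1), "> 0")
  # goodness of fit aggregated over 20 seeds: total Pearson X2 statistic
  # against its chi-square reference at alpha = 0.01
  set.seed(42)
  lam_grid <- runif(200, 0.5, 8)
  x2 <- 0
  for (sd in 1:20) {
    cts <- sample_counts(lam_grid, seed = sd)
    x2 <- x2 + sum((cts - lam_grid)^2 / lam_grid)
  }
  dof <- 20 * length(lam_grid)
  expect_gt(x2, qchisq(0.005, dof))
  expect_lt(x2, qchisq(0.995, dof))
})

test_that("the generated world has the advertised cross-species structure", {
  w <- get_test_world()
  wc <- w$config
  expect_setequal(names(w$genomes), c("ref", wc$species))
  # shared fraction of the reference vocabulary plus species-specific motifs
  shared <- intersect(w$motif_sets$ref, w$motif_sets$speciesA)
  expect_equal(length(shared), round(wc$sharing_fraction * wc$n_motifs))
  expect_equal(length(w$motif_sets$speciesA), wc$n_motifs)
  # every task's weighted motifs belong to its species' vocabulary
  for (tk in w$tasks) {
    expect_true(all(names(tk$weights) %in% w$motif_sets[[tk$species]]))
  }
  expect_equal(sum(vapply(w$tasks, `[[`, "", "species") == "ref"),
               wc$n_pretrain_tasks)
})

test_that("sharing fraction 1 and 0 bound the motif overlap", {
  w1 <- generate_world(world_config("tiny", seed = 2, sharing_fraction = 1,
                                    ref_windows = c(train = 4L, validation = 2L,
                                                    test = 2L),
                                    species_windows = c(train = 2L,
                                                        validation = 2L,
                                                        test = 2L),
                                    n_pretrain_tasks = 2L),
                       file.path(tempdir(), "w_share1"))
  expect_setequal(w1$motif_sets$speciesA, w1$motif_sets$ref)
  w0 <- generate_world(world_config("tiny", seed = 2, sharing_fraction = 0,
                                    ref_windows = c(train = 4L, validation = 2L,
                                                    test = 2L),
                                    species_windows = c(train = 2L,
                                                        validation = 2L,
                                                        test = 2L),
                                    n_pretrain_tasks = 2L),
                       file.path(tempdir(), "w_share0"))
  expect_length(intersect(w0$motif_sets$speciesA, w0$motif_sets$ref), 0L)
})

test_that("world files parse back through the standard readers", {
  w <- get_test_world()
  psl <- parse_psl(file.path(w$dir, "speciesA.psl"))
  expect_equal(nrow(psl), nrow(w$psl$speciesA))
  fa <- read_fasta(file.path(w$dir, "ref.fa"))
  expect_identical(unname(fa[1]), w$genomes$ref)
  w2 <- load_world(w$dir)
  expect_equal(w2$windows$ref$id, w$windows$ref$id)
  expect_identical(names(w2$tasks), names(w$tasks))
})

test_that("split labels partition windows and leakage stays below the ceiling", {
  w <- get_test_world()
  for (sp in c("ref", w$config$species)) {
    expect_true(all(w$windows[[sp]]$split %in%
                      c("train", "validation", "test")))
    expect_false(any(duplicated(w$windows[[sp]]$id)))
  }
  asg <- w$assignments$speciesA
  held <- asg[asg$label != "train", ]
  expect_gt(nrow(held), 0)
  # mean residual homology of held-out windows against the reference
  # training set stays small
  expect_lte(mean(held$homology_proportion), 0.2)
})

test_that("dataset labels reproduce the generator's counts exactly", {
  w <- get_test_world()
  wc <- w$config
  d <- world_dataset(w, "ref", tasks = names(w$tasks)[1])
  ex <- d$examples[[3]]
  off <- (wc$input_length - wc$crop_length) / 2
  b0 <- (ex$window$start + off) / wc$bin_size
  nb <- wc$crop_length / wc$bin_size
  expect_equal(unname(ex$y[, 1]),
               w$counts[[names(w$tasks)[1]]][(b0 + 1):(b0 + nb)],
               tolerance = 1e-9)
})

test_that("true rates explain the sampled counts well above noise", {
  # identifiability ceiling of the benchmark: the generating rates account
  # for the counts at a usefully high correlation, so models have signal
  # worth recovering (learnability of that signal end-to-end is exercised
  # by the transfer experiment in the acceptance suite)
  w <- get_test_world()
  wc <- w$config
  nbg <- nchar(w$genomes$ref) %/% wc$bin_size
  ids <- names(w$tasks)[vapply(w$tasks, `[[`, "", "species") == "ref"][1:6]
  rs <- vapply(ids, function(id) {
    tk <- w$tasks[[id]]
    lam <- task_rates(w$occurrences$ref,
                      list(weights = unlist(tk$weights), baseline = tk$baseline,
                           bandwidth = tk$bandwidth,
                           motif_length = tk$motif_length),
                      nbg, wc$bin_size)
    pearson(lam, w$counts[[id]])
  }, numeric(1))
  expect_gte(stats::median(rs), 0.5)
})
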