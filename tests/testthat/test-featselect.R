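test_that("sliding windows count L - w + 1 and match a loop oracle", {
  set.seed(32)
  L <- 40
  S <- rnorm(L)
  seq <- random_seq(L)
  ws <- window_scores(S, seq, w = 5, record_id = "r")
  expect_equal(nrow(ws), L - 5 + 1)
  manual <- vapply(0:(L - 5), function(st) mean(S[(st + 1):(st + 5)]), 1)
  expect_equal(ws$mean_score, manual)
  expect_equal(ws$subsequence,
               vapply(0:(L - 5), function(st) substr(seq, st + 1, st + 5), ""))

  one <- window_scores(rep(1, 10), random_seq(10), w = 10)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mean_score, 1)

  allones <- window_scores(rep(1, 30), random_seq(30), w = 20)
  expect_true(all(allones$mean_score == 1))
  expect_equal(nrow(allones), 11L)

  expect_error(window_scores(S, seq, w = 41), "exceeds")
})

test_that("centered peak scores average w + 1 values and flag truncation", {
  S <- rep(3, 20)
  for (i in c(4, 10, 15)) {
    expect_equal(as.numeric(centered_peak_score(S, i, 8)), 3)
  }
  imp <- rep(0, 21)
  imp[11] <- 1  # impulse at 0-based index 10
  expect_equal(as.numeric(centered_peak_score(imp, 10, 8)), 1 / 9)
  expect_false(attr(centered_peak_score(imp, 10, 8), "truncated"))
  expect_true(attr(centered_peak_score(imp, 1, 8), "truncated"))

  set.seed(33)
  S <- rnorm(50)
  track <- centered_peak_track(S, 6)
  expect_equal(nrow(track), 50L)
  manual <- vapply(0:49, function(i) {
    lo <- max(0, i - 3)
    hi <- min(49, i + 3)
    mean(S[(lo + 1):(hi + 1)])
  }, 1)
  expect_equal(track$score, manual)
  expect_equal(track$truncated, c(rep(TRUE, 3), rep(FALSE, 44), rep(TRUE, 3)))
})

test_that("top peaks respect non-maximum suppression", {
  S <- rep(0, 60)
  S[c(11, 31, 51)] <- c(5, 9, 7)  # 0-based 10, 30, 50
  pk <- top_peak_windows(S, w = 4, n = 3, min_sep = 10)
  # highest peak window covers the strongest impulse (ties over the w/2
  # plateau break toward the lower index)
  expect_lte(abs(pk$center[1] - 30), 2)
  expect_true(all(abs(outer(pk$center, pk$center, "-"))[lower.tri(matrix(0, 3, 3))] >= 10))
})

test_that("subsequence selection matches a brute-force sort oracle", {
  set.seed(34)
  windows <- NULL
  for (r in c("r1", "r2", "r3")) {
    S <- rnorm(30)
    windows <- rbind(windows, window_scores(S, random_seq(30), 5, r))
  }
  sel <- select_subsequences(windows, "global", n = 10)
  oracle <- windows[windows$mean_score > 0, ]
  oracle <- oracle[order(-oracle$mean_score, oracle$record_id, oracle$start), ]
  expect_equal(sel$mean_score, utils::head(oracle, 10)$mean_score)
  expect_equal(sel$start, utils::head(oracle, 10)$start)
  expect_true(all(sel$mean_score > 0))

  # per-site keeps top n within each record
  ps <- select_subsequences(windows, "per_site", n = 2)
  expect_equal(unname(table(ps$record_id)[c("r1", "r2", "r3")]),
               rep(2L, 3), ignore_attr = TRUE)

  # input order invariance
  shuffled <- windows[sample(nrow(windows)), ]
  sel2 <- select_subsequences(shuffled, "global", n = 10)
  expect_equal(sel, sel2)

  # two records, global n = 1 -> the higher mean wins
  two <- data.frame(record_id = c("a", "b"), start = c(0L, 0L), w = 3L,
                    mean_score = c(5, 3), subsequence = c("AAA", "CCC"))
  expect_equal(select_subsequences(two, "global", 1)$record_id, "a")

  # all means negative -> empty with warning
  neg <- data.frame(record_id = "a", start = 0:2, w = 3L,
                    mean_score = c(-1, -2, -0.5),
                    subsequence = c("AAA", "CCC", "GGG"))
  expect_warning(out <- select_subsequences(neg, "global", 5), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("export writes FASTA and BED with correct offset arithmetic", {
  genome <- toy_genome()
  win_start <- 5000 - 5000  # record window begins at chrA:1000 below
  seq <- as.character(Biostrings::subseq(genome[["chrA"]], 1001, 1100))
  S <- rep(0, 100)
  S[11:30] <- 1  # favour the window starting at array index 10
  ws <- window_scores(S, seq, w = 20, record_id = "g1:orig",
                      chrom = "chrA", win_start = 1000)
  sel <- select_subsequences(ws, "global", n = 5)
  expect_equal(sel$gstart[1], 1000 + sel$start[1])
  expect_equal(sel$gend[1] - sel$gstart[1], 20)
  expect_equal(sel$start[1], 10)

  dir <- tempfile()
  paths <- export_for_motif_search(sel, dir)
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_length(fa, nrow(sel))
  bed <- read.delim(paths[["bed"]], header = FALSE)
  expect_equal(nrow(bed), nrow(sel))
  # round-trip: BED intervals re-extracted from the genome match the FASTA
  for (i in seq_len(nrow(bed))) {
    ext <- as.character(Biostrings::subseq(genome[[bed$V1[i]]],
                                           bed$V2[i] + 1, bed$V3[i]))
    expect_equal(ext, as.character(fa[[i]]))
  }
  expect_true(file.exists(paths[["script"]]))
  expect_match(readLines(paths[["script"]])[3], "-size 200")

  # no provenance -> FASTA only, with a warning
  sel2 <- sel[, setdiff(names(sel), c("chrom", "gstart", "gend"))]
  expect_warning(p2 <- export_for_motif_search(sel2, tempfile()),
                 "provenance")
  expect_named(p2, "fasta")
})

test_that("PWMs are column-stochastic with argmax consensus", {
  slices <- rep("TTCCTGGGAATT", 5)
  pwm <- pwm_from_peaks(slices, peak_centers = rep(5, 5), flank = 5)
  expect_equal(dim(pwm$values), c(4L, 11L))
  expect_true(all(colSums(pwm$values) == 1))
  expect_true(all(pwm$values %in% c(0, 1)))
  expect_match(pwm$consensus, "CCTGGGAA")

  two <- pwm_from_peaks(c("AAAA", "CCCC"), c(1, 1), flank = 1)
  expect_equal(unname(two$values[, 1]), c(0.5, 0.5, 0, 0))

  # peaks too close to the edge are skipped
  expect_warning(pwm_from_peaks(c("ACGTACGT", "ACGTACGT"), c(0, 4), 2),
                 "skipped")
  expect_error(suppressWarnings(pwm_from_peaks("ACGT", 0, 2)), "no usable")

  set.seed(35)
  sub <- vapply(1:7, function(i) random_seq(21), "")
  p <- pwm_from_peaks(sub, rep(10, 7), flank = 10)
  expect_equal(unname(colSums(p$values)), rep(1, 21), tolerance = 1e-9)
})

test_that("motif distances are signed offsets from the window midpoint", {
  expect_equal(motif_distances(5000, 10000)$distance, 0)
  expect_equal(motif_distances(0, 10000)$distance, -5000)
  set.seed(36)
  centers <- sample(0:9999, 50)
  d <- motif_distances(centers, 10000)$distance
  expect_true(all(d >= -5000 & d <= 5000))
})

test_that("smoothed densities integrate to one and behave under bandwidth", {
  set.seed(37)
  d <- smooth_density(rnorm(200, sd = 50), bandwidth = 20)
  area <- sum(diff(d$x) * (utils::head(d$density, -1) +
                             utils::tail(d$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)

  single <- smooth_density(42, bandwidth = 5)
  expect_equal(single$x[which.max(single$density)], 42, tolerance = 1)

  sym <- c(-10, -5, 0, 5, 10)
  ds <- smooth_density(sym, bandwidth = 3)
  expect_lt(abs(max(ds$density) - ds$density[which.min(abs(ds$x + ds$x[which.max(ds$density)]))]),
            1e-6)

  wide <- smooth_density(sym, bandwidth = 12)
  expect_lt(max(wide$density), max(ds$density))

  expect_error(smooth_density(numeric(0), 1), "empty")
})

test_that("percentile ranks reproduce the printed pairs", {
  expect_equal(percentile_rank(2, 264), 99.2)
  expect_equal(percentile_rank(4, 264), 98.5)
  expect_equal(percentile_rank(7, 264), 97.3)
  expect_equal(percentile_rank(264, 264), 0)
  expect_error(percentile_rank(265, 264), "rank")
})

test_that("motif result tables parse, rank and answer substring queries", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("Motif Name\tConsensus\tP-value\tLog P-value",
               "CTCF(Zf)\tNNCCASYAGRKGGCRS\t1e-30\t-69.1",
               "RBPJ(?)/RBPJ-ChIP\tCCTGGGAA\t1e-10\t-23.0",
               "GATA3(Zf)\tAGATAASR\t1e-20\t-46.1"), path)
  res <- parse_motif_results(path)
  expect_equal(res$motif[1], "CTCF(Zf)")
  expect_equal(res$rank, 1:3)
  expect_equal(res$p_value, sort(res$p_value))
  rb <- motif_rank(res, "RBPJ")
  expect_equal(rb$rank, 3L)
  expect_equal(rb$percentile, percentile_rank(3, 3))
  expect_error(motif_rank(res, "NOSUCH"), "no motif")

  # ties keep input order
  tie <- tempfile()
  writeLines(c("Motif Name\tP-value", "first\t0.5", "second\t0.5",
               "best\t0.1"), tie)
  res2 <- parse_motif_results(tie)
  expect_equal(res2$motif, c("best", "first", "second"))

  nop <- tempfile()
  writeLines(c("Motif Name\tScore", "x\t1"), nop)
  expect_error(parse_motif_results(nop), "p-value")
})
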