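test_that("read_sites computes midpoints and preserves order", {
  bed <- write_bed(data.frame(chrom = c("chr1", "chr2", "chr1"),
                              start = c(100, 10, 0),
                              end = c(200, 11, 9)))
  sites <- read_sites(bed, label = 1)
  expect_equal(nrow(sites), 3L)
  expect_equal(sites$center, c(150, 10, 4))
  expect_equal(sites$chrom, c("chr1", "chr2", "chr1"))
  expect_true(all(sites$label == 1L))
  expect_equal(anyDuplicated(sites$site_id), 0L)
})

test_that("read_sites rejects malformed and empty files", {
  bad <- tempfile()
  writeLines(c("chr1\t1\t10", "chr2\t5"), bad)
  expect_error(read_sites(bad, 0), "line 2")
  nonnum <- tempfile()
  writeLines("chr1\tx\t10", nonnum)
  expect_error(read_sites(nonnum, 0), "line 1")
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(read_sites(empty, 0), "empty")
})

test_that("extract_windows slices 0-based half-open and uppercases", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAACCCGGGTTT"))
  sites <- data.frame(chrom = "chr1", center = 6, label = 1L,
                      site_id = "s1")
  rec <- extract_windows(genome, sites, L = 4)
  # [center - L/2, center + L/2) = [4, 8) over AAACCCGGGTTT
  expect_equal(rec$sequence, "CCGG")
  expect_equal(rec$win_start, 4)

  lower <- Biostrings::DNAStringSet(c(chr1 = "acgtacgt"))
  rec2 <- extract_windows(lower,
                          data.frame(chrom = "chr1", center = 4,
                                     label = 0L, site_id = "s2"), L = 4)
  expect_equal(rec2$sequence, "GTAC")
})

test_that("out-of-bounds windows are skipped with a warning", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAACCCGGGTTT"))
  sites <- data.frame(chrom = rep("chr1", 2), center = c(1, 6),
                      label = 1L, site_id = c("edge", "ok"))
  expect_warning(rec <- extract_windows(genome, sites, L = 10),
                 "bounds")
  expect_equal(rec$origin_site, "ok")
})

test_that("one_hot_encode maps bases to channels and N to zero columns", {
  expect_equal(unname(one_hot_encode("ACGT")), diag(4))
  expect_equal(unname(one_hot_encode("NN")), matrix(0, 4, 2))
  m <- one_hot_encode("CCTGGGAA")
  expect_equal(unname(colSums(m)), rep(1, 8))
  expect_equal(unname(rowSums(m)), c(2, 2, 3, 1))  # A, C, G, T counts
  expect_error(one_hot_encode("ACXG"), "position 3")
})

test_that("one-hot encode/decode round-trips and tracks N columns", {
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 40, TRUE), collapse = "")
    m <- one_hot_encode(s)
    expect_identical(one_hot_decode(m), s)
    expect_equal(sum(colSums(m) == 0),
                 lengths(regmatches(s, gregexpr("N", s))))
    expect_true(all(colSums(m) %in% c(0, 1)))
  }
})

test_that("reverse_complement pairs bases, keeps N, and is an involution", {
  expect_equal(reverse_complement("CCTGGGAA"), "TTCCCAGG")
  expect_equal(reverse_complement("N"), "N")
  expect_error(reverse_complement("ACGU"), "position 4")
  set.seed(6)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 30, TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("encoding a reverse complement flips channels and positions", {
  set.seed(7)
  s <- random_seq(25)
  m <- one_hot_encode(s)
  mrc <- one_hot_encode(reverse_complement(s))
  expect_equal(unname(mrc), unname(m[4:1, ncol(m):1]))
})

test_that("augmentation yields six tagged variants agreeing on overlaps", {
  genome <- toy_genome()
  sites <- data.frame(chrom = "chrA", center = 1500, label = 1L,
                      site_id = "g1")
  spec <- augmentation_spec(seed = 42)
  rec <- augment_sites(genome, sites, L = 100, spec)
  expect_equal(nrow(rec), 6L)
  expect_setequal(rec$variant_tag,
                  c("orig", "shiftL", "shiftR", "rc", "rc_shiftL",
                    "rc_shiftR"))
  expect_true(all(rec$origin_site == "g1"))
  expect_true(all(nchar(rec$sequence) == 100))

  # same seed, same shift magnitudes
  rec2 <- augment_sites(genome, sites, L = 100, augmentation_spec(seed = 42))
  expect_identical(rec, rec2)

  # shifted forward windows overlap the original on L - k positions
  orig <- rec$sequence[rec$variant_tag == "orig"]
  shl <- rec$sequence[rec$variant_tag == "shiftL"]
  k <- -rec$offset[rec$variant_tag == "shiftL"]
  expect_gte(k, 1); expect_lte(k, 5)
  expect_equal(substr(shl, k + 1, 100), substr(orig, 1, 100 - k))
  # rc variants are the reverse complements of the forward ones
  expect_equal(rec$sequence[rec$variant_tag == "rc"],
               reverse_complement(orig))
})

test_that("splits partition sites without leakage and deterministically", {
  genome <- toy_genome()
  pos_sites <- data.frame(chrom = "chrA",
                          center = seq(300, 2700, length.out = 10),
                          label = 1L, site_id = paste0("g", 1:10))
  neg_sites <- data.frame(chrom = "chrB",
                          center = seq(300, 1700, length.out = 10),
                          label = 0L, site_id = paste0("c", 1:10))
  pos <- augment_sites(genome, pos_sites, 100, augmentation_spec(seed = 2))
  neg <- extract_windows(genome, neg_sites, 100)

  sp <- assemble_splits(pos, neg, c(train = 0.8, val = 0, test = 0.2),
                        seed = 3)
  expect_s3_class(sp, "dardn_splits")
  # 8 positive sites x 6 variants in train, 2 x 6 in test; no site straddles
  expect_equal(length(unique(sp$train$origin_site[sp$train$label == 1])), 8L)
  expect_equal(length(unique(sp$test$origin_site[sp$test$label == 1])), 2L)
  expect_length(intersect(sp$train$origin_site, sp$test$origin_site), 0L)
  all_ids <- sort(c(sp$train$record_id, sp$val$record_id, sp$test$record_id))
  expect_identical(all_ids, sort(c(pos$record_id, neg$record_id)))

  sp2 <- assemble_splits(pos, neg, c(train = 0.8, val = 0, test = 0.2),
                         seed = 3)
  expect_identical(sp$train$record_id, sp2$train$record_id)

  expect_error(assemble_splits(pos[0, ], neg,
                               c(train = 0.8, val = 0, test = 0.2), 1),
               "positive")
})

test_that("augmenting 72 sites yields 432 positive records", {
  # count contract only: 6 variants per gained site
  genome <- Biostrings::DNAStringSet(c(chrZ = random_seq(9000, seed = 8)))
  sites <- data.frame(chrom = "chrZ",
                      center = round(seq(200, 8800, length.out = 72)),
                      label = 1L, site_id = sprintf("s%02d", 1:72))
  rec <- augment_sites(genome, sites, L = 50, augmentation_spec(seed = 1))
  expect_equal(nrow(rec), 72L * 6L)
})
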