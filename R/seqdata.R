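#' Read a BED-like site list
#'
#' Reads a tab-separated, BED-style file (0-based half-open intervals, at
#' least three columns: chrom, start, end) of CTCF site intervals and
#' returns one row per site with its center position and class label.
#'
#' @param path Path to a BED3+ file.
#' @param label Class label applied to every site: 1 for cancer-specific
#'   ("gained") sites, 0 for constitutive sites.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `center`
#'   (0-based, `floor((start + end) / 2)`), `label` and `site_id` (fourth
#'   BED column when present, otherwise `chrom:start-end`; made unique).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr2\t10\t11"), bed)
#' read_sites(bed, label = 1)
#' @export
read_sites <- function(path, label) {
  stopifnot(length(label) == 1, label %in% c(0, 1))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty site file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop(sprintf("malformed line %d in %s: fewer than 3 tab-separated fields",
                 which(nf < 3L)[1], path))
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end < start)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: invalid start/end coordinates",
                 bad[1], path))
  }
  site_id <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) >= 4L && nzchar(p[4L])) p[4L]
    else sprintf("%s:%d-%d", chrom[i], as.integer(start[i]), as.integer(end[i]))
  }, "")
  data.frame(chrom = chrom, start = start, end = end,
             center = floor((start + end) / 2), label = as.integer(label),
             site_id = make.unique(site_id), stringsAsFactors = FALSE)
}

#' @keywords internal
load_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("`genome` must be a DNAStringSet or path to a FASTA file")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract fixed-length windows centered on sites
#'
#' Cuts an `L`-bp window `[center - L/2, center + L/2)` (0-based half-open)
#' around each site center out of the genome.  Windows that exceed
#' chromosome bounds, reference unknown chromosomes, or contain more than
#' `max_n_fraction` ambiguous bases are excluded with a warning.
#'
#' @param genome A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param sites A site table from [read_sites()] (or any `data.frame` with
#'   `chrom`, `center`, `label`, `site_id` columns).
#' @param L Window length in bp (even).
#' @param max_n_fraction Maximum tolerated fraction of `N` bases.
#' @return A `data.frame` of sequence records with columns `record_id`,
#'   `origin_site`, `chrom`, `win_start` (0-based genomic start of the
#'   window), `sequence` (uppercase), `label`, `variant_tag` (`"orig"`) and
#'   `offset` (0).
#' @export
extract_windows <- function(genome, sites, L, max_n_fraction = 0.1) {
  genome <- load_genome(genome)
  stopifnot(L > 0, L %% 2 == 0)
  half <- L / 2
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (!s$chrom %in% names(genome)) {
      warning(sprintf("site %s: chromosome %s not in genome; skipped",
                      s$site_id, s$chrom))
      next
    }
    w0 <- s$center - half
    w1 <- s$center + half
    if (w0 < 0 || w1 > length(genome[[s$chrom]])) {
      warning(sprintf("site %s: window [%d, %d) exceeds chromosome bounds; skipped",
                      s$site_id, w0, w1))
      next
    }
    seq <- toupper(as.character(Biostrings::subseq(genome[[s$chrom]],
                                                   w0 + 1L, w1)))
    n_frac <- lengths(regmatches(seq, gregexpr("N", seq, fixed = TRUE))) / L
    if (n_frac > max_n_fraction) {
      warning(sprintf("site %s: %.0f%% ambiguous bases; skipped",
                      s$site_id, 100 * n_frac))
      next
    }
    rows[[i]] <- data.frame(record_id = paste0(s$site_id, ":orig"),
                            origin_site = s$site_id, chrom = s$chrom,
                            win_start = w0, sequence = seq,
                            label = s$label, variant_tag = "orig",
                            offset = 0L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    stop("no extractable windows: every site was out of bounds or filtered")
  }
  rownames(out) <- NULL
  out
}

#' One-hot encode a DNA sequence
#'
#' Maps a sequence over `{A, C, G, T, N}` (any case) to a 4 x L binary
#' matrix with channel order A, C, G, T.  `N` becomes an all-zero column,
#' so column sums are 1 for unambiguous bases and 0 for `N`.
#'
#' @param seq A single DNA string.
#' @return A 4 x `nchar(seq)` numeric matrix with rownames `A`,`C`,`G`,`T`.
#' @examples
#' one_hot_encode("ACGT")  # 4 x 4 identity
#' @export
one_hot_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(ch, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("invalid character '%s' at position %d", ch[bad], bad))
  }
  L <- length(ch)
  m <- matrix(0, nrow = 4L, ncol = L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  keep <- idx <= 4L
  m[cbind(idx[keep], which(keep))] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot_encode()]: all-zero columns decode to `N`.
#'
#' @param m A 4 x L one-hot matrix (rows A, C, G, T).
#' @return A single DNA string.
#' @export
one_hot_decode <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 4)
  if (ncol(m) == 0L) return("")
  idx <- max.col(t(m), ties.method = "first")
  out <- c("A", "C", "G", "T")[idx]
  out[colSums(m) == 0] <- "N"
  paste(out, collapse = "")
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.  Applying the
#' function twice returns the input.
#'
#' @param seq A single DNA string over `{A, C, G, T, N}` (any case).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("CCTGGGAA")  # "TTCCCAGG"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) {
    bad <- regexpr("[^ACGTN]", s)
    stop(sprintf("invalid character '%s' at position %d",
                 substr(s, bad, bad), bad))
  }
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Augmentation settings
#'
#' Controls the reverse-complement-and-shift augmentation applied to gained
#' sites: windows are re-extracted after shifting the center left and right
#' by magnitudes drawn uniformly from `min_shift..max_shift` bp (drawn once
#' per direction per site), and each of the three windows is also reverse
#' complemented, giving six variants per site.
#'
#' @param do_revcomp Add reverse-complement variants (default `TRUE`).
#' @param min_shift,max_shift Shift magnitude bounds in bp (defaults 1, 5).
#' @param seed Integer seed for the shift draws.
#' @return A list of class `dardn_augmentation_spec`.
#' @export
augmentation_spec <- function(do_revcomp = TRUE, min_shift = 1L,
                              max_shift = 5L, seed = 1L) {
  stopifnot(min_shift >= 1, min_shift <= max_shift)
  structure(list(do_revcomp = isTRUE(do_revcomp),
                 min_shift = as.integer(min_shift),
                 max_shift = as.integer(max_shift),
                 seed = as.integer(seed)),
            class = "dardn_augmentation_spec")
}

#' Augment sites by shifting and reverse complementing
#'
#' For every site, extracts the original window plus windows shifted left
#' and right by per-site random magnitudes, and (by default) the reverse
#' complements of all three — six variants per site, tagged `orig`,
#' `shiftL`, `shiftR`, `rc`, `rc_shiftL`, `rc_shiftR`.  Shifted windows are
#' re-extracted from the genome; any variant whose window leaves the
#' chromosome is dropped with a warning.
#'
#' @inheritParams extract_windows
#' @param spec An [augmentation_spec()].
#' @return A `data.frame` of sequence records (same columns as
#'   [extract_windows()]); `offset` is the signed center shift in bp.
#' @export
augment_sites <- function(genome, sites, L, spec = augmentation_spec()) {
  genome <- load_genome(genome)
  stopifnot(inherits(spec, "dardn_augmentation_spec"))
  set.seed(spec$seed)
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    kL <- sample(spec$min_shift:spec$max_shift, 1L)
    kR <- sample(spec$min_shift:spec$max_shift, 1L)
    variants <- data.frame(tag = c("orig", "shiftL", "shiftR"),
                           offset = c(0L, -kL, kR),
                           stringsAsFactors = FALSE)
    recs <- vector("list", nrow(variants))
    for (v in seq_len(nrow(variants))) {
      vs <- s
      vs$center <- s$center + variants$offset[v]
      rec <- tryCatch(
        suppressWarnings(extract_windows(genome, vs, L)),
        error = function(e) NULL)
      if (is.null(rec)) {
        warning(sprintf("site %s: variant %s out of bounds; dropped",
                        s$site_id, variants$tag[v]))
        next
      }
      rec$variant_tag <- variants$tag[v]
      rec$offset <- variants$offset[v]
      rec$record_id <- paste0(s$site_id, ":", variants$tag[v])
      recs[[v]] <- rec
    }
    recs <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
    if (is.null(recs)) next
    if (spec$do_revcomp) {
      rc <- recs
      rc$sequence <- vapply(rc$sequence, reverse_complement, "",
                            USE.NAMES = FALSE)
      rc$variant_tag <- sub("^orig$", "rc", rc$variant_tag)
      rc$variant_tag <- sub("^shift", "rc_shift", rc$variant_tag)
      rc$record_id <- paste0(s$site_id, ":", rc$variant_tag)
      recs <- rbind(recs, rc)
    }
    out[[i]] <- recs
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) stop("augmentation produced no records")
  rownames(out) <- NULL
  out
}

#' Assemble leakage-safe train/validation/test splits
#'
#' Partitions records into splits by their `origin_site`, separately within
#' each class, so that all augmented variants of one site land in exactly
#' one split.  Deterministic under `seed`.
#'
#' @param pos,neg Record `data.frame`s (positive / negative class) with at
#'   least `record_id`, `origin_site`, `sequence`, `label` columns.
#' @param fractions Named numeric vector `c(train=, val=, test=)` summing
#'   to 1 (a zero entry disables that split).
#' @param seed Integer seed for the site shuffles.
#' @return A list of class `dardn_splits` with elements `train`, `val`,
#'   `test` (record `data.frame`s), `fractions` and `seed`.
#' @export
assemble_splits <- function(pos, neg,
                            fractions = c(train = 0.8, val = 0.1, test = 0.1),
                            seed = 1L) {
  if (is.null(names(fractions))) names(fractions) <- c("train", "val", "test")
  stopifnot(length(fractions) == 3,
            all(names(fractions) == c("train", "val", "test")),
            abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  stopifnot(all(pos$label == 1), all(neg$label == 0))
  set.seed(seed)

  split_sites <- function(records) {
    sites <- unique(records$origin_site)
    sites <- sample(sites)
    counts <- diff(round(cumsum(c(0, fractions)) * length(sites)))
    membership <- rep(names(fractions), counts)
    stats::setNames(membership, sites)
  }
  mpos <- split_sites(pos)
  mneg <- split_sites(neg)

  take <- function(which_split) {
    out <- rbind(pos[mpos[pos$origin_site] == which_split, , drop = FALSE],
                 neg[mneg[neg$origin_site] == which_split, , drop = FALSE])
    rownames(out) <- NULL
    out
  }
  out <- list(train = take("train"), val = take("val"), test = take("test"),
              fractions = fractions, seed = as.integer(seed))
  for (nm in c("train", "val", "test")) {
    if (fractions[[nm]] > 0 && !any(out[[nm]]$label == 1)) {
      stop(sprintf("split '%s' has zero positive sites; use more sites or different fractions", nm))
    }
  }
  structure(out, class = "dardn_splits")
}

#' Encode sequences into a one-hot array
#'
#' Stacks [one_hot_encode()] results into a `4 x L x n` array, the input
#' layout the classifier consumes.
#'
#' @param seqs Character vector of equal-length DNA sequences.
#' @param ids Optional slice names (defaults to `names(seqs)`).
#' @return A numeric array of dimension `c(4, L, length(seqs))`.
#' @export
encode_sequences <- function(seqs, ids = names(seqs)) {
  stopifnot(length(seqs) > 0)
  L <- nchar(seqs[[1]])
  if (!all(nchar(seqs) == L)) stop("all sequences must have equal length")
  arr <- array(0, dim = c(4L, L, length(seqs)),
               dimnames = list(c("A", "C", "G", "T"), NULL, ids))
  for (i in seq_along(seqs)) arr[, , i] <- one_hot_encode(seqs[[i]])
  arr
}

#' Write split records and a provenance manifest
#'
#' Serializes each split as a tab-delimited table of records and writes a
#' `manifest.tsv` mapping every record to its origin site, variant and
#' split.
#'
#' @param splits A `dardn_splits` object from [assemble_splits()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest `data.frame`.
#' @export
write_splits <- function(splits, dir) {
  stopifnot(inherits(splits, "dardn_splits"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  for (nm in c("train", "val", "test")) {
    df <- splits[[nm]]
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(df)) {
      manifest <- rbind(manifest,
                        data.frame(record_id = df$record_id,
                                   origin_site = df$origin_site,
                                   variant_tag = df$variant_tag,
                                   label = df$label, split = nm,
                                   stringsAsFactors = FALSE))
    }
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
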