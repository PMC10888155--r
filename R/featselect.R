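#' Sliding-window mean scores
#'
#' Slides a length-`w` window with single-bp stride across a per-base
#' score vector, producing exactly `L - w + 1` windows, each scored by the
#' mean of its `w` per-base scores and carrying its subsequence.
#'
#' @param scores Per-base score vector of length L (e.g. gated DeepLIFT
#'   scores).
#' @param seq The corresponding DNA sequence of length L.
#' @param w Window length in bp (`w <= L`).
#' @param record_id Identifier attached to every window.
#' @param chrom,win_start Optional genomic provenance of the record window
#'   (0-based genomic start); carried through so selections can be exported
#'   as BED intervals.
#' @return A `data.frame` with columns `record_id`, `start` (0-based array
#'   index), `w`, `mean_score`, `subsequence`, and, when provenance is
#'   given, `chrom`, `gstart`, `gend` (0-based half-open).
#' @export
window_scores <- function(scores, seq, w, record_id = NA_character_,
                          chrom = NULL, win_start = NULL) {
  L <- length(scores)
  if (nchar(seq) != L) stop("`seq` length does not match `scores` length")
  if (w > L) stop("window length w = ", w, " exceeds sequence length ", L)
  means <- data.table::frollmean(scores, w, align = "left")[seq_len(L - w + 1)]
  start <- 0:(L - w)
  out <- data.frame(record_id = record_id, start = start, w = w,
                    mean_score = means,
                    subsequence = substring(seq, start + 1, start + w),
                    stringsAsFactors = FALSE)
  if (!is.null(chrom) && !is.null(win_start)) {
    out$chrom <- chrom
    out$gstart <- win_start + start
    out$gend <- win_start + start + w
  }
  out
}

#' Centered moving-average score at one index
#'
#' Mean of the `w + 1` per-base scores in `[i - w/2, i + w/2]` (0-based
#' index `i`, even `w`) — the smoothing used to locate score peaks.  Near
#' the sequence boundary the window is truncated to the available values
#' and the result is flagged.
#'
#' @param scores Per-base score vector.
#' @param i 0-based center index.
#' @param w Even window size; the mean runs over `w + 1` values.
#' @return A number with attribute `truncated` (logical).
#' @export
centered_peak_score <- function(scores, i, w) {
  stopifnot(w > 0, w %% 2 == 0, i >= 0, i <= length(scores) - 1)
  lo <- max(0, i - w / 2)
  hi <- min(length(scores) - 1, i + w / 2)
  structure(mean(scores[(lo + 1):(hi + 1)]),
            truncated = (hi - lo) < w)
}

#' Centered moving-average track
#'
#' [centered_peak_score()] evaluated at every index.
#'
#' @inheritParams centered_peak_score
#' @return A `data.frame` with columns `index` (0-based), `score`,
#'   `truncated`.
#' @export
centered_peak_track <- function(scores, w) {
  stopifnot(w > 0, w %% 2 == 0)
  L <- length(scores)
  half <- w / 2
  cs <- cumsum(c(0, scores))
  i <- 0:(L - 1)
  lo <- pmax(0, i - half)
  hi <- pmin(L - 1, i + half)
  data.frame(index = i, score = (cs[hi + 2] - cs[lo + 1]) / (hi - lo + 1),
             truncated = (hi - lo) < w)
}

#' Top score peaks with non-maximum suppression
#'
#' Ranks centered moving-average peaks by score and greedily keeps the
#' highest ones whose centers are at least `min_sep` bp apart, returning
#' up to `n` peaks.  Boundary-truncated windows are excluded by default.
#'
#' @inheritParams centered_peak_score
#' @param n Maximum number of peaks.
#' @param min_sep Minimum center-to-center separation in bp (default `w`).
#' @param exclude_truncated Drop boundary-truncated windows (default
#'   `TRUE`).
#' @return A `data.frame` with columns `center` (0-based index) and
#'   `score`, in decreasing score order.
#' @export
top_peak_windows <- function(scores, w, n = 10L, min_sep = w,
                             exclude_truncated = TRUE) {
  track <- centered_peak_track(scores, w)
  if (exclude_truncated) track <- track[!track$truncated, , drop = FALSE]
  track <- track[order(-track$score, track$index), , drop = FALSE]
  kept <- integer(0)
  for (j in seq_len(nrow(track))) {
    ci <- track$index[j]
    if (all(abs(ci - kept) >= min_sep)) {
      kept <- c(kept, ci)
      if (length(kept) >= n) break
    }
  }
  out <- track[match(kept, track$index), c("index", "score")]
  names(out) <- c("center", "score")
  rownames(out) <- NULL
  out
}

#' Select top-scoring subsequences
#'
#' From sliding-window scores (rows of [window_scores()] output, typically
#' concatenated over many records), selects the `n` windows with the
#' highest positive mean scores — either globally across all records
#' (default, matching the aggregate-then-select strategy) or the top `n`
#' within each record.  Windows with non-positive mean score are never
#' selected.  Ties are broken by (`record_id`, `start`) ascending, so the
#' selection is invariant to input row order.
#'
#' @param windows A `data.frame` of windows from [window_scores()].
#' @param strategy `"global"` (default) or `"per_site"`.
#' @param n Number of subsequences to keep (per record for `"per_site"`).
#' @param min_sep Optional non-maximum suppression: minimum start-to-start
#'   separation in bp between selected windows of the same record
#'   (`NULL`, the default, allows overlaps).
#' @return The selected rows, ordered by decreasing `mean_score` (ties by
#'   `record_id`, `start`).
#' @export
select_subsequences <- function(windows, strategy = c("global", "per_site"),
                                n = 1000L, min_sep = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(n >= 1)
  pos <- windows[!is.na(windows$mean_score) & windows$mean_score > 0, ,
                 drop = FALSE]
  pos <- pos[order(-pos$mean_score, pos$record_id, pos$start), ,
             drop = FALSE]
  if (!is.null(min_sep)) {
    keep <- logical(nrow(pos))
    taken <- list()
    for (j in seq_len(nrow(pos))) {
      rid <- pos$record_id[j]
      st <- pos$start[j]
      prev <- taken[[rid]]
      if (is.null(prev) || all(abs(st - prev) >= min_sep)) {
        keep[j] <- TRUE
        taken[[rid]] <- c(prev, st)
      }
    }
    pos <- pos[keep, , drop = FALSE]
  }
  out <- if (strategy == "global") {
    utils::head(pos, n)
  } else {
    do.call(rbind, lapply(split(pos, pos$record_id),
                          function(df) utils::head(df, n)))
  }
  out <- out[order(-out$mean_score, out$record_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no windows with positive mean score; empty selection")
  out
}

#' Export selected subsequences for motif enrichment
#'
#' Writes the selected windows as `selected.fasta` and, when genomic
#' provenance (`chrom`, `gstart`, `gend`) is present, as a 0-based
#' half-open `selected.bed` plus a `run_homer.sh` stub invoking
#' `findMotifsGenome.pl` with a 200-bp search space.  Without provenance
#' only the FASTA is written, with a warning.
#'
#' @param selected Output of [select_subsequences()].
#' @param out_dir Output directory (created if missing).
#' @param genome_id Genome assembly name written into the stub (default
#'   `"hg38"`).
#' @return Invisibly, a named vector of the paths written.
#' @export
export_for_motif_search <- function(selected, out_dir, genome_id = "hg38") {
  if (nrow(selected) == 0L) stop("empty selection; nothing to export")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(selected$subsequence)
  names(fa) <- sprintf("%s:%d", selected$record_id, selected$start)
  fa_path <- file.path(out_dir, "selected.fasta")
  Biostrings::writeXStringSet(fa, fa_path)
  paths <- c(fasta = fa_path)
  if (all(c("chrom", "gstart", "gend") %in% names(selected))) {
    bed <- data.frame(chrom = selected$chrom,
                      start = as.integer(selected$gstart),
                      end = as.integer(selected$gend),
                      name = names(fa),
                      score = signif(selected$mean_score, 6),
                      strand = ".")
    bed_path <- file.path(out_dir, "selected.bed")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    sh_path <- file.path(out_dir, "run_homer.sh")
    writeLines(c("#!/bin/sh",
                 "# known-motif enrichment on the selected subsequences",
                 sprintf("findMotifsGenome.pl selected.bed %s homer_out -size 200",
                         genome_id)),
               sh_path)
    paths <- c(paths, bed = bed_path, script = sh_path)
  } else {
    warning("no genomic provenance in selection; FASTA written without BED")
  }
  invisible(paths)
}

#' Position weight matrix around aligned peaks
#'
#' Aligns `(2 * flank + 1)`-bp slices of the supplied sequences at their
#' peak centers and tabulates per-column base frequencies; the consensus
#' takes the most frequent base in each column.  Records whose peak sits
#' closer than `flank` to either edge are skipped with a warning.
#'
#' @param seqs Character vector of sequences.
#' @param peak_centers 0-based peak center index per sequence.
#' @param flank Half-width of the logo in bp.
#' @return A list of class `dardn_pwm` with `values` (4 x `(2*flank+1)`
#'   column-stochastic matrix, rows A, C, G, T), `k`, `n_sequences` and
#'   `consensus`.
#' @export
pwm_from_peaks <- function(seqs, peak_centers, flank) {
  stopifnot(length(seqs) == length(peak_centers), flank >= 0)
  k <- 2L * flank + 1L
  slices <- character(0)
  for (i in seq_along(seqs)) {
    ci <- peak_centers[i]
    L <- nchar(seqs[i])
    if (ci - flank < 0 || ci + flank > L - 1) {
      warning(sprintf("record %d: peak at %d closer than flank to the edge; skipped",
                      i, ci))
      next
    }
    slices <- c(slices, substr(seqs[i], ci - flank + 1, ci + flank + 1))
  }
  if (length(slices) == 0L) stop("no usable records for the PWM")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(slices),
                                    baseOnly = TRUE)[c("A", "C", "G", "T"), ,
                                                     drop = FALSE]
  tot <- colSums(cm)
  tot[tot == 0] <- 1
  vals <- sweep(cm, 2, tot, "/")
  consensus <- paste(rownames(vals)[apply(vals, 2, which.max)],
                     collapse = "")
  structure(list(values = vals, k = k, n_sequences = length(slices),
                 consensus = consensus),
            class = "dardn_pwm")
}

#' @export
print.dardn_pwm <- function(x, ...) {
  cat(sprintf("PWM over %d aligned %d-bp slices; consensus %s\n",
              x$n_sequences, x$k, x$consensus))
  invisible(x)
}

#' Write a PWM as a tab-delimited matrix
#'
#' @param pwm A `dardn_pwm`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "dardn_pwm"))
  utils::write.table(pwm$values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  invisible(path)
}

#' Signed distances from window centers to the site center
#'
#' The CTCF site sits at the midpoint `L/2` of each extracted window, so a
#' hit at array index `c` lies `c - L/2` bp from the site (negative
#' upstream in array coordinates).
#'
#' @param centers 0-based array indices of motif hits or selected windows.
#' @param L Window length in bp.
#' @return A `data.frame` with columns `center` and `distance`.
#' @export
motif_distances <- function(centers, L) {
  stopifnot(all(centers >= 0), all(centers < L))
  data.frame(center = centers, distance = centers - L / 2)
}

#' Gaussian-smoothed distance density
#'
#' Kernel density of a distance sample on a regular grid spanning the data
#' (Gaussian kernel, fixed bandwidth); the curve integrates to 1 on the
#' grid.
#'
#' @param distances Numeric vector (non-empty).
#' @param bandwidth Gaussian kernel bandwidth in bp (> 0).
#' @return A `data.frame` with columns `x` and `density`.
#' @export
smooth_density <- function(distances, bandwidth) {
  if (length(distances) == 0L) stop("empty distance vector")
  stopifnot(bandwidth > 0)
  d <- stats::density(distances, bw = bandwidth, kernel = "gaussian",
                      n = 1024, cut = 5)
  data.frame(x = d$x, density = d$y)
}

#' Percentile rank of a motif among enriched motifs
#'
#' `(total - rank) / total * 100`, reported to one decimal: rank 1 of 264
#' is the 99.6th percentile, rank 2 the 99.2th.
#'
#' @param rank 1-based significance rank (1 = most enriched).
#' @param total Total number of enriched motifs.
#' @return The percentile as a single number (one decimal).
#' @examples
#' percentile_rank(2, 264)  # 99.2
#' @export
percentile_rank <- function(rank, total) {
  stopifnot(total >= 1)
  if (rank < 1 || rank > total) stop("`rank` must lie in [1, total]")
  round((total - rank) / total * 100, 1)
}

#' Parse a known-motif enrichment results table
#'
#' Reads a tab-delimited results table in the style of HOMER's
#' `knownResults.txt` (header row; a motif-name column and a p-value
#' column) and returns motifs ordered by significance, ties keeping input
#' order.
#'
#' @param path Path to the results table.
#' @return A `data.frame` with columns `rank`, `motif`, `p_value`.
#' @export
parse_motif_results <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  cols <- names(tab)
  name_col <- grep("motif ?name", cols, ignore.case = TRUE, value = TRUE)
  if (length(name_col) == 0L) name_col <- cols[1]
  p_col <- grep("^p.?value", cols, ignore.case = TRUE, value = TRUE)
  if (length(p_col) == 0L)
    p_col <- grep("p.?value", cols[!grepl("log", cols, ignore.case = TRUE)],
                  ignore.case = TRUE, value = TRUE)
  if (length(p_col) == 0L) stop("no p-value column found in ", path)
  p <- suppressWarnings(as.numeric(tab[[p_col[1]]]))
  if (anyNA(p)) stop("non-numeric p-values in ", path)
  ord <- order(p)  # stable: ties keep input order
  data.frame(rank = seq_len(nrow(tab)), motif = tab[[name_col[1]]][ord],
             p_value = p[ord], stringsAsFactors = FALSE)
}

#' Rank of a motif by name substring
#'
#' Case-insensitive substring query against a parsed enrichment table.
#'
#' @param results Output of [parse_motif_results()].
#' @param query Name fragment, e.g. `"RBPJ"`.
#' @return A list with `rank`, `total` and `percentile`; errors when the
#'   query matches nothing.
#' @export
motif_rank <- function(results, query) {
  hit <- grepl(query, results$motif, ignore.case = TRUE, fixed = FALSE)
  if (!any(hit)) stop("no motif matching '", query, "'")
  r <- min(results$rank[hit])
  list(rank = r, total = nrow(results),
       percentile = percentile_rank(r, nrow(results)))
}
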