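#' Simulation benchmark settings
#'
#' Configuration for the motif-insertion validation benchmark: long random
#' background sequences are generated, every occurrence of the query motif
#' is scrubbed, and the motif is then written back at random non-overlapping
#' positions in a fixed fraction of the sequences, with ground-truth
#' insertion coordinates retained.  Defaults follow the benchmark built
#' around the RBPJ consensus (`CCTGGGAA`, the Notch-pathway positive
#' control in T-ALL): 10 insertions per positive sequence in 33% of
#' sequences.
#'
#' @param n_sequences Number of sequences.
#' @param L Sequence length in bp.
#' @param motif Query motif over `{A, C, G, T}` (default `"CCTGGGAA"`).
#' @param inserted_fraction Fraction of sequences that receive insertions
#'   (default 0.33).
#' @param insertions_per_site Insertions per positive sequence (default 10).
#' @param gc_content Background GC fraction (default 0.5).
#' @param seed Integer seed controlling the whole benchmark.
#' @return A list of class `dardn_simulation_config`.
#' @export
simulation_config <- function(n_sequences, L, motif = "CCTGGGAA",
                              inserted_fraction = 0.33,
                              insertions_per_site = 10L, gc_content = 0.5,
                              seed = 1L) {
  stopifnot(n_sequences >= 1, L >= 1,
            inserted_fraction > 0, inserted_fraction < 1,
            insertions_per_site >= 1,
            nchar(motif) >= 1, !grepl("[^ACGT]", toupper(motif)),
            insertions_per_site * nchar(motif) <= L,
            gc_content > 0, gc_content < 1)
  structure(list(n_sequences = as.integer(n_sequences), L = as.integer(L),
                 motif = toupper(motif),
                 inserted_fraction = inserted_fraction,
                 insertions_per_site = as.integer(insertions_per_site),
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "dardn_simulation_config")
}

#' @keywords internal
random_dna <- function(L, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate i.i.d. background sequences
#'
#' Draws `n` sequences of length `L` with independent bases,
#' `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`.  A stand-in for
#' CTCF-free genomic background; real sequences can be supplied instead
#' anywhere a character vector of sequences is accepted.
#'
#' @param n Number of sequences.
#' @param L Sequence length in bp.
#' @param gc GC fraction, strictly inside (0, 1).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return Character vector of `n` sequences.
#' @export
generate_background <- function(n, L, gc = 0.5, seed = NULL) {
  if (n <= 0 || L <= 0) stop("`n` and `L` must be positive")
  if (gc <= 0 || gc >= 1) stop("`gc` must be strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) random_dna(L, gc), "")
}

#' Find motif occurrence starts (0-based, overlapping)
#'
#' @param seq A DNA string.
#' @param motif Motif over `{A, C, G, T}`.
#' @return Integer vector of 0-based start positions (including overlapping
#'   occurrences).
#' @export
motif_starts <- function(seq, motif) {
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
  as.integer(Biostrings::start(hits)) - 1L
}

#' Scrub every occurrence of a motif
#'
#' Replaces each occurrence of `motif` (forward strand; optionally also its
#' reverse complement) with a uniformly random same-length substring, and
#' rescans until the full sequence is motif-free — replacements that
#' themselves create new occurrences are resampled.  Length is unchanged.
#'
#' @param seq A DNA string.
#' @param motif Motif over `{A, C, G, T}`.
#' @param both_strands Also scrub the motif's reverse complement
#'   (default `FALSE`).
#' @param max_iter Rescan bound before giving up (default 100).
#' @return The scrubbed sequence.
#' @export
scrub_motif <- function(seq, motif, both_strands = FALSE, max_iter = 100L) {
  motif <- toupper(motif)
  targets <- motif
  if (both_strands) targets <- unique(c(motif, reverse_complement(motif)))
  m <- nchar(motif)
  for (iter in seq_len(max_iter)) {
    starts <- sort(unique(unlist(lapply(targets, motif_starts, seq = seq))))
    if (length(starts) == 0L) return(seq)
    # replace left to right; later occurrences may be destroyed, rescan next pass
    for (s in starts) {
      if (any(vapply(targets, function(t) {
        substr(seq, s + 1L, s + m) == t
      }, TRUE))) {
        substr(seq, s + 1L, s + m) <- random_dna(m)
      }
    }
  }
  stop("scrub_motif: motif still present after ", max_iter, " passes")
}

#' Insert a motif at random non-overlapping positions
#'
#' Overwrites `k` non-overlapping, uniformly chosen positions of a (already
#' scrubbed) sequence with `motif`.  Substitution keeps the sequence length
#' constant.  Placements are resampled (up to `max_attempts`) until exactly
#' `k` occurrences are present — overwriting can otherwise create spurious
#' extra occurrences at insertion boundaries.
#'
#' @param seq A scrubbed DNA string.
#' @param motif Motif over `{A, C, G, T}`.
#' @param k Number of insertions.
#' @param max_attempts Placement retry bound (default 1000).
#' @return A list with `sequence` (modified string) and `starts` (sorted
#'   0-based insertion starts).
#' @details Placements are drawn uniformly over all non-overlapping
#'   configurations via the standard combination bijection (choose `k` of
#'   the `L - k*(m-1)` gap-reduced slots), so even dense packings are
#'   sampled directly rather than by rejection.
#' @export
insert_motif <- function(seq, motif, k, max_attempts = 1000L) {
  motif <- toupper(motif)
  m <- nchar(motif)
  L <- nchar(seq)
  if (k * m > L) stop("cannot place ", k, " non-overlapping copies in ", L, " bp")
  n_slots <- L - k * m + k  # positions after collapsing each copy to 1 slot
  for (attempt in seq_len(max_attempts)) {
    q <- sort(sample.int(n_slots, k))
    starts <- q + (seq_len(k) - 1L) * (m - 1L) - 1L  # 0-based
    cand <- seq
    for (s in starts) substr(cand, s + 1L, s + m) <- motif
    # overwriting can create spurious extra occurrences at copy boundaries;
    # resample until exactly k remain
    if (length(motif_starts(cand, motif)) == k) {
      return(list(sequence = cand, starts = starts))
    }
  }
  stop("insert_motif: no placement with exactly k occurrences after ",
       max_attempts, " attempts")
}

#' Build the motif-insertion simulation benchmark
#'
#' Generates background sequences, scrubs all motif occurrences from every
#' sequence, then inserts the motif `insertions_per_site` times into a
#' random `round(n * inserted_fraction)` subset (label 1); the rest keep
#' label 0.  Bit-identical across runs with the same config seed.
#'
#' @param config A [simulation_config()].
#' @return A list of class `dardn_simulation` with `records` (a
#'   `data.frame`: `record_id`, `sequence`, `label`) and `truth` (a
#'   `data.frame`: `record_id`, `label`, plus list-column `starts` of
#'   0-based insertion starts) and the `config`.
#' @export
build_simulation_set <- function(config) {
  stopifnot(inherits(config, "dardn_simulation_config"))
  set.seed(config$seed)
  n <- config$n_sequences
  seqs <- generate_background(n, config$L, config$gc_content)
  seqs <- vapply(seqs, scrub_motif, "", motif = config$motif,
                 USE.NAMES = FALSE)
  n_pos <- round(n * config$inserted_fraction)
  pos_idx <- sort(sample.int(n, n_pos))
  labels <- integer(n)
  labels[pos_idx] <- 1L
  starts <- vector("list", n)
  starts[] <- list(integer(0))
  for (i in pos_idx) {
    ins <- insert_motif(seqs[i], config$motif, config$insertions_per_site)
    seqs[i] <- ins$sequence
    starts[[i]] <- ins$starts
  }
  ids <- sprintf("sim_%05d", seq_len(n))
  records <- data.frame(record_id = ids, sequence = seqs, label = labels,
                        stringsAsFactors = FALSE)
  truth <- data.frame(record_id = ids, label = labels,
                      stringsAsFactors = FALSE)
  truth$starts <- starts
  structure(list(records = records, truth = truth, config = config),
            class = "dardn_simulation")
}

#' Write a simulation benchmark to disk
#'
#' Emits `sequences.fasta` and a tab-delimited `truth.tsv` with columns
#' `record_id`, `label` and comma-separated 0-based insertion starts.
#'
#' @param sim A `dardn_simulation` from [build_simulation_set()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "dardn_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(sim$records$sequence)
  names(fa) <- sim$records$record_id
  fa_path <- file.path(dir, "sequences.fasta")
  Biostrings::writeXStringSet(fa, fa_path)
  truth <- data.frame(record_id = sim$truth$record_id,
                      label = sim$truth$label,
                      starts = vapply(sim$truth$starts, paste, "",
                                      collapse = ","),
                      stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa_path, truth = truth_path))
}
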