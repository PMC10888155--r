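#' Build the constitutive-frequency DeepLIFT reference
#'
#' Averages a seeded random sample (`round(n * fraction)` matrices, at
#' least one) of constitutive-site one-hot matrices element-wise, yielding
#' a 4 x L profile of per-position base frequencies — the null input
#' against which contributions are measured.
#'
#' @param onehots Constitutive one-hot matrices: a `4 x L x n` array or a
#'   list of 4 x L matrices.
#' @param fraction Sampling fraction in (0, 1] (default 0.8).
#' @param seed Optional integer seed for the sample.
#' @return A list of class `dardn_reference` with `values` (4 x L matrix),
#'   `source_fraction`, `seed`, `n_sites_used`.
#' @export
build_reference <- function(onehots, fraction = 0.8, seed = NULL) {
  x <- as_onehot_array(onehots)
  n <- dim(x)[3]
  if (n < 1) stop("at least one constitutive matrix is required")
  stopifnot(fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_used <- max(1L, round(n * fraction))
  sel <- sort(sample.int(n, n_used))
  L <- dim(x)[2]
  vals <- matrix(rowMeans(matrix(x[, , sel, drop = FALSE], nrow = 4L * L)),
                 nrow = 4L, dimnames = list(c("A", "C", "G", "T"), NULL))
  structure(list(values = vals, source_fraction = fraction,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 n_sites_used = n_used),
            class = "dardn_reference")
}

#' DeepLIFT contributions under the Rescale rule
#'
#' Decomposes the difference between the model's gained-site logit on an
#' input and on the reference into per-position, per-channel contribution
#' scores by multiplier backpropagation: linear layers (convolutions, the
#' width-1 residual projection, average pooling, dense layers) pass
#' multipliers through their transposed linear maps, ReLUs use the Rescale
#' rule (delta-activation over delta-pre-activation, with a gradient
#' fallback below `threshold`), and the residual addition routes
#' multipliers into both summands.  Contributions satisfy
#' summation-to-delta: they sum to `o2(input) - o2(reference)`.
#' Attribution targets the raw logit; the softmax head is not part of the
#' attribution path.
#'
#' @param model A trained `dardn_model`.
#' @param x A 4 x L one-hot matrix.
#' @param reference A `dardn_reference` from [build_reference()] (or a
#'   4 x L matrix).
#' @param target Target logit, `"o2"` (gained, default) or `"o1"`.
#' @param record_id Optional identifier stored in the result.
#' @param threshold Near-zero pre-activation-difference threshold for the
#'   gradient fallback (default 1e-7).
#' @return A list of class `dardn_contributions` with `channel_scores`
#'   (4 x L), `gated_scores` (length L; the score of the observed base at
#'   each position, 0 at `N`), `sequence` (the decoded input), `target`,
#'   `record_id`, `o_input`, `o_reference` and `delta` (the targeted
#'   logit difference).
#' @export
deeplift_rescale <- function(model, x, reference, target = c("o2", "o1"),
                             record_id = NA_character_, threshold = 1e-7) {
  stopifnot(inherits(model, "dardn_model"))
  target <- match.arg(target)
  ref <- if (inherits(reference, "dardn_reference")) reference$values
         else reference
  stopifnot(is.matrix(x), nrow(x) == 4, is.matrix(ref), nrow(ref) == 4)
  if (!all(dim(x) == dim(ref)))
    stop("input and reference must have the same dimensions")
  idx <- if (target == "o2") 2L else 1L
  res <- cpp_deeplift(model$params, x, ref, target_index = idx,
                      thr = threshold)
  channel_scores <- res$channel_scores
  dimnames(channel_scores) <- list(c("A", "C", "G", "T"), NULL)
  seq <- one_hot_decode(x)
  out <- structure(list(channel_scores = channel_scores,
                        gated_scores = NULL, sequence = seq,
                        target = target,
                        record_id = record_id,
                        o_input = stats::setNames(res$o_input, c("o1", "o2")),
                        o_reference = stats::setNames(res$o_reference,
                                                      c("o1", "o2")),
                        delta = res$o_input[idx] - res$o_reference[idx]),
                   class = "dardn_contributions")
  out$gated_scores <- gate_scores(out, seq)
  out
}

#' Gate channel contributions to the observed nucleotides
#'
#' At every position, selects the contribution of the base actually
#' present in the sequence; `N` positions score 0.
#'
#' @param track A `dardn_contributions` object or a 4 x L channel-score
#'   matrix (rows A, C, G, T).
#' @param seq The DNA sequence of length L.
#' @return A numeric vector of length L.
#' @export
gate_scores <- function(track, seq) {
  scores <- if (inherits(track, "dardn_contributions")) track$channel_scores
            else track
  stopifnot(is.matrix(scores), nrow(scores) == 4)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(ch) != ncol(scores))
    stop("sequence length does not match score track length")
  idx <- match(ch, c("A", "C", "G", "T"))
  out <- numeric(length(ch))
  obs <- !is.na(idx)
  out[obs] <- scores[cbind(idx[obs], which(obs))]
  out
}

#' Write a contribution track as a tab-delimited table
#'
#' One row per position: 0-based `position`, observed `base`, and the
#' gated DeepLIFT score.
#'
#' @param track A `dardn_contributions` object.
#' @param path Output file.
#' @param seq Optional sequence; defaults to the decoded one-hot input
#'   stored in the track.
#' @return Invisibly, `path`.
#' @export
write_contributions <- function(track, path, seq = track$sequence) {
  stopifnot(inherits(track, "dardn_contributions"))
  L <- length(track$gated_scores)
  base <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  utils::write.table(
    data.frame(position = 0:(L - 1), base = base,
               gated_score = track$gated_scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
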