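#' @keywords internal
split_records_by_site <- function(records, fractions, seed) {
  pos <- records[records$label == 1, , drop = FALSE]
  neg <- records[records$label == 0, , drop = FALSE]
  if (!"origin_site" %in% names(pos)) {
    pos$origin_site <- pos$record_id
    neg$origin_site <- neg$record_id
  }
  assemble_splits(pos, neg, fractions, seed)
}

# Score-centroid refinement of a peak center: positive-part weighted mean
# index over the peak window, so slices from different records align on
# the score mass rather than on the (tie-prone) raw argmax.
#' @keywords internal
#' @noRd
centroid_refine <- function(scores, center, w) {
  lo <- max(0, center - w / 2)
  hi <- min(length(scores) - 1, center + w / 2)
  s <- pmax(scores[(lo + 1):(hi + 1)], 0)
  if (sum(s) <= 0) return(center)
  as.integer(floor(sum((lo:hi) * s) / sum(s) + 0.5))
}

#' Run the motif-insertion simulation experiment end to end
#'
#' Generates the simulation benchmark, trains the dual-kernel residual CNN
#' on a site-level train/validation/test split, evaluates hold-out
#' classification (accuracy, confusion counts, MCC), attributes every
#' positive hold-out record with DeepLIFT against the averaged
#' negative-sequence reference, and summarizes localization: the fraction
#' of top centered-mean score peaks that land on true insertions, and the
#' consensus of the position weight matrix built from the highest-peak
#' slices.
#'
#' @param sim_config A [simulation_config()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param fractions Site-level split fractions (default 80/10/10).
#' @param reference_fraction Fraction of negative training records
#'   averaged into the DeepLIFT reference (default 0.8).
#' @param w_peak Even window size of the centered moving average used for
#'   peak localization (default 8, the motif length of the default
#'   benchmark).
#' @param top_peaks Number of non-overlapping peaks examined per positive
#'   record (default 10, the number of insertions).
#' @param flank Half-width of the PWM around the highest peak (default
#'   10).
#' @param seed Optional master seed; when given it overrides the seeds of
#'   all stage configs (data: `seed`; model init: `seed + 1`; training:
#'   `seed + 2`; split: `seed + 3`; reference: `seed + 4`).
#' @param out_dir Optional directory; when given, the simulation FASTA,
#'   truth table, training history, per-record localization table, PWM and
#'   a plain-text report are written there.
#' @return A list of class `dardn_report`; key fields: `accuracy`
#'   (hold-out accuracy in percent), `confusion`, `mcc`, `localization`
#'   (per-record `data.frame` with `hits_in_top`, `n_top`), `consensus`,
#'   `pwm`, `history`, `seeds`, `n_test`, `config`.
#' @export
run_simulation_experiment <- function(sim_config,
                                      model_cfg = model_config(),
                                      train_cfg = train_config(),
                                      fractions = c(train = 0.8, val = 0.1,
                                                    test = 0.1),
                                      reference_fraction = 0.8,
                                      w_peak = 8L, top_peaks = 10L,
                                      flank = 10L, seed = NULL,
                                      out_dir = NULL) {
  stopifnot(inherits(sim_config, "dardn_simulation_config"))
  split_seed <- sim_config$seed + 3L
  ref_seed <- sim_config$seed + 4L
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    sim_config$seed <- seed
    model_cfg$seed <- seed + 1L
    train_cfg$seed <- seed + 2L
    split_seed <- seed + 3L
    ref_seed <- seed + 4L
  }

  sim <- build_simulation_set(sim_config)
  splits <- split_records_by_site(sim$records, fractions, split_seed)

  arrays <- lapply(splits[c("train", "val", "test")], function(df) {
    list(x = encode_sequences(df$sequence, df$record_id), y = df$label)
  })

  model <- build_model(model_cfg)
  model <- dardn_train(model, arrays$train$x, arrays$train$y,
                       arrays$val$x, arrays$val$y, train_cfg)

  pred <- predict(model, arrays$test$x)
  conf <- confusion_counts(pred$predicted_label, arrays$test$y)
  accuracy <- 100 * mean(pred$predicted_label == arrays$test$y)

  # attribution of positive hold-out records against the negative-profile
  # reference built from training negatives
  neg_train <- arrays$train$x[, , arrays$train$y == 0, drop = FALSE]
  reference <- build_reference(neg_train, reference_fraction, ref_seed)

  test_df <- splits$test
  truth <- sim$truth[match(test_df$record_id, sim$truth$record_id), ]
  pos_rows <- which(test_df$label == 1)
  m <- nchar(sim_config$motif)

  loc <- NULL
  peak_seqs <- character(0)
  peak_centers <- integer(0)
  tracks <- vector("list", length(pos_rows))
  for (jj in seq_along(pos_rows)) {
    j <- pos_rows[jj]
    x <- arrays$test$x[, , j]
    track <- deeplift_rescale(model, x, reference,
                              record_id = test_df$record_id[j])
    tracks[[jj]] <- track
    peaks <- top_peak_windows(track$gated_scores, w_peak, n = top_peaks,
                              min_sep = w_peak)
    starts <- truth$starts[[j]]
    hit <- vapply(peaks$center, function(ci) {
      any(ci + w_peak / 2 >= starts & ci - w_peak / 2 <= starts + m - 1)
    }, TRUE)
    loc <- rbind(loc, data.frame(record_id = test_df$record_id[j],
                                 hits_in_top = sum(hit),
                                 n_top = nrow(peaks)))
    peak_seqs <- c(peak_seqs, test_df$sequence[j])
    peak_centers <- c(peak_centers,
                      centroid_refine(track$gated_scores, peaks$center[1],
                                      w_peak))
  }

  pwm <- if (length(peak_seqs)) {
    tryCatch(pwm_from_peaks(peak_seqs, peak_centers, flank),
             error = function(e) {
               warning("no PWM: ", conditionMessage(e))
               NULL
             })
  } else NULL

  report <- structure(list(
    kind = "simulation",
    config = list(sim = sim_config, model = model_cfg, train = train_cfg,
                  fractions = fractions,
                  reference_fraction = reference_fraction,
                  w_peak = w_peak, top_peaks = top_peaks, flank = flank),
    seeds = c(data = sim_config$seed, model = model_cfg$seed,
              train = train_cfg$seed, split = split_seed, ref = ref_seed),
    n_train = length(arrays$train$y), n_val = length(arrays$val$y),
    n_test = length(arrays$test$y),
    history = model$history,
    accuracy = accuracy, confusion = conf, mcc = mcc(conf),
    localization = loc,
    peak_centers = peak_centers,
    tracks = tracks,
    reference = reference,
    test_records = cbind(test_df,
                         truth_starts = I(truth$starts)),
    consensus = if (is.null(pwm)) NA_character_ else pwm$consensus,
    pwm = pwm,
    model = model), class = "dardn_report")

  if (!is.null(out_dir)) write_report(report, sim, out_dir)
  report
}

#' @export
print.dardn_report <- function(x, ...) {
  cat(sprintf("%s experiment: %d train / %d val / %d test records\n",
              x$kind, x$n_train, x$n_val, x$n_test))
  cat(sprintf("hold-out accuracy %.1f%%  MCC %.3f  (TP %d TN %d FP %d FN %d)\n",
              x$accuracy, x$mcc, x$confusion$TP, x$confusion$TN,
              x$confusion$FP, x$confusion$FN))
  if (!is.null(x$localization) && nrow(x$localization)) {
    cat(sprintf("localization: mean %.1f / min %d of top-%d peaks on true insertions (%d positive records)\n",
                mean(x$localization$hits_in_top),
                min(x$localization$hits_in_top),
                x$config$top_peaks, nrow(x$localization)))
  }
  if (!is.null(x$consensus) && !is.na(x$consensus)) {
    cat(sprintf("peak-slice consensus: %s\n", x$consensus))
  }
  invisible(x)
}

#' @keywords internal
write_report <- function(report, sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim)) write_simulation(sim, out_dir)
  utils::write.table(report$history, file.path(out_dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$localization)) {
    utils::write.table(report$localization,
                       file.path(out_dir, "localization.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$pwm)) {
    write_pwm(report$pwm, file.path(out_dir, "pwm.tsv"))
  }
  metrics <- data.frame(
    metric = c("accuracy_pct", "mcc", "TP", "TN", "FP", "FN"),
    value = c(report$accuracy, report$mcc, report$confusion$TP,
              report$confusion$TN, report$confusion$FP,
              report$confusion$FN))
  utils::write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Run site-list discovery end to end
#'
#' The discovery pipeline on real inputs: read gained and constitutive
#' site lists, extract genome windows, augment the gained sites (reverse
#' complement and stochastic shifts), assemble leakage-safe splits, train,
#' evaluate the hold-out split, attribute positive hold-out records
#' (original orientation) with DeepLIFT against the constitutive
#' reference, score length-`w_select` sliding windows on the gated
#' scores, select the top subsequences, and export them for external
#' motif enrichment.
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @param gained,const Site tables from [read_sites()] or BED paths.
#' @param L Window length in bp.
#' @param model_cfg,train_cfg Model and training settings.
#' @param aug_spec An [augmentation_spec()] applied to gained sites only.
#' @param fractions Site-level split fractions.
#' @param reference_fraction Constitutive sampling fraction for the
#'   DeepLIFT reference.
#' @param w_select Sliding-window length for subsequence selection
#'   (default 20).
#' @param n_select Number of subsequences to select globally (default
#'   1000).
#' @param strategy Selection strategy, `"global"` or `"per_site"`.
#' @param out_dir Optional export directory for FASTA/BED and metrics.
#' @param seed Master seed applied as in [run_simulation_experiment()].
#' @return A list of class `dardn_report` with hold-out `confusion`,
#'   `mcc`, `accuracy`, the `selected` window table and export `paths`.
#' @export
run_discovery <- function(genome, gained, const, L,
                          model_cfg = model_config(),
                          train_cfg = train_config(),
                          aug_spec = augmentation_spec(),
                          fractions = c(train = 0.8, val = 0.1, test = 0.1),
                          reference_fraction = 0.8, w_select = 20L,
                          n_select = 1000L,
                          strategy = c("global", "per_site"),
                          out_dir = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  genome <- load_genome(genome)
  if (is.character(gained)) gained <- read_sites(gained, 1)
  if (is.character(const)) const <- read_sites(const, 0)
  split_seed <- aug_spec$seed + 3L
  ref_seed <- aug_spec$seed + 4L
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    aug_spec$seed <- seed
    model_cfg$seed <- seed + 1L
    train_cfg$seed <- seed + 2L
    split_seed <- seed + 3L
    ref_seed <- seed + 4L
  }

  pos <- augment_sites(genome, gained, L, aug_spec)
  neg <- extract_windows(genome, const, L)
  splits <- assemble_splits(pos, neg, fractions, split_seed)

  arrays <- lapply(splits[c("train", "val", "test")], function(df) {
    list(x = encode_sequences(df$sequence, df$record_id), y = df$label)
  })

  model <- build_model(model_cfg)
  model <- dardn_train(model, arrays$train$x, arrays$train$y,
                       arrays$val$x, arrays$val$y, train_cfg)

  pred <- predict(model, arrays$test$x)
  conf <- confusion_counts(pred$predicted_label, arrays$test$y)
  accuracy <- 100 * mean(pred$predicted_label == arrays$test$y)

  neg_train <- arrays$train$x[, , arrays$train$y == 0, drop = FALSE]
  reference <- build_reference(neg_train, reference_fraction, ref_seed)

  test_df <- splits$test
  pos_rows <- which(test_df$label == 1 & test_df$variant_tag == "orig")
  windows <- NULL
  for (j in pos_rows) {
    x <- arrays$test$x[, , j]
    track <- deeplift_rescale(model, x, reference,
                              record_id = test_df$record_id[j])
    windows <- rbind(windows,
                     window_scores(track$gated_scores, test_df$sequence[j],
                                   w_select,
                                   record_id = test_df$record_id[j],
                                   chrom = test_df$chrom[j],
                                   win_start = test_df$win_start[j]))
  }
  selected <- if (is.null(windows)) {
    warning("no positive original-orientation records in the test split; nothing selected")
    NULL
  } else {
    select_subsequences(windows, strategy, n_select)
  }

  paths <- NULL
  if (!is.null(out_dir) && !is.null(selected) && nrow(selected)) {
    paths <- export_for_motif_search(selected, out_dir)
  }

  report <- structure(list(
    kind = "discovery",
    config = list(L = L, model = model_cfg, train = train_cfg,
                  aug = aug_spec, fractions = fractions,
                  reference_fraction = reference_fraction,
                  w_select = w_select, n_select = n_select,
                  strategy = strategy),
    seeds = c(aug = aug_spec$seed, model = model_cfg$seed,
              train = train_cfg$seed, split = split_seed, ref = ref_seed),
    n_train = length(arrays$train$y), n_val = length(arrays$val$y),
    n_test = length(arrays$test$y),
    history = model$history,
    accuracy = accuracy, confusion = conf, mcc = mcc(conf),
    selected = selected, paths = paths, model = model),
    class = "dardn_report")
  if (!is.null(out_dir)) write_report(report, NULL, out_dir)
  report
}

#' Subsample a site table
#'
#' Seeded random subsampling of sites, used by the robustness protocol
#' (resampling constitutive background sites and gained foreground sites).
#'
#' @param sites A site table.
#' @param n Number of sites to keep; alternatively give `fraction`.
#' @param fraction Fraction of sites to keep.
#' @param seed Integer seed.
#' @return The subsampled site table.
#' @export
subsample_sites <- function(sites, n = NULL, fraction = NULL, seed = 1L) {
  if (is.null(n) == is.null(fraction))
    stop("give exactly one of `n` or `fraction`")
  if (is.null(n)) n <- round(nrow(sites) * fraction)
  stopifnot(n >= 1, n <= nrow(sites))
  set.seed(seed)
  out <- sites[sort(sample.int(nrow(sites), n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Robustness sweep by site resampling
#'
#' Repeats the discovery pipeline over seeded subsamples of the gained
#' and/or constitutive site lists, mirroring the resampling robustness
#' protocol (defaults scaled to the supplied site tables: about 68% of
#' constitutive sites and a fixed number of gained sites per run).
#'
#' @inheritParams run_discovery
#' @param n_runs Number of resampling runs (default 5).
#' @param const_fraction Fraction of constitutive sites kept per run
#'   (default 0.68).
#' @param n_gained Number of gained sites kept per run (default: all).
#' @param seed Base seed; run `r` uses `seed + 100 * r` as its master
#'   seed.
#' @param ... Passed on to [run_discovery()].
#' @return A list of `dardn_report`s, one per run.
#' @export
run_robustness <- function(genome, gained, const, L, n_runs = 5L,
                           const_fraction = 0.68, n_gained = NULL,
                           seed = 1L, ...) {
  if (is.character(gained)) gained <- read_sites(gained, 1)
  if (is.character(const)) const <- read_sites(const, 0)
  lapply(seq_len(n_runs), function(r) {
    rs <- seed + 100L * r
    g <- if (is.null(n_gained)) gained
         else subsample_sites(gained, n = n_gained, seed = rs)
    b <- subsample_sites(const, fraction = const_fraction, seed = rs + 1L)
    run_discovery(genome, g, b, L, seed = rs + 2L, ...)
  })
}
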