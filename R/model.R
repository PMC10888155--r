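#' Model architecture settings
#'
#' The classifier is an ensemble of two convolutional branches with
#' distinct initial kernel sizes, applied in parallel to the same 4 x L
#' one-hot input.  Each branch stacks two same-padded 1-D convolutions
#' (ReLU activations) and carries a residual connection from the branch
#' input — projected by a width-1 convolution to match channel counts — to
#' the pre-activation of the second ReLU.  Branch outputs are globally
#' average-pooled (making the head independent of L), concatenated, and
#' passed through one fully connected hidden layer to two output logits
#' `o1` (constitutive) and `o2` (gained).
#'
#' The default kernel sizes 4 and 8 bp target motif-scale patterns: 8
#' matches the length of a full consensus such as RBPJ's `CCTGGGAA`, 4 its
#' shorter core fragments.
#'
#' @param kernel_a,kernel_b Kernel widths (bp) of the two branches; must
#'   differ (defaults 4 and 8).
#' @param channels Convolution channels per branch (default 32).
#' @param blocks_per_branch Convolution layers per branch; this
#'   implementation supports the two-layer residual block only.
#' @param pooling Pooling flavour; only `"average"` is supported (average
#'   pooling keeps every layer of the attribution path linear).
#' @param fc_hidden Width of the fully connected hidden layer (default 64).
#' @param seed Integer seed for weight initialization.
#' @return A list of class `dardn_model_config`.
#' @export
model_config <- function(kernel_a = 4L, kernel_b = 8L, channels = 32L,
                         blocks_per_branch = 2L, pooling = "average",
                         fc_hidden = 64L, seed = 1L) {
  stopifnot(kernel_a >= 1, kernel_b >= 1, kernel_a != kernel_b,
            channels >= 1, fc_hidden >= 1)
  if (!identical(as.integer(blocks_per_branch), 2L))
    stop("only blocks_per_branch = 2 (one residual block) is supported")
  pooling <- match.arg(pooling, "average")
  structure(list(kernel_a = as.integer(kernel_a),
                 kernel_b = as.integer(kernel_b),
                 channels = as.integer(channels),
                 blocks_per_branch = 2L, pooling = pooling,
                 fc_hidden = as.integer(fc_hidden),
                 seed = as.integer(seed)),
            class = "dardn_model_config")
}

#' @keywords internal
init_params <- function(config) {
  set.seed(config$seed)
  C <- config$channels
  H <- config$fc_hidden
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  list(W1a = he(C, 4L * config$kernel_a), b1a = numeric(C),
       W2a = he(C, C * config$kernel_a), b2a = numeric(C),
       Wpa = he(C, 4L),
       W1b = he(C, 4L * config$kernel_b), b1b = numeric(C),
       W2b = he(C, C * config$kernel_b), b2b = numeric(C),
       Wpb = he(C, 4L),
       W3 = he(H, 2L * C), b3 = numeric(H),
       W4 = he(2L, H), b4 = numeric(2L))
}

#' Build an untrained classifier
#'
#' Instantiates the dual-branch residual CNN with deterministically seeded
#' weights (He-scaled Gaussians, zero biases).  The parameter count is
#' independent of sequence length, so one model can score sequences of any
#' length not shorter than the larger kernel.
#'
#' @param config A [model_config()].
#' @return An object of class `dardn_model` (list with `params`, `config`,
#'   and `NULL` `history`).
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "dardn_model_config"))
  structure(list(params = init_params(config), config = config,
                 history = NULL), class = "dardn_model")
}

#' @export
print.dardn_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("dual-kernel residual CNN (kernels %d/%d, %d channels, fc %d): %d parameters\n",
              cfg$kernel_a, cfg$kernel_b, cfg$channels, cfg$fc_hidden, n_par))
  if (!is.null(x$history)) {
    cat(sprintf("trained %d epoch(s); best val MCC %.3f\n",
                nrow(x$history), max(x$history$val_mcc, na.rm = TRUE)))
  }
  invisible(x)
}

#' @keywords internal
as_onehot_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (is.list(x)) {
    stopifnot(length(x) > 0)
    x <- array(unlist(x), dim = c(4L, ncol(x[[1L]]), length(x)))
  }
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[1] == 4)
  x
}

#' Predict gained-site probabilities
#'
#' Runs the forward pass and maps the two logits to the gained-site
#' probability `p = softmax(o1, o2)[2]`; the predicted label is 1 whenever
#' `p >= 0.5`.
#'
#' @param object A `dardn_model`.
#' @param x One-hot input: a `4 x L x n` array, a single 4 x L matrix, or
#'   a list of matrices.
#' @param ... Unused.
#' @return A `data.frame` with columns `o1`, `o2`, `p`, `predicted_label`.
#' @export
predict.dardn_model <- function(object, x, ...) {
  x <- as_onehot_array(x)
  kmax <- max(object$config$kernel_a, object$config$kernel_b)
  if (dim(x)[2] < kmax) {
    stop("sequence length ", dim(x)[2], " is shorter than the largest kernel (",
         kmax, ")")
  }
  o <- cpp_forward_logits(object$params, x)
  p <- 1 / (1 + exp(o[, 1] - o[, 2]))
  data.frame(o1 = o[, 1], o2 = o[, 2], p = p,
             predicted_label = as.integer(p >= 0.5))
}

#' Binary cross-entropy loss
#'
#' Mean over records of `-(y log p + (1 - y) log(1 - p))`, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p Predicted gained-site probabilities.
#' @param y True labels in `{0, 1}`.
#' @return A single non-negative number.
#' @examples
#' bce_loss(0.5, 1)  # log(2)
#' @export
bce_loss <- function(p, y) {
  if (length(p) != length(y)) stop("`p` and `y` must have equal length")
  stopifnot(all(y %in% c(0, 1)))
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Confusion counts for binary predictions
#'
#' @param predicted,truth Label vectors in `{0, 1}` of equal length.
#' @return A list of class `dardn_confusion` with fields `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` must have equal length")
  stopifnot(all(predicted %in% c(0, 1)), all(truth %in% c(0, 1)))
  structure(list(TP = sum(predicted == 1 & truth == 1),
                 TN = sum(predicted == 0 & truth == 0),
                 FP = sum(predicted == 1 & truth == 0),
                 FN = sum(predicted == 0 & truth == 1)),
            class = "dardn_confusion")
}

#' @export
print.dardn_confusion <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d  (MCC %.3f)\n",
              x$TP, x$TN, x$FP, x$FN, mcc(x)))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`;
#' +1 for perfect prediction, -1 for total disagreement.  When any marginal
#' factor of the denominator is zero the coefficient is defined as 0 (the
#' value for an uninformative predictor).
#'
#' @param tp Either a `dardn_confusion` object or the TP count.
#' @param tn,fp,fn Remaining counts when `tp` is numeric.
#' @return A single number in `[-1, 1]`.
#' @examples
#' mcc(76, 5108, 2, 21)
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(tp, "dardn_confusion") || is.list(tp)) {
    c0 <- tp
    tp <- c0$TP; tn <- c0$TN; fp <- c0$FP; fn <- c0$FN
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Training settings
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 16).
#' @param max_epochs Upper bound on epochs (default 30; 0 returns the
#'   model unchanged).
#' @param early_stop_patience Stop after this many epochs without
#'   improvement in validation MCC (default 6); ignored when no validation
#'   data is supplied.
#' @param class_balance `"none"` (default: plain shuffled batches; class
#'   imbalance is expected to be handled upstream by augmentation, and the
#'   natural class prior keeps the 0.5 decision threshold calibrated),
#'   `"balanced_batches"` (each mini-batch drawn half-and-half from the two
#'   classes, recycling the minority), or `"weighted"` (per-sample loss
#'   weights inversely proportional to class frequency).
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to
#'   weight matrices, not biases (default 1e-3; regularizes the sparse
#'   motif detectors toward sharp, exact matches).
#' @param lr_decay Multiplicative step decay of the learning rate (default
#'   0.5; 1 disables decay).
#' @param lr_decay_every Epochs between decay steps (default 6).
#' @param perfect_stop_loss Stop as soon as validation MCC reaches 1 and
#'   the epoch's training loss is at or below this value (`NA`, the
#'   default, disables: under weight decay the later, sharper checkpoint
#'   generalizes measurably better than the first validation-perfect one,
#'   and the patience rule already bounds the extra epochs).
#' @param seed Integer seed for batch shuffling.
#' @return A list of class `dardn_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16L,
                         max_epochs = 30L, early_stop_patience = 6L,
                         class_balance = c("none", "balanced_batches",
                                           "weighted"),
                         weight_decay = 1e-3, lr_decay = 0.5,
                         lr_decay_every = 6L,
                         perfect_stop_loss = NA, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 0,
            early_stop_patience >= 1, weight_decay >= 0, lr_decay > 0,
            lr_decay <= 1, lr_decay_every >= 1)
  class_balance <- match.arg(class_balance)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 class_balance = class_balance,
                 weight_decay = weight_decay, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 perfect_stop_loss = perfect_stop_loss,
                 seed = as.integer(seed)),
            class = "dardn_train_config")
}

#' @keywords internal
make_batches <- function(y, batch_size, class_balance) {
  n <- length(y)
  if (class_balance == "balanced_batches") {
    pos <- which(y == 1)
    neg <- which(y == 0)
    recycle <- function(idx, total) {
      out <- integer(0)
      while (length(out) < total) out <- c(out, sample(idx))
      out[seq_len(total)]
    }
    nb <- ceiling(n / batch_size)
    bp <- ceiling(batch_size / 2)
    bn <- batch_size - bp
    ps <- recycle(pos, nb * bp)
    ns <- recycle(neg, nb * bn)
    lapply(seq_len(nb), function(b) {
      c(ps[((b - 1) * bp + 1):(b * bp)], ns[((b - 1) * bn + 1):(b * bn)])
    })
  } else {
    ord <- sample(n)
    split(ord, ceiling(seq_along(ord) / batch_size))
  }
}

#' Train the classifier
#'
#' Minimizes binary cross-entropy with Adam.  When validation data is
#' given, per-epoch validation loss and MCC are recorded, the parameters
#' from the best validation epoch (highest MCC; ties resolved toward lower
#' validation loss) are kept, and training stops early after
#' `early_stop_patience` epochs without an MCC improvement.
#'
#' @param model A `dardn_model` from [build_model()].
#' @param x Training one-hot array (`4 x L x n`).
#' @param y Training labels in `{0, 1}` (both classes required).
#' @param val_x,val_y Optional validation data.
#' @param config A [train_config()].
#' @return The trained `dardn_model`; `$history` holds a `data.frame` with
#'   per-epoch `train_loss`, `val_loss` and `val_mcc`.
#' @export
dardn_train <- function(model, x, y, val_x = NULL, val_y = NULL,
                        config = train_config()) {
  stopifnot(inherits(model, "dardn_model"),
            inherits(config, "dardn_train_config"))
  x <- as_onehot_array(x)
  stopifnot(dim(x)[3] == length(y), all(y %in% c(0, 1)))
  if (config$max_epochs > 0 && (sum(y == 1) == 0 || sum(y == 0) == 0))
    stop("training data must contain both classes")
  kmax <- max(model$config$kernel_a, model$config$kernel_b)
  if (dim(x)[2] < kmax)
    stop("sequence length shorter than the largest kernel")
  has_val <- !is.null(val_x) && !is.null(val_y)
  if (has_val) val_x <- as_onehot_array(val_x)

  n <- length(y)
  wts <- rep(1, n)
  if (config$class_balance == "weighted") {
    wts[y == 1] <- n / (2 * sum(y == 1))
    wts[y == 0] <- n / (2 * sum(y == 0))
  }

  params <- model$params
  zeros <- lapply(params, function(p) p * 0)
  m <- zeros
  v <- zeros
  t_step <- 0L
  history <- NULL
  best <- list(params = params, mcc = -Inf, loss = Inf, epoch = 0L)
  wait <- 0L
  set.seed(config$seed)

  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$learning_rate *
      config$lr_decay^((epoch - 1) %/% config$lr_decay_every)
    batches <- make_batches(y, config$batch_size, config$class_balance)
    res <- cpp_train_epoch(params, m, v, t_step, x, y, wts, batches,
                           lr, 0.9, 0.999, 1e-8, config$weight_decay)
    params <- res$params
    m <- res$m
    v <- res$v
    t_step <- res$t
    if (!is.finite(res$loss)) {
      stop(sprintf("training diverged at epoch %d (last finite epoch: %d)",
                   epoch, epoch - 1L))
    }
    val_loss <- NA_real_
    val_mcc <- NA_real_
    if (has_val) {
      tmp_model <- structure(list(params = params, config = model$config),
                             class = "dardn_model")
      pr <- predict(tmp_model, val_x)
      val_loss <- bce_loss(pr$p, val_y)
      val_mcc <- mcc(confusion_counts(pr$predicted_label, val_y))
      improved_mcc <- val_mcc > best$mcc + 1e-12
      improved_tie <- abs(val_mcc - best$mcc) <= 1e-12 && val_loss < best$loss
      if (improved_mcc || improved_tie) {
        best$params <- params
        best$loss <- val_loss
        best$epoch <- epoch
      }
      if (improved_mcc) {
        best$mcc <- val_mcc
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = res$loss,
                                val_loss = val_loss, val_mcc = val_mcc))
    if (has_val && wait >= config$early_stop_patience) break
    if (has_val && !is.na(config$perfect_stop_loss) &&
        isTRUE(val_mcc == 1) && res$loss <= config$perfect_stop_loss) break
  }

  model$params <- if (has_val && best$epoch > 0L) best$params else params
  model$history <- history
  model$train_config <- config
  model
}

#' Save and restore a trained model
#'
#' The checkpoint embeds the architecture configuration, the parameters
#' and the training history.
#'
#' @param model A `dardn_model`.
#' @param path Checkpoint file path (RDS format).
#' @return `write_model` invisibly returns `path`; `read_model` returns
#'   the restored `dardn_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "dardn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dardn_model")) stop("not a dardn model checkpoint")
  model
}
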