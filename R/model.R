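#' Model configuration
#'
#' Hyperparameters of the deep bidirectional LSTM site classifier. The
#' architecture follows the published design - four bidirectional LSTM
#' layers feeding a fully connected dense layer and a single sigmoid output
#' unit, trained with class-weighted binary cross-entropy, a very large
#' epoch budget and early stopping on validation F1 (decision threshold
#' 0.5) with a patience of 20 epochs. Hidden sizes, learning rate and batch
#' size are not fixed by that design and default to values suitable for
#' CPU-scale training.
#'
#' @param n_bilstm_layers Number of bidirectional LSTM layers (default 4).
#' @param hidden_units LSTM units per direction per layer (default 64).
#' @param dense_units Units in the fully connected layer (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 256).
#' @param max_epochs Epoch ceiling (default 10000; early stopping normally
#'   halts far sooner).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param class_weighting `"balanced"` (weight class c by `N / (2 * N_c)`)
#'   or `"none"`.
#' @param seed Seed for weight initialization and minibatch shuffling.
#' @param clip_norm Global gradient-norm clip (default 5; 0 disables).
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_bilstm_layers = 4L, hidden_units = 64L,
                         dense_units = 32L, learning_rate = 1e-3,
                         batch_size = 256L, max_epochs = 10000L,
                         patience = 20L,
                         class_weighting = c("balanced", "none"),
                         seed = 1L, clip_norm = 5) {
  class_weighting <- match.arg(class_weighting)
  stopifnot(n_bilstm_layers >= 1L, hidden_units >= 1L, dense_units >= 1L,
            learning_rate > 0, batch_size >= 1L, max_epochs >= 0L,
            patience >= 1L)
  structure(list(n_bilstm_layers = as.integer(n_bilstm_layers),
                 hidden_units = as.integer(hidden_units),
                 dense_units = as.integer(dense_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_metric = "f1",
                 patience = as.integer(patience),
                 class_weighting = class_weighting,
                 seed = as.integer(seed), clip_norm = clip_norm),
            class = "model_config")
}

#' Protein-level train/test/validate split
#'
#' Shuffles protein identifiers with a seeded generator and assigns
#' `floor(f_test * n)` to test, `floor(f_validate * n)` to validate, and the
#' remainder to train, so every window of one protein lands in exactly one
#' partition and the three partitions come from independent proteins.
#'
#' @param protein_ids Character vector of protein identifiers (>= 3).
#' @param seed Integer seed.
#' @param fractions Numeric triple `(train, test, validate)` summing to 1;
#'   default `c(0.70, 0.15, 0.15)`.
#' @return An object of class `split_assignment`: list with `assignment`
#'   (named character vector id -> `"train"|"test"|"validate"`), `seed`,
#'   `fractions`.
#' @examples
#' sp <- split_proteins(sprintf("P%02d", 1:20), seed = 1)
#' table(sp$assignment)  # 14 train / 3 test / 3 validate
#' @export
split_proteins <- function(protein_ids, seed,
                           fractions = c(train = 0.70, test = 0.15, validate = 0.15)) {
  n <- length(protein_ids)
  if (n < 3L) stop("need at least 3 proteins to split")
  if (anyDuplicated(protein_ids)) stop("duplicate protein ids")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  shuffled <- with_seed(seed, sample(protein_ids))
  n_test <- floor(fractions[[2L]] * n)
  n_val <- floor(fractions[[3L]] * n)
  part <- rep("train", n)
  if (n_test > 0L) part[seq_len(n_test)] <- "test"
  if (n_val > 0L) part[n_test + seq_len(n_val)] <- "validate"
  assignment <- stats::setNames(part, shuffled)[protein_ids]
  structure(list(assignment = assignment, seed = as.integer(seed),
                 fractions = fractions),
            class = "split_assignment")
}

#' @rdname split_proteins
#' @param split A `split_assignment`.
#' @param partition `"train"`, `"test"` or `"validate"`.
#' @return `partition_ids()`: the protein ids in that partition.
#' @export
partition_ids <- function(split, partition) {
  names(split$assignment)[split$assignment == partition]
}

#' Class weights for imbalanced site labels
#'
#' Cleavage sites are vastly outnumbered by non-sites; the balanced scheme
#' weights class `c` by `N / (2 * N_c)` so the classifier pays more
#' attention to the underrepresented positive class.
#'
#' @param labels 0/1 integer labels.
#' @param scheme `"balanced"` or `"none"`.
#' @return Named numeric vector `c(negative = w0, positive = w1)`.
#' @examples
#' class_weights(rep(c(1, 0), c(100, 900)))  # positive 5, negative ~0.556
#' @export
class_weights <- function(labels, scheme = c("balanced", "none")) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(c(negative = 1, positive = 1))
  n <- length(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- n - n_pos
  if (n_pos == 0L) stop("class absent: positive (no cleavage sites in labels)")
  if (n_neg == 0L) stop("class absent: negative (no non-sites in labels)")
  c(negative = n / (2 * n_neg), positive = n / (2 * n_pos))
}

# Glorot-uniform initial parameters for the full network; forget-gate
# biases start at 1 (standard LSTM practice)
init_params <- function(config, input_dim = N_FEATURES) {
  H <- config$hidden_units
  D <- config$dense_units
  glorot <- function(nr, nc) {
    s <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -s, s), nr, nc)
  }
  lstm_dir <- function(in_dim) {
    b <- matrix(0, 1L, 4L * H)
    b[1L, (H + 1L):(2L * H)] <- 1
    list(W = glorot(in_dim, 4L * H), U = glorot(H, 4L * H), b = b)
  }
  with_seed(config$seed, {
    layers <- lapply(seq_len(config$n_bilstm_layers), function(l) {
      in_dim <- if (l == 1L) input_dim else 2L * H
      list(fw = lstm_dir(in_dim), bw = lstm_dir(in_dim))
    })
    list(layers = layers,
         dense = list(W = glorot(2L * H, D), b = matrix(0, 1L, D)),
         out = list(W = glorot(D, 1L), b = matrix(0, 1L, 1L)))
  })
}

# windows array (n, 8, 30) -> cube (n, 30, 8) expected by the C++ core
windows_to_cube <- function(x) aperm(x, c(1L, 3L, 2L))

#' Train the bidirectional LSTM site classifier
#'
#' Trains on the windows of the `train` partition with class-weighted
#' binary cross-entropy and Adam, monitoring F1 (at decision threshold 0.5)
#' on the `validate` partition after every epoch. Training halts when
#' validation F1 has not improved for `patience` epochs or at `max_epochs`;
#' the returned parameters are those of the best-F1 epoch, and the training
#' log records every epoch.
#'
#' @param windows An `encoded_windows` object covering at least the train
#'   and validate partitions.
#' @param split A [split_proteins()] assignment.
#' @param config A [model_config()].
#' @param init Optional initial parameter list (used by [transfer_model()]).
#' @param freeze_layers Number of bottom bidirectional layers excluded from
#'   updates (default 0).
#' @param protease Optional protease identifier recorded on the model.
#' @param provenance `"direct"`, `"generic"` or `"transferred"`.
#' @return An object of class `trained_brnn`: `params`, `config`,
#'   `training_log` (epoch, train_loss, val_f1), `best_epoch`,
#'   `best_val_f1`, `provenance`, `protease`, `freeze_layers`.
#' @export
train_brnn <- function(windows, split, config, init = NULL, freeze_layers = 0L,
                       protease = NULL, provenance = "direct") {
  stopifnot(inherits(windows, "encoded_windows"),
            inherits(split, "split_assignment"),
            inherits(config, "model_config"))
  part <- split$assignment[windows$protein_id]
  tr <- which(part == "train")
  va <- which(part == "validate")
  if (length(tr) == 0L || length(va) == 0L) {
    stop("windows must cover both the train and validate partitions")
  }
  y_tr <- windows$label[tr]
  if (length(unique(y_tr)) < 2L) {
    stop("degenerate training set: only one class present")
  }
  cw <- class_weights(y_tr, config$class_weighting)
  w_tr <- ifelse(y_tr == 1L, cw[["positive"]], cw[["negative"]])
  params <- init %||% init_params(config, input_dim = dim(windows$x)[3L])
  fit <- .lstm_fit(params,
                   windows_to_cube(windows$x[tr, , , drop = FALSE]),
                   as.numeric(y_tr), as.numeric(w_tr),
                   windows_to_cube(windows$x[va, , , drop = FALSE]),
                   as.numeric(windows$label[va]),
                   config$batch_size, config$learning_rate,
                   config$max_epochs, config$patience,
                   as.integer(freeze_layers), config$seed, config$clip_norm)
  structure(list(protease = protease, params = fit$params, config = config,
                 provenance = provenance, freeze_layers = as.integer(freeze_layers),
                 training_log = as.data.frame(fit$log),
                 best_epoch = fit$best_epoch, best_val_f1 = fit$best_val_f1,
                 class_weights = cw, input_dim = dim(windows$x)[3L]),
            class = "trained_brnn")
}

#' @export
print.trained_brnn <- function(x, ...) {
  cat("<trained_brnn>", x$provenance,
      if (!is.null(x$protease)) paste0("model for ", x$protease),
      "| layers:", x$config$n_bilstm_layers, "x", x$config$hidden_units,
      "| epochs:", nrow(x$training_log),
      "| best val F1:", format(x$best_val_f1, digits = 4), "\n")
  invisible(x)
}

#' Pretrain a group-generic model
#'
#' Trains on windows pooled over all proteases of one registry group (see
#' [encode_group()]): a site is positive when any group member cleaves it.
#' The result seeds protease-specific models via [transfer_model()].
#'
#' @inheritParams train_brnn
#' @param group Group tag recorded on the model.
#' @return A `trained_brnn` with `provenance = "generic"`.
#' @export
pretrain_generic <- function(windows, split, config, group = NULL) {
  train_brnn(windows, split, config, protease = group, provenance = "generic")
}

#' Transfer a generic model to one protease
#'
#' Initializes from the generic model's weights, freezes the bottom
#' `freeze_layers` bidirectional layers (their parameters are bit-identical
#' before and after fine-tuning) and continues training on the
#' protease-specific windows. With `max_epochs = 0` in `config` the output
#' model equals the generic model.
#'
#' @param generic A `trained_brnn` with matching input dimensionality.
#' @param windows Protease-specific `encoded_windows`.
#' @param split A [split_proteins()] assignment.
#' @param config A [model_config()] for fine-tuning.
#' @param freeze_layers Bottom bidirectional layers to freeze (default 1).
#' @param protease Protease identifier recorded on the model.
#' @return A `trained_brnn` with `provenance = "transferred"`.
#' @export
transfer_model <- function(generic, windows, split, config, freeze_layers = 1L,
                           protease = NULL) {
  stopifnot(inherits(generic, "trained_brnn"))
  if (generic$input_dim != dim(windows$x)[3L]) {
    stop("input dimensionality mismatch between generic model (",
         generic$input_dim, ") and windows (", dim(windows$x)[3L], ")")
  }
  if (config$max_epochs == 0L) {
    m <- generic
    m$provenance <- "transferred"
    m$protease <- protease
    m$freeze_layers <- as.integer(freeze_layers)
    m$training_log <- m$training_log[0, ]
    return(m)
  }
  train_brnn(windows, split, config, init = generic$params,
             freeze_layers = freeze_layers, protease = protease,
             provenance = "transferred")
}

#' Train an ensemble of site classifiers
#'
#' Trains `k` members on identical data and configuration, differing only
#' in seed (`config$seed + 0 .. k - 1`, which changes weight initialization
#' and minibatch shuffling). When `generic` is given each member is
#' fine-tuned from it with [transfer_model()]; otherwise members are trained
#' from scratch. The ensemble prediction is the arithmetic mean of member
#' sigmoid outputs.
#'
#' @inheritParams train_brnn
#' @param k Number of members (default 5).
#' @param generic Optional generic `trained_brnn` to transfer from.
#' @param freeze_layers Frozen bottom layers when transferring (default 1).
#' @return An object of class `brnn_ensemble`.
#' @export
train_ensemble <- function(windows, split, config, k = 5L, generic = NULL,
                           freeze_layers = 1L, protease = NULL) {
  stopifnot(k >= 1L)
  members <- lapply(seq_len(k), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    if (is.null(generic)) {
      train_brnn(windows, split, cfg, protease = protease)
    } else {
      transfer_model(generic, windows, split, cfg,
                     freeze_layers = freeze_layers, protease = protease)
    }
  })
  structure(list(members = members, k = as.integer(k), protease = protease),
            class = "brnn_ensemble")
}

#' @export
print.brnn_ensemble <- function(x, ...) {
  cat("<brnn_ensemble>", x$k, "member(s)",
      if (!is.null(x$protease)) paste0("for ", x$protease), "\n")
  invisible(x)
}

#' Score encoded windows with a model or ensemble
#'
#' @param model A `trained_brnn` or `brnn_ensemble`.
#' @param windows An `encoded_windows` object.
#' @return Numeric vector of sigmoid scores in \[0, 1\] (ensemble: mean over
#'   members).
#' @export
predict_windows <- function(model, windows) {
  xc <- windows_to_cube(windows$x)
  if (inherits(model, "trained_brnn")) {
    return(as.numeric(.lstm_predict(model$params, xc)))
  }
  stopifnot(inherits(model, "brnn_ensemble"))
  s <- vapply(model$members, function(m) as.numeric(.lstm_predict(m$params, xc)),
              numeric(length(windows$label)))
  if (length(windows$label) == 1L) mean(s) else rowMeans(matrix(s, ncol = model$k))
}

#' Predict cleavage sites for one protein
#'
#' Scores every candidate site of the protein with the ensemble (arithmetic
#' mean of member sigmoid outputs).
#'
#' @param model A `brnn_ensemble` or `trained_brnn`.
#' @param protein A [protein_record()] with `L >= 2`.
#' @param provider Feature provider used for encoding.
#' @return Annotation `data.frame` with one row per candidate P1
#'   (`source = "prediction"`, `score` in \[0, 1\]).
#' @export
predict_sites <- function(model, protein, provider = zero_provider()) {
  if (protein$length < 2L) stop("protein must have at least 2 residues")
  enc <- encode_windows(list(protein),
                        data.frame(protein_id = character(0), p1 = integer(0)),
                        provider)
  prot <- if (inherits(model, "brnn_ensemble")) model$protease else model$protease
  data.frame(protease = prot %||% NA_character_, protein_id = protein$id,
             p1 = enc$p1, source = "prediction",
             score = predict_windows(model, enc), stringsAsFactors = FALSE)
}
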