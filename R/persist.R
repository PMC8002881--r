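# Plain-text persistence for trained models: a model directory holds
# config.json, weights.json (every matrix as {dim, data}) and
# training_log.tsv; an ensemble directory holds member_1/ .. member_k/.

params_to_plain <- function(params) {
  enc <- function(m) list(dim = dim(m), data = as.numeric(m))
  list(layers = lapply(params$layers, function(l) {
    list(fw = lapply(l$fw, enc), bw = lapply(l$bw, enc))
  }),
  dense = lapply(params$dense, enc),
  out = lapply(params$out, enc))
}

params_from_plain <- function(plain) {
  dec <- function(e) matrix(unlist(e$data), unlist(e$dim)[1L], unlist(e$dim)[2L])
  list(layers = lapply(plain$layers, function(l) {
    list(fw = lapply(l$fw, dec), bw = lapply(l$bw, dec))
  }),
  dense = lapply(plain$dense, dec),
  out = lapply(plain$out, dec))
}

#' Save / load a trained model or ensemble
#'
#' Models are stored as plain text: `config.json`, `weights.json` (full
#' double precision) and `training_log.tsv`; ensembles as one subdirectory
#' per member plus an `ensemble.json` manifest.
#'
#' @param model A `trained_brnn` or `brnn_ensemble`.
#' @param dir Directory to write (created if needed).
#' @return `save_model()`: `dir` invisibly; `load_model()` /
#'   `load_ensemble()`: the restored object.
#' @export
save_model <- function(model, dir) {
  if (inherits(model, "brnn_ensemble")) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(k = model$k, protease = model$protease),
                         file.path(dir, "ensemble.json"), auto_unbox = TRUE)
    for (i in seq_len(model$k)) {
      save_model(model$members[[i]], file.path(dir, sprintf("member_%d", i)))
    }
    return(invisible(dir))
  }
  stopifnot(inherits(model, "trained_brnn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(protease = model$protease, provenance = model$provenance,
               freeze_layers = model$freeze_layers,
               best_epoch = model$best_epoch, best_val_f1 = model$best_val_f1,
               input_dim = model$input_dim, config = unclass(model$config))
  jsonlite::write_json(meta, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(params_to_plain(model$params),
                       file.path(dir, "weights.json"), digits = NA)
  write.table(model$training_log, file.path(dir, "training_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"))
  cfg <- do.call(model_config, meta$config[setdiff(names(meta$config),
                                                   "early_stop_metric")])
  log <- read.delim(file.path(dir, "training_log.tsv"))
  structure(list(protease = meta$protease %||% NULL,
                 params = params_from_plain(
                   jsonlite::read_json(file.path(dir, "weights.json"))),
                 config = cfg, provenance = meta$provenance,
                 freeze_layers = as.integer(meta$freeze_layers),
                 training_log = log, best_epoch = meta$best_epoch,
                 best_val_f1 = meta$best_val_f1,
                 input_dim = as.integer(meta$input_dim)),
            class = "trained_brnn")
}

#' @rdname save_model
#' @export
load_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "ensemble.json"))
  members <- lapply(seq_len(man$k), function(i) {
    load_model(file.path(dir, sprintf("member_%d", i)))
  })
  structure(list(members = members, k = as.integer(man$k),
                 protease = man$protease %||% NULL),
            class = "brnn_ensemble")
}
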