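#' Training configuration
#'
#' Tiny-scale defaults chosen for from-scratch training on synthetic
#' corpora: AdamW with learning rate 2e-3, small batches, and a 10%
#' held-out split for best-epoch checkpoint selection by held-out accuracy
#' (equivalently micro-F1).
#'
#' @param lr Learning rate.
#' @param batch_size Instances per AdamW step (gradients are averaged).
#' @param epochs Number of passes over the training instances.
#' @param weight_decay Decoupled weight decay.
#' @param seed Seed governing data shuffling and parameter initialization.
#' @param scheme Label scheme name the instances must follow.
#' @param entity_masking Whether instances were generated with entity
#'   masking (bookkeeping; masking happens at instance generation).
#' @param model One of `"encoder"`, `"bert_gat"`, `"t5_slim_dec"`,
#'   `"t5_ar_dec"`.
#' @param holdout_fraction Fraction of sentences held out for epoch
#'   selection (0 disables selection; the final epoch is kept).
#' @param early_stop_accuracy Stop once held-out accuracy reaches this
#'   value (1 = only on a perfect epoch; `Inf` never stops early).
#' @param lr_decay_epoch Epoch at which the learning rate is multiplied by
#'   `lr_decay_factor` (`Inf` disables the step decay).
#' @param lr_decay_factor Step decay multiplier.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 2e-3, batch_size = 4L, epochs = 25L,
                         weight_decay = 0.01, seed = 0L, scheme = "ddi5",
                         entity_masking = TRUE,
                         model = c("encoder", "bert_gat", "t5_slim_dec", "t5_ar_dec"),
                         holdout_fraction = 0.1, early_stop_accuracy = 1,
                         lr_decay_epoch = Inf, lr_decay_factor = 0.3) {
  model <- match.arg(model)
  stopifnot(lr > 0, batch_size >= 1L, epochs >= 1L, weight_decay >= 0,
            holdout_fraction >= 0, holdout_fraction < 1)
  structure(
    list(lr = lr, batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         weight_decay = weight_decay, seed = as.integer(seed), scheme = scheme,
         entity_masking = isTRUE(entity_masking), model = model,
         holdout_fraction = holdout_fraction,
         early_stop_accuracy = early_stop_accuracy,
         lr_decay_epoch = lr_decay_epoch, lr_decay_factor = lr_decay_factor),
    class = "train_config"
  )
}

#' Prepare instances for the neural models
#'
#' Encodes each instance's marked text with the tokenizer and, when parses
#' are given, builds the model-token adjacency matrix by constructing the
#' word-level dependency adjacency and projecting it through the
#' word-to-subword alignment (markers and sequence start/end tokens become
#' special positions with self-loops only). Instances are joined to parses
#' by sentence id.
#'
#' @param instances List of [relation_instance()] objects.
#' @param tokenizer A [build_tokenizer()].
#' @param parses Optional named list of [dependency_parse()] objects keyed
#'   by sentence id.
#' @return List of examples: `ids`, `A` (or `NULL`), `label`, `sentence_id`.
#' @export
prepare_dataset <- function(instances, tokenizer, parses = NULL) {
  lapply(instances, function(inst) {
    enc <- encode_text(tokenizer, inst$marked_text)
    A <- NULL
    if (!is.null(parses)) {
      parse <- parses[[inst$sentence_id]]
      if (is.null(parse)) stop("no dependency parse for sentence '", inst$sentence_id, "'")
      if (length(parse$tokens) != length(enc$words)) {
        stop("parse/instance token count mismatch for sentence '", inst$sentence_id,
             "': ", length(parse$tokens), " vs ", length(enc$words))
      }
      A <- project_to_subwords(build_word_adjacency(parse), enc$alignment)
    }
    list(ids = enc$ids, A = A, label = inst$label, sentence_id = inst$sentence_id)
  })
}

# Identity adjacency of matching size for the no-graph ablation.
identity_adjacency <- function(dataset) {
  lapply(dataset, function(ex) { ex$A <- diag(1, length(ex$ids)); ex })
}

#' Train a relation classification model
#'
#' Seeded AdamW with the cross-entropy loss; the autoregressive baseline
#' decoder is trained with teacher forcing. Per-epoch mean training loss is
#' logged and the best epoch by held-out accuracy is kept.
#'
#' @param model_config An [encoder_config()] (its seed is overridden by the
#'   training seed for full determinism).
#' @param dataset Examples from [prepare_dataset()].
#' @param labels Ordered label vocabulary.
#' @param config A [train_config()].
#' @param vocab_size Tokenizer vocabulary size.
#' @param gat_config A [gat_config()] for the `bert_gat` model.
#' @param pool Pooling for the encoder-classifier heads.
#' @return A `deprex_fit` list: `model` (best checkpoint), `log` (data
#'   frame of epoch, loss, holdout accuracy), `config`.
#' @export
train <- function(model_config, dataset, labels, config, vocab_size,
                  gat_config = NULL, pool = "mean") {
  if (length(dataset) == 0L) stop("cannot train on an empty instance set")
  bad <- setdiff(vapply(dataset, `[[`, "", "label"), labels)
  if (length(bad)) {
    ids <- vapply(dataset, `[[`, "", "sentence_id")[vapply(dataset, `[[`, "", "label") %in% bad]
    stop("label(s) outside the scheme: ", paste(unique(bad), collapse = ", "),
         " (e.g. instance of sentence '", ids[1], "')")
  }
  model_config$seed <- config$seed
  model <- new_model(config$model, model_config, vocab_size, labels,
                     gat_config = gat_config, pool = pool)
  set.seed(config$seed + 1L)
  n <- length(dataset)
  # hold out whole sentences, not instances: instances of one sentence share
  # its context, so an instance-level split leaks and rewards memorization
  sids <- vapply(dataset, `[[`, "", "sentence_id")
  uniq_sid <- unique(sids)
  n_hold_sent <- floor(config$holdout_fraction * length(uniq_sid))
  hold_sids <- if (n_hold_sent > 0L) sample(uniq_sid, n_hold_sent) else character()
  hold_idx <- which(sids %in% hold_sids)
  train_idx <- setdiff(seq_len(n), hold_idx)
  if (!length(train_idx)) stop("holdout fraction leaves no training instances")
  y <- match(vapply(dataset, `[[`, "", "label"), labels)
  opt <- adamw_init(model$params, lr = config$lr, weight_decay = config$weight_decay)
  log <- data.frame(epoch = integer(), loss = numeric(), holdout_accuracy = numeric())
  best <- list(acc = -1, params = model$params)
  for (ep in seq_len(config$epochs)) {
    if (ep == config$lr_decay_epoch) opt$lr <- opt$lr * config$lr_decay_factor
    ord <- sample(train_idx)
    total_loss <- 0
    b <- 1L
    while (b <= length(ord)) {
      batch <- ord[seq(b, min(b + config$batch_size - 1L, length(ord)))]
      gsum <- NULL
      for (i in batch) {
        ex <- dataset[[i]]
        lg <- model_loss_grads(model, ex$ids, ex$A, y[i], train = TRUE)
        total_loss <- total_loss + lg$loss
        gsum <- if (is.null(gsum)) lg$grads else tree_add(gsum, lg$grads)
      }
      step <- adamw_step(model$params, tree_scale(gsum, 1 / length(batch)), opt)
      model$params <- step$params
      opt <- step$state
      b <- b + config$batch_size
    }
    acc <- if (length(hold_idx)) {
      preds <- vapply(hold_idx, function(i) {
        model_predict_label(model, dataset[[i]]$ids, dataset[[i]]$A)
      }, character(1))
      mean(preds == vapply(dataset[hold_idx], `[[`, "", "label"))
    } else {
      NA_real_
    }
    log <- rbind(log, data.frame(epoch = ep, loss = total_loss / length(ord),
                                 holdout_accuracy = acc))
    if (is.na(acc) || acc >= best$acc) {
      best <- list(acc = acc, params = model$params)
    }
    if (!is.na(acc) && acc >= config$early_stop_accuracy && ep >= 2L) break
  }
  model$params <- best$params
  structure(list(model = model, log = log, config = config), class = "deprex_fit")
}

#' @export
print.deprex_fit <- function(x, ...) {
  cat("<deprex_fit ", x$model$kind, ">: ", nrow(x$log), " epoch(s), final loss ",
      signif(utils::tail(x$log$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Predict labels for prepared examples
#'
#' @param fit A [train()] fit (or a bare `deprex_model`).
#' @param dataset Examples from [prepare_dataset()].
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(fit, dataset) {
  model <- if (inherits(fit, "deprex_fit")) fit$model else fit
  vapply(dataset, function(ex) model_predict_label(model, ex$ids, ex$A), character(1))
}

# ---- checkpoint serialization (plain text: JSON) -----------------------

# Flatten a parameter tree into path-addressed leaves. Positional list
# components are encoded as their (character) index; parameter names are
# never purely numeric, so the encoding is unambiguous.
flatten_leaves <- function(x, path = character()) {
  if (is.list(x)) {
    nms <- names(x)
    out <- list()
    for (i in seq_along(x)) {
      comp <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, flatten_leaves(x[[i]], c(path, comp)))
    }
    out
  } else {
    list(list(path = as.list(path), dim = as.list(dim(x)), values = as.numeric(x)))
  }
}

assign_leaf <- function(tree, comps, value) {
  k <- comps[[1]]
  key <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
  if (length(comps) == 1L) {
    tree[[key]] <- value
  } else {
    tree[[key]] <- assign_leaf(tree[[key]], comps[-1], value)
  }
  tree
}

#' Save a model checkpoint
#'
#' Writes `config.json` (architecture and label vocabulary) and
#' `params.json` (every tensor as a path-addressed flat array with its
#' dimensions, full precision) into `dir`.
#'
#' @param model A `deprex_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(
    kind = model$kind, labels = model$labels, pool = model$pool,
    vocab_size = model$vocab_size,
    config = unclass(model$config),
    gat_config = if (!is.null(model$gat_config)) unclass(model$gat_config)
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(flatten_leaves(model$params), file.path(dir, "params.json"),
                       digits = NA)
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Directory written by [save_model()].
#' @return A `deprex_model`.
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  leaves <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = FALSE)
  ec <- do.call(encoder_config, cfg$config[c("d_model", "n_heads", "d_ff", "n_layers",
                                             "dropout", "max_len", "seed")])
  gc <- if (!is.null(cfg$gat_config)) {
    do.call(gat_config, cfg$gat_config[c("n_heads", "head_dim", "negative_slope",
                                         "n_gat_layers", "concat_heads")])
  }
  model <- new_model(cfg$kind, ec, cfg$vocab_size, cfg$labels,
                     gat_config = gc, pool = cfg$pool)
  for (leaf in leaves) {
    v <- as.numeric(unlist(leaf$values))
    if (length(leaf$dim)) dim(v) <- unlist(leaf$dim)
    model$params <- assign_leaf(model$params, unlist(leaf$path), v)
  }
  model
}
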