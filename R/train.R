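# Training orchestration: AdamW, epoch loop with validation-based model
# selection and early stopping, prediction, checkpointing.

adamw_init <- function(params) {
  ps <- collect_params(params)
  for (p in ps) { p$m <- 0 * p$v; p$u <- 0 * p$v }
  list(ps = ps, t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adamw_step <- function(opt, lr, weight_decay) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (p in opt$ps) {
    g <- if (is.null(p$g)) 0 * p$v else p$g
    p$m <- opt$beta1 * p$m + (1 - opt$beta1) * g
    p$u <- opt$beta2 * p$u + (1 - opt$beta2) * g * g
    step <- (p$m / c1) / (sqrt(p$u / c2) + opt$eps)
    if (isTRUE(p$decay) && weight_decay > 0) step <- step + weight_decay * p$v
    p$v <- p$v - lr * step
  }
  opt
}

zero_grads <- function(opt) for (p in opt$ps) p$g <- NULL

check_finite_sample <- function(out, ids) {
  if (any(!is.finite(out$s$v)))
    stop("non-finite response vector at pair (", ids[1], ", ", ids[2],
         "); first non-finite stage: response_vector")
  if (any(!is.finite(out$aff$v)))
    stop("non-finite affinity prediction at pair (", ids[1], ", ", ids[2],
         "); first non-finite stage: affinity_head")
}

#' Train the joint affinity + binding-region model
#'
#' Runs AdamW over per-sample gradients with minibatch averaging, logs the
#' joint training loss and validation MSE per epoch, retains the best
#' checkpoint by validation MSE and stops early when validation MSE has not
#' improved for `patience` epochs.  Fully deterministic given
#' `tcfg$seed` (initialization, shuffling and dropout all draw from the
#' seeded session RNG).
#'
#' The affinity-head output bias is initialized to the mean training
#' affinity, so optimization starts from the label mean rather than zero.
#'
#' @param store featurized inputs from [featurize_dataset()].
#' @param affinities data.frame with drug_id, protein_id, affinity.
#' @param cfg a [dta_config()].
#' @param tcfg a [train_config()].
#' @param split optional list with `train_indices` / `valid_indices` (rows
#'   of `affinities`, e.g. one fold of [make_cv_splits()]); by default all
#'   rows train and validation equals the training set.
#' @return An object of class `dta_model`: best parameter snapshot, config,
#'   vocabulary and the per-epoch training log.
#' @export
train_dta <- function(store, affinities, cfg = dta_config(), tcfg = train_config(),
                      split = NULL) {
  stopifnot(inherits(store, "dta_store"))
  if (is.null(split))
    split <- list(train_indices = seq_len(nrow(affinities)),
                  valid_indices = seq_len(nrow(affinities)))
  tr <- split$train_indices
  va <- split$valid_indices
  set.seed(tcfg$seed)
  params <- init_model_params(cfg, length(store$vocab$tokens))
  head_b <- params$mix$head[[length(params$mix$head)]]$b
  head_b$v[] <- mean(affinities$affinity[tr])
  opt <- adamw_init(params)

  samples <- lapply(seq_len(nrow(affinities)), function(i) {
    pin <- store$proteins[[affinities$protein_id[i]]]
    din <- store$drugs[[affinities$drug_id[i]]]
    if (is.null(pin)) stop("protein '", affinities$protein_id[i], "' not in store")
    if (is.null(din)) stop("drug '", affinities$drug_id[i], "' not in store")
    list(pin = pin, din = din, aff = affinities$affinity[i],
         y = site_label_vector(pin, affinities$affinity[i], cfg$L_P),
         ids = c(affinities$drug_id[i], affinities$protein_id[i]))
  })

  log <- data.frame(epoch = integer(0), train_loss = numeric(0), val_mse = numeric(0))
  best <- list(mse = Inf, snap = snapshot_params(params), epoch = 0L)
  wait <- 0L
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample(tr)
    ep_loss <- 0
    nb <- 0L
    for (b0 in seq(1L, length(ord), by = tcfg$batch_size)) {
      idx <- ord[b0:min(b0 + tcfg$batch_size - 1L, length(ord))]
      zero_grads(opt)
      bl <- 0
      for (i in idx) {
        sm <- samples[[i]]
        tp <- ag_tape()
        out <- fwd_model(tp, params, cfg, sm$pin, sm$din, training = TRUE)
        check_finite_sample(out, sm$ids)
        l <- fwd_loss(tp, out, sm$aff, sm$y, cfg)
        ag_backward(tp, l, seed = 1 / length(idx))
        bl <- bl + l$v[1L]
      }
      bl <- bl / length(idx)
      if (!is.finite(bl)) stop("non-finite joint loss in epoch ", ep, "; stage: joint_loss")
      opt <- adamw_step(opt, tcfg$lr, tcfg$weight_decay)
      ep_loss <- ep_loss + bl
      nb <- nb + 1L
    }
    val_mse <- eval_mse(params, cfg, samples[va])
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / max(nb, 1L),
                                 val_mse = val_mse))
    if (val_mse < best$mse - 1e-12) {
      best <- list(mse = val_mse, snap = snapshot_params(params), epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tcfg$patience) break
    }
  }
  if (identical(tcfg$selection, "best")) restore_params(params, best$snap)
  structure(list(params = params, cfg = cfg, vocab = store$vocab,
                 train_cfg = tcfg, log = log, best_epoch = best$epoch),
            class = "dta_model")
}

eval_mse <- function(params, cfg, samples) {
  if (!length(samples)) return(NA_real_)
  pr <- vapply(samples, function(sm) {
    tp <- ag_tape()
    fwd_model(tp, params, cfg, sm$pin, sm$din, training = FALSE)$aff$v[1L]
  }, numeric(1))
  mean((pr - vapply(samples, `[[`, 0, "aff"))^2)
}

#' @export
print.dta_model <- function(x, ...) {
  cat("<dta_model> preset:", x$cfg$preset, "| epochs run:", nrow(x$log),
      "| best epoch:", x$best_epoch,
      "| best val MSE:", format(min(x$log$val_mse), digits = 4), "\n")
  invisible(x)
}

#' Predict affinities and binding regions for drug-protein pairs
#'
#' Evaluation mode (dropout off): two calls on the same input produce
#' identical output.
#'
#' @param model a [train_dta()] result.
#' @param store featurized inputs (use the training vocabulary).
#' @param pairs data.frame with drug_id, protein_id.
#' @param scales region scales S to report (default from the model config).
#' @return data.frame with predicted affinity, response-peak position and
#'   one `[start, end)` interval pair per scale.
#' @export
predict_dta <- function(model, store, pairs, scales = model$cfg$S_scales) {
  stopifnot(inherits(model, "dta_model"))
  cfg <- model$cfg
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pin <- store$proteins[[pairs$protein_id[i]]]
    din <- store$drugs[[pairs$drug_id[i]]]
    if (is.null(pin)) stop("protein '", pairs$protein_id[i], "' not in store")
    if (is.null(din)) stop("drug '", pairs$drug_id[i], "' not in store")
    tp <- ag_tape()
    out <- fwd_model(tp, model$params, cfg, pin, din, training = FALSE)
    s <- as.numeric(out$s$v)
    row <- data.frame(drug_id = pairs$drug_id[i], protein_id = pairs$protein_id[i],
                      pred_affinity = out$aff$v[1L], peak_pos = which.max(s) - 1L,
                      peak_score = max(s))
    for (S in scales) {
      reg <- predict_binding_region(s, S)
      row[[paste0("start_S", S)]] <- reg[1L]
      row[[paste0("end_S", S)]] <- reg[2L]
    }
    row
  })
  do.call(rbind, rows)
}

#' Write a predictions table
#' @param predictions data.frame from [predict_dta()].
#' @param path output TSV.
#' @export
write_predictions <- function(predictions, path) {
  data.table::fwrite(data.table::as.data.table(predictions), path, sep = "\t")
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single portable RDS file holding parameter values,
#' configuration and vocabulary.
#'
#' @param model a `dta_model`.
#' @param path checkpoint file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(values = snapshot_params(model$params), cfg = model$cfg,
               vocab = model$vocab, train_cfg = model$train_cfg,
               log = model$log, best_epoch = model$best_epoch), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `dta_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  params <- with_seed(0L, init_model_params(ck$cfg, length(ck$vocab$tokens)))
  restore_params(params, ck$values)
  structure(list(params = params, cfg = ck$cfg, vocab = ck$vocab,
                 train_cfg = ck$train_cfg, log = ck$log, best_epoch = ck$best_epoch),
            class = "dta_model")
}

#' Evaluate predictions against ground truth
#'
#' Convenience wrapper producing the full metrics report, including
#' binding-region hit accuracy per scale when site annotations are
#' available.
#'
#' @param predictions data.frame from [predict_dta()].
#' @param affinities data.frame with drug_id, protein_id, affinity.
#' @param sites optional named list protein_id -> interval matrix.
#' @param dataset_mode,threshold,direction see [metrics_report()].
#' @return A metrics report list.
#' @export
evaluate_predictions <- function(predictions, affinities, sites = NULL,
                                 dataset_mode = "generic", threshold = NULL,
                                 direction = NULL) {
  key <- function(d) paste(d$drug_id, d$protein_id, sep = "\r")
  m <- match(key(predictions), key(affinities))
  if (any(is.na(m))) stop("evaluate_predictions: pair(s) missing from ground truth")
  labels <- affinities$affinity[m]
  regions <- NULL; truth_sites <- NULL
  if (!is.null(sites)) {
    ann <- vapply(predictions$protein_id, function(id) {
      iv <- sites[[id]]
      !is.null(iv) && nrow(as_interval_matrix(iv)) > 0L
    }, logical(1))
    if (any(ann)) {
      scol <- grep("^start_S", names(predictions), value = TRUE)
      scales <- sub("^start_S", "", scol)
      regions <- lapply(scales, function(S) {
        lapply(which(ann), function(i)
          c(predictions[[paste0("start_S", S)]][i], predictions[[paste0("end_S", S)]][i]))
      })
      names(regions) <- paste0("S", scales)
      truth_sites <- lapply(which(ann), function(i) sites[[predictions$protein_id[i]]])
    }
  }
  metrics_report(predictions$pred_affinity, labels, dataset_mode = dataset_mode,
                 threshold = threshold, direction = direction,
                 regions = regions, sites = truth_sites)
}
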