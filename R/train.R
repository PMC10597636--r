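# Training loop (AdamW, masked MSE) and window prediction.

fcn_weight_lists <- function(params, n_layers) {
  list(W = lapply(seq_len(n_layers), function(i) params[[sprintf("conv%d_W", i)]]),
       b = lapply(seq_len(n_layers), function(i) params[[sprintf("conv%d_b", i)]]))
}

# build token / target / mask matrices aligned to network positions:
# the value for window start a sits at position a + centre_offset(l_a)
batch_tensors <- function(records, profiles, cfg) {
  B <- length(records)
  L <- cfg$max_len
  off <- centre_offset(cfg$l_a)
  tokens <- matrix(6L, L, B)
  targets <- matrix(0, L, B)
  mask <- matrix(0, L, B)
  for (j in seq_len(B)) {
    tokens[, j] <- tokens_of(records[[j]], L)
    if (!is.null(profiles)) {
      v <- profiles[[j]]$values
      targets[off + seq_along(v), j] <- v
      mask[off + seq_along(v), j] <- 1
    }
  }
  list(tokens = tokens, targets = targets, mask = mask)
}

# Positions beyond this row index provably cannot influence any valid
# prediction, so batches are truncated there: a convolutional output at
# head position p sees inputs within n_layers*(kernel-1)/2 of p, and the
# last valid head position is maxN - l_a + 1 + centre_offset <= maxN; the
# transformer masks padding keys out of attention, so padding rows never
# reach a valid output at all.  The U-Net's pooling pyramid resists a
# simple cone bound and always runs at full length.
effective_len <- function(cfg, max_n) {
  switch(cfg$architecture,
         fcn = {
           rf_half <- cfg$n_layers * ((cfg$kernel - 1L) %/% 2L)
           min(cfg$max_len, max_n + max(0L, rf_half - centre_offset(cfg$l_a)))
         },
         transformer = min(cfg$max_len, max_n),
         cfg$max_len)
}

adam_init <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adamw_step <- function(params, grads, opt, lr, wd, betas, eps = 1e-8) {
  opt$step <- opt$step + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^opt$step; c2 <- 1 - b2^opt$step
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * gr
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * gr^2
    upd <- (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
    params[[nm]] <- params[[nm]] - lr * (upd + wd * params[[nm]])
  }
  list(params = params, opt = opt)
}

surrogate_batch_grad <- function(model, tokens, targets, mask) {
  cfg <- model$config
  if (cfg$architecture == "fcn") {
    wl <- fcn_weight_lists(model$params, cfg$n_layers)
    res <- cpp_fcn_grad(tokens, model$params$E, wl$W, wl$b,
                        as.numeric(model$params$head_w),
                        model$params$head_b, cfg$kernel, targets, mask)
    grads <- list(E = res$gE)
    for (i in seq_len(cfg$n_layers)) {
      grads[[sprintf("conv%d_W", i)]] <- res$gW[[i]]
      grads[[sprintf("conv%d_b", i)]] <- res$gb[[i]]
    }
    grads$head_w <- matrix(res$gwhead, ncol = 1L)
    grads$head_b <- res$gbhead
    list(loss = res$loss, grads = grads)
  } else {
    r_backprop_batch(cfg$architecture, tokens, model$params, cfg,
                     targets, mask)
  }
}

surrogate_forward <- function(model, tokens) {
  cfg <- model$config
  if (cfg$architecture == "fcn") {
    wl <- fcn_weight_lists(model$params, cfg$n_layers)
    cpp_fcn_predict(tokens, model$params$E, wl$W, wl$b,
                    as.numeric(model$params$head_w), model$params$head_b,
                    cfg$kernel)
  } else {
    r_predict_batch(cfg$architecture, tokens, model$params, cfg)
  }
}

masked_mse <- function(pred, targets, mask) {
  sum(((pred - targets) * mask)^2) / sum(mask)
}

#' Train a surrogate on oracle-labelled sequences
#'
#' Minimises mean-squared error over valid window starts only (padding and
#' out-of-range positions are excluded by the mask) with AdamW.  For a fixed
#' configuration seed the shuffling, and hence the loss trajectory on a
#' fixed machine, is reproducible.
#'
#' @param model an [build_surrogate()] model.
#' @param labeled an [label_dataset()] result (sequences + oracle profiles).
#' @param epochs number of passes; default from the model configuration.
#' @param validation optional second `af_labeled` set; its loss is recorded
#'   per epoch.
#' @param checkpoint_dir if non-`NULL`, the model is written there after
#'   every epoch via [save_surrogate()].
#' @param verbose log per-epoch losses.
#' @return list with `model` (updated) and `history` (data frame with one
#'   row per completed epoch: training loss, validation loss, seconds).
#' @export
train_surrogate <- function(model, labeled, epochs = NULL,
                            validation = NULL, checkpoint_dir = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(model, "af_surrogate"), inherits(labeled, "af_labeled"))
  cfg <- model$config
  if (length(labeled$records) == 0L) af_stop("empty training collection")
  if (labeled$config$l_a != cfg$l_a)
    af_stop(sprintf("l_a mismatch: labels use %d, model expects %d",
                    labeled$config$l_a, cfg$l_a))
  if (!is.na(cfg$W) && labeled$config$W != cfg$W)
    af_stop(sprintf("W mismatch: labels use %d, model expects %d",
                    labeled$config$W, cfg$W))
  if (is.null(epochs)) epochs <- cfg$epochs
  if (epochs < 1L) af_stop("epochs must be >= 1")
  lens <- vapply(labeled$records, `[[`, 0L, "n")
  if (any(lens > cfg$max_len))
    af_stop("training sequences longer than max_len")

  tensors <- batch_tensors(labeled$records, labeled$profiles, cfg)
  val_tensors <- if (!is.null(validation))
    batch_tensors(validation$records, validation$profiles, cfg)
  n <- length(labeled$records)
  if (is.null(model$opt)) model$opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), seconds = numeric(0))

  with_seed(cfg$seed + 104729L * (model$trained_epochs + 1L), {
    for (e in seq_len(epochs)) {
      t0 <- proc.time()[["elapsed"]]
      # length-bucketed batches (random tie-break, so composition varies
      # across epochs), processed in shuffled order
      ord <- order(lens, stats::runif(n))
      starts <- seq(1L, n, by = cfg$batch_size)
      loss_num <- 0; loss_den <- 0
      for (start in sample(starts)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        L_eff <- effective_len(cfg, max(lens[idx]))
        rows <- seq_len(L_eff)
        gb <- surrogate_batch_grad(model,
                                   tensors$tokens[rows, idx, drop = FALSE],
                                   tensors$targets[rows, idx, drop = FALSE],
                                   tensors$mask[rows, idx, drop = FALSE])
        w <- sum(tensors$mask[, idx])
        loss_num <- loss_num + gb$loss * w
        loss_den <- loss_den + w
        st <- adamw_step(model$params, gb$grads, model$opt, cfg$lr,
                         cfg$weight_decay, cfg$betas)
        model$params <- st$params
        model$opt <- st$opt
      }
      val_loss <- NA_real_
      if (!is.null(validation)) {
        vp <- surrogate_forward(model, val_tensors$tokens)
        val_loss <- masked_mse(vp, val_tensors$targets, val_tensors$mask)
      }
      secs <- proc.time()[["elapsed"]] - t0
      model$trained_epochs <- model$trained_epochs + 1L
      history <- rbind(history, data.frame(
        epoch = model$trained_epochs, train_loss = loss_num / loss_den,
        val_loss = val_loss, seconds = secs))
      if (verbose)
        message(sprintf("epoch %d: train %.5f%s (%.1fs)",
                        model$trained_epochs, loss_num / loss_den,
                        if (is.na(val_loss)) "" else
                          sprintf(", val %.5f", val_loss), secs))
      if (!is.null(checkpoint_dir))
        save_surrogate(model, file.path(checkpoint_dir,
                                        sprintf("epoch%03d.rds",
                                                model$trained_epochs)))
    }
  })
  model$history <- rbind(model$history, history)
  list(model = model, history = history)
}

#' Predict the accessibility profile of one or more sequences
#'
#' Inference is deterministic; per-sequence results do not depend on batch
#' composition.  Sequences longer than the model maximum are rejected with
#' a pointer to [predict_long()].
#'
#' @param model a trained `af_surrogate`.
#' @param seqs one `af_seq` or a list of them.
#' @param batch_size forward-pass chunk size.
#' @return one `af_profile` (single input) or a list of them.
#' @export
predict_window <- function(model, seqs, batch_size = 512L) {
  stopifnot(inherits(model, "af_surrogate"))
  single <- inherits(seqs, "af_seq")
  records <- as_seq_list(seqs)
  cfg <- model$config
  for (r in records) {
    if (r$n < cfg$l_a)
      af_stop(sprintf("sequence '%s' (%d nt) is shorter than l_a = %d",
                      r$id, r$n, cfg$l_a))
    if (r$n > cfg$max_len)
      af_stop(sprintf("sequence '%s' (%d nt) exceeds max_len = %d; use predict_long()",
                      r$id, r$n, cfg$max_len))
  }
  off <- centre_offset(cfg$l_a)
  out <- vector("list", length(records))
  lens <- vapply(records, `[[`, 0L, "n")
  for (start in seq(1L, length(records), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(records))
    tensors <- batch_tensors(records[idx], NULL, cfg)
    rows <- seq_len(effective_len(cfg, max(lens[idx])))
    preds <- surrogate_forward(model, tensors$tokens[rows, , drop = FALSE])
    for (j in seq_along(idx)) {
      rec <- records[[idx[j]]]
      vals <- preds[off + seq_len(rec$n - cfg$l_a + 1L), j]
      out[[idx[j]]] <- new_profile(rec$id, cfg$l_a, cfg$W, vals)
    }
  }
  if (single) out[[1L]] else out
}
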