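# Shared fixtures for surrogate tests: tiny labelled sets built in code and
# a double-precision FCN forward pass (built from the R conv primitive) used
# to cross-check the single-precision compute core.

tiny_labeled <- function(n, len_range, l_a, W = 30L, seed = 1L,
                         mode = "uniform") {
  stem_max <- max(1L, (len_range[1] - 3L) %/% 2L)
  params <- sampler_params(len_min = len_range[1], len_max = len_range[2],
                           stem_min = 1L, stem_max = stem_max)
  ds <- generate_dataset(n, mode, params, seed)
  label_dataset(ds, oracle_config(l_a, W))
}

r_fcn_forward <- function(model, tokens_mat) {
  cfg <- model$config
  p <- model$params
  preds <- matrix(0, cfg$max_len, ncol(tokens_mat))
  for (b in seq_len(ncol(tokens_mat))) {
    A <- p$E[tokens_mat[, b], , drop = FALSE]
    for (i in seq_len(cfg$n_layers)) {
      A <- accessfold:::relu_r(accessfold:::conv_r_fwd(
        A, p[[sprintf("conv%d_W", i)]], p[[sprintf("conv%d_b", i)]],
        cfg$kernel))
    }
    preds[, b] <- drop(A %*% p$head_w) + p$head_b
  }
  preds
}

rel_err <- function(a, b) abs(a - b) / pmax(1e-4, abs(a), abs(b))
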