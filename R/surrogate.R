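#' Surrogate model configuration
#'
#' Defaults follow the reference training protocol: embedding dimension 120
#' over the six token states (A, C, G, U, N, padding), maximum input length
#' 440, ten epochs of AdamW at batch size 256, masked mean-squared-error
#' loss over valid window starts, and one of three architectures: a fully
#' convolutional network of 40 constant-width layers, a U-Net with 3
#' downsampling, 35 bottleneck and 3 upsampling layers (with skip
#' connections), or a 6-block, 8-head transformer encoder with learned
#' positional embeddings.
#'
#' @param architecture `"fcn"`, `"unet"` or `"transformer"`.
#' @param embed_dim embedding / channel width (default 120).
#' @param max_len maximum sequence length the model accepts (default 440).
#' @param epochs,batch_size training protocol (defaults 10 and 256).
#' @param lr,weight_decay,betas AdamW hyperparameters (defaults 1e-4, 0.01,
#'   (0.9, 0.999)).
#' @param seed seed for parameter initialisation and training shuffles.
#' @param l_a window length the model predicts; must match the labelling
#'   oracle.
#' @param W maximal pair span of the labelling oracle; recorded so that
#'   checkpoints refuse mismatched labels and predictions carry their
#'   provenance.
#' @param n_layers convolutional layer count for `fcn` (default 40) or
#'   transformer block count (default 6); ignored for `unet`.
#' @param kernel convolution kernel size (default 5).
#' @param n_heads attention heads for the transformer (default 8;
#'   `embed_dim` must be divisible by it).
#' @param ffn_mult transformer feed-forward expansion factor (default 4).
#' @param unet_depth 3-vector: layers on the bottom-up path, bottleneck and
#'   top-down path (default `c(3, 35, 3)`).
#' @return an object of class `af_surrogate_config`.
#' @export
surrogate_config <- function(architecture = c("fcn", "unet", "transformer"),
                             embed_dim = 120L, max_len = 440L,
                             epochs = 10L, batch_size = 256L,
                             lr = 1e-4, weight_decay = 0.01,
                             betas = c(0.9, 0.999), seed = 1L, l_a = 35L,
                             W = 100L,
                             n_layers = NULL, kernel = 5L, n_heads = 8L,
                             ffn_mult = 4L, unet_depth = c(3L, 35L, 3L)) {
  architecture <- match.arg(architecture)
  if (is.null(n_layers))
    n_layers <- if (architecture == "transformer") 6L else 40L
  cfg <- list(architecture = architecture, embed_dim = as.integer(embed_dim),
              max_len = as.integer(max_len), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), lr = lr,
              weight_decay = weight_decay, betas = as.numeric(betas),
              seed = as.integer(seed), l_a = as.integer(l_a),
              W = as.integer(W),
              n_layers = as.integer(n_layers), kernel = as.integer(kernel),
              n_heads = as.integer(n_heads), ffn_mult = as.integer(ffn_mult),
              unet_depth = as.integer(unet_depth))
  if (cfg$embed_dim < 1L) af_stop("embed_dim must be >= 1")
  if (cfg$max_len < cfg$l_a) af_stop("max_len must be >= l_a")
  if (cfg$epochs < 1L) af_stop("epochs must be >= 1")
  if (cfg$batch_size < 1L) af_stop("batch_size must be >= 1")
  if (cfg$kernel < 1L || cfg$kernel %% 2L == 0L)
    af_stop("kernel must be odd and >= 1")
  if (cfg$n_layers < 1L) af_stop("n_layers must be >= 1")
  if (architecture == "transformer" && cfg$embed_dim %% cfg$n_heads != 0L)
    af_stop("embed_dim must be divisible by n_heads")
  if (length(cfg$unet_depth) != 3L || any(cfg$unet_depth < 1L))
    af_stop("unet_depth must be three positive layer counts")
  if (architecture == "unet" && cfg$unet_depth[1] != cfg$unet_depth[3])
    af_stop("unet_depth must have equal bottom-up and top-down stage counts",
            " (the skip connections pair them one-to-one)")
  structure(cfg, class = "af_surrogate_config")
}

# offset between a window start and the position whose network output
# predicts it: outputs are read at the window centre, so a receptive field
# of width r covers bases symmetric around the window rather than only its
# left end.
centre_offset <- function(l_a) (l_a - 1L) %/% 2L

surrogate_fingerprint <- function(cfg) {
  depth <- switch(cfg$architecture,
                  fcn = as.character(cfg$n_layers),
                  unet = paste(cfg$unet_depth, collapse = "-"),
                  transformer = sprintf("%dx%dh", cfg$n_layers, cfg$n_heads))
  sprintf("%s/d%d/k%d/depth%s/maxlen%d/la%d/vocab6",
          cfg$architecture, cfg$embed_dim, cfg$kernel, depth,
          cfg$max_len, cfg$l_a)
}

he_mat <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build an untrained surrogate model
#'
#' Parameter initialisation is fully determined by `config$seed`: calling
#' twice with the same configuration yields identical parameters.
#'
#' @param config an [surrogate_config()].
#' @return class `af_surrogate`: `config`, `params` (named list of numeric
#'   arrays), `fingerprint`, `trained_epochs`.
#' @export
build_surrogate <- function(config) {
  stopifnot(inherits(config, "af_surrogate_config"))
  d <- config$embed_dim; k <- config$kernel
  params <- with_seed(config$seed, {
    p <- list(E = matrix(rnorm(6L * d), 6L, d))
    if (config$architecture == "fcn") {
      for (i in seq_len(config$n_layers)) {
        p[[sprintf("conv%d_W", i)]] <- he_mat(k * d, d, k * d)
        p[[sprintf("conv%d_b", i)]] <- numeric(d)
      }
    } else if (config$architecture == "unet") {
      for (i in seq_len(config$unet_depth[1])) {
        p[[sprintf("down%d_W", i)]] <- he_mat(k * d, d, k * d)
        p[[sprintf("down%d_b", i)]] <- numeric(d)
      }
      for (i in seq_len(config$unet_depth[2])) {
        p[[sprintf("mid%d_W", i)]] <- he_mat(k * d, d, k * d)
        p[[sprintf("mid%d_b", i)]] <- numeric(d)
      }
      for (i in seq_len(config$unet_depth[3])) {
        p[[sprintf("up%d_W", i)]] <- he_mat(k * 2L * d, d, k * 2L * d)
        p[[sprintf("up%d_b", i)]] <- numeric(d)
      }
    } else {
      p$pos <- matrix(rnorm(config$max_len * d), config$max_len, d)
      dff <- config$ffn_mult * d
      for (i in seq_len(config$n_layers)) {
        nm <- function(s) sprintf("blk%d_%s", i, s)
        p[[nm("Wq")]] <- he_mat(d, d, 2L * d)
        p[[nm("Wk")]] <- he_mat(d, d, 2L * d)
        p[[nm("Wv")]] <- he_mat(d, d, 2L * d)
        p[[nm("Wo")]] <- he_mat(d, d, 2L * d)
        p[[nm("bo")]] <- numeric(d)
        p[[nm("ln1_g")]] <- rep(1, d); p[[nm("ln1_b")]] <- numeric(d)
        p[[nm("W1")]] <- he_mat(d, dff, d); p[[nm("b1")]] <- numeric(dff)
        p[[nm("W2")]] <- he_mat(dff, d, dff); p[[nm("b2")]] <- numeric(d)
        p[[nm("ln2_g")]] <- rep(1, d); p[[nm("ln2_b")]] <- numeric(d)
      }
      p$lnf_g <- rep(1, d); p$lnf_b <- numeric(d)
    }
    p$head_w <- matrix(rnorm(d, sd = sqrt(1 / d)), d, 1L)
    p$head_b <- 0
    p
  })
  structure(list(config = config, params = params,
                 fingerprint = surrogate_fingerprint(config),
                 trained_epochs = 0L, opt = NULL, history = NULL),
            class = "af_surrogate")
}

#' @export
print.af_surrogate <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<af_surrogate> %s | %d parameters | %d epochs trained\n",
              x$fingerprint, np, x$trained_epochs))
  invisible(x)
}

# token codes 1..6 = A C G U N PAD, right-padded to max_len
tokens_of <- function(record, max_len) {
  if (record$n > max_len)
    af_stop(sprintf("sequence '%s' (%d nt) exceeds max_len = %d; use predict_long()",
                    record$id, record$n, max_len))
  codes <- seq_codes(record) + 1L
  c(codes, rep(6L, max_len - record$n))
}

#' Embed a sequence into the surrogate feature space
#'
#' Assigns each residue its token vector, fills positions beyond the
#' sequence end with the padding vector, and (for the transformer
#' architecture) adds the learned positional vectors elementwise.  The
#' returned mask flags the `n - l_a + 1` valid window starts.
#'
#' @param seq an `af_seq` with `n <= max_len`.
#' @param model an `af_surrogate` whose embedding is used.
#' @return list with `features` (`max_len` x `embed_dim`) and `mask`
#'   (logical of length `max_len`, `TRUE` at valid window starts).
#' @export
embed_sequence <- function(seq, model) {
  cfg <- model$config
  toks <- tokens_of(seq, cfg$max_len)
  feats <- model$params$E[toks, , drop = FALSE]
  if (cfg$architecture == "transformer") feats <- feats + model$params$pos
  if (seq$n < cfg$l_a)
    af_stop(sprintf("sequence '%s' is shorter than l_a", seq$id))
  mask <- rep(FALSE, cfg$max_len)
  mask[seq_len(seq$n - cfg$l_a + 1L)] <- TRUE
  list(features = feats, mask = mask)
}
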