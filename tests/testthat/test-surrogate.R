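small_cfg <- function(arch, seed = 11L, ...) {
  surrogate_config(arch, embed_dim = 8L, max_len = 24L, l_a = 5L, W = 30L,
                   kernel = 3L, n_heads = 2L, unet_depth = c(1L, 2L, 1L),
                   seed = seed, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(surrogate_config(epochs = 0), "epochs")
  expect_error(surrogate_config(batch_size = 0), "batch_size")
  expect_error(surrogate_config(max_len = 10, l_a = 35), "max_len")
  expect_error(surrogate_config(embed_dim = 0), "embed_dim")
  expect_error(surrogate_config("bert"), "arg")
  expect_error(surrogate_config("transformer", embed_dim = 30, n_heads = 8),
               "divisible")
  expect_error(surrogate_config(kernel = 4), "odd")
})

test_that("architectures have the documented depths", {
  fcn <- build_surrogate(surrogate_config("fcn", embed_dim = 4))
  expect_length(grep("^conv\\d+_W$", names(fcn$params)), 40L)
  unet <- build_surrogate(surrogate_config("unet", embed_dim = 4))
  expect_length(grep("^down\\d+_W$", names(unet$params)), 3L)
  expect_length(grep("^mid\\d+_W$", names(unet$params)), 35L)
  expect_length(grep("^up\\d+_W$", names(unet$params)), 3L)
  trf <- build_surrogate(surrogate_config("transformer", embed_dim = 16,
                                          max_len = 48))
  expect_length(grep("^blk\\d+_Wq$", names(trf$params)), 6L)
  # embedding covers the six states A C G U N PAD
  expect_identical(dim(trf$params$E), c(6L, 16L))
  expect_identical(dim(trf$params$pos), c(48L, 16L))
})

test_that("initialisation is a pure function of the seed", {
  for (arch in c("fcn", "unet", "transformer")) {
    a <- build_surrogate(small_cfg(arch, n_layers = 2L))
    b <- build_surrogate(small_cfg(arch, n_layers = 2L))
    expect_identical(a$params, b$params)
    c <- build_surrogate(small_cfg(arch, n_layers = 2L, seed = 12L))
    expect_false(identical(a$params, c$params))
  }
})

test_that("embedding marks valid starts and is local in the residues", {
  cfg <- surrogate_config("fcn", embed_dim = 8, max_len = 440, l_a = 35,
                          n_layers = 2)
  model <- build_surrogate(cfg)
  full <- seq_record("f", paste(rep("ACGU", 110), collapse = ""))
  emb <- embed_sequence(full, model)
  expect_identical(dim(emb$features), c(440L, 8L))
  expect_identical(sum(emb$mask), 406L)          # 440 - 35 + 1 valid starts
  short <- seq_record("s", strrep("A", 35))
  expect_identical(sum(embed_sequence(short, model)$mask), 1L)
  # single-residue change moves exactly one feature row
  s1 <- seq_record("a", paste(rep("A", 50), collapse = ""))
  s2 <- seq_record("b", paste(c(rep("A", 20), "G", rep("A", 29)), collapse = ""))
  e1 <- embed_sequence(s1, model)$features
  e2 <- embed_sequence(s2, model)$features
  expect_identical(which(rowSums(abs(e1 - e2)) > 0), 21L)
  too_long <- seq_record("l", strrep("A", 441))
  expect_error(embed_sequence(too_long, model), "max_len")
})

test_that("prediction length contract and batching independence hold", {
  cfg <- surrogate_config("fcn", embed_dim = 8, max_len = 440, l_a = 35,
                          n_layers = 2, seed = 3)
  model <- build_surrogate(cfg)
  full <- seq_record("f", paste(rep("GACU", 110), collapse = ""))
  expect_length(predict_window(model, full)$values, 406L)
  exact <- seq_record("e", strrep("G", 35))
  expect_length(predict_window(model, exact)$values, 1L)
  set.seed(8)
  others <- lapply(1:20, function(i) random_seq(sample(35:100, 1),
                                                paste0("o", i)))
  alone <- predict_window(model, full)
  in_batch <- predict_window(model, c(list(full), others))[[1]]
  expect_lt(max(abs(alone$values - in_batch$values)), 1e-5)
  expect_error(predict_window(model, seq_record("l", strrep("A", 441))),
               "predict_long")
  expect_error(predict_window(model, seq_record("t", strrep("A", 10))), "l_a")
})

test_that("analytic gradients match finite differences (all architectures)", {
  set.seed(9)
  for (arch in c("unet", "transformer", "fcn")) {
    cfg <- small_cfg(arch, n_layers = 2L)
    model <- build_surrogate(cfg)
    recs <- lapply(1:3, function(i)
      random_seq(sample(cfg$l_a:cfg$max_len, 1), paste0("s", i),
                 p = c(.25, .25, .25, .25, 0)))
    profs <- lapply(recs, function(r)
      accessfold:::new_profile(r$id, cfg$l_a, cfg$W, rnorm(r$n - cfg$l_a + 1)))
    tens <- accessfold:::batch_tensors(recs, profs, cfg)
    gb <- accessfold:::surrogate_batch_grad(model, tens$tokens, tens$targets,
                                            tens$mask)
    # reference loss in double precision (R forward for every architecture)
    lossfun <- function(params) {
      m2 <- model; m2$params <- params
      pred <- if (arch == "fcn") r_fcn_forward(m2, tens$tokens) else
        accessfold:::r_predict_batch(arch, tens$tokens, params, cfg)
      accessfold:::masked_mse(pred, tens$targets, tens$mask)
    }
    worst <- 0
    for (nm in names(model$params)) {
      for (trial in 1:2) {
        idx <- sample(length(model$params[[nm]]), 1)
        eps <- 1e-5
        pp <- model$params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
        pm <- model$params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
        fd <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
        worst <- max(worst, rel_err(fd, gb$grads[[nm]][idx]))
      }
    }
    tol <- if (arch == "fcn") 2e-3 else 1e-5  # fcn core runs in float32
    expect_lt(worst, tol)
  }
})

test_that("the float32 FCN forward agrees with a double-precision replica", {
  cfg <- small_cfg("fcn", n_layers = 3L)
  model <- build_surrogate(cfg)
  set.seed(10)
  recs <- lapply(1:4, function(i) random_seq(sample(5:24, 1), paste0("q", i)))
  tens <- accessfold:::batch_tensors(recs, NULL, cfg)
  a <- accessfold:::surrogate_forward(model, tens$tokens)
  b <- r_fcn_forward(model, tens$tokens)
  expect_lt(max(abs(a - b)), 1e-4)
})

test_that("batch truncation at the receptive-field cone is exact", {
  # training batches are cut at the last row that can influence a valid
  # prediction; loss and gradients must match the full-length computation
  set.seed(14)
  for (arch in c("fcn", "transformer")) {
    cfg <- small_cfg(arch, n_layers = 2L)
    model <- build_surrogate(cfg)
    recs <- lapply(1:4, function(i)
      random_seq(sample(cfg$l_a:(cfg$max_len - 8L), 1), paste0("s", i)))
    profs <- lapply(recs, function(r)
      accessfold:::new_profile(r$id, cfg$l_a, cfg$W, rnorm(r$n - cfg$l_a + 1)))
    tens <- accessfold:::batch_tensors(recs, profs, cfg)
    rows <- seq_len(accessfold:::effective_len(
      cfg, max(vapply(recs, `[[`, 0L, "n"))))
    full <- accessfold:::surrogate_batch_grad(model, tens$tokens,
                                              tens$targets, tens$mask)
    cut <- accessfold:::surrogate_batch_grad(
      model, tens$tokens[rows, , drop = FALSE],
      tens$targets[rows, , drop = FALSE], tens$mask[rows, , drop = FALSE])
    expect_equal(cut$loss, full$loss, tolerance = 1e-6)
    for (nm in names(full$grads))
      expect_equal(cut$grads[[nm]], full$grads[[nm]], tolerance = 1e-5)
  }
})

test_that("padded positions never contribute to the loss or its gradients", {
  cfg <- small_cfg("fcn", n_layers = 2L)
  model <- build_surrogate(cfg)
  lab <- tiny_labeled(8, c(8, 20), l_a = cfg$l_a, W = cfg$W, seed = 4)
  tens <- accessfold:::batch_tensors(lab$records, lab$profiles, cfg)
  garbage <- tens$targets
  garbage[tens$mask == 0] <- 1e6
  g1 <- accessfold:::surrogate_batch_grad(model, tens$tokens, tens$targets,
                                          tens$mask)
  g2 <- accessfold:::surrogate_batch_grad(model, tens$tokens, garbage,
                                          tens$mask)
  expect_identical(g1$loss, g2$loss)
  expect_identical(g1$grads, g2$grads)
})

test_that("training descends, is reproducible, and validates its inputs", {
  lab <- tiny_labeled(60, c(30, 40), l_a = 10L, W = 25L, seed = 21)
  cfg <- surrogate_config("fcn", embed_dim = 16L, max_len = 40L, l_a = 10L,
                          W = 25L, n_layers = 3L, epochs = 5L,
                          batch_size = 16L, lr = 1e-3, seed = 13L)
  model <- build_surrogate(cfg)
  res <- train_surrogate(model, lab)
  expect_identical(nrow(res$history), 5L)
  expect_lt(tail(res$history$train_loss, 1), res$history$train_loss[1])
  res2 <- train_surrogate(build_surrogate(cfg), lab)
  expect_equal(res$history$train_loss, res2$history$train_loss,
               tolerance = 1e-10)

  bad_cfg <- surrogate_config("fcn", embed_dim = 16L, max_len = 40L,
                              l_a = 12L, W = 25L, n_layers = 2L)
  expect_error(train_surrogate(build_surrogate(bad_cfg), lab), "l_a mismatch")
  empty <- lab; empty$records <- list(); empty$profiles <- list()
  expect_error(train_surrogate(model, empty), "empty")
  expect_error(train_surrogate(model, lab, epochs = 0), "epochs")
})

test_that("a batch of identical sequences predicts identically", {
  cfg <- small_cfg("fcn", n_layers = 2L)
  model <- build_surrogate(cfg)
  rec <- random_seq(20, "same")
  lab <- structure(list(
    records = rep(list(rec), 6),
    profiles = rep(list(accessfold:::new_profile("same", cfg$l_a, cfg$W,
                                                 rep(1.5, 16))), 6),
    config = oracle_config(cfg$l_a, cfg$W), model = NULL, n_skipped = 0L),
    class = "af_labeled")
  res <- train_surrogate(model, lab, epochs = 2)
  tens <- accessfold:::batch_tensors(lab$records, NULL, cfg)
  preds <- accessfold:::surrogate_forward(res$model, tens$tokens)
  expect_true(all(abs(preds - preds[, 1]) < 1e-7))
})
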