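# Independent reference computations used by the oracle tests.

random_seq <- function(n, id = "rnd", p = c(.24, .24, .24, .24, .04)) {
  seq_record(id, paste(sample(c("A", "C", "G", "U", "N"), n, TRUE, p),
                       collapse = ""))
}

# Unconstrained ensemble (no span test anywhere), plain interval dynamic
# program in linear arithmetic; only usable for short sequences.  The
# accessibility of a window is obtained by recomputing Z with the window's
# bases barred from pairing.
mccaskill_unconstrained <- function(record, model, l_a) {
  res <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  n <- length(res)
  h <- model$min_hairpin
  s <- exp(-model$stack_bonus / model$RT)
  pairw <- function(i, j) {
    e <- pair_energy_of_test(model, res[i], res[j])
    if (is.na(e)) 0 else exp(-e / model$RT)
  }
  z_of <- function(blocked) {
    Zb <- matrix(0, n, n)
    Z <- matrix(1, n + 1L, n + 1L)  # Z[i, j+1] = partition of [i, j]
    zint <- function(i, j) if (i > j) 1 else Z[i, j + 1L]
    for (len in 2:n) for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      if (j - i >= h + 1L && !blocked[i] && !blocked[j]) {
        w <- pairw(i, j)
        if (w > 0) {
          inner <- zint(i + 1L, j - 1L)
          stk <- if (j - i - 2L >= h + 1L) (s - 1) * Zb[i + 1L, j - 1L] else 0
          Zb[i, j] <- w * (inner + stk)
        }
      }
      acc <- zint(i, j - 1L)
      if (j - h - 1L >= i)
        for (k in i:(j - h - 1L)) acc <- acc + zint(i, k - 1L) * Zb[k, j]
      Z[i, j + 1L] <- acc
    }
    zint(1L, n)
  }
  ztot <- z_of(rep(FALSE, n))
  vals <- numeric(n - l_a + 1L)
  for (a in seq_along(vals)) {
    blocked <- rep(FALSE, n)
    blocked[a:(a + l_a - 1L)] <- TRUE
    vals[a] <- -model$RT * log(z_of(blocked) / ztot)
  }
  vals
}

# local copy of the pair lookup so this helper shares no code path with the
# package internals it checks
pair_energy_of_test <- function(model, x, y) {
  key <- paste(sort(c(x, y)), collapse = "")
  e <- model$pair_energies[[key]]
  if (is.null(e)) NA_real_ else e
}
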