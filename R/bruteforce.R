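#' Enumerate all admissible secondary structures
#'
#' Exhaustively enumerates every non-pseudoknotted structure obeying the
#' pairing rules, minimum hairpin and maximal span of the given model.
#' Intended as an independent correctness oracle for small inputs.
#'
#' @param seq an `af_seq` record with `n <= 18` (exponential guard).
#' @param model an energy model.
#' @param W maximal pair span.
#' @return a list of structures, each a 2-column matrix of 1-based paired
#'   positions (0 rows = the open chain).
#' @export
enumerate_structures <- function(seq, model = build_energy_model(),
                                 W = 100L) {
  stopifnot(inherits(seq, "af_seq"))
  if (seq$n > 18L) af_stop("enumeration limited to sequences of <= 18 bases")
  res <- strsplit(seq$seq, "", fixed = TRUE)[[1]]
  h <- model$min_hairpin
  can_pair <- function(i, j) {
    j - i >= h + 1L && j - i <= W &&
      !is.na(pair_energy_of(model, res[i], res[j])) &&
      res[i] != "N" && res[j] != "N"
  }
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), 0, 2)))
    out <- rec(i + 1L, j)                       # base i unpaired
    for (k in seq.int(i + 1L, j)) {
      if (!can_pair(i, k)) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    out
  }
  rec(1L, seq$n)
}

structure_energy <- function(pairs, res, model) {
  if (nrow(pairs) == 0L) return(0)
  e <- sum(vapply(seq_len(nrow(pairs)), function(r)
    pair_energy_of(model, res[pairs[r, 1]], res[pairs[r, 2]]), 0))
  if (model$stack_bonus != 0) {
    key <- paste(pairs[, 1], pairs[, 2])
    stacked <- sum(paste(pairs[, 1] + 1L, pairs[, 2] - 1L) %in% key)
    e <- e + model$stack_bonus * stacked
  }
  e
}

#' Accessibility by exhaustive enumeration
#'
#' Same contract as [accessibility_profile()], but `Z` and `Z_unpaired` are
#' obtained by direct summation of Boltzmann weights over the enumerated
#' structure set.  This is the independent oracle the dynamic program is
#' validated against.
#'
#' @inheritParams accessibility_profile
#' @return an `af_profile`.
#' @export
brute_force_accessibility <- function(seq, config = oracle_config(),
                                      model = build_energy_model()) {
  stopifnot(inherits(seq, "af_seq"))
  if (seq$n > 18L) af_stop("brute force limited to sequences of <= 18 bases")
  if (seq$n < config$l_a)
    af_stop(sprintf("sequence '%s' is shorter than l_a", seq$id))
  res <- strsplit(seq$seq, "", fixed = TRUE)[[1]]
  structs <- enumerate_structures(seq, model, config$W)
  weights <- vapply(structs, function(s)
    exp(-structure_energy(s, res, model) / model$RT), 0)
  z <- sum(weights)
  n_win <- seq$n - config$l_a + 1L
  vals <- numeric(n_win)
  for (a in seq_len(n_win)) {
    b <- a + config$l_a - 1L
    free <- vapply(structs, function(s) {
      if (nrow(s) == 0L) return(TRUE)
      paired <- c(s[, 1], s[, 2])
      !any(paired >= a & paired <= b)
    }, TRUE)
    vals[a] <- -model$RT * log(sum(weights[free]) / z)
  }
  new_profile(seq$id, config$l_a, config$W, vals)
}
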