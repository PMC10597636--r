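#' Oracle configuration
#'
#' @param l_a subregion (window) length in bases for which accessibility is
#'   computed; default 35, the value used for prokaryotic
#'   translation-efficiency prediction.
#' @param W maximal base-pair span: pairs (i,j) with `j - i > W` are
#'   excluded from the ensemble (local folding); default 100.
#' @return an object of class `af_oracle_config`.
#' @export
oracle_config <- function(l_a = 35L, W = 100L) {
  l_a <- as.integer(l_a); W <- as.integer(W)
  if (is.na(l_a) || l_a < 1L) af_stop("l_a must be >= 1")
  if (is.na(W) || W < 1L) af_stop("W must be >= 1")
  structure(list(l_a = l_a, W = W), class = "af_oracle_config")
}

#' Span-constrained partition function
#'
#' Computes the partition function over all non-pseudoknotted secondary
#' structures in which every pair (i,j) satisfies
#' `min_hairpin + 1 <= j - i <= W` and has a finite pair energy.  All
#' returned quantities are on the natural-log scale.
#'
#' @param seq an `af_seq` record.
#' @param model an [build_energy_model()] energy model.
#' @param W maximal pair span in bases.
#' @return class `af_partition`: `log_z` (log of the total partition value;
#'   at least 0 since the open chain always contributes weight 1), `log_zb`
#'   (N x N matrix, `log_zb[i, j]` the log partition value of structures on
#'   `[i, j]` closed by the pair (i,j); `-Inf` where undefined), and
#'   `log_prefix` (exterior prefix partition values, length N + 1).
#' @export
constrained_partition <- function(seq, model = build_energy_model(), W) {
  stopifnot(inherits(seq, "af_seq"))
  W <- as.integer(W)
  if (seq$n < 1L) af_stop("sequence must have length >= 1")
  st <- cpp_partition(seq_codes(seq), as.numeric(t(pair_logweights(model))),
                      model$stack_bonus, model$min_hairpin, model$RT, W)
  structure(list(id = seq$id, log_z = st$log_z, log_zb = st$log_zb,
                 log_prefix = st$log_prefix, W = W, model = model),
            class = "af_partition")
}

#' Exact accessibility profile of every window
#'
#' For each window start `a` (1-based, windows of `l_a` bases), the
#' accessibility is `-RT * log(Z_unpaired(a) / Z)` where `Z_unpaired(a)` is
#' the span-constrained partition value restricted to structures in which no
#' base of the window is paired (pairs enclosing the whole window from
#' outside remain allowed).  Values are nonnegative up to numerical
#' tolerance and are reported in kcal/mol.
#'
#' @param seq an `af_seq` record with `seq$n >= l_a`.
#' @param config an [oracle_config()].
#' @param model an [build_energy_model()] energy model.
#' @return class `af_profile`: `id`, `l_a`, `W`, `values`
#'   (length `n - l_a + 1`, one per window start).
#' @export
accessibility_profile <- function(seq, config = oracle_config(),
                                  model = build_energy_model()) {
  stopifnot(inherits(seq, "af_seq"), inherits(config, "af_oracle_config"))
  if (seq$n < config$l_a)
    af_stop(sprintf("sequence '%s' (%d nt) is shorter than l_a = %d",
                    seq$id, seq$n, config$l_a))
  res <- cpp_access_profile(seq_codes(seq),
                            as.numeric(t(pair_logweights(model))),
                            model$stack_bonus, model$min_hairpin, model$RT,
                            config$W, config$l_a)
  new_profile(seq$id, config$l_a, config$W, res$profile)
}

new_profile <- function(id, l_a, W, values) {
  structure(list(id = id, l_a = as.integer(l_a), W = as.integer(W),
                 values = as.numeric(values)), class = "af_profile")
}

#' @export
print.af_profile <- function(x, ...) {
  cat(sprintf("<af_profile> %s: %d windows (l_a=%d, W=%d), range %.3f..%.3f kcal/mol\n",
              x$id, length(x$values), x$l_a, x$W,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Label a sequence collection with oracle accessibility profiles
#'
#' Order-preserving; sequences shorter than `l_a` are skipped with a logged
#' warning.  Batch processing is resumable: pass a previous (partial) result
#' as `done` and already-labelled ids are not recomputed.
#'
#' @param seqs an `af_dataset`, list of `af_seq`, or single record.
#' @param config an [oracle_config()].
#' @param model an energy model.
#' @param progress_every log a progress message every this many sequences
#'   (0 = silent).
#' @param done optional previous `af_labeled` result to resume from.
#' @return class `af_labeled`: `records`, `profiles` (parallel lists),
#'   `config`, `model`, `n_skipped`.
#' @export
label_dataset <- function(seqs, config = oracle_config(),
                          model = build_energy_model(),
                          progress_every = 0L, done = NULL) {
  records <- as_seq_list(seqs)
  prev <- list()
  if (!is.null(done)) {
    stopifnot(inherits(done, "af_labeled"))
    prev <- stats::setNames(done$profiles,
                            vapply(done$profiles, `[[`, "", "id"))
  }
  out_rec <- list(); out_prof <- list(); n_skipped <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (rec$n < config$l_a) {
      warning(sprintf("skipping '%s': length %d < l_a = %d",
                      rec$id, rec$n, config$l_a), call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    prof <- if (!is.null(prev[[rec$id]])) prev[[rec$id]] else
      accessibility_profile(rec, config, model)
    out_rec[[length(out_rec) + 1L]] <- rec
    out_prof[[length(out_prof) + 1L]] <- prof
    if (progress_every > 0L && i %% progress_every == 0L)
      message(sprintf("labelled %d / %d sequences", i, length(records)))
  }
  structure(list(records = out_rec, profiles = out_prof, config = config,
                 model = model, n_skipped = n_skipped),
            class = "af_labeled")
}

#' @export
print.af_labeled <- function(x, ...) {
  cat(sprintf("<af_labeled> %d labelled sequences (l_a=%d, W=%d), %d skipped\n",
              length(x$profiles), x$config$l_a, x$config$W, x$n_skipped))
  invisible(x)
}
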