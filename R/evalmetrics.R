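#' Normalised mean square error
#'
#' `mean((pred - target)^2)` divided by a normaliser of the target vector;
#' the default normaliser is `mean(target)` ("MSE divided by the target
#' value").  Alternative normalisers are selectable but the default is used
#' throughout the package's own evaluation.
#'
#' @param pred,target equal-length numeric vectors.
#' @param normaliser `"mean"` (default), `"meansq"`, or `"var"`.
#' @return a nonnegative scalar, 0 iff `pred == target` elementwise.
#' @export
nmse <- function(pred, target, normaliser = c("mean", "meansq", "var")) {
  normaliser <- match.arg(normaliser)
  if (length(pred) != length(target))
    af_stop("pred and target must have equal length")
  if (length(pred) < 1L) af_stop("empty input")
  if (anyNA(pred) || anyNA(target)) af_stop("NA values in input")
  denom <- switch(normaliser,
                  mean = mean(target),
                  meansq = mean(target^2),
                  var = stats::var(target))
  if (!is.finite(denom) || denom <= 0)
    af_stop("target normaliser is not positive")
  mean((pred - target)^2) / denom
}

#' Spearman's rank correlation
#'
#' Rank correlation with average ranks for ties; invariant under strictly
#' increasing transforms of either argument.  A constant input vector makes
#' the correlation undefined and is reported as an error rather than
#' silently returned as 0.
#'
#' @param pred,target equal-length numeric vectors (length >= 2).
#' @return a value in \[-1, 1\].
#' @export
spearman_rho <- function(pred, target) {
  if (length(pred) != length(target))
    af_stop("pred and target must have equal length")
  if (length(pred) < 2L) af_stop("need at least two values")
  if (anyNA(pred) || anyNA(target)) af_stop("NA values in input")
  if (length(unique(pred)) == 1L || length(unique(target)) == 1L)
    af_stop("rank correlation undefined for a constant input vector")
  cor(pred, target, method = "spearman")
}

profile_map <- function(profiles) {
  if (inherits(profiles, "af_labeled")) profiles <- profiles$profiles
  if (inherits(profiles, "af_profile")) profiles <- list(profiles)
  stats::setNames(profiles, vapply(profiles, `[[`, "", "id"))
}

#' Evaluate predicted profiles against oracle profiles
#'
#' Pools every window value of every sequence into one global NMSE and one
#' global Spearman correlation (the scatter-plot view of agreement); a
#' per-sequence breakdown is returned alongside.
#'
#' @param predicted,truth lists of `af_profile` (or `af_labeled`) with
#'   matching ids, `l_a` and lengths.
#' @return class `af_eval_report`: `nmse`, `spearman_rho`, `n_sequences`,
#'   `n_values`, `l_a`, `W`, `per_sequence` (data frame).
#' @export
evaluate <- function(predicted, truth) {
  pm <- profile_map(predicted)
  tm <- profile_map(truth)
  only_p <- setdiff(names(pm), names(tm))
  only_t <- setdiff(names(tm), names(pm))
  if (length(only_p) || length(only_t))
    af_stop("id mismatch between predictions and truth; only in predictions: [",
            paste(head(only_p, 5L), collapse = ", "),
            "], only in truth: [", paste(head(only_t, 5L), collapse = ", "),
            "]")
  ids <- names(pm)
  la <- unique(vapply(c(pm, tm), `[[`, 0L, "l_a"))
  if (length(la) != 1L) af_stop("profiles disagree on l_a")
  per <- lapply(ids, function(id) {
    p <- pm[[id]]$values; t <- tm[[id]]$values
    if (length(p) != length(t))
      af_stop("profile length mismatch for id '", id, "'")
    data.frame(id = id, n_values = length(p),
               nmse = mean((p - t)^2) / mean(t),
               spearman_rho = if (length(p) >= 2L &&
                                  length(unique(p)) > 1L &&
                                  length(unique(t)) > 1L)
                 cor(p, t, method = "spearman") else NA_real_)
  })
  pred_all <- unlist(lapply(ids, function(id) pm[[id]]$values))
  truth_all <- unlist(lapply(ids, function(id) tm[[id]]$values))
  structure(list(nmse = nmse(pred_all, truth_all),
                 spearman_rho = spearman_rho(pred_all, truth_all),
                 n_sequences = length(ids), n_values = length(pred_all),
                 l_a = la, W = tm[[1L]]$W,
                 per_sequence = do.call(rbind, per)),
            class = "af_eval_report")
}

#' @export
print.af_eval_report <- function(x, ...) {
  cat(sprintf("<af_eval_report> %d sequences, %d values (l_a=%d)\n",
              x$n_sequences, x$n_values, x$l_a))
  cat(sprintf("  NMSE        %.4f\n  Spearman rho %.4f\n",
              x$nmse, x$spearman_rho))
  invisible(x)
}

#' Correlate accessibility with protein abundance
#'
#' Scores each sequence by the accessibility of a single window (the window
#' whose start is `offset`, 1-based; for inputs following the
#' 120-bases-around-the-start-codon convention this selects the window
#' covering the start codon) and returns the signed Spearman correlation
#' between scores and abundances.  Both the signed value and its magnitude
#' are logged.
#'
#' @param profiles list of `af_profile` keyed by sequence id.
#' @param abundance data frame with columns `id` and `abundance`.
#' @param offset 1-based window start used as the score; must be within
#'   every profile.
#' @return the signed Spearman correlation.
#' @export
abundance_correlation <- function(profiles, abundance, offset = 1L) {
  pm <- profile_map(profiles)
  if (!all(c("id", "abundance") %in% names(abundance)))
    af_stop("abundance table needs columns 'id' and 'abundance'")
  missing <- setdiff(abundance$id, names(pm))
  if (length(missing))
    af_stop(length(missing), " abundance ids have no profile (first: '",
            missing[1L], "')")
  offset <- as.integer(offset)
  short <- vapply(pm[abundance$id], function(p)
    offset < 1L || offset > length(p$values), TRUE)
  if (any(short))
    af_stop("offset ", offset, " out of range for ", sum(short), " profiles")
  scores <- vapply(pm[abundance$id], function(p) p$values[offset], 0)
  rho <- spearman_rho(scores, abundance$abundance)
  message(sprintf("abundance correlation at offset %d: rho = %.4f (|rho| = %.4f, n = %d)",
                  offset, rho, abs(rho), length(scores)))
  rho
}
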