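#' Plan overlapping prediction windows for a long sequence
#'
#' A sequence longer than the model maximum is divided into `window_len`-base
#' windows shifted by `shift` bases (consecutive windows overlap by
#' `window_len - shift` bases); if the regular grid does not end exactly at
#' the sequence end, the last window is anchored at `N - window_len`.
#' Because prediction quality degrades near window edges, `trim` bases at
#' each interior window end are treated as unreliable: every global window
#' start is supplied by exactly one window, with the boundary between
#' neighbouring windows at the midpoint of their overlap (for the default
#' 110-base overlap this is the 55-base trim rule; an irregular last overlap
#' is split at its own midpoint).
#'
#' @param N sequence length (bases).
#' @param window_len window size (default 440).
#' @param shift window shift (default 330); must be smaller than
#'   `window_len` so windows overlap.
#' @param trim unreliable edge width (default 55); `2 * trim` must not
#'   exceed the regular overlap.
#' @param l_a window (subregion) length of the profiles being stitched.
#' @return class `af_window_plan`: `windows` (data frame of 0-based
#'   half-open `[start, end)` intervals), `supply` (data frame of first/last
#'   0-based global window starts each window is responsible for), and the
#'   parameters.
#' @export
plan_windows <- function(N, window_len = 440L, shift = 330L, trim = 55L,
                         l_a = 35L) {
  N <- as.integer(N); window_len <- as.integer(window_len)
  shift <- as.integer(shift); trim <- as.integer(trim)
  l_a <- as.integer(l_a)
  if (N < l_a) af_stop("sequence shorter than l_a")
  if (shift < 1L || shift >= window_len)
    af_stop("shift must be in [1, window_len - 1] so that windows overlap")
  overlap <- window_len - shift
  if (2L * trim > overlap)
    af_stop("2 * trim exceeds the window overlap")
  if (l_a > overlap - overlap %/% 2L + 1L)  # window must reach its boundary
    af_stop("window overlap too small for this l_a")

  if (N <= window_len) {
    windows <- data.frame(start = 0L, end = N)
    supply <- data.frame(first = 0L, last = N - l_a)
  } else {
    offs <- seq.int(0L, N - window_len, by = shift)
    if (tail(offs, 1L) != N - window_len) offs <- c(offs, N - window_len)
    k <- length(offs)
    bounds <- integer(k + 1L)        # supply boundaries in start space
    bounds[1L] <- 0L
    bounds[k + 1L] <- N - l_a + 1L
    for (i in seq_len(k - 1L)) {
      ov <- offs[i] + window_len - offs[i + 1L]
      bounds[i + 1L] <- offs[i + 1L] + ov %/% 2L
    }
    windows <- data.frame(start = offs, end = offs + window_len)
    supply <- data.frame(first = bounds[seq_len(k)],
                         last = bounds[-1L] - 1L)
    # every supplied start must be producible by its window
    if (any(supply$first < windows$start) ||
        any(supply$last > windows$start + window_len - l_a))
      af_stop("window plan is infeasible for these parameters")
    if (any(supply$last < supply$first))
      af_stop("window plan leaves a window with nothing to supply")
  }
  structure(list(N = N, window_len = window_len, shift = shift,
                 trim = trim, l_a = l_a, windows = windows,
                 supply = supply),
            class = "af_window_plan")
}

#' @export
print.af_window_plan <- function(x, ...) {
  cat(sprintf("<af_window_plan> N=%d, %d windows (len %d, shift %d, trim %d)\n",
              x$N, nrow(x$windows), x$window_len, x$shift, x$trim))
  invisible(x)
}

#' Stitch per-window profiles into a full-length profile
#'
#' Copies each window's assigned local values to their global starts; a pure
#' function of its inputs.  Window profiles must come in plan order with the
#' exact local lengths the plan implies.
#'
#' @param profiles list of `af_profile`, one per planned window.
#' @param plan an [plan_windows()] plan.
#' @param id id for the stitched profile.
#' @return an `af_profile` of length `N - l_a + 1`.
#' @export
stitch <- function(profiles, plan, id = NULL) {
  stopifnot(inherits(plan, "af_window_plan"))
  k <- nrow(plan$windows)
  if (length(profiles) != k)
    af_stop(sprintf("expected %d window profiles, got %d", k,
                    length(profiles)))
  n_out <- plan$N - plan$l_a + 1L
  out <- rep(NA_real_, n_out)
  for (i in seq_len(k)) {
    p <- profiles[[i]]
    w_len <- plan$windows$end[i] - plan$windows$start[i]
    expect_len <- w_len - plan$l_a + 1L
    if (length(p$values) != expect_len)
      af_stop(sprintf("window %d profile has %d values, expected %d",
                      i, length(p$values), expect_len))
    gstarts <- plan$supply$first[i]:plan$supply$last[i]   # 0-based global
    lstarts <- gstarts - plan$windows$start[i]            # 0-based local
    if (any(!is.na(out[gstarts + 1L])))
      af_stop("window plan assigns a start twice")
    out[gstarts + 1L] <- p$values[lstarts + 1L]
  }
  if (anyNA(out)) af_stop("window plan leaves unassigned starts")
  if (is.null(id)) id <- profiles[[1L]]$id
  new_profile(id, plan$l_a, profiles[[1L]]$W, out)
}

#' Predict accessibility for a sequence of arbitrary length
#'
#' For sequences no longer than the model maximum this is identical to
#' [predict_window()]; longer sequences are cut into overlapping windows per
#' [plan_windows()], predicted per window, and stitched with the
#' edge-trimming assignment rule.
#'
#' @param model a trained `af_surrogate`.
#' @param seq an `af_seq` with `n >= l_a`.
#' @param window_len,shift,trim window plan parameters; defaults are the
#'   model maximum length, 3/4 of it, and half the resulting overlap
#'   (equal to 440/330/55 for the default model size).
#' @return an `af_profile` with `n - l_a + 1` values.
#' @export
predict_long <- function(model, seq, window_len = NULL, shift = NULL,
                         trim = NULL) {
  stopifnot(inherits(model, "af_surrogate"), inherits(seq, "af_seq"))
  cfg <- model$config
  if (is.null(window_len)) window_len <- cfg$max_len
  if (window_len > cfg$max_len)
    af_stop("window_len exceeds the model maximum length")
  if (is.null(shift)) shift <- as.integer(round(0.75 * window_len))
  if (is.null(trim)) trim <- (window_len - shift) %/% 2L
  if (seq$n <= cfg$max_len && seq$n <= window_len)
    return(predict_window(model, seq))
  plan <- plan_windows(seq$n, window_len, shift, trim, cfg$l_a)
  subs <- lapply(seq_len(nrow(plan$windows)), function(i) {
    s <- plan$windows$start[i]; e <- plan$windows$end[i]
    seq_record(sprintf("%s|w%d", seq$id, i), substr(seq$seq, s + 1L, e))
  })
  profs <- predict_window(model, subs)
  stitch(profs, plan, id = seq$id)
}
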