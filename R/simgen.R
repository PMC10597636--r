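#' Sampler parameters for artificial RNA generation
#'
#' Two samplers produce training sequences: a uniform sampler drawing
#' residues i.i.d. from a per-sequence categorical distribution whose
#' probability vector is Dirichlet-distributed, and a structured sampler
#' that additionally plants a single stem (two reverse-complementary
#' regions separated by a loop) into a uniform-sampler sequence, with
#' wobble pairs, internal-loop substitutions and substitution propagation
#' governed by per-sequence Beta-distributed Bernoulli rates.
#'
#' @param len_min,len_max sequence length bounds (bases); length is drawn
#'   uniformly on `[len_min, len_max]`, both ends inclusive.
#' @param dirichlet_alpha positive 5-vector of Dirichlet concentrations over
#'   (A, C, G, U, N).  The default `[1,1,1,1,0.1]` makes the undetermined
#'   nucleotide N rare (mean frequency 0.1/4.1).
#' @param stem_min,stem_max planted stem length bounds (base pairs).
#' @param loop_min minimum number of bases between the two stem halves.
#' @param wobble_beta Beta(shape1, shape2) for the per-sequence probability
#'   that a G or U stem position receives its Watson-Crick partner rather
#'   than a wobble (G-U) partner.  Mean 4/5 favours Watson-Crick pairs.
#' @param loopsub_beta Beta parameters for the per-sequence probability that
#'   a second-stem base is substituted to create an internal loop.
#' @param propagate_beta Beta parameters for the per-sequence probability
#'   that the base immediately after a substituted base is also substituted.
#' @return an object of class `af_sampler_params`.
#' @export
sampler_params <- function(len_min = 100L, len_max = 440L,
                           dirichlet_alpha = c(1, 1, 1, 1, 0.1),
                           stem_min = 8L, stem_max = 48L, loop_min = 3L,
                           wobble_beta = c(4, 1), loopsub_beta = c(1, 15),
                           propagate_beta = c(2, 1)) {
  p <- list(len_min = as.integer(len_min), len_max = as.integer(len_max),
            dirichlet_alpha = as.numeric(dirichlet_alpha),
            stem_min = as.integer(stem_min), stem_max = as.integer(stem_max),
            loop_min = as.integer(loop_min),
            wobble_beta = as.numeric(wobble_beta),
            loopsub_beta = as.numeric(loopsub_beta),
            propagate_beta = as.numeric(propagate_beta))
  if (p$len_min < 1L) af_stop("len_min must be >= 1")
  if (p$len_max < p$len_min) af_stop("len_max must be >= len_min")
  if (length(p$dirichlet_alpha) != 5L || any(p$dirichlet_alpha <= 0))
    af_stop("dirichlet_alpha must be 5 positive values over (A,C,G,U,N)")
  if (p$stem_min < 1L) af_stop("stem_min must be >= 1")
  if (p$stem_max < p$stem_min) af_stop("stem_max must be >= stem_min")
  if (p$loop_min < 0L) af_stop("loop_min must be >= 0")
  for (nm in c("wobble_beta", "loopsub_beta", "propagate_beta"))
    if (length(p[[nm]]) != 2L || any(p[[nm]] <= 0))
      af_stop(nm, " must be two positive Beta shape parameters")
  if (2L * p$stem_max + p$loop_min > p$len_min)
    af_stop("2*stem_max + loop_min must be <= len_min ",
            "so that a planted stem always fits")
  structure(p, class = "af_sampler_params")
}

check_sampler_params <- function(params) {
  if (!inherits(params, "af_sampler_params"))
    af_stop("params must be created by sampler_params()")
  params
}

# Watson-Crick complements; N has no partner and is resolved from Cat(pi)
WC_PARTNER <- c(A = "U", C = "G", G = "C", U = "A")
WOBBLE_PARTNER <- c(G = "U", U = "G")

#' Draw one uniform-sampler sequence
#'
#' Length is uniform on `[len_min, len_max]`; a composition vector `pi` is
#' drawn once per sequence from `Dirichlet(dirichlet_alpha)` and residues are
#' then i.i.d. `Cat(pi)` over (A, C, G, U, N).
#'
#' @param params an [sampler_params()] object.
#' @param seed integer seed; the (params, seed) pair fully determines the
#'   output.
#' @param id record id; defaults to a seed-derived name.
#' @return an `af_seq` record with attributes `pi` (the composition used)
#'   and `seed`.
#' @export
sample_uniform_sequence <- function(params = sampler_params(), seed,
                                    id = sprintf("unif_%d", seed)) {
  check_sampler_params(params)
  stopifnot(length(seed) == 1L, is.finite(seed))
  with_seed(seed, {
    n <- sample(params$len_min:params$len_max, 1L)
    g <- rgamma(5L, shape = params$dirichlet_alpha)
    pi <- g / sum(g)
    residues <- sample(AF_ALPHABET, n, replace = TRUE, prob = pi)
    rec <- seq_record(id, paste(residues, collapse = ""))
    attr(rec, "pi") <- pi
    attr(rec, "seed") <- as.integer(seed)
    rec
  })
}

#' Draw one structured-sampler sequence with its stem annotation
#'
#' Starts from a uniform-sampler draw, then plants a stem: a first stem
#' region of length `l ~ unif(stem_min, stem_max)` at start
#' `s1 ~ unif(0, N - 2l - d)` (0-based), a loop of
#' `d ~ unif(loop_min, N - 2l)` bases, and a second stem region rewritten to
#' be the reverse complement of the first (antiparallel geometry: first-stem
#' offset `i` pairs with second-stem offset `l - 1 - i`).  For G/U
#' first-stem bases the partner is Watson-Crick with per-sequence
#' probability `mu_wobble ~ Beta(4, 1)`, else wobble.  Second-stem bases are
#' then substituted (internal loops) with probability
#' `mu_loopsub ~ Beta(1, 15)`, replacements drawn from `Cat(pi)`; the base
#' immediately after a substituted base is itself substituted with
#' probability `mu_propagate ~ Beta(2, 1)` (one step, no chaining).
#'
#' @inheritParams sample_uniform_sequence
#' @return a list with elements `record` (`af_seq`) and `annotation`
#'   (`af_stem_annotation`), the latter recording every stochastic choice:
#'   positions, the latent `mu` values, the wobble mask over first-stem
#'   offsets (`"wc"`, `"wobble"`, or `NA` for non-G/U bases), the
#'   substitution mask over second-stem offsets (`"intact"`,
#'   `"substituted"`, `"propagated"`), the second stem as first built
#'   (before substitutions) and the replacement bases drawn.
#' @export
sample_structured_sequence <- function(params = sampler_params(), seed,
                                       id = sprintf("struct_%d", seed)) {
  check_sampler_params(params)
  stopifnot(length(seed) == 1L, is.finite(seed))
  with_seed(seed, {
    # uniform part, same draw order as sample_uniform_sequence
    n <- sample(params$len_min:params$len_max, 1L)
    g <- rgamma(5L, shape = params$dirichlet_alpha)
    pi <- g / sum(g)
    residues <- sample(AF_ALPHABET, n, replace = TRUE, prob = pi)

    l <- sample(params$stem_min:params$stem_max, 1L)
    d <- sample(params$loop_min:(n - 2L * l), 1L)
    s1 <- sample(0L:(n - 2L * l - d), 1L)  # 0-based start, inclusive ends
    s2 <- s1 + l + d
    mu_wobble <- rbeta(1L, params$wobble_beta[1], params$wobble_beta[2])
    mu_loopsub <- rbeta(1L, params$loopsub_beta[1], params$loopsub_beta[2])
    mu_propagate <- rbeta(1L, params$propagate_beta[1],
                          params$propagate_beta[2])

    wobble_mask <- rep(NA_character_, l)
    stem2 <- character(l)
    for (i in 0:(l - 1L)) {            # first-stem offsets, 0-based
      base <- residues[s1 + i + 1L]
      t2 <- l - 1L - i                  # second-stem offset paired with i
      if (base %in% c("G", "U")) {
        wc <- runif(1L) < mu_wobble     # success = Watson-Crick partner
        wobble_mask[i + 1L] <- if (wc) "wc" else "wobble"
        stem2[t2 + 1L] <- if (wc) WC_PARTNER[[base]] else
          WOBBLE_PARTNER[[base]]
      } else if (base == "N") {
        stem2[t2 + 1L] <- sample(AF_ALPHABET, 1L, prob = pi)  # N cannot pair
      } else {
        stem2[t2 + 1L] <- WC_PARTNER[[base]]
      }
    }
    stem2_built <- paste(stem2, collapse = "")

    sub_mask <- rep("intact", l)
    replacements <- rep(NA_character_, l)
    for (t in 0:(l - 1L)) {             # scan second stem 5'->3'
      if (sub_mask[t + 1L] == "propagated") {
        replacements[t + 1L] <- sample(AF_ALPHABET, 1L, prob = pi)
        stem2[t + 1L] <- replacements[t + 1L]
        next                            # propagation applies once
      }
      if (runif(1L) < mu_loopsub) {
        sub_mask[t + 1L] <- "substituted"
        replacements[t + 1L] <- sample(AF_ALPHABET, 1L, prob = pi)
        stem2[t + 1L] <- replacements[t + 1L]
        if (t + 1L <= l - 1L && runif(1L) < mu_propagate)
          sub_mask[t + 2L] <- "propagated"
      }
    }
    residues[(s2 + 1L):(s2 + l)] <- stem2

    rec <- seq_record(id, paste(residues, collapse = ""))
    attr(rec, "pi") <- pi
    attr(rec, "seed") <- as.integer(seed)
    ann <- structure(list(
      stem_len = l, loop_len = d, stem1_start = s1, stem2_start = s2,
      pi = pi, mu_wobble = mu_wobble, mu_loopsub = mu_loopsub,
      mu_propagate = mu_propagate, wobble_mask = wobble_mask,
      substitution_mask = sub_mask, stem2_built = stem2_built,
      replacements = replacements, seed = as.integer(seed)),
      class = "af_stem_annotation")
    list(record = rec, annotation = ann)
  })
}

#' Verify a stem annotation against its sequence
#'
#' Re-derives the pairing and substitution state recorded in an annotation
#' and checks it against the sequence: rebuilding the second stem from the
#' first stem and the wobble mask must reproduce `stem2_built`, applying the
#' recorded replacements at masked positions must reproduce the final second
#' stem, and every intact position must hold a Watson-Crick or wobble pair.
#'
#' @param record an `af_seq` from [sample_structured_sequence()].
#' @param annotation the matching `af_stem_annotation`.
#' @return `TRUE` invisibly; errors describe the first inconsistency.
#' @export
verify_stem_annotation <- function(record, annotation) {
  a <- annotation
  res <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  l <- a$stem_len
  if (a$stem2_start + l > record$n) af_stop("stem exceeds sequence end")
  stem1 <- res[(a$stem1_start + 1L):(a$stem1_start + l)]
  stem2 <- res[(a$stem2_start + 1L):(a$stem2_start + l)]
  built <- strsplit(a$stem2_built, "", fixed = TRUE)[[1]]
  for (i in 0:(l - 1L)) {
    t2 <- l - 1L - i
    b <- stem1[i + 1L]
    expect <- if (b %in% c("G", "U")) {
      if (is.na(a$wobble_mask[i + 1L]))
        af_stop("wobble mask missing for G/U stem position ", i)
      if (a$wobble_mask[i + 1L] == "wc") WC_PARTNER[[b]] else
        WOBBLE_PARTNER[[b]]
    } else if (b == "N") built[t2 + 1L] else WC_PARTNER[[b]]
    if (built[t2 + 1L] != expect)
      af_stop("rebuilt second stem disagrees at stem offset ", t2)
  }
  final <- built
  subbed <- a$substitution_mask != "intact"
  final[subbed] <- a$replacements[subbed]
  if (any(final != stem2))
    af_stop("recorded substitutions do not reproduce the sequence")
  for (t in 0:(l - 1L)) {
    if (subbed[t + 1L]) next
    i <- l - 1L - t
    p <- paste0(stem1[i + 1L], stem2[t + 1L])
    ok <- p %in% c("AU", "UA", "GC", "CG", "GU", "UG") ||
      stem1[i + 1L] == "N"
    if (!ok) af_stop("intact stem offset ", t, " does not pair (", p, ")")
  }
  invisible(TRUE)
}

#' Generate a dataset of artificial RNA sequences
#'
#' In `uniform` mode all sequences come from the uniform sampler.  In
#' `structured` mode sequences alternate uniform, structured, uniform, ...
#' so that half of the dataset (the ceiling half being uniform when `n` is
#' odd) carries a planted stem, matching the half-and-half composition of
#' the structured training dataset.  Per-sequence seeds are derived from the
#' master seed so any single sequence is regenerable in isolation via
#' [sample_uniform_sequence()] / [sample_structured_sequence()] with the
#' seed stored in its record.
#'
#' @param n number of sequences (default ten million, the full training
#'   scale).
#' @param mode `"uniform"` or `"structured"`.
#' @param params an [sampler_params()] object.
#' @param seed master seed.
#' @return an `af_dataset`: list with `records` (list of `af_seq`),
#'   `annotations` (per-record stem annotation or `NULL`), `mode`, `params`,
#'   `seed`.
#' @export
generate_dataset <- function(n = 1e7, mode = c("uniform", "structured"),
                             params = sampler_params(), seed) {
  mode <- match.arg(mode)
  check_sampler_params(params)
  if (length(n) != 1L || is.na(n) || n < 0) af_stop("n must be >= 0")
  n <- as.integer(n)
  seeds <- if (n > 0)
    with_seed(seed, sample.int(.Machine$integer.max - 1L, n)) else integer(0)
  records <- vector("list", n)
  annotations <- vector("list", n)
  for (i in seq_len(n)) {
    structured <- mode == "structured" && i %% 2L == 0L
    if (structured) {
      draw <- sample_structured_sequence(
        params, seeds[i], id = sprintf("struct_%06d", i))
      records[[i]] <- draw$record
      annotations[[i]] <- draw$annotation
    } else {
      records[[i]] <- sample_uniform_sequence(
        params, seeds[i], id = sprintf("unif_%06d", i))
    }
  }
  structure(list(records = records, annotations = annotations,
                 mode = mode, params = params, seed = seed),
            class = "af_dataset")
}

#' @export
print.af_dataset <- function(x, ...) {
  n_ann <- sum(!vapply(x$annotations, is.null, logical(1)))
  cat(sprintf("<af_dataset> %d sequences (%s mode, %d with stem annotations)\n",
              length(x$records), x$mode, n_ann))
  invisible(x)
}
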