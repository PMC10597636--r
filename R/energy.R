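#' Build a base-pairing energy model
#'
#' The folding oracle scores a secondary structure as the sum of its pair
#' energies plus an optional bonus for every pair of adjacently stacked base
#' pairs; the Boltzmann weight is `exp(-E / RT)`.  The defaults are a
#' deliberately simple, fully self-contained model (GC -3.0, AU -2.0,
#' GU -1.0 kcal/mol, no stacking term) whose correctness is provable by
#' exhaustive enumeration; arbitrary pair tables can be supplied, including
#' externally derived ones via [read_energy_model()].
#'
#' @param pair_energies named list of pair energies in kcal/mol; names are
#'   two bases from A, C, G, U in either order (unordered pairs).  Entries
#'   replace or extend the defaults.
#' @param stack_bonus energy (kcal/mol) added for each pair of adjacent
#'   stacked base pairs (i,j), (i+1,j-1); negative values stabilise helices.
#' @param min_hairpin minimum number of unpaired bases enclosed by a pair
#'   (steric minimum, default 3).
#' @param RT thermal energy in kcal/mol (default 0.6163, 310.15 K).
#' @return an object of class `af_energy_model`.
#' @export
build_energy_model <- function(pair_energies = NULL, stack_bonus = 0,
                               min_hairpin = 3L, RT = 0.6163) {
  # keys are canonical: the two bases in alphabetical order
  defaults <- list(CG = -3.0, AU = -2.0, GU = -1.0)
  if (!is.null(pair_energies)) {
    if (is.null(names(pair_energies)) || any(names(pair_energies) == ""))
      af_stop("pair_energies must be a named list like list(GC = -3)")
    for (nm in names(pair_energies)) {
      bases <- strsplit(toupper(nm), "", fixed = TRUE)[[1]]
      if (length(bases) != 2L || !all(bases %in% c("A", "C", "G", "U")))
        af_stop("pair '", nm, "' must name two bases from A, C, G, U")
      key <- paste(sort(bases), collapse = "")
      defaults[[key]] <- as.numeric(pair_energies[[nm]])
    }
  }
  if (!is.finite(RT) || RT <= 0) af_stop("RT must be positive")
  if (min_hairpin < 0) af_stop("min_hairpin must be >= 0")
  structure(list(pair_energies = defaults, stack_bonus = stack_bonus,
                 min_hairpin = as.integer(min_hairpin), RT = RT),
            class = "af_energy_model")
}

#' @export
print.af_energy_model <- function(x, ...) {
  pe <- paste(sprintf("%s=%.2f", names(x$pair_energies),
                      unlist(x$pair_energies)), collapse = " ")
  cat(sprintf("<af_energy_model> pairs: %s | stack %.2f | min hairpin %d | RT %.4f\n",
              pe, x$stack_bonus, x$min_hairpin, x$RT))
  invisible(x)
}

# 5x5 matrix of log Boltzmann pair weights (-E/RT), NA = forbidden.
# N (code 4) never pairs.
pair_logweights <- function(model) {
  m <- matrix(NA_real_, 5, 5, dimnames = list(AF_ALPHABET, AF_ALPHABET))
  for (nm in names(model$pair_energies)) {
    b <- strsplit(nm, "", fixed = TRUE)[[1]]
    w <- -model$pair_energies[[nm]] / model$RT
    m[b[1], b[2]] <- w
    m[b[2], b[1]] <- w
  }
  m
}

pair_energy_of <- function(model, x, y) {
  key <- paste(sort(c(x, y)), collapse = "")
  e <- model$pair_energies[[key]]
  if (is.null(e)) NA_real_ else e
}

#' Read an energy-model override file
#'
#' Flat `key=value` text format: `pair.GC=-3.0` entries set pair energies;
#' `stack_bonus`, `min_hairpin` and `RT` set the scalar fields.  Lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return an `af_energy_model`.
#' @export
read_energy_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) af_stop("malformed line in energy model file: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  pairs <- list()
  args <- list()
  for (i in seq_along(keys)) {
    if (startsWith(keys[i], "pair.")) {
      pairs[[sub("^pair\\.", "", keys[i])]] <- vals[i]
    } else if (keys[i] %in% c("stack_bonus", "min_hairpin", "RT")) {
      args[[keys[i]]] <- vals[i]
    } else af_stop("unknown energy model key: ", keys[i])
  }
  do.call(build_energy_model,
          c(list(pair_energies = if (length(pairs)) pairs else NULL), args))
}
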