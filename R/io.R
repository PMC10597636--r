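# File formats: FASTA in/out (via Biostrings), profile TSV, stem-annotation
# TSV with run-length-encoded masks, model checkpoints with a JSON sidecar.
# All writers are atomic (write to a temporary file, then rename).

AF_FORMAT_VERSION <- "accessfold-profile-v1"

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) af_stop("could not move output into place: ", path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Standard multi-line FASTA; T/t is mapped to U, lowercase is uppercased,
#' ids are the first whitespace-delimited token of the header.  Characters
#' outside A, C, G, U, T, N are rejected with the file line and column;
#' duplicate ids are rejected.
#'
#' @param path FASTA file.
#' @return list of `af_seq` records.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    af_stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  seqs <- unname(as.character(set))
  bad <- grepl("[^ACGUTNacgutn]", seqs)
  if (any(bad)) {
    k <- which(bad)[1L]
    loc <- locate_fasta_char(path, k, regexpr("[^ACGUTNacgutn]", seqs[k]))
    af_stop(sprintf("illegal character in record '%s' at line %d, column %d",
                    ids[k], loc[1L], loc[2L]))
  }
  lapply(seq_along(ids), function(i) seq_record(ids[i], seqs[i]))
}

# map the p-th residue of the k-th record back to a file line/column
locate_fasta_char <- function(path, record_index, pos) {
  lines <- readLines(path, warn = FALSE)
  rec <- 0L; seen <- 0L
  for (ln in seq_along(lines)) {
    if (startsWith(lines[ln], ">")) { rec <- rec + 1L; seen <- 0L; next }
    if (rec != record_index) next
    w <- nchar(lines[ln])
    if (seen + w >= pos) return(c(ln, pos - seen))
    seen <- seen + w
  }
  c(NA_integer_, NA_integer_)
}

#' Write sequences to a FASTA file
#'
#' @param seqs list of `af_seq` records (or an `af_dataset`).
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  records <- as_seq_list(seqs)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  atomic_write(path, function(tmp)
    Biostrings::writeXStringSet(set, tmp, width = width))
}

#' Write accessibility profiles to a TSV file
#'
#' One row per window: `id`, `start` (1-based window left end) and
#' `accessibility` (kcal/mol, 4 decimal places), preceded by `#` header
#' lines recording the format version, `l_a`, `W` and the producing model
#' fingerprint.
#'
#' @param profiles list of `af_profile` (or an `af_labeled`).
#' @param path output file.
#' @param fingerprint model fingerprint recorded in the header (`"oracle"`
#'   for exact labels).
#' @export
write_profiles <- function(profiles, path, fingerprint = "oracle") {
  if (inherits(profiles, "af_labeled")) profiles <- profiles$profiles
  if (inherits(profiles, "af_profile")) profiles <- list(profiles)
  la <- unique(vapply(profiles, `[[`, 0L, "l_a"))
  W <- unique(vapply(profiles, `[[`, 0L, "W"))
  if (length(la) > 1L || length(W) > 1L)
    af_stop("profiles disagree on l_a or W")
  if (length(la) == 0L) { la <- NA_integer_; W <- NA_integer_ }
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c(
      paste0("# ", AF_FORMAT_VERSION),
      sprintf("# l_a=%d W=%d model=%s version=%s", la, W, fingerprint,
              as.character(utils::packageVersion("accessfold"))),
      "id\tstart\taccessibility"), con)
    for (p in profiles) {
      if (length(p$values) == 0L) next
      writeLines(sprintf("%s\t%d\t%.4f", p$id, seq_along(p$values),
                         p$values), con)
    }
  })
}

#' Read accessibility profiles from a TSV file
#'
#' Validates the header and the per-id start contiguity (1..n, strictly
#' increasing) and reconstructs the profiles exactly as written.
#'
#' @param path file written by [write_profiles()].
#' @return list of `af_profile`.
#' @export
read_profiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !identical(lines[1L], paste0("# ", AF_FORMAT_VERSION)))
    af_stop("not an accessfold profile file (bad or missing header): ", path)
  meta <- lines[2L]
  int_field <- function(key) {
    v <- sub(sprintf(".*%s=(-?[0-9]+|NA).*", key), "\\1", meta)
    if (v == "NA" || v == meta) NA_integer_ else as.integer(v)
  }
  la <- int_field("l_a")
  W <- int_field("W")
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(list())
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) af_stop("malformed profile row")
  ids <- vapply(parts, `[`, "", 1L)
  starts <- as.integer(vapply(parts, `[`, "", 2L))
  vals <- as.numeric(vapply(parts, `[`, "", 3L))
  out <- list()
  for (id in unique(ids)) {
    sel <- ids == id
    s <- starts[sel]
    if (!identical(s, seq_len(length(s))))
      af_stop("non-contiguous starts for id '", id, "'")
    out[[length(out) + 1L]] <- new_profile(id, la, W, vals[sel])
  }
  out
}

# ---- stem annotations -----------------------------------------------------

mask_rle <- function(mask) {
  codes <- c(intact = "i", substituted = "s", propagated = "p",
             wc = "w", wobble = "g", none = "n")
  m <- ifelse(is.na(mask), "none", mask)
  r <- rle(unname(codes[m]))
  paste0(r$values, r$lengths, collapse = "")
}

mask_unrle <- function(txt) {
  names <- c(i = "intact", s = "substituted", p = "propagated",
             w = "wc", g = "wobble", n = NA_character_)
  m <- gregexpr("([ispwgn])([0-9]+)", txt)[[1]]
  if (m[1L] == -1L) return(character(0))
  pieces <- regmatches(txt, gregexpr("([ispwgn])([0-9]+)", txt))[[1]]
  unlist(lapply(pieces, function(p) {
    rep(names[[substr(p, 1L, 1L)]], as.integer(substr(p, 2L, nchar(p))))
  }))
}

#' Write stem annotations to a sidecar TSV
#'
#' Columns: `id, l, d, stem1_start, stem2_start, mu_wobble, mu_loopsub,
#' mu_propagate, wobble_mask, substitution_mask, stem2_built, replacements`;
#' masks are stored in a compact run-length encoding (`i`ntact,
#' `s`ubstituted, `p`ropagated, `w`atson-crick, wobble `g`, `n`one).
#' Positions are 0-based as in the annotations themselves.
#'
#' @param dataset an `af_dataset` (only records with annotations are
#'   written) or a named list of annotations.
#' @param path output file.
#' @export
write_annotations <- function(dataset, path) {
  if (inherits(dataset, "af_dataset")) {
    keep <- !vapply(dataset$annotations, is.null, TRUE)
    anns <- dataset$annotations[keep]
    ids <- vapply(dataset$records[keep], `[[`, "", "id")
  } else {
    anns <- dataset
    ids <- names(dataset)
  }
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines(paste("id", "l", "d", "stem1_start", "stem2_start",
                     "mu_wobble", "mu_loopsub", "mu_propagate",
                     "wobble_mask", "substitution_mask", "stem2_built",
                     "replacements", sep = "\t"), con)
    for (i in seq_along(anns)) {
      a <- anns[[i]]
      repl <- paste(ifelse(is.na(a$replacements), ".", a$replacements),
                    collapse = "")
      writeLines(paste(ids[i], a$stem_len, a$loop_len, a$stem1_start,
                       a$stem2_start, sprintf("%.6f", a$mu_wobble),
                       sprintf("%.6f", a$mu_loopsub),
                       sprintf("%.6f", a$mu_propagate),
                       mask_rle(a$wobble_mask), mask_rle(a$substitution_mask),
                       a$stem2_built, repl, sep = "\t"), con)
    }
  })
}

#' Read stem annotations written by [write_annotations()]
#'
#' @param path annotation TSV.
#' @return named list of `af_stem_annotation`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  out <- list()
  for (i in seq_len(nrow(df))) {
    repl <- strsplit(df$replacements[i], "", fixed = TRUE)[[1]]
    repl[repl == "."] <- NA_character_
    out[[df$id[i]]] <- structure(list(
      stem_len = as.integer(df$l[i]), loop_len = as.integer(df$d[i]),
      stem1_start = as.integer(df$stem1_start[i]),
      stem2_start = as.integer(df$stem2_start[i]),
      pi = NULL, mu_wobble = as.numeric(df$mu_wobble[i]),
      mu_loopsub = as.numeric(df$mu_loopsub[i]),
      mu_propagate = as.numeric(df$mu_propagate[i]),
      wobble_mask = mask_unrle(df$wobble_mask[i]),
      substitution_mask = mask_unrle(df$substitution_mask[i]),
      stem2_built = df$stem2_built[i], replacements = repl,
      seed = NA_integer_), class = "af_stem_annotation")
  }
  out
}

# ---- checkpoints ----------------------------------------------------------

#' Save a surrogate model checkpoint
#'
#' The parameter container goes into an RDS file; a JSON sidecar
#' (`<path>.json`) carries the full configuration, fingerprint, seed and the
#' oracle settings so that loading can verify them.
#'
#' @param model an `af_surrogate`.
#' @param path checkpoint path (`.rds`).
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "af_surrogate"))
  atomic_write(path, function(tmp) saveRDS(model, tmp))
  sidecar <- list(fingerprint = model$fingerprint,
                  config = unclass(model$config),
                  trained_epochs = model$trained_epochs,
                  package_version =
                    as.character(utils::packageVersion("accessfold")))
  atomic_write(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(sidecar, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Load a surrogate model checkpoint
#'
#' Verifies the stored fingerprint against the sidecar (when present) and
#' against the rebuilt architecture description.
#'
#' @param path checkpoint path written by [save_surrogate()].
#' @return an `af_surrogate`.
#' @export
load_surrogate <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "af_surrogate")) af_stop("not a surrogate checkpoint")
  if (!identical(model$fingerprint, surrogate_fingerprint(model$config)))
    af_stop("checkpoint fingerprint does not match its configuration")
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path)
    if (!identical(sc$fingerprint, model$fingerprint))
      af_stop("checkpoint fingerprint does not match its sidecar")
  }
  model
}
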