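# Sequence ingestion, range extraction, composition and scrambling.
# All downstream analyses operate on seq_record objects built here.

#' The twenty canonical amino-acid one-letter codes
#'
#' Fixed alphabet used by every composition-based statistic in the package.
#' Order is alphabetical and stable across releases.
#'
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Create a protein sequence record
#'
#' A \code{seq_record} is the package's basic sequence container: an id, a
#' residue string restricted to the 20 canonical amino acids, and an optional
#' 1-based inclusive source range locating the record inside a parent protein
#' (e.g. an IDR excised from a full-length sequence).
#'
#' @param id Character label, non-empty.
#' @param residues Character scalar over the canonical amino-acid alphabet.
#' @param source_range Optional integer vector \code{c(start, end)}, 1-based
#'   inclusive, whose width must equal \code{nchar(residues)}.
#' @return An object of class \code{seq_record}.
#' @examples
#' seq_record("toy", "MKRSPT")
#' @export
seq_record <- function(id, residues, source_range = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) {
    stop("record '", id, "': empty sequence", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(residues, "", fixed = TRUE)[[1]]), AMINO_ACIDS)
  if (length(bad) > 0L) {
    stop("record '", id, "': non-canonical residue(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(source_range)) {
    source_range <- as.integer(source_range)
    stopifnot(length(source_range) == 2L)
    if (source_range[2] - source_range[1] + 1L != nchar(residues)) {
      stop("record '", id, "': source_range width ",
           source_range[2] - source_range[1] + 1L,
           " does not match sequence length ", nchar(residues), call. = FALSE)
    }
  }
  structure(list(id = id, residues = residues, source_range = source_range),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  rng <- if (is.null(x$source_range)) "" else
    sprintf(" [%d-%d]", x$source_range[1], x$source_range[2])
  cat(sprintf("<seq_record> %s%s, %d aa\n", x$id, rng, nchar(x$residues)))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$residues)

# Coerce a character scalar or seq_record to seq_record.
as_seq_record <- function(x, id = "seq") {
  if (inherits(x, "seq_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(seq_record(id, x))
  stop("expected a seq_record or a single character string", call. = FALSE)
}

seq_chars <- function(rec) strsplit(rec$residues, "", fixed = TRUE)[[1]]

#' Read protein sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into a list of \code{\link{seq_record}}s,
#' preserving record order. Residues outside the 20-letter canonical alphabet
#' are handled according to \code{ambiguity_policy}: \code{"drop"} removes
#' them with a warning, \code{"error"} aborts naming the offending record.
#' Headers of the form \code{id/start-end} (as written by
#' \code{\link{write_fasta}}) restore the record's source range.
#'
#' @param path Path to a FASTA file.
#' @param ambiguity_policy One of \code{"drop"} (default) or \code{"error"}.
#' @return List of \code{seq_record}, one per FASTA entry.
#' @export
read_fasta <- function(path, ambiguity_policy = c("drop", "error")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(headers))) {
    stop("malformed FASTA header (empty) in ", path, call. = FALSE)
  }
  recs <- vector("list", length(set))
  for (k in seq_along(set)) {
    hdr <- sub("\\s.*$", "", headers[k])  # first whitespace-delimited token
    rng <- NULL
    m <- regmatches(hdr, regexec("^(.*)/(\\d+)-(\\d+)$", hdr))[[1]]
    id <- hdr
    if (length(m) == 4L) {
      id <- m[2]
      rng <- c(as.integer(m[3]), as.integer(m[4]))
    }
    resid <- toupper(gsub("[\\s*]", "", as.character(set[[k]]), perl = TRUE))
    chars <- strsplit(resid, "", fixed = TRUE)[[1]]
    bad <- !(chars %in% AMINO_ACIDS)
    if (any(bad)) {
      if (ambiguity_policy == "error") {
        stop("record '", id, "': non-canonical residue(s) ",
             paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
      }
      warning("record '", id, "': dropped ", sum(bad),
              " non-canonical residue(s) (",
              paste(unique(chars[bad]), collapse = ", "), ")", call. = FALSE)
      resid <- paste(chars[!bad], collapse = "")
    }
    if (!nzchar(resid)) {
      stop("record '", id, "': sequence empty after dropping non-canonical ",
           "residues", call. = FALSE)
    }
    # A range restored from the header must still match the cleaned length.
    if (!is.null(rng) && rng[2] - rng[1] + 1L != nchar(resid)) rng <- NULL
    recs[[k]] <- seq_record(id, resid, rng)
  }
  recs
}

#' Write sequence records to a FASTA file
#'
#' Sequences are wrapped at \code{width} columns. Records carrying a source
#' range are written with the header \code{id/start-end}, which
#' \code{\link{read_fasta}} parses back.
#'
#' @param records List of \code{seq_record} (or a single record).
#' @param path Output file path.
#' @param width Line-wrap column, default 60.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  set <- Biostrings::AAStringSet(vapply(records, function(r) r$residues, ""))
  names(set) <- vapply(records, function(r) {
    if (is.null(r$source_range)) r$id else
      sprintf("%s/%d-%d", r$id, r$source_range[1], r$source_range[2])
  }, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract a residue range from a sequence record
#'
#' Coordinates are 1-based inclusive, matching the usual protein-region
#' convention (e.g. an IDR given as residues 187-549 of the full-length
#' protein). The returned record remembers the range in \code{source_range};
#' if the input already has a source range, the new range is expressed in the
#' original parent's coordinates.
#'
#' @param rec A \code{seq_record}.
#' @param start,end 1-based inclusive positions, \code{1 <= start <= end <= L}.
#' @return A \code{seq_record} of length \code{end - start + 1}.
#' @examples
#' r <- seq_record("x", strrep("A", 549))
#' length(extract_range(r, 187, 549))  # 363
#' @export
extract_range <- function(rec, start, end) {
  rec <- as_seq_record(rec)
  start <- as.integer(start); end <- as.integer(end)
  L <- nchar(rec$residues)
  if (is.na(start) || is.na(end) || start < 1L || end > L || start > end) {
    stop("record '", rec$id, "': invalid range ", start, "-", end,
         " for length ", L, call. = FALSE)
  }
  off <- if (is.null(rec$source_range)) 0L else rec$source_range[1] - 1L
  seq_record(rec$id, substr(rec$residues, start, end),
             source_range = c(start + off, end + off))
}

#' Amino-acid composition of a sequence
#'
#' Counts and fractional content of each of the 20 canonical amino acids.
#'
#' @param rec A \code{seq_record} or character scalar.
#' @return An object of class \code{composition_vector}: a list with
#'   \code{counts} (named integer, length 20), \code{fractions} (named
#'   numeric summing to 1) and \code{total}.
#' @examples
#' composition("AG")$fractions[c("A", "G")]  # 0.5 0.5
#' @export
composition <- function(rec) {
  rec <- as_seq_record(rec)
  counts <- count_residues(rec$residues)
  total <- sum(counts)
  structure(list(counts = counts, fractions = counts / total, total = total),
            class = "composition_vector")
}

# Residue counts over the fixed 20-letter alphabet (fast path used throughout).
count_residues <- function(residues) {
  idx <- match(strsplit(residues, "", fixed = TRUE)[[1]], AMINO_ACIDS)
  counts <- tabulate(idx, nbins = 20L)
  names(counts) <- AMINO_ACIDS
  counts
}

#' @export
print.composition_vector <- function(x, ...) {
  cat("<composition_vector> total =", x$total, "\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Randomly scramble a sequence
#'
#' Returns a uniform-random permutation of the residues (the multiset is
#' preserved, so composition is invariant). Deterministic for a fixed seed;
#' the caller's RNG state is left untouched.
#'
#' @param rec A \code{seq_record} or character scalar.
#' @param seed Integer seed (required, for reproducibility).
#' @return A \code{seq_record} with id suffixed \code{"_scrambled"}.
#' @export
scramble <- function(rec, seed) {
  rec <- as_seq_record(rec)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  chars <- seq_chars(rec)
  perm <- with_seed(seed, sample.int(length(chars)))
  seq_record(paste0(rec$id, "_scrambled"), paste(chars[perm], collapse = ""))
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
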