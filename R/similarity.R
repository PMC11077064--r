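# Linear-sequence conservation: global pairwise alignment identity and
# similarity, plus the scrambled-self null baseline that calibrates what
# "no linear homology" looks like for a given composition.

#' Alignment parameters
#'
#' EMBOSS-needle-style defaults: BLOSUM62, gap open 10, gap extend 0.5.
#'
#' @param matrix Substitution matrix name (any matrix shipped with
#'   Biostrings, e.g. \code{"BLOSUM62"}, \code{"BLOSUM45"}, \code{"PAM250"}).
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @param denominator \code{"alignment"} (default): percentages are over all
#'   alignment columns, gap columns included scoring 0.
#'   \code{"shorter"}: over the shorter sequence's length.
#' @return An \code{align_params} list.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5,
                         denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, denominator = denominator),
            class = "align_params")
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise alignment identity and similarity
#'
#' Needleman-Wunsch global alignment under the configured substitution
#' matrix and affine gap penalties. Percent identity is the fraction of
#' alignment columns with identical residues; percent similarity is the
#' fraction of columns whose residue pair has a positive substitution score
#' (identities included). With the default denominator, gap columns count
#' in the denominator and score 0.
#'
#' @param a,b \code{seq_record} or character scalar.
#' @param params An \code{\link{align_params}} object.
#' @return An \code{alignment_similarity} list: \code{id_a}, \code{id_b},
#'   \code{pct_identity}, \code{pct_similarity}, \code{aln_length},
#'   \code{params}.
#' @examples
#' align_similarity("KKKK", "RRRR")$pct_similarity  # 100 (K/R scores +2)
#' @export
align_similarity <- function(a, b, params = align_params()) {
  a <- as_seq_record(a, "a"); b <- as_seq_record(b, "b")
  # Canonicalize the argument order before aligning: when several
  # alignments tie for the optimal score, the traceback picks one
  # depending on which sequence is the pattern, which would make the
  # reported percentages order-dependent.
  swapped <- b$residues < a$residues
  p1 <- if (swapped) b else a
  p2 <- if (swapped) a else b
  submat <- get_submat(params$matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1$residues), Biostrings::AAString(p2$residues),
    substitutionMatrix = submat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  no_gap <- pa != "-" & pb != "-"
  ident <- sum(no_gap & pa == pb)
  simil <- sum(submat[cbind(pa[no_gap], pb[no_gap])] > 0)
  denom <- if (params$denominator == "alignment") length(pa)
           else min(nchar(p1$residues), nchar(p2$residues))
  structure(list(id_a = a$id, id_b = b$id,
                 pct_identity = 100 * ident / denom,
                 pct_similarity = 100 * simil / denom,
                 aln_length = length(pa), params = params),
            class = "alignment_similarity")
}

#' @export
print.alignment_similarity <- function(x, ...) {
  cat(sprintf("<alignment_similarity> %s vs %s: %.1f%% id, %.1f%% sim (%d cols)\n",
              x$id_a, x$id_b, x$pct_identity, x$pct_similarity, x$aln_length))
  invisible(x)
}

#' Scrambled-self alignment baseline
#'
#' Aligns a sequence against n random scrambles of itself and summarizes the
#' percent similarity: the null level of alignment similarity expected with
#' identical composition but no conserved linear order.
#'
#' @param a \code{seq_record} or character scalar.
#' @param n Number of scrambles, >= 1.
#' @param seed Integer seed (scramble k uses seed + k).
#' @param params An \code{\link{align_params}} object.
#' @return List: \code{mean}, \code{min}, \code{max}, \code{values}
#'   (per-scramble percent similarity), \code{n}.
#' @export
scrambled_baseline <- function(a, n = 10L, seed, params = align_params()) {
  stopifnot(n >= 1L)
  a <- as_seq_record(a, "a")
  vals <- vapply(seq_len(n), function(k) {
    align_similarity(a, scramble(a, seed + k), params)$pct_similarity
  }, 0)
  list(mean = mean(vals), min = min(vals), max = max(vals),
       values = vals, n = n)
}

#' All-vs-all alignment similarity matrices
#'
#' Evaluates every unordered pair once and mirrors the results. Optionally
#' appends a scrambled-self baseline column (mean percent similarity of
#' each sequence against \code{n_scrambles} scrambles of itself) — the
#' conventional "*" column of a similarity heatmap.
#'
#' @param seqs List of \code{seq_record} with unique ids.
#' @param params An \code{\link{align_params}} object.
#' @param with_scrambled Compute the scrambled-self baseline column.
#' @param n_scrambles Scrambles per sequence for the baseline.
#' @param seed Integer seed (required when \code{with_scrambled}).
#' @return A \code{similarity_matrix}: list with \code{pct_identity} and
#'   \code{pct_similarity} (symmetric matrices, diagonal 100),
#'   \code{scrambled} (named vector or NULL), \code{params}.
#' @export
similarity_matrix <- function(seqs, params = align_params(),
                              with_scrambled = FALSE, n_scrambles = 10L,
                              seed = NULL) {
  stopifnot(length(seqs) >= 2L)
  seqs <- lapply(seqs, as_seq_record)
  ids <- vapply(seqs, function(s) s$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  n <- length(seqs)
  mid <- msim <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- align_similarity(seqs[[i]], seqs[[j]], params)
      mid[i, j] <- mid[j, i] <- r$pct_identity
      msim[i, j] <- msim[j, i] <- r$pct_similarity
    }
  }
  scr <- NULL
  if (with_scrambled) {
    if (is.null(seed)) stop("seed required for the scrambled baseline",
                            call. = FALSE)
    scr <- vapply(seq_len(n), function(i) {
      scrambled_baseline(seqs[[i]], n = n_scrambles,
                         seed = seed + 1000L * i, params = params)$mean
    }, 0)
    names(scr) <- ids
  }
  structure(list(pct_identity = mid, pct_similarity = msim,
                 scrambled = scr, params = params),
            class = "similarity_matrix")
}
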