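# Normalized chi-square compositional dissimilarity (chi-score).
#
# The score is the chi-square test-of-homogeneity statistic on the 2 x K
# contingency table of amino-acid counts, normalized so that compositionally
# identical sequences score 0 and sequences sharing no residues score 1.
# With two rows the normalization sqrt(chi2 / N) is Cramer's V; the raw chi2
# and N are returned so the phi-squared variant (chi2/N) is recoverable.

# Core statistic on two count vectors over the fixed 20-letter alphabet.
# Columns with zero total are dropped (0/0 contribution). Returns chi2.
chi2_counts <- function(c1, c2) {
  col <- c1 + c2
  keep <- col > 0
  c1 <- c1[keep]; c2 <- c2[keep]; col <- col[keep]
  n1 <- sum(c1); n2 <- sum(c2); N <- n1 + n2
  e1 <- n1 * col / N
  e2 <- n2 * col / N
  sum((c1 - e1)^2 / e1) + sum((c2 - e2)^2 / e2)
}

#' Chi-score: compositional dissimilarity between two sequences
#'
#' Builds the 2 x K contingency table of amino-acid counts (rows = sequences,
#' columns = amino acids present in at least one sequence), computes the
#' chi-square homogeneity statistic with expected counts from the table
#' margins, and normalizes it to \code{sqrt(chi2 / N)} where N is the total
#' residue count over both rows (Cramer's V for a two-row table). The score
#' is 0 exactly when the two fractional compositions are equal and 1 exactly
#' when the sequences share no amino-acid letters. No p-value is computed:
#' the statistic is used as a dissimilarity measure, not a hypothesis test.
#'
#' The classical test is count-based, so with \code{equal_weight = FALSE}
#' (the default) a longer sequence carries more weight. With
#' \code{equal_weight = TRUE} each row is rescaled to the mean of the two
#' totals before the statistic is formed, giving the two sequences equal
#' influence regardless of length.
#'
#' @param a,b \code{seq_record}, character scalar, or
#'   \code{composition_vector}.
#' @param equal_weight Rescale both rows to a common total first.
#' @return Object of class \code{chi_score_result}: \code{score} in [0,1],
#'   \code{chi2}, \code{n_total}, \code{dropped_columns} (amino acids absent
#'   from both sequences) and \code{normalization} = \code{"cramers-v"}.
#' @examples
#' chi_score("AG", "GA")$score        # 0: identical composition
#' chi_score("AAAA", "GGGG")$score    # 1: no shared letters
#' @export
chi_score <- function(a, b, equal_weight = FALSE) {
  ca <- as_counts(a)
  cb <- as_counts(b)
  if (sum(ca) == 0 || sum(cb) == 0) stop("empty sequence", call. = FALSE)
  if (equal_weight) {
    m <- (sum(ca) + sum(cb)) / 2
    ca <- ca / sum(ca) * m
    cb <- cb / sum(cb) * m
  }
  chi_score_from_counts(ca, cb)
}

chi_score_from_counts <- function(ca, cb) {
  N <- sum(ca) + sum(cb)
  chi2 <- chi2_counts(ca, cb)
  score <- sqrt(chi2 / N)
  # clamp floating-point overshoot; exact endpoints are part of the contract
  score <- min(max(score, 0), 1)
  structure(list(score = score, chi2 = chi2, n_total = N,
                 dropped_columns = AMINO_ACIDS[(ca + cb) == 0],
                 normalization = "cramers-v"),
            class = "chi_score_result")
}

#' @export
print.chi_score_result <- function(x, ...) {
  cat(sprintf("<chi_score_result> score = %.6f (chi2 = %.4f, N = %d)\n",
              x$score, x$chi2, x$n_total))
  invisible(x)
}

as_counts <- function(x) {
  if (inherits(x, "composition_vector")) return(x$counts)
  count_residues(as_seq_record(x)$residues)
}

#' Chi-score of a sequence against the standardized uniform reference
#'
#' Compares a sequence against a pseudo-sequence of the same total length
#' containing exactly 5\% of each of the 20 amino acids (fractional expected
#' counts permitted). This is the "standardized sequence" reference column
#' of an all-vs-all compositional dissimilarity matrix.
#'
#' @param a \code{seq_record}, character scalar, or \code{composition_vector}.
#' @return A \code{chi_score_result}.
#' @examples
#' score_vs_uniform(paste(AMINO_ACIDS, collapse = ""))$score  # 0
#' @export
score_vs_uniform <- function(a) {
  ca <- as_counts(a)
  N <- sum(ca)
  if (N == 0) stop("empty sequence", call. = FALSE)
  ref <- rep(N * 0.05, 20L)
  names(ref) <- AMINO_ACIDS
  chi_score_from_counts(ca, ref)
}

#' All-vs-all chi-score matrix
#'
#' Evaluates every unordered pair of sequences once and mirrors the result
#' into a symmetric matrix with zero diagonal (20 sequences give 190
#' evaluated pairs). Optionally appends the score of each sequence against
#' the standardized uniform reference.
#'
#' @param seqs List of \code{seq_record} with unique ids.
#' @param include_reference Add a \code{ref_uniform} attribute column.
#' @param equal_weight Passed to \code{\link{chi_score}}.
#' @return A \code{chi_score_matrix}: numeric matrix with id dimnames;
#'   attribute \code{ref_uniform} (named vector) when requested.
#' @export
chi_score_matrix <- function(seqs, include_reference = FALSE,
                             equal_weight = FALSE) {
  stopifnot(length(seqs) >= 2L)
  ids <- vapply(seqs, function(s) as_seq_record(s)$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  comps <- lapply(seqs, as_counts)
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cv1 <- comps[[i]]; cv2 <- comps[[j]]
      if (equal_weight) {
        tot <- (sum(cv1) + sum(cv2)) / 2
        cv1 <- cv1 / sum(cv1) * tot
        cv2 <- cv2 / sum(cv2) * tot
      }
      m[i, j] <- m[j, i] <- chi_score_from_counts(cv1, cv2)$score
    }
  }
  if (include_reference) {
    ref <- vapply(comps, function(cv) {
      s <- score_vs_uniform(structure(list(counts = cv, total = sum(cv)),
                                      class = "composition_vector"))
      s$score
    }, 0)
    names(ref) <- ids
    attr(m, "ref_uniform") <- ref
  }
  class(m) <- c("chi_score_matrix", class(m))
  m
}
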