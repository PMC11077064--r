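# Physicochemical and motif profiling of disordered regions: charge tracks,
# isoelectric point, CDK phosphorylation consensus sites, AT-hooks,
# phospho-site window matrices, and the site-count-vs-length regression.

BASIC_RESIDUES <- c("K", "R")
ACIDIC_RESIDUES <- c("D", "E")

# Side-chain and termini pKa tables. "bjellqvist" is the ExPASy set;
# "emboss" is the EMBOSS iep set. Positive charge: K, R, H, N-terminus;
# negative: D, E, C, Y, C-terminus.
PKA_TABLES <- list(
  bjellqvist = c(C = 9.0, D = 4.05, E = 4.45, H = 5.98, K = 10.0, R = 12.0,
                 Y = 10.0, nterm = 7.5, cterm = 3.55),
  emboss = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5,
             Y = 10.1, nterm = 8.6, cterm = 3.6)
)

#' Net charge per residue track
#'
#' Centered sliding mean of per-residue charge (K, R = +1; D, E = -1; all
#' other residues 0, histidine included, following the neutral-pH
#' convention). Positions near the ends use the truncated window.
#'
#' @param rec \code{seq_record} or character scalar.
#' @param window Odd window width, \code{<=} sequence length.
#' @return Numeric vector of length L, values in [-1, 1].
#' @examples
#' ncpr_track("KKKKK", 3)  # all +1
#' @export
ncpr_track <- function(rec, window = 25L) {
  rec <- as_seq_record(rec)
  window <- as.integer(window)
  L <- nchar(rec$residues)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window > L) stop("window exceeds sequence length", call. = FALSE)
  chars <- seq_chars(rec)
  q <- (chars %in% BASIC_RESIDUES) - (chars %in% ACIDIC_RESIDUES)
  half <- window %/% 2L
  cs <- c(0, cumsum(q))
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + half, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fraction of charged residues
#'
#' (K + R + D + E) / length.
#'
#' @param rec \code{seq_record} or character scalar.
#' @return Number in [0, 1].
#' @export
fcr <- function(rec) {
  rec <- as_seq_record(rec)
  chars <- seq_chars(rec)
  mean(chars %in% c(BASIC_RESIDUES, ACIDIC_RESIDUES))
}

# Henderson-Hasselbalch net charge at a given pH.
net_charge_at_ph <- function(counts, ph, pka, include_termini) {
  pos_frac <- function(pk) 1 / (1 + 10^(ph - pk))   # protonated fraction
  neg_frac <- function(pk) 1 / (1 + 10^(pk - ph))   # deprotonated fraction
  q <- counts["K"] * pos_frac(pka["K"]) +
       counts["R"] * pos_frac(pka["R"]) +
       counts["H"] * pos_frac(pka["H"]) -
       counts["D"] * neg_frac(pka["D"]) -
       counts["E"] * neg_frac(pka["E"]) -
       counts["C"] * neg_frac(pka["C"]) -
       counts["Y"] * neg_frac(pka["Y"])
  if (include_termini) {
    q <- q + pos_frac(pka["nterm"]) - neg_frac(pka["cterm"])
  }
  unname(q)
}

#' Isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the sequence is zero,
#' found by bisection on [0, 14] to a tolerance of 1e-3. The charge sums the
#' protonatable side chains (D, E, C, Y, H, K, R) and, by default, the free
#' termini. Net charge is strictly decreasing in pH, so the root is unique.
#'
#' @param rec \code{seq_record} or character scalar.
#' @param pka_set \code{"bjellqvist"} (ExPASy-style, default) or
#'   \code{"emboss"}, or a named numeric vector with entries C, D, E, H, K,
#'   R, Y, nterm, cterm.
#' @param include_termini Include the terminal charges (default TRUE).
#' @return The pI (numeric).
#' @examples
#' isoelectric_point("KKKK") > 7   # basic peptide
#' @export
isoelectric_point <- function(rec, pka_set = "bjellqvist",
                              include_termini = TRUE) {
  rec <- as_seq_record(rec)
  pka <- if (is.character(pka_set)) {
    if (!pka_set %in% names(PKA_TABLES)) {
      stop("unknown pKa set '", pka_set, "'", call. = FALSE)
    }
    PKA_TABLES[[pka_set]]
  } else {
    stopifnot(all(c("C", "D", "E", "H", "K", "R", "Y", "nterm", "cterm")
                  %in% names(pka_set)))
    pka_set
  }
  counts <- count_residues(rec$residues)
  lo <- 0; hi <- 14
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (net_charge_at_ph(counts, mid, pka, include_termini) > 0) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

#' CDK/cyclin phosphorylation consensus sites
#'
#' Overlapping scan for the minimal consensus \code{[S/T]P} (position i has
#' S or T and position i+1 has P) and the optimal consensus
#' \code{[S/T]PX[R/K]} (additionally, position i+3 has K or R). Every
#' optimal site is also a minimal site.
#'
#' @param rec \code{seq_record} or character scalar.
#' @return List with integer vectors \code{minimal} and \code{optimal}
#'   (1-based positions of the phospho-acceptor S/T).
#' @examples
#' cdk_sites("TPAR")  # minimal 1, optimal 1
#' @export
cdk_sites <- function(rec) {
  rec <- as_seq_record(rec)
  chars <- seq_chars(rec)
  L <- length(chars)
  if (L < 2L) return(list(minimal = integer(0), optimal = integer(0)))
  i <- seq_len(L - 1L)
  minimal <- i[chars[i] %in% c("S", "T") & chars[i + 1L] == "P"]
  optimal <- minimal[minimal + 3L <= L &
                       chars[minimal + 3L] %in% c("K", "R")]
  list(minimal = minimal, optimal = optimal)
}

#' Phospho-dead transform
#'
#' Replaces the S/T of every \code{[S/T]P} site with alanine (the
#' "P-dead" construct transform). Length is unchanged and the result has no
#' minimal CDK site; the transform is idempotent.
#'
#' @param rec \code{seq_record} or character scalar.
#' @return A \code{seq_record} with id suffixed \code{"_Pdead"}.
#' @examples
#' phospho_dead("MSPATPK")$residues  # "MAPAAPK"
#' @export
phospho_dead <- function(rec) {
  rec <- as_seq_record(rec)
  out <- gsub("[ST](?=P)", "A", rec$residues, perl = TRUE)
  seq_record(paste0(rec$id, "_Pdead"), out,
             source_range = rec$source_range)
}

#' Find AT-hook motifs
#'
#' Locates every occurrence of the core (default \code{"GRP"}) and accepts a
#' hit when at least \code{min_basic} K/R residues lie within \code{flank}
#' positions on either side of the core (both sides combined). Overlapping
#' identical cores are reported once.
#'
#' @param rec \code{seq_record} or character scalar.
#' @param core Regular expression for the motif core; \code{"G.RP"} admits
#'   the degenerate spaced core.
#' @param flank Context width on each side (default 3).
#' @param min_basic Minimum K/R count in the combined context (default 2).
#' @return \code{data.frame(start, end, match)} — core coordinates and the
#'   context-extended matched text. Zero rows when nothing matches.
#' @examples
#' find_at_hooks("RKRGRPRKEE")  # the canonical AT-hook
#' @export
find_at_hooks <- function(rec, core = "GRP", flank = 3L, min_basic = 2L) {
  rec <- as_seq_record(rec)
  chars <- seq_chars(rec)
  L <- length(chars)
  m <- gregexpr(core, rec$residues)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0)))
  }
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  keep <- vapply(seq_along(starts), function(k) {
    lo <- max(1L, starts[k] - flank)
    hi <- min(L, ends[k] + flank)
    ctx <- chars[c(seq(lo, length.out = starts[k] - lo),
                   seq(ends[k] + 1L, length.out = hi - ends[k]))]
    sum(ctx %in% BASIC_RESIDUES) >= min_basic
  }, NA)
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    start = starts, end = ends,
    match = vapply(seq_along(starts), function(k) {
      substr(rec$residues, max(1L, starts[k] - flank),
             min(L, ends[k] + flank))
    }, ""))
}

#' Position frequency matrix of phospho-site windows
#'
#' Builds a 20 x (2 flank + 1) position frequency matrix from the residues
#' surrounding each site (site centered; default flank 4 gives 9 columns,
#' i.e. the eight residues immediately surrounding the modified amino
#' acid). Sites too close to a sequence end are padded with a gap symbol
#' that is excluded from the frequencies, so each column sums to 1 over the
#' residues actually observed.
#'
#' @param seqs_and_sites List of \code{list(rec, positions)} pairs.
#' @param flank Context width on each side, >= 1.
#' @param include_center Keep the central (site) column (default TRUE); when
#'   FALSE the matrix has 2 flank columns, the site excluded.
#' @return Numeric matrix, rows = amino acids, columns = window offsets
#'   (\code{-flank ... +flank}).
#' @export
site_window_matrix <- function(seqs_and_sites, flank = 4L,
                               include_center = TRUE) {
  flank <- as.integer(flank)
  stopifnot(flank >= 1L)
  offsets <- (-flank):flank
  if (!include_center) offsets <- offsets[offsets != 0L]
  counts <- matrix(0, 20L, length(offsets),
                   dimnames = list(AMINO_ACIDS, as.character(offsets)))
  n_sites <- 0L
  for (item in seqs_and_sites) {
    rec <- as_seq_record(item[[1]])
    chars <- seq_chars(rec)
    L <- length(chars)
    for (p in item[[2]]) {
      stopifnot(p >= 1L, p <= L)
      n_sites <- n_sites + 1L
      for (k in seq_along(offsets)) {
        q <- p + offsets[k]
        if (q >= 1L && q <= L) {
          counts[chars[q], k] <- counts[chars[q], k] + 1
        }
      }
    }
  }
  if (n_sites == 0L) stop("no sites supplied", call. = FALSE)
  colsum <- colSums(counts)
  sweep(counts, 2L, ifelse(colsum > 0, colsum, 1), "/")
}

#' Regression of CDK site count on sequence length
#'
#' Ordinary least squares of the minimal \code{[S/T]P} site count on
#' sequence length across a set of feature profiles, with the Pearson
#' correlation. Quantifies whether site number scales linearly with
#' disordered-region length.
#'
#' @param profiles List of \code{feature_profile} objects (or any lists
#'   with \code{length} and \code{cdk_minimal} fields), >= 3.
#' @return List: \code{slope}, \code{intercept}, \code{r}.
#' @export
sites_vs_length_fit <- function(profiles) {
  stopifnot(length(profiles) >= 3L)
  x <- vapply(profiles, function(p) as.numeric(p$length), 0)
  y <- vapply(profiles, function(p) length(p$cdk_minimal), 0)
  if (stats::sd(x) == 0) stop("zero length variance", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), r = r)
}

#' Full feature profile of a sequence
#'
#' Bundles the charge, pI and motif features of one sequence: NCPR track,
#' positions of basic and acidic residues, FCR, pI, minimal and optimal CDK
#' consensus sites, and AT-hooks.
#'
#' @param rec \code{seq_record} or character scalar.
#' @param ncpr_window Odd window for the NCPR track.
#' @param pka_set,include_termini Passed to \code{\link{isoelectric_point}}.
#' @return A \code{feature_profile} list.
#' @export
feature_profile <- function(rec, ncpr_window = 25L,
                            pka_set = "bjellqvist", include_termini = TRUE) {
  rec <- as_seq_record(rec)
  chars <- seq_chars(rec)
  sites <- cdk_sites(rec)
  win <- min(ncpr_window, nchar(rec$residues))
  if (win %% 2L == 0L) win <- win - 1L
  structure(list(
    sequence_id = rec$id,
    length = nchar(rec$residues),
    ncpr_track = ncpr_track(rec, win),
    charge_positions = list(basic = which(chars %in% BASIC_RESIDUES),
                            acidic = which(chars %in% ACIDIC_RESIDUES)),
    fcr = fcr(rec),
    pi = isoelectric_point(rec, pka_set, include_termini),
    cdk_minimal = sites$minimal,
    cdk_optimal = sites$optimal,
    at_hooks = find_at_hooks(rec)
  ), class = "feature_profile")
}

#' @export
print.feature_profile <- function(x, ...) {
  cat(sprintf(
    "<feature_profile> %s: %d aa, FCR %.3f, pI %.2f, %d/%d CDK sites (minimal/optimal), %d AT-hook(s)\n",
    x$sequence_id, x$length, x$fcr, x$pi,
    length(x$cdk_minimal), length(x$cdk_optimal), nrow(x$at_hooks)))
  invisible(x)
}
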