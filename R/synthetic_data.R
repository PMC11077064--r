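# Seeded generators emulating the statistical structure the analyses assume:
# ortholog families sharing composition with randomized linear order,
# modular sequences with known compositional boundaries, and per-timepoint
# chromosome/cytosol ROI intensity series with multiplicative noise.

#' A realistic disordered-region composition preset
#'
#' Amino-acid fractions qualitatively emulating a basic, phospho-site-rich
#' disordered region: enriched in S, T, P, K and R, depleted in W, C and F.
#' The exact values are package constants, not estimates from any dataset.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
idr_composition <- function() {
  w <- c(A = 6, C = 0.5, D = 4, E = 5, F = 1, G = 6, H = 2, I = 3, K = 9,
         L = 5, M = 1.5, N = 4, P = 9, Q = 4, R = 8, S = 12, T = 9, V = 4,
         W = 0.5, Y = 1.5)
  w <- w[AMINO_ACIDS]
  w / sum(w)
}

#' A single-residue-biased composition
#'
#' Weight \code{weight} on \code{residue}, the remainder spread uniformly
#' over the other 19 amino acids. Useful for building strongly modular
#' synthetic sequences.
#'
#' @param residue One canonical amino-acid letter.
#' @param weight Fraction assigned to \code{residue}, in (0, 1].
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
biased_composition <- function(residue, weight = 0.8) {
  stopifnot(residue %in% AMINO_ACIDS, weight > 0, weight <= 1)
  p <- rep((1 - weight) / 19, 20L)
  names(p) <- AMINO_ACIDS
  p[residue] <- weight
  p
}

check_composition <- function(composition) {
  stopifnot(is.numeric(composition), length(composition) == 20L)
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
    stop("composition must be 20 non-negative fractions summing to 1",
         call. = FALSE)
  }
  if (is.null(names(composition))) names(composition) <- AMINO_ACIDS
  composition[AMINO_ACIDS]
}

#' Sample an i.i.d. sequence from a composition
#'
#' @param composition Named 20-vector of fractions summing to 1.
#' @param length Sequence length.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param id Record id.
#' @return A \code{seq_record}.
#' @export
sample_sequence <- function(composition, length, seed, id = "synthetic") {
  composition <- check_composition(composition)
  stopifnot(length >= 1L)
  chars <- with_seed(seed,
    sample(AMINO_ACIDS, size = length, replace = TRUE, prob = composition))
  seq_record(id, paste(chars, collapse = ""))
}

#' Generate a family of compositionally homologous sequences
#'
#' Independent i.i.d. sequences drawn from one shared composition. Members
#' share amino-acid composition (all-vs-all chi-scores near 0 at realistic
#' lengths) but have randomized linear order, so pairwise alignment
#' similarity sits near the scrambled-self baseline — the synthetic analogue
#' of an ortholog set with compositional but not linear homology.
#'
#' @param composition Named 20-vector of fractions summing to 1.
#' @param n_members Number of sequences.
#' @param lengths Either one length for all members, a vector of
#'   per-member lengths, or a \code{c(min, max)} range to sample from
#'   (interpreted as a range when exactly 2 values are given for
#'   more than 2 members). All lengths must be >= 20.
#' @param seed Integer seed.
#' @param prefix Id prefix; members are \code{prefix_1 ... prefix_n}.
#' @return List of \code{seq_record}.
#' @export
make_family <- function(composition, n_members, lengths = 300L, seed,
                        prefix = "fam") {
  composition <- check_composition(composition)
  stopifnot(n_members >= 1L)
  lens <- with_seed(seed, {
    if (length(lengths) == 1L) {
      rep.int(as.integer(lengths), n_members)
    } else if (length(lengths) == n_members) {
      as.integer(lengths)
    } else if (length(lengths) == 2L) {
      sample(seq.int(lengths[1], lengths[2]), n_members, replace = TRUE)
    } else {
      stop("lengths must be scalar, per-member, or c(min, max)",
           call. = FALSE)
    }
  })
  if (any(lens < 20L)) stop("member lengths must be >= 20", call. = FALSE)
  lapply(seq_len(n_members), function(k) {
    sample_sequence(composition, lens[k], seed = seed + k,
                    id = sprintf("%s_%d", prefix, k))
  })
}

#' Generate a modular sequence with known boundaries
#'
#' Concatenates i.i.d. segments of given compositions and lengths, returning
#' both the sequence and the true junction positions (cumulative segment
#' lengths) as ground truth for segmentation-recovery tests.
#'
#' @param segments List of \code{list(composition, length)} pairs, >= 2.
#' @param seed Integer seed.
#' @param id Record id.
#' @return List with \code{record} (a \code{seq_record}) and
#'   \code{boundaries} (integer junction positions; a boundary at p lies
#'   between residues p and p + 1).
#' @export
make_modular <- function(segments, seed, id = "modular") {
  stopifnot(length(segments) >= 2L)
  parts <- lapply(seq_along(segments), function(k) {
    seg <- segments[[k]]
    comp <- check_composition(seg[[1]])
    sample_sequence(comp, seg[[2]], seed = seed + 1000L * k)$residues
  })
  lens <- vapply(segments, function(s) as.integer(s[[2]]), 0L)
  list(record = seq_record(id, paste(parts, collapse = "")),
       boundaries = cumsum(lens)[-length(lens)])
}

#' Generate a synthetic chromosome/cytosol ROI series
#'
#' Per cell and timepoint, chromosome and cytosolic mean intensities are set
#' so the noise-free partition coefficient equals the programmed per-stage
#' value, then multiplied by lognormal noise with coefficient of variation
#' \code{noise_cv}. Stage labels cycle metaphase, anaphase, telophase,
#' with \code{frames_per_stage} frames each.
#'
#' @param n_cells Number of cells.
#' @param stage_partition Named numeric: programmed partition coefficient per
#'   stage. Default echoes a metaphase-low / telophase-high partitioning
#'   pattern.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   intensity noise, >= 0.
#' @param seed Integer seed.
#' @param frames_per_stage Frames per stage per cell.
#' @return \code{data.frame} with columns cell_id, timepoint, stage, i_chr,
#'   a_chr, i_cyt, a_cyt.
#' @export
make_roi_series <- function(n_cells = 6L,
                            stage_partition = c(metaphase = 0.24,
                                                anaphase = 0.40,
                                                telophase = 0.56),
                            noise_cv = 0.1, seed, frames_per_stage = 2L) {
  stopifnot(noise_cv >= 0, n_cells >= 1L, frames_per_stage >= 1L)
  stopifnot(all(stage_partition > 0), all(stage_partition < 1))
  stages <- rep(names(stage_partition), each = frames_per_stage)
  a_chr <- 150; a_cyt <- 600; i_cyt0 <- 100
  with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    rows <- lapply(seq_len(n_cells), function(cell) {
      p <- stage_partition[stages]
      # i_chr solving p = i_chr*a_chr / (i_chr*a_chr + i_cyt*a_cyt), noise-free
      i_chr0 <- p / (1 - p) * (i_cyt0 * a_cyt) / a_chr
      noise <- function(n) {
        if (noise_cv == 0) rep.int(1, n)
        else stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      data.frame(cell_id = sprintf("cell_%d", cell),
                 timepoint = seq_along(stages),
                 stage = stages,
                 i_chr = i_chr0 * noise(length(stages)),
                 a_chr = a_chr,
                 i_cyt = i_cyt0 * noise(length(stages)),
                 a_cyt = a_cyt,
                 row.names = NULL)
    })
    do.call(rbind, rows)
  })
}
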