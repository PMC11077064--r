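# Live-imaging quantitation from ROI-statistics tables: chromosome/cytosol
# enrichment ratio, chromosome partition coefficient, and the
# metaphase-normalized fold-change series. Image segmentation is upstream;
# the CSV column contract (cell_id, timepoint, stage, i_chr, a_chr, i_cyt,
# a_cyt) is the boundary.

ROI_COLUMNS <- c("cell_id", "timepoint", "stage", "i_chr", "a_chr",
                 "i_cyt", "a_cyt")

#' Read an ROI-statistics table
#'
#' CSV with the required header columns \code{cell_id, timepoint, stage,
#' i_chr, a_chr, i_cyt, a_cyt}: per cell and timepoint, the mean
#' background-subtracted chromosome and cytosolic ROI intensities and the
#' ROI areas. Negative intensities (possible after background subtraction)
#' are clamped to 0 with a warning; non-positive areas are an error.
#'
#' @param path Path to the CSV file.
#' @return A validated \code{data.frame}.
#' @export
read_roi_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_roi(df)
}

validate_roi <- function(df) {
  missing_cols <- setdiff(ROI_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("ROI table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("i_chr", "i_cyt")) {
    neg <- !is.na(df[[col]]) & df[[col]] < 0
    if (any(neg)) {
      warning(sum(neg), " negative ", col,
              " value(s) clamped to 0 (background over-subtraction)",
              call. = FALSE)
      df[[col]][neg] <- 0
    }
  }
  if (any(df$a_chr <= 0) || any(df$a_cyt <= 0)) {
    stop("ROI areas must be strictly positive", call. = FALSE)
  }
  df
}

#' Chromosome partition coefficient
#'
#' The fraction of total signal residing on chromosomes:
#' \deqn{P = \frac{I_{chr} A_{chr}}{I_{chr} A_{chr} + I_{cyt} A_{cyt}}}
#' i.e. chromosome signal times chromosome area divided by the sum of the
#' same plus cytosolic intensity times cytosolic area. Values lie in
#' [0, 1]; rescaling all intensities by a common factor leaves the
#' coefficient unchanged. Vectorized.
#'
#' @param i_chr,a_chr Chromosome ROI mean intensity and area, or a
#'   \code{data.frame}/list with the four ROI columns as first argument.
#' @param i_cyt,a_cyt Cytosolic ROI mean intensity and area.
#' @return Numeric vector of partition coefficients.
#' @examples
#' partition_coefficient(3, 1, 1, 1)  # 0.75
#' @export
partition_coefficient <- function(i_chr, a_chr = NULL, i_cyt = NULL,
                                  a_cyt = NULL) {
  if (is.list(i_chr)) {
    r <- i_chr
    i_chr <- r$i_chr; a_chr <- r$a_chr; i_cyt <- r$i_cyt; a_cyt <- r$a_cyt
  }
  stopifnot(all(a_chr > 0), all(a_cyt > 0),
            all(i_chr >= 0), all(i_cyt >= 0))
  chr <- i_chr * a_chr
  cyt <- i_cyt * a_cyt
  if (any(chr + cyt == 0)) {
    stop("partition coefficient undefined: chromosome and cytosolic ",
         "signal are both zero", call. = FALSE)
  }
  chr / (chr + cyt)
}

#' Chromosome/cytosol enrichment ratio
#'
#' Ratio of mean chromosome ROI intensity to mean cytosolic intensity.
#' Vectorized.
#'
#' @param i_chr Chromosome intensity, or a \code{data.frame}/list with
#'   \code{i_chr} and \code{i_cyt} columns.
#' @param i_cyt Cytosolic intensity, > 0.
#' @return Numeric vector of ratios.
#' @examples
#' enrichment_ratio(29, 10)  # 2.9
#' @export
enrichment_ratio <- function(i_chr, i_cyt = NULL) {
  if (is.list(i_chr)) {
    r <- i_chr
    i_chr <- r$i_chr; i_cyt <- r$i_cyt
  }
  if (any(i_cyt <= 0)) {
    stop("enrichment ratio undefined: cytosolic intensity must be > 0",
         call. = FALSE)
  }
  i_chr / i_cyt
}

#' Per-cell partition series normalized to a reference stage
#'
#' For each cell, computes the partition coefficient and enrichment ratio
#' at every timepoint and the fold change of the chosen metric relative to
#' the mean metric over that cell's reference-stage rows (so reference
#' timepoints average to 1 within each cell).
#'
#' @param rows ROI \code{data.frame} (one or several cells).
#' @param reference_stage Stage label used as the normalization reference
#'   (default \code{"metaphase"}).
#' @param metric Metric to normalize: \code{"i_chr"} (chromosome intensity,
#'   default) or \code{"partition"}.
#' @return A \code{partition_series} data frame: the input columns plus
#'   \code{partition}, \code{enrichment} (NA where \code{i_cyt} is 0) and
#'   \code{fold_change}.
#' @export
fold_change_series <- function(rows, reference_stage = "metaphase",
                               metric = c("i_chr", "partition")) {
  metric <- match.arg(metric)
  rows <- validate_roi(rows)
  rows$partition <- partition_coefficient(rows)
  rows$enrichment <- ifelse(rows$i_cyt > 0, rows$i_chr / rows$i_cyt,
                            NA_real_)
  rows$fold_change <- NA_real_
  for (cell in unique(rows$cell_id)) {
    sel <- rows$cell_id == cell
    ref <- sel & rows$stage == reference_stage
    if (!any(ref)) {
      stop("cell '", cell, "' has no rows at reference stage '",
           reference_stage, "'", call. = FALSE)
    }
    v <- if (metric == "i_chr") rows$i_chr else rows$partition
    ref_mean <- mean(v[ref])
    if (ref_mean == 0) {
      stop("cell '", cell, "': reference-stage mean of ", metric,
           " is zero", call. = FALSE)
    }
    rows$fold_change[sel] <- v[sel] / ref_mean
  }
  class(rows) <- c("partition_series", class(rows))
  rows
}

#' Cross-cell partition summary by mitotic stage
#'
#' Per-cell partition coefficients are averaged within each stage, then
#' summarized across cells (mean and standard deviation per stage). The
#' first two stages are compared with a two-sample, two-tailed Welch
#' t-test.
#'
#' @param series A \code{partition_series} (or ROI data frame;
#'   \code{\link{fold_change_series}} is applied if the partition column is
#'   absent).
#' @param stages Stage labels to summarize (default metaphase and
#'   telophase).
#' @return List: \code{summary} data frame (stage, n_cells, mean, sd) and
#'   \code{p_value} for the two-stage comparison.
#' @export
summarize_by_stage <- function(series,
                               stages = c("metaphase", "telophase")) {
  if (!"partition" %in% names(series)) {
    series <- validate_roi(series)
    series$partition <- partition_coefficient(series)
  }
  per_cell <- lapply(stages, function(st) {
    sub <- series[series$stage == st, ]
    vals <- tapply(sub$partition, sub$cell_id, mean)
    vals[!is.na(vals)]
  })
  names(per_cell) <- stages
  n_cells <- vapply(per_cell, length, 0L)
  if (any(n_cells < 2L)) {
    stop("need at least 2 cells per stage; got ",
         paste(sprintf("%s=%d", stages, n_cells), collapse = ", "),
         call. = FALSE)
  }
  smry <- data.frame(stage = stages, n_cells = n_cells,
                     mean = vapply(per_cell, mean, 0),
                     sd = vapply(per_cell, stats::sd, 0),
                     row.names = NULL)
  p <- tryCatch(
    stats::t.test(per_cell[[1]], per_cell[[2]],
                  alternative = "two.sided")$p.value,
    error = function(e) {
      # degenerate: zero variance in both groups
      if (mean(per_cell[[1]]) == mean(per_cell[[2]])) 1 else 0
    })
  list(summary = smry, p_value = p)
}
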