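# Self-assessment computations: the naive per-cell false-negative rate from
# bulk-heterozygous SNP recovery, and the summary ratios used when comparing
# call sets.

#' Estimate per-cell false-negative rates from bulk-heterozygous SNPs
#'
#' SNPs heterozygous in both the normal and tumor bulk of the individual
#' are heterozygous in every tumor cell, so any cell where the heterozygous
#' status cannot be recovered is a false negative. A SNP is evaluable in a
#' cell when its site carries more than `min_depth` qualified reads there;
#' the cell's FNR is the fraction of evaluable SNPs not called
#' heterozygous (homozygous or uncertain).
#'
#' Two pooled figures are reported, since per-cell averaging and pooling
#' over all (cell, SNP) cases are both defensible: `average_fnr` is the
#' unweighted mean of per-cell FNRs (cells with no evaluable SNP dropped),
#' and `pooled_fnr` divides total unrecovered by total evaluable.
#'
#' @param bulk_het_snps Data frame of SNP sites (`chrom`, `pos`)
#'   heterozygous in both bulks.
#' @param cell_calls Per-cell genotype calls: data frame `cell`, `chrom`,
#'   `pos`, `call`, `depth`.
#' @param min_depth Depth gate; only calls with depth strictly greater are
#'   evaluable (default 5).
#' @return List of class `fnr_report`: `per_cell` (data frame `cell`,
#'   `n_evaluable`, `n_recovered`, `fnr`, with `fnr = NA` when nothing was
#'   evaluable), `average_fnr`, `pooled_fnr`.
#' @export
estimate_fnr <- function(bulk_het_snps, cell_calls, min_depth = 5L) {
  skey <- paste(bulk_het_snps$chrom, bulk_het_snps$pos)
  at_snp <- paste(cell_calls$chrom, cell_calls$pos) %in% skey
  evaluable <- at_snp & cell_calls$depth > min_depth
  cc <- cell_calls[evaluable, , drop = FALSE]
  cells <- unique(cell_calls$cell)
  per <- do.call(rbind, lapply(cells, function(cell) {
    x <- cc[cc$cell == cell, , drop = FALSE]
    n_eval <- nrow(x)
    n_rec <- sum(is_het(x$call))
    data.frame(cell = cell, n_evaluable = n_eval, n_recovered = n_rec,
               fnr = if (n_eval == 0L) NA_real_ else 1 - n_rec / n_eval,
               stringsAsFactors = FALSE)
  }))
  tot_eval <- sum(per$n_evaluable)
  structure(list(
    per_cell = per,
    average_fnr = mean(per$fnr, na.rm = TRUE),
    pooled_fnr = if (tot_eval == 0L) NA_real_
      else 1 - sum(per$n_recovered) / tot_eval
  ), class = "fnr_report")
}

#' @export
print.fnr_report <- function(x, ...) {
  cat(sprintf("FNR over %d cells: average %.3f, pooled %.3f\n",
              nrow(x$per_cell), x$average_fnr, x$pooled_fnr))
  invisible(x)
}

#' Summarize call-set overlaps as ratios and rounded percentages
#'
#' @param numerators,denominators Non-negative counts (denominators strictly
#'   positive), recycled to equal length.
#' @param labels Optional names for the rows.
#' @param digits Decimal places for the displayed percentage (default 0,
#'   matching whole-percent reporting of overlap ratios).
#' @return Data frame `label`, `numerator`, `denominator`, `fraction`,
#'   `percent` (rounded to `digits`).
#' @export
comparison_summary <- function(numerators, denominators, labels = NULL,
                               digits = 0L) {
  if (any(denominators <= 0)) stop("denominators must be > 0")
  if (any(numerators < 0)) stop("numerators must be >= 0")
  n <- max(length(numerators), length(denominators))
  numerators <- rep_len(numerators, n)
  denominators <- rep_len(denominators, n)
  if (is.null(labels))
    labels <- paste0(numerators, "/", denominators)
  frac <- numerators / denominators
  data.frame(label = labels, numerator = numerators,
             denominator = denominators, fraction = frac,
             percent = round(100 * frac, digits),
             stringsAsFactors = FALSE)
}

#' Fraction of examined sites that are polymorphic
#'
#' The strategy needs an anchor SNP within one read length of a target, so
#' its reach is bounded by SNP density.
#'
#' @param n_polymorphic Number of polymorphic sites.
#' @param n_sites Total sites examined (> 0).
#' @return List `fraction` and `percent` (one decimal).
#' @export
snp_density <- function(n_polymorphic, n_sites) {
  if (n_sites <= 0) stop("n_sites must be > 0")
  frac <- n_polymorphic / n_sites
  list(fraction = frac, percent = round(100 * frac, 1L))
}
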