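# Somatic-mutation identification.
#
# A site becomes a candidate mutation only when it is heterozygous in
# enough single tumor cells, homozygous-reference in the normal bulk (with
# enough normal coverage to trust that genotype), mutated in the tumor bulk
# as well, outside germline-SNP exclusion lists and amplified-region
# blacklists, and inside the targeted exome (plus flanks) when a target
# file is given. The per-record filters are the standard VCF annotations
# with strict thresholds.

#' Filter configuration for mutation identification
#'
#' All comparisons downstream are strict, matching the wording of the
#' thresholds: QUAL greater than 20, FS less than 40, QD greater than 1.5,
#' GQ greater than 20, more than 5 qualified reads in single cells and more
#' than 20 in bulk, minor allele frequency greater than 0.01 for exclusion,
#' at least three supporting tumor cells.
#'
#' @param min_qual,max_fs,min_qd,min_gq,min_mq Record-level thresholds.
#' @param min_cell_depth,min_bulk_depth Depth gates (strict `>`).
#' @param maf_cutoff Population minor-allele-frequency above which a known
#'   polymorphism excludes the site (strict `>`).
#' @param min_support_cells Minimum number of mutated tumor cells.
#' @param flank_bp Flank around target regions considered in scope.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 20, max_fs = 40, min_qd = 1.5,
                          min_gq = 20, min_mq = 20,
                          min_cell_depth = 5, min_bulk_depth = 20,
                          maf_cutoff = 0.01, min_support_cells = 3L,
                          flank_bp = 90L) {
  cfg <- list(min_qual = min_qual, max_fs = max_fs, min_qd = min_qd,
              min_gq = min_gq, min_mq = min_mq,
              min_cell_depth = min_cell_depth,
              min_bulk_depth = min_bulk_depth, maf_cutoff = maf_cutoff,
              min_support_cells = as.integer(min_support_cells),
              flank_bp = as.integer(flank_bp))
  if (any(vapply(cfg, function(x) x < 0, logical(1))))
    stop("all filter thresholds must be >= 0")
  structure(cfg, class = "filter_config")
}

#' Apply the record-level filters to one variant record
#'
#' Checks, in order: QUAL, FS, QD, GQ, depth (the cell gate for
#' `role = "cell"`, the bulk gate for `role = "bulk"`). The record fails on
#' the first violated criterion, with that criterion's name as the reason.
#' An absent (`NA`) annotation cannot satisfy a strict inequality and fails
#' its criterion.
#'
#' @param rec One variant record: a list or one-row data frame with fields
#'   `qual`, `fs`, `qd`, `gq`, `dp` (see [read_vcf_min()]).
#' @param cfg A [filter_config()].
#' @param role `"cell"` or `"bulk"`; selects the depth gate.
#' @return List `pass` (logical) and `reason` (criterion name, or `NA` on
#'   pass).
#' @export
filter_record <- function(rec, cfg = filter_config(),
                          role = c("cell", "bulk")) {
  role <- match.arg(role)
  ok <- function(x, test) !is.na(x) && test(x)
  checks <- list(
    QUAL = ok(rec$qual, function(x) x > cfg$min_qual),
    FS = ok(rec$fs, function(x) x < cfg$max_fs),
    QD = ok(rec$qd, function(x) x > cfg$min_qd),
    GQ = ok(rec$gq, function(x) x > cfg$min_gq),
    DP = ok(rec$dp, function(x)
      x > if (role == "cell") cfg$min_cell_depth else cfg$min_bulk_depth)
  )
  failed <- names(checks)[!unlist(checks)]
  if (length(failed))
    list(pass = FALSE, reason = failed[1])
  else
    list(pass = TRUE, reason = NA_character_)
}

#' Remove candidates at known polymorphic or excluded sites
#'
#' A candidate is removed when its site appears in any site-level exclusion
#' list (e.g. SNVs called in the individual's normal bulk, or known SNP
#' catalogues), falls in any exclusion region, or appears in the
#' minor-allele-frequency table with MAF strictly greater than
#' `maf_cutoff`.
#'
#' @param candidates Data frame with `chrom`, `pos`.
#' @param site_lists List of data frames with `chrom`, `pos` (exact-site
#'   exclusions). May be empty.
#' @param region_lists List of BED-style data frames with `chrom`, `start`,
#'   `end` (0-based half-open). May be empty.
#' @param maf_table Optional data frame `chrom`, `pos`, `maf`.
#' @param maf_cutoff Exclusion threshold on MAF (strict `>`).
#' @return The surviving subset of `candidates`.
#' @export
exclude_known_sites <- function(candidates, site_lists = list(),
                                region_lists = list(), maf_table = NULL,
                                maf_cutoff = 0.01) {
  if (nrow(candidates) == 0L) return(candidates)
  keep <- rep(TRUE, nrow(candidates))
  ckey <- paste(candidates$chrom, candidates$pos)
  for (s in site_lists)
    keep <- keep & !(ckey %in% paste(s$chrom, s$pos))
  for (r in region_lists)
    keep <- keep & !pos_in_regions(candidates$chrom, candidates$pos, r)
  if (!is.null(maf_table) && nrow(maf_table) > 0L) {
    common <- maf_table[maf_table$maf > maf_cutoff, , drop = FALSE]
    keep <- keep & !(ckey %in% paste(common$chrom, common$pos))
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum supporting cells for significance under a binomial noise model
#'
#' If a spurious variant appears independently in each of `n_cells` cells
#' with probability `fp_rate`, the number of cells showing it is
#' `Binomial(n_cells, fp_rate)`. The smallest support count `k` whose upper
#' tail probability `P[X >= k]` falls below `alpha` is the evidence needed
#' to call a somatic mutation. The pipeline default bypasses this
#' computation and uses the fixed literal `k = 3`.
#'
#' @param n_cells Number of tumor cells examined.
#' @param fp_rate Per-cell false-positive probability, in (0, 1).
#' @param alpha Significance level, in (0, 1).
#' @return Integer `k`.
#' @export
min_support_cells <- function(n_cells, fp_rate, alpha) {
  stopifnot(fp_rate > 0, fp_rate < 1, alpha > 0, alpha < 1)
  for (k in seq_len(n_cells + 1L)) {
    # P[X >= k] for X ~ Binomial(n_cells, fp_rate)
    if (pbinom(k - 1L, n_cells, fp_rate, lower.tail = FALSE) < alpha)
      return(k)
  }
  n_cells + 1L
}

#' Call somatic candidate mutations across single cells and bulks
#'
#' Implements the identification logic: a (site, alt) is reported when
#' \itemize{
#'   \item it is called heterozygous (`0/1` or `1/0`) in at least
#'     `cfg$min_support_cells` cells whose records pass [filter_record()]
#'     with the cell depth gate;
#'   \item the normal bulk is confidently homozygous-reference there: a
#'     normal record exists with GT `0/0` and more than `min_bulk_depth`
#'     reads -- a missing record, low coverage, or any variant genotype in
#'     the normal excludes the site (low normal coverage is precisely the
#'     mechanism that lets dropped-out germline SNPs masquerade as somatic
#'     mutations);
#'   \item the tumor bulk carries the variant (GT `0/1`, `1/0` or `1/1`)
#'     with more than `min_bulk_depth` reads;
#'   \item the site is outside every blacklist region (potentially
#'     amplified tumor regions, supplied as BED) and every exclusion set,
#'     and inside the target regions plus `flank_bp` when targets are
#'     given.
#' }
#'
#' @param cell_records Named list of `variant_records` data frames, one per
#'   cell (names are cell IDs; unnamed lists use each element's
#'   `sample_id` attribute).
#' @param normal_bulk_records `variant_records` for the normal bulk.
#'   Required: calling somatic mutations without a reliable normal genotype
#'   is exactly how germline SNPs get miscalled as mutations.
#' @param tumor_bulk_records `variant_records` for the tumor bulk.
#' @param cfg A [filter_config()].
#' @param site_exclusions,region_exclusions,maf_table Passed to
#'   [exclude_known_sites()].
#' @param amplified_blacklist Optional BED data frame of potentially
#'   amplified regions to drop.
#' @param targets Optional BED data frame of targeted (exome) regions;
#'   candidates must fall within a target or its `cfg$flank_bp` flank.
#' @return Data frame of candidates: `chrom`, `pos`, `ref`, `alt`,
#'   `n_support`, `supporting_cells` (comma-joined cell IDs),
#'   `in_tumor_bulk` (always `TRUE` for survivors).
#' @export
call_mutations <- function(cell_records, normal_bulk_records,
                           tumor_bulk_records, cfg = filter_config(),
                           site_exclusions = list(),
                           region_exclusions = list(), maf_table = NULL,
                           amplified_blacklist = NULL, targets = NULL) {
  if (missing(normal_bulk_records) || is.null(normal_bulk_records))
    stop("a normal bulk sample is required to call somatic mutations")
  ids <- names(cell_records)
  if (is.null(ids))
    ids <- vapply(cell_records, function(x)
      attr(x, "sample_id") %||% NA_character_, character(1))
  if (anyNA(ids)) stop("cell_records must be named or carry sample_id")

  # het calls passing record filters, tallied per (site, alt)
  support <- list()
  for (i in seq_along(cell_records)) {
    rec <- cell_records[[i]]
    for (j in seq_len(nrow(rec))) {
      r <- rec[j, ]
      if (!r$gt %in% c("0/1", "1/0")) next
      if (!filter_record(r, cfg, "cell")$pass) next
      k <- paste(r$chrom, r$pos, r$ref, r$alt, sep = "\r")
      support[[k]] <- c(support[[k]], ids[i])
    }
  }
  if (length(support) == 0L) return(empty_candidates())
  parts <- strsplit(names(support), "\r", fixed = TRUE)
  cand <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    n_support = lengths(support),
    supporting_cells = vapply(support, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  cand <- cand[cand$n_support >= cfg$min_support_cells, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_candidates())

  # normal bulk must be confidently hom-ref; tumor bulk must carry the variant
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    nb <- normal_bulk_records[normal_bulk_records$chrom == cand$chrom[i] &
                                normal_bulk_records$pos == cand$pos[i], ]
    if (nrow(nb) == 0L) return(FALSE)
    nb <- nb[1, ]
    if (is.na(nb$dp) || nb$dp <= cfg$min_bulk_depth) return(FALSE)
    if (!identical(nb$gt, "0/0")) return(FALSE)
    tb <- tumor_bulk_records[tumor_bulk_records$chrom == cand$chrom[i] &
                               tumor_bulk_records$pos == cand$pos[i] &
                               tumor_bulk_records$alt == cand$alt[i], ]
    if (nrow(tb) == 0L) return(FALSE)
    tb <- tb[1, ]
    if (is.na(tb$dp) || tb$dp <= cfg$min_bulk_depth) return(FALSE)
    tb$gt %in% c("0/1", "1/0", "1/1")
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]

  cand <- exclude_known_sites(cand, site_exclusions, region_exclusions,
                              maf_table, cfg$maf_cutoff)
  if (!is.null(amplified_blacklist) && nrow(cand) > 0L)
    cand <- cand[!pos_in_regions(cand$chrom, cand$pos, amplified_blacklist),
                 , drop = FALSE]
  if (!is.null(targets) && nrow(cand) > 0L) {
    flanked <- targets
    flanked$start <- pmax(0L, flanked$start - cfg$flank_bp)
    flanked$end <- flanked$end + cfg$flank_bp
    cand <- cand[pos_in_regions(cand$chrom, cand$pos, flanked), ,
                 drop = FALSE]
  }
  cand$in_tumor_bulk <- rep(TRUE, nrow(cand))
  cand <- cand[order(cand$chrom, cand$pos, cand$alt), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

empty_candidates <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), n_support = integer(0),
             supporting_cells = character(0), in_tumor_bulk = logical(0),
             stringsAsFactors = FALSE)
}
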