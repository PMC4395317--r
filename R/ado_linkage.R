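# Linked-SNP allele-dropout detection.
#
# A germline SNP heterozygous in the individual and within one read length
# of a target site shares the target's amplification fate. Seeing both SNP
# alleles in a cell certifies that no dropout occurred in the region, which
# is what licenses promoting a non-mutant call at the target to a confirmed
# wild-type; seeing only one allele flags dropout, and the target stays
# undefined.

#' Find target sites anchored to nearby heterozygous germline SNPs
#'
#' Pairs every target site with every germline heterozygous SNP on the same
#' chromosome strictly closer than `read_length` base pairs (default 90,
#' the read length: only then can single reads span both sites). The bound
#' is strict -- a distance of exactly `read_length` is excluded -- and a
#' target with several qualifying SNPs yields several pairs.
#'
#' @param targets Data frame of target sites with columns `chrom`, `pos`
#'   (1-based), sorted by `(chrom, pos)`.
#' @param germline_het_snps Data frame of anchor SNP sites, same columns and
#'   sorting. The SNPs must be heterozygous in both the normal and tumor
#'   bulk of the individual.
#' @param read_length Linkage window in bp (strict upper bound on distance).
#' @return Data frame with columns `chrom`, `target_pos`, `anchor_pos`,
#'   `distance`, one row per (target, anchor) pair.
#' @export
find_linked_pairs <- function(targets, germline_het_snps, read_length = 90L) {
  check_sorted(targets, "targets")
  check_sorted(germline_het_snps, "germline_het_snps")
  out <- list()
  for (ch in unique(targets$chrom)) {
    tp <- targets$pos[targets$chrom == ch]
    sp <- germline_het_snps$pos[germline_het_snps$chrom == ch]
    if (length(sp) == 0L) next
    for (p in tp) {
      hit <- sp[abs(sp - p) < read_length & sp != p]
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, target_pos = p, anchor_pos = hit,
          distance = abs(hit - p), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), target_pos = integer(0),
                      anchor_pos = integer(0), distance = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

check_sorted <- function(sites, what) {
  n <- nrow(sites)
  if (n <= 1L) return(invisible())
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(n)))
    stop(what, " must be sorted by (chrom, pos)")
  invisible()
}

#' Classify allele dropout from the anchor SNP's genotype call
#'
#' The anchor SNP is heterozygous in the individual, so in a cell without
#' dropout both alleles must be seen: a heterozygous call means
#' `"NO_DROPOUT"`, a homozygous call means one allele failed to amplify
#' (`"DROPOUT"`), and an `"UNCERTAIN"` call is `"UNINFORMATIVE"`.
#'
#' @param anchor_call Genotype call string(s) at the anchor SNP in the cell,
#'   as produced by [call_genotype()]; `NA` (no data) is uninformative.
#' @return Character vector of verdicts in
#'   `{"NO_DROPOUT", "DROPOUT", "UNINFORMATIVE"}`.
#' @export
classify_ado <- function(anchor_call) {
  ifelse(is_het(anchor_call), "NO_DROPOUT",
         ifelse(is_hom(anchor_call), "DROPOUT", "UNINFORMATIVE"))
}

#' Ternary genotype code for a target site in one cell
#'
#' Implements the matrix semantics: `1` when the target is called
#' heterozygous for the mutant allele; `-1` (confirmed wild-type) only when
#' the target is called homozygous-reference *and* at least one anchor SNP
#' proves both haplotypes amplified (`"NO_DROPOUT"`); `0` (undefined)
#' otherwise -- including the false-negative scenario where every anchor
#' reports dropout, so absence of the mutant allele proves nothing.
#'
#' A `"DROPOUT"` verdict from a second anchor does not veto a `"NO_DROPOUT"`
#' one: regional dropout boundaries can fall between anchors, and evidence
#' of both alleles at any anchor suffices.
#'
#' @param target_call Genotype call string at the target site in the cell.
#' @param verdicts Character vector of [classify_ado()] verdicts from all
#'   anchors of this target in this cell (may be empty).
#' @param ref,alt Reference and mutant base at the target.
#' @return Integer code in `{1, -1, 0}`.
#' @export
confirm_wildtype <- function(target_call, verdicts, ref, alt) {
  if (length(target_call) != 1L) stop("target_call must be a single call")
  if (is.na(target_call)) target_call <- "UNCERTAIN"
  if (is_het(target_call) && grepl(alt, target_call, fixed = TRUE))
    return(1L)
  hom_ref <- identical(target_call, genotype_name(ref, ref))
  if (hom_ref && any(verdicts == "NO_DROPOUT")) return(-1L)
  0L
}

#' Ternary codes for many cells and target sites
#'
#' Batch driver over [confirm_wildtype()]: for each cell and each target
#' site, looks up the target's genotype call and the calls at all linked
#' anchor SNPs, classifies dropout, and emits the matrix code.
#'
#' @param targets Data frame with `chrom`, `pos`, `ref`, `alt` (one row per
#'   target site).
#' @param pairs Linked pairs from [find_linked_pairs()] for these targets.
#' @param calls Data frame of per-cell genotype calls with columns `cell`,
#'   `chrom`, `pos`, `call` (missing (cell, site) rows are treated as
#'   `UNCERTAIN`).
#' @return Data frame `cell`, `chrom`, `pos`, `ref`, `alt`, `code`.
#' @export
confirm_wildtypes <- function(targets, pairs, calls) {
  key <- function(cell, chrom, pos) paste(cell, chrom, pos, sep = "\r")
  lut <- setNames(calls$call, key(calls$cell, calls$chrom, calls$pos))
  cells <- unique(calls$cell)
  anchors_by_target <- split(pairs$anchor_pos,
                             key("", pairs$chrom, pairs$target_pos))
  out <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    cell <- cells[ci]
    code <- integer(nrow(targets))
    for (ti in seq_len(nrow(targets))) {
      ch <- targets$chrom[ti]; p <- targets$pos[ti]
      tcall <- lut[key(cell, ch, p)]
      apos <- anchors_by_target[[key("", ch, p)]]
      verdicts <- if (length(apos))
        classify_ado(unname(lut[key(cell, ch, apos)])) else character(0)
      code[ti] <- confirm_wildtype(unname(tcall), verdicts,
                                   targets$ref[ti], targets$alt[ti])
    }
    out[[ci]] <- data.frame(cell = cell, chrom = targets$chrom,
                            pos = targets$pos, ref = targets$ref,
                            alt = targets$alt, code = code,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Self-validation: concordance of linked heterozygous SNP pairs
#'
#' Measures the strategy's own error rate on pairs of germline SNPs that
#' are both heterozygous in the individual and less than one read length
#' apart. Whenever one member of a pair is called heterozygous in a cell
#' (proving both haplotypes amplified in the region), the other member
#' should be heterozygous too; a homozygous call there is a discordance --
#' exactly the event that would turn a confirmed wild-type into an error.
#' Both orientations of each pair are evaluated per cell, since either
#' member can play the conditioning role.
#'
#' @param snp_pairs Data frame of linked SNP pairs with columns `chrom`,
#'   `target_pos`, `anchor_pos` (as from [find_linked_pairs()] run on the
#'   het-SNP list against itself, or any two-column pairing).
#' @param calls Per-cell genotype calls: data frame `cell`, `chrom`, `pos`,
#'   `call`.
#' @return List `n_informative` (cases with the first site called het),
#'   `n_discordant` (of those, second site called hom), `error_rate`
#'   (`n_discordant / n_informative`, `NA` when there are no informative
#'   cases).
#' @export
validate_pair_concordance <- function(snp_pairs, calls) {
  key <- function(cell, chrom, pos) paste(cell, chrom, pos, sep = "\r")
  lut <- setNames(calls$call, key(calls$cell, calls$chrom, calls$pos))
  cells <- unique(calls$cell)
  n_inf <- 0L; n_dis <- 0L
  for (cell in cells) {
    c1 <- unname(lut[key(cell, snp_pairs$chrom, snp_pairs$target_pos)])
    c2 <- unname(lut[key(cell, snp_pairs$chrom, snp_pairs$anchor_pos)])
    for (ori in 1:2) {
      s1 <- if (ori == 1L) c1 else c2
      s2 <- if (ori == 1L) c2 else c1
      inf <- is_het(s1)
      n_inf <- n_inf + sum(inf)
      n_dis <- n_dis + sum(inf & is_hom(s2))
    }
  }
  concordance_summary(n_inf, n_dis)
}

#' Concordance summary from raw counts
#'
#' The arithmetic of [validate_pair_concordance()] exposed directly, for
#' use with externally tabulated counts.
#'
#' @param n_informative Number of informative (cell, pair, orientation)
#'   cases.
#' @param n_discordant Number of those where the second site was called
#'   homozygous.
#' @return List `n_informative`, `n_discordant`, `error_rate` (`NA` for a
#'   zero denominator).
#' @export
concordance_summary <- function(n_informative, n_discordant) {
  rate <- if (n_informative == 0L) NA_real_ else n_discordant / n_informative
  list(n_informative = as.integer(n_informative),
       n_discordant = as.integer(n_discordant),
       error_rate = rate)
}
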