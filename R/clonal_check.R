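# Clonal-incompatibility detection.
#
# Under clonal growth, two mutations that originate in different lineages
# never co-occur in one cell. The telltale pattern over a ternary matrix is
# a site pair (a, b) with three cells: x mutant at a and confirmed
# wild-type at b, y the reverse, and z mutant at both. Because wild-types
# here are *confirmed* by linked SNPs, dropout cannot fake the -1 entries,
# so a hit implies recurrent mutation, cell fusion, or an artifact.

#' Enumerate mutation patterns incompatible with clonal growth
#'
#' For every unordered site pair and every cell triple, reports the cases
#' where cell `x` is `(1, -1)`, cell `y` is `(-1, 1)`, and cell `z` is
#' `(1, 1)` over `(site_a, site_b)`. Orientation is normalized so `cell_x`
#' carries `site_a`'s mutation, with `site_a` the earlier of the pair in
#' column order; every witness triple is listed. Site pairs lying on the
#' same chromosome within `flag_bp` of each other are flagged as possible
#' shared-amplicon artifacts (`linked_pair` column) but not suppressed.
#'
#' @param matrix Ternary genotype matrix (see [build_matrix()]).
#' @param flag_bp Distance under which a same-chromosome site pair is
#'   flagged (default 90).
#' @return Data frame `site_a`, `site_b`, `cell_x`, `cell_y`, `cell_z`,
#'   `linked_pair`, sorted and de-duplicated.
#' @export
find_incompatible_cases <- function(matrix, flag_bp = 90L) {
  sites <- colnames(matrix)
  cells <- rownames(matrix)
  out <- list()
  ns <- length(sites)
  if (ns >= 2L) for (a in seq_len(ns - 1L)) for (b in seq((a + 1L), ns)) {
    va <- matrix[, a]; vb <- matrix[, b]
    both <- cells[!is.na(va) & !is.na(vb) & va == 1L & vb == 1L]
    if (length(both) == 0L) next
    xs <- cells[!is.na(va) & !is.na(vb) & va == 1L & vb == -1L]
    ys <- cells[!is.na(va) & !is.na(vb) & va == -1L & vb == 1L]
    if (length(xs) == 0L || length(ys) == 0L) next
    g <- expand.grid(cell_x = xs, cell_y = ys, cell_z = both,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$site_a <- sites[a]
    g$site_b <- sites[b]
    out[[length(out) + 1L]] <- g[, c("site_a", "site_b",
                                     "cell_x", "cell_y", "cell_z")]
  }
  if (length(out) == 0L)
    return(data.frame(site_a = character(0), site_b = character(0),
                      cell_x = character(0), cell_y = character(0),
                      cell_z = character(0), linked_pair = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(res$site_a, res$site_b, res$cell_x, res$cell_y,
                   res$cell_z), , drop = FALSE]
  res$linked_pair <- sites_within(res$site_a, res$site_b, flag_bp)
  rownames(res) <- NULL
  res
}

# TRUE when two site labels are on one chromosome within `bp` of each other.
sites_within <- function(label_a, label_b, bp) {
  parse1 <- function(lab) {
    core <- sub(":.*$", "", lab)
    parts <- strsplit(core, "_", fixed = TRUE)
    list(chrom = vapply(parts, `[`, "", 1L),
         pos = as.integer(vapply(parts, `[`, "", 2L)))
  }
  a <- parse1(label_a); b <- parse1(label_b)
  a$chrom == b$chrom & abs(a$pos - b$pos) < bp
}

#' Summarize clonal consistency of a genotype matrix
#'
#' @param matrix Ternary genotype matrix.
#' @param flag_bp Passed to [find_incompatible_cases()].
#' @return List of class `clonal_report`: `consistent` (no cases found),
#'   `n_incompatible_pairs` (unordered site pairs), `witnesses_per_pair`
#'   (data frame `site_a`, `site_b`, `n_witness_triples`), `cases` (the
#'   full enumeration).
#' @export
check_clonal_consistency <- function(matrix, flag_bp = 90L) {
  cases <- find_incompatible_cases(matrix, flag_bp)
  pair_key <- paste(cases$site_a, cases$site_b, sep = " / ")
  per_pair <- if (nrow(cases)) {
    tab <- table(pair_key)
    pk <- strsplit(names(tab), " / ", fixed = TRUE)
    data.frame(site_a = vapply(pk, `[`, "", 1L),
               site_b = vapply(pk, `[`, "", 2L),
               n_witness_triples = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(site_a = character(0), site_b = character(0),
               n_witness_triples = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(consistent = nrow(cases) == 0L,
                 n_incompatible_pairs = nrow(per_pair),
                 witnesses_per_pair = per_pair,
                 cases = cases),
            class = "clonal_report")
}

#' @export
print.clonal_report <- function(x, ...) {
  if (x$consistent) {
    cat("mutation patterns consistent with the clonal growth model\n")
  } else {
    cat(x$n_incompatible_pairs, "site pair(s) incompatible with clonal",
        "growth;", nrow(x$cases), "witness triple(s)\n")
    print(x$witnesses_per_pair)
  }
  invisible(x)
}
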