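# The ternary cells-by-sites genotype matrix: 1 = confirmed mutant,
# -1 = confirmed wild-type, 0 = undefined, NA = site belongs to another
# dataset's panel and was never assayed for this cell.

#' Canonical site label
#'
#' @param chrom Chromosome (any of `"21"`, `"chr21"`, `"Chr21"`).
#' @param pos 1-based position.
#' @param ref,alt Reference and mutant base.
#' @return Labels like `"Chr21_37664570:G->T"`.
#' @export
site_label <- function(chrom, pos, ref, alt) {
  chrom <- sub("^[Cc]hr", "", chrom)
  sprintf("Chr%s_%d:%s->%s", chrom, as.integer(pos), ref, alt)
}

#' Build the ternary genotype matrix from per-cell codes
#'
#' Entries default to `0` (undefined) for every (cell, site) in the same
#' panel -- a cell with no data at a site of its own panel is undefined,
#' never `NA` -- and to `NA` across panels. Conflicting codes for one
#' (cell, site) are an error.
#'
#' @param codes Data frame with columns `cell`, `site` (site labels; see
#'   [site_label()]) and `code` in `{1, -1, 0}`. The output of
#'   [confirm_wildtypes()] can be used after adding a `site` column.
#' @param cells,sites Optional orderings (default: order of first
#'   appearance in `codes`).
#' @param cell_panel,site_panel Optional named vectors mapping cell IDs and
#'   site labels to panel/dataset names; a (cell, site) pair from different
#'   panels is `NA`. With either map absent, all entries share one panel.
#' @return Integer matrix, cells as rows, sites as columns.
#' @export
build_matrix <- function(codes, cells = unique(codes$cell),
                         sites = unique(codes$site),
                         cell_panel = NULL, site_panel = NULL) {
  if (!all(codes$code %in% MATRIX_CODES))
    stop("unknown genotype matrix code: ",
         codes$code[!codes$code %in% MATRIX_CODES][1])
  dup <- duplicated(paste(codes$cell, codes$site, sep = "\r"))
  if (any(dup)) {
    k <- paste(codes$cell, codes$site, sep = "\r")
    for (d in unique(k[dup]))
      if (length(unique(codes$code[k == d])) > 1L)
        stop("conflicting codes for (cell, site): ",
             gsub("\r", ", ", d, fixed = TRUE))
  }
  m <- matrix(0L, length(cells), length(sites),
              dimnames = list(cells, sites))
  m[cbind(match(codes$cell, cells), match(codes$site, sites))] <-
    as.integer(codes$code)
  # the panel mask takes precedence: a site outside a cell's panel was
  # never assayed for it, whatever codes were supplied
  if (!is.null(cell_panel) && !is.null(site_panel)) {
    cp <- cell_panel[cells]
    sp <- site_panel[sites]
    m[outer(cp, sp, `!=`)] <- NA_integer_
  }
  m
}

#' Count matrix entries equal to a code over a cell subset
#'
#' @param matrix Ternary genotype matrix (see [build_matrix()],
#'   [read_matrix()]).
#' @param code One of `1`, `-1`, `0`.
#' @param cells Optional character vector of cell IDs (default: all rows);
#'   unknown IDs are an error.
#' @return Integer count (`NA` entries never match).
#' @export
count_codes <- function(matrix, code, cells = rownames(matrix)) {
  if (!all(cells %in% rownames(matrix)))
    stop("unknown cell id: ", setdiff(cells, rownames(matrix))[1])
  sum(matrix[cells, , drop = FALSE] == code, na.rm = TRUE)
}

#' The bundled confirmed-genotype matrix of 97 single tumor cells
#'
#' A 97-cell by 18-site ternary matrix of confirmed genotypes from two
#' published single-cell tumor exome datasets: 80 myeloproliferative
#' neoplasm cells (`LC-` rows, 14 sites) and 17 kidney-tumor cells
#' (`RC-` rows, 4 sites); sites of the other dataset's panel are `NA`.
#'
#' @return The matrix, via [read_matrix()].
#' @export
example_matrix <- function() {
  read_matrix(system.file("extdata", "table1_confirmed_genotypes.tsv",
                          package = "snpanchor", mustWork = TRUE))
}
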