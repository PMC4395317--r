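# Readers/writers for the plain-text formats the toolkit touches:
# 6-column samtools-mpileup subset (SNVs only), a minimal VCF 4.x subset,
# BED3 region lists, and the ternary cells-by-sites genotype matrix TSV.
# Coordinates: pileup/VCF/matrix are 1-based, BED is 0-based half-open.

#' Convert Phred quality to error probability
#'
#' @param q Integer Phred score(s), `e = 10^(-q/10)`.
#' @return Numeric vector of error probabilities in `[0, 1]`.
#' @export
phred_to_error <- function(q) 10^(-q / 10)

#' Convert error probability to the nearest integer Phred score
#'
#' @param e Error probabilities in `[0, 1]`; values are capped at Phred 93
#'   (the highest score the text encoding can carry).
#' @return Integer Phred scores.
#' @export
error_to_phred <- function(e) {
  q <- round(-10 * log10(pmax(e, 1e-300)))
  as.integer(pmin(q, 93L))
}

#' Read a 6-column mpileup file (SNV subset)
#'
#' Parses the `chrom pos ref depth bases quals` dialect written by
#' `samtools mpileup`. Read-start (`^X`) and read-end (`$`) markers are
#' stripped; `.`/`,` are resolved to the reference base; base case is
#' upper-cased (strand is ignored downstream -- the FS filter handles strand
#' bias). Indel tokens are a hard error: this reader supports the SNV subset
#' only.
#'
#' @param path Path to the pileup file.
#' @param sample_id Sample identifier; defaults to the file stem.
#' @return A data frame of class `pileup` with one row per column of the
#'   pileup: `chrom`, `pos`, `ref`, `depth`, and list-columns `bases`
#'   (character vectors) and `errs` (per-base error probabilities decoded
#'   from Phred+33). The sample id is stored in attribute `sample_id`.
#' @seealso [write_pileup()]
#' @export
read_pileup <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  chrom <- character(n); pos <- integer(n); ref <- character(n)
  depth <- integer(n)
  bases <- vector("list", n); errs <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L)
      stop("pileup line ", i, ": expected 6 tab-separated columns, got ",
           length(f))
    chrom[i] <- f[1]
    pos[i] <- as.integer(f[2])
    ref[i] <- toupper(f[3])
    depth[i] <- as.integer(f[4])
    dec <- decode_pileup_bases(f[5], f[6], ref[i], depth[i], i)
    bases[[i]] <- dec$bases
    errs[[i]] <- dec$errs
  }
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, depth = depth,
                    stringsAsFactors = FALSE)
  out$bases <- bases
  out$errs <- errs
  attr(out, "sample_id") <- sample_id
  class(out) <- c("pileup", class(out))
  out
}

# Decode one pileup base/quality string pair into base calls and error probs.
decode_pileup_bases <- function(bstr, qstr, ref, depth, line_no) {
  if (depth == 0L) {
    if (!bstr %in% c("*", ""))
      stop("pileup line ", line_no, ": depth 0 but base string is '", bstr, "'")
    return(list(bases = character(0), errs = numeric(0)))
  }
  if (grepl("[+-][0-9]", bstr))
    stop("pileup line ", line_no,
         ": indel token found; only the SNV subset is supported")
  # strip read-start marker '^' plus the following mapping-quality char, and '$'
  bstr <- gsub("\\^.", "", bstr)
  bstr <- gsub("$", "", bstr, fixed = TRUE)
  ch <- strsplit(bstr, "")[[1]]
  bad <- !(ch %in% c("A", "C", "G", "T", "a", "c", "g", "t", ".", ","))
  if (any(bad))
    stop("pileup line ", line_no, ": unsupported pileup character '",
         ch[bad][1], "'")
  bases <- toupper(ch)
  bases[bases %in% c(".", ",")] <- ref
  q <- utf8ToInt(qstr) - 33L
  if (length(bases) != depth || length(q) != depth)
    stop("pileup line ", line_no, ": depth ", depth,
         " disagrees with base/quality string length (",
         length(bases), "/", length(q), ")")
  list(bases = bases, errs = phred_to_error(q))
}

#' Write a pileup data frame as a 6-column mpileup file
#'
#' Inverse of [read_pileup()]: bases equal to the reference are written as
#' `.`, error probabilities are re-encoded as integer Phred+33 characters
#' (exact round-trip when the input came from integer Phred scores).
#'
#' @param pileup A `pileup` data frame as returned by [read_pileup()] or
#'   [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  lines <- vapply(seq_len(nrow(pileup)), function(i) {
    b <- pileup$bases[[i]]
    e <- pileup$errs[[i]]
    if (length(b) == 0L) {
      bstr <- "*"; qstr <- "*"
    } else {
      bstr <- paste(ifelse(b == pileup$ref[i], ".", b), collapse = "")
      qstr <- intToUtf8(error_to_phred(e) + 33L)
    }
    paste(pileup$chrom[i], pileup$pos[i], pileup$ref[i],
          length(b), bstr, qstr, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal VCF 4.x subset
#'
#' Parses single-sample VCF records, keeping biallelic SNV rows only
#' (single-base REF and ALT). `QUAL` is taken from column 6, `FS` and `QD`
#' from INFO, and `GQ`, `DP`, `GT` from the single sample's FORMAT fields.
#' Indel and multi-allelic rows are skipped; their count is reported in the
#' `n_skipped` attribute and via a message.
#'
#' @param path Path to an uncompressed VCF file.
#' @param sample_id Sample identifier; defaults to the file stem.
#' @return A data frame of class `variant_records` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `qual`, `fs`, `qd`, `gq`, `dp` (numeric, `NA` when
#'   absent) and `gt` (one of `"0/0"`, `"0/1"`, `"1/0"`, `"1/1"`, `"./."`).
#'   Attributes: `sample_id`, `n_skipped`.
#' @export
read_vcf_min <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) == 0L) stop("VCF at ", path, ": missing #CHROM header line")
  body <- lines[seq_along(lines) > hdr[1] & nzchar(lines)]
  body <- body[!startsWith(body, "#")]
  n_skipped <- 0L
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L)
      stop("VCF at ", path, ": record ", i,
           " has fewer than 10 columns (single-sample VCF required)")
    ref <- f[4]; alt <- f[5]
    if (nchar(ref) != 1L || nchar(alt) != 1L || grepl(",", alt, fixed = TRUE)) {
      n_skipped <- n_skipped + 1L
      next
    }
    info <- parse_kv(f[8], ";")
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    smp <- strsplit(f[10], ":", fixed = TRUE)[[1]]
    gt <- if ("GT" %in% fmt) smp[match("GT", fmt)] else NA_character_
    gt <- gsub("|", "/", gt, fixed = TRUE)
    if (!is.na(gt) && !gt %in% c("0/0", "0/1", "1/0", "1/1", "./."))
      stop("VCF at ", path, ": unsupported GT code '", gt, "' at record ", i)
    num_fmt <- function(key) {
      if (key %in% fmt) suppressWarnings(as.numeric(smp[match(key, fmt)]))
      else NA_real_
    }
    rows[[i]] <- data.frame(
      chrom = f[1], pos = as.integer(f[2]), ref = ref, alt = alt,
      qual = suppressWarnings(as.numeric(f[6])),
      fs = suppressWarnings(as.numeric(info[["FS"]])),
      qd = suppressWarnings(as.numeric(info[["QD"]])),
      gq = num_fmt("GQ"), dp = num_fmt("DP"), gt = gt,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), fs = numeric(0), qd = numeric(0),
                      gq = numeric(0), dp = numeric(0), gt = character(0),
                      stringsAsFactors = FALSE)
  if (n_skipped > 0L)
    message("read_vcf_min: skipped ", n_skipped,
            " non-SNV record(s) in ", basename(path))
  attr(out, "sample_id") <- sample_id
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("variant_records", class(out))
  out
}

parse_kv <- function(s, sep) {
  out <- list()
  if (is.na(s) || s == "." || !nzchar(s)) return(out)
  for (kv in strsplit(s, sep, fixed = TRUE)[[1]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) out[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    else out[[kv]] <- NA_character_
  }
  out
}

#' Write variant records as a minimal single-sample VCF
#'
#' @param records A `variant_records` data frame (see [read_vcf_min()]).
#' @param path Output path.
#' @param sample_id Sample column name in the header.
#' @return `path`, invisibly.
#' @export
write_vcf_min <- function(records, path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- attr(records, "sample_id") %||% "SAMPLE"
  fmt1 <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    info <- paste0("FS=", fmt1(r$fs), ";QD=", fmt1(r$qd))
    smp <- paste(ifelse(is.na(r$gt), "./.", r$gt), fmt1(r$gq), fmt1(r$dp),
                 sep = ":")
    paste(r$chrom, r$pos, ".", r$ref, r$alt, fmt1(r$qual), ".", info,
          "GT:GQ:DP", smp, sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED3 region file
#'
#' @param path Path to a 3-column BED file (0-based, half-open intervals).
#' @return A data frame with columns `chrom`, `start`, `end`; zero rows for
#'   an empty file.
#' @export
read_regions <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end"),
                    colClasses = c("character", "integer", "integer"))
  if (any(out$start >= out$end))
    stop("BED at ", path, ": start must be < end")
  out
}

#' Write a BED3 region file
#'
#' @param regions Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# TRUE for 1-based positions falling inside any 0-based half-open region.
pos_in_regions <- function(chrom, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    pos > regions$start[i] & pos <= regions$end[i])
  }
  hit
}

MATRIX_CODES <- c(-1L, 0L, 1L)

#' Read a ternary genotype matrix from TSV
#'
#' The format mirrors the published layout: a header row of site labels in
#' `Chr21_37664570:G->T` style, cell IDs in the first column, and entries in
#' `{1, -1, 0, NA}` -- mutant, confirmed wild-type, undefined, and
#' not-applicable (site belongs to another dataset's panel).
#'
#' @param path Path to the TSV file.
#' @return An integer matrix with cell IDs as row names and site labels as
#'   column names.
#' @seealso [write_matrix()], [build_matrix()]
#' @export
read_matrix <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = "NA", colClasses = "character",
                    quote = "", comment.char = "")
  cells <- tab[[1]]
  if (anyDuplicated(cells))
    stop("duplicate cell ID in matrix: ", cells[duplicated(cells)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "integer")
  bad <- !is.na(m) & !(m %in% MATRIX_CODES)
  if (any(bad)) stop("unknown genotype matrix code: ", m[bad][1])
  raw <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(m) & !is.na(raw) & raw != "NA"))
    stop("unknown genotype matrix code: ",
         raw[is.na(m) & !is.na(raw) & raw != "NA"][1])
  rownames(m) <- cells
  m
}

#' Write a ternary genotype matrix as TSV
#'
#' Inverse of [read_matrix()].
#'
#' @param matrix Integer matrix with cell-ID row names and site-label column
#'   names; entries in `{1, -1, 0, NA}`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  bad <- !is.na(matrix) & !(matrix %in% MATRIX_CODES)
  if (any(bad)) stop("unknown genotype matrix code: ", matrix[bad][1])
  tab <- data.frame(Cell = rownames(matrix), matrix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
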