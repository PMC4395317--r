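# Shared fixtures and independent brute-force oracles.

# Quadratic all-pairs filter: the oracle for find_linked_pairs().
brute_force_pairs <- function(targets, snps, read_length = 90L) {
  out <- list()
  for (i in seq_len(nrow(targets))) for (j in seq_len(nrow(snps))) {
    if (targets$chrom[i] != snps$chrom[j]) next
    d <- abs(targets$pos[i] - snps$pos[j])
    if (d > 0L && d < read_length)
      out[[length(out) + 1L]] <- data.frame(
        chrom = targets$chrom[i], target_pos = targets$pos[i],
        anchor_pos = snps$pos[j], distance = d, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), target_pos = integer(0),
                      anchor_pos = integer(0), distance = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Exhaustive quintuple enumeration: the oracle for find_incompatible_cases().
# Every role in the pattern requires a confirmed code (1 or -1) at both
# sites, so only cells confirmed at both sites can enter a triple; the
# triple loop is exhaustive over those.
brute_force_incompatible <- function(m) {
  sites <- colnames(m); cells <- rownames(m)
  out <- list()
  for (a in seq_along(sites)) for (b in seq_along(sites)) {
    if (a >= b) next
    va_all <- m[, a]; vb_all <- m[, b]
    cand <- cells[!is.na(va_all) & !is.na(vb_all) &
                    va_all != 0L & vb_all != 0L]
    for (x in cand) for (y in cand) for (z in cand) {
      if (x == y || x == z || y == z) next
      va <- m[c(x, y, z), a]; vb <- m[c(x, y, z), b]
      if (va[1] == 1L && vb[1] == -1L && va[2] == -1L && vb[2] == 1L &&
          va[3] == 1L && vb[3] == 1L)
        out[[length(out) + 1L]] <- data.frame(
          site_a = sites[a], site_b = sites[b], cell_x = x, cell_y = y,
          cell_z = z, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(site_a = character(0), site_b = character(0),
                      cell_x = character(0), cell_y = character(0),
                      cell_z = character(0), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$site_a, res$site_b, res$cell_x, res$cell_y,
                   res$cell_z), ]
  rownames(res) <- NULL
  res
}

# Random ternary matrix with plausible code frequencies.
random_ternary_matrix <- function(n_cells, n_sites,
                                  probs = c(0.1, 0.7, 0.15, 0.05)) {
  m <- matrix(sample(c(-1L, 0L, 1L, NA), n_cells * n_sites, replace = TRUE,
                     prob = probs),
              n_cells, n_sites,
              dimnames = list(sprintf("c%02d", seq_len(n_cells)),
                              sprintf("Chr1_%d:A->T",
                                      seq_len(n_sites) * 1000L)))
  m
}

# Genotype calls for every cell of a simulated read set, optionally
# restricted to a set of positions.
sim_cell_calls <- function(reads, comp, prior = genotype_prior(comp),
                           positions = NULL, ...) {
  do.call(rbind, lapply(names(reads$cells), function(id) {
    p <- reads$cells[[id]]
    if (!is.null(positions)) p <- p[p$pos %in% positions, , drop = FALSE]
    cbind(cell = id, call_genotypes(p, prior, comp, ...),
          stringsAsFactors = FALSE)
  }))
}

table1_matrix <- function() {
  read_matrix(test_path_fixture())
}

test_path_fixture <- function() {
  system.file("extdata", "table1_confirmed_genotypes.tsv",
              package = "snpanchor", mustWork = TRUE)
}
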