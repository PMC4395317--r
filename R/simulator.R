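# Seeded simulator of single-cell sequencing with regional allele dropout.
#
# Dropout is modelled per amplification segment, not per site: a failed
# amplification event silences one haplotype across a whole region, which
# is exactly why a linked SNP within one read length shares the target's
# fate. Sequencing errors follow the GC-weighted misread model of the
# genotype caller. Cells descend from a perfect binary lineage tree;
# somatic mutations are placed on tree nodes, and an optional fusion event
# produces cells carrying the union of two lineages' mutation sets.

#' Simulation configuration
#'
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical outputs.
#' @param n_cells Number of single cells.
#' @param genome_length Simulated region length in bp (one chromosome,
#'   `"chr1"`).
#' @param gc_content GC fraction (default 0.41, the exome-wide average).
#' @param snp_density Heterozygous germline SNPs per bp (default 0.004,
#'   matching the ~0.4% of exonic sites that are polymorphic).
#' @param n_snps Override: exact SNP count (otherwise
#'   `round(snp_density * genome_length)`).
#' @param frac_paired Fraction of SNPs placed as pairs less than
#'   `read_length` apart (anchors for each other).
#' @param n_somatic Number of somatic mutation sites.
#' @param lineage_depth Depth of the perfect binary lineage tree (2^depth
#'   leaves).
#' @param fusion Optional integer pair of leaf indices; when set, the last
#'   `n_fusion_cells` cells carry the union of both leaves' mutation sets.
#' @param n_fusion_cells Number of fusion cells (default 1).
#' @param ado_rate Per-(cell, segment) probability that one haplotype drops
#'   out (default 0.2, inside the 0.07-0.44 range reported across
#'   amplification platforms).
#' @param segment_length Amplification-segment length in bp (>= 90;
#'   default 10000).
#' @param depth_mean Mean per-site read depth in cells (Poisson).
#' @param phred_q Phred quality assigned to every simulated base (the
#'   quality distribution is a point mass, keeping pileup round-trips
#'   exact); default 30, i.e. error 1e-3.
#' @param bulk_depth Mean per-site depth in the bulk samples.
#' @param read_length Read length in bp (the linkage window).
#' @param anchor_targets Place each somatic site within `read_length` of an
#'   existing germline SNP, inside the same amplification segment (default
#'   `TRUE`; the regime in which anchored wild-type confirmation is exact).
#' @param low_normal_depth_sites Optional positions at which the normal
#'   bulk is sequenced at `low_normal_depth` instead of `bulk_depth` --
#'   the miscall mechanism where a thinly covered germline SNP passes for
#'   homozygous in the normal.
#' @param low_normal_depth Mean normal-bulk depth at those sites (default
#'   10).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cells = 8L, genome_length = 1e6,
                       gc_content = 0.41, snp_density = 0.004,
                       n_snps = NULL, frac_paired = 0.5, n_somatic = 20L,
                       lineage_depth = 2L, fusion = NULL,
                       n_fusion_cells = 1L, ado_rate = 0.2,
                       segment_length = 10000L, depth_mean = 30,
                       phred_q = 30L, bulk_depth = 50,
                       read_length = 90L, anchor_targets = TRUE,
                       low_normal_depth_sites = NULL,
                       low_normal_depth = 10) {
  stopifnot(ado_rate >= 0, ado_rate <= 1, frac_paired >= 0, frac_paired <= 1,
            segment_length >= 90L, gc_content > 0, gc_content < 1)
  if (is.null(n_snps)) n_snps <- round(snp_density * genome_length)
  cfg <- list(seed = as.integer(seed), n_cells = as.integer(n_cells),
              genome_length = as.integer(genome_length),
              gc_content = gc_content, snp_density = snp_density,
              n_snps = as.integer(n_snps), frac_paired = frac_paired,
              n_somatic = as.integer(n_somatic),
              lineage_depth = as.integer(lineage_depth), fusion = fusion,
              n_fusion_cells = as.integer(n_fusion_cells),
              ado_rate = ado_rate,
              segment_length = as.integer(segment_length),
              depth_mean = depth_mean, phred_q = as.integer(phred_q),
              bulk_depth = bulk_depth, read_length = as.integer(read_length),
              anchor_targets = isTRUE(anchor_targets),
              low_normal_depth_sites = low_normal_depth_sites,
              low_normal_depth = low_normal_depth)
  structure(cfg, class = "sim_config")
}

segment_of <- function(pos, segment_length) {
  (as.integer(pos) - 1L) %/% segment_length + 1L
}

# heap-indexed perfect binary tree: node 1 is the root, leaves are
# 2^depth .. 2^(depth+1)-1; the ancestors of a leaf are found by halving.
leaf_nodes <- function(depth) seq(2^depth, 2^(depth + 1L) - 1L)

node_ancestors <- function(node) {
  anc <- node
  while (node > 1L) {
    node <- node %/% 2L
    anc <- c(anc, node)
  }
  anc
}

#' Simulate the ground truth of a single-cell tumor experiment
#'
#' Places heterozygous germline SNPs (a configured fraction as closely
#' linked pairs), assigns somatic mutations to nodes of a binary lineage
#' tree, assigns cells to leaves (optionally with fusion cells carrying
#' two lineages' mutations), phases all alleles onto two haplotypes, and
#' samples regional dropout per (cell, segment), silencing one uniformly
#' chosen haplotype over the whole segment.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_truth`: `cfg`; `snps` (data frame `chrom`,
#'   `pos`, `ref`, `alt`, `hap`, `segment`); `muts` (same plus
#'   `origin_node`); `cells` (data frame `cell`, `leaf`, `is_fusion`);
#'   `carriers` (cells x mutations logical matrix); `dropout` (cells x
#'   segments integer matrix, 0 = none, 1/2 = lost haplotype);
#'   `n_segments`.
#' @export
simulate_truth <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$genome_length
  n_segments <- segment_of(L, cfg$segment_length)

  # germline het SNPs: paired placement first, then singletons
  n_pairs <- round(cfg$frac_paired * cfg$n_snps / 2)
  n_single <- cfg$n_snps - 2L * n_pairs
  p1 <- sample.int(L - cfg$read_length - 1L, n_pairs)
  offs <- sample(10:(cfg$read_length - 1L), n_pairs, replace = TRUE)
  pos <- sort(unique(c(p1, p1 + offs,
                       sample.int(L, n_single))))
  nsnp <- length(pos)
  w <- base_comp_model(cfg$gc_content)$w
  ref <- sample(DNA_BASES, nsnp, replace = TRUE, prob = w)
  alt <- vapply(ref, function(r)
    sample(setdiff(DNA_BASES, r), 1L), character(1))
  snps <- data.frame(chrom = rep("chr1", nsnp), pos = pos, ref = ref,
                     alt = unname(alt),
                     hap = sample(1:2, nsnp, replace = TRUE),
                     segment = segment_of(pos, cfg$segment_length),
                     stringsAsFactors = FALSE)

  # somatic mutation sites, optionally anchored to a SNP in the same segment
  mpos <- integer(0)
  if (cfg$n_somatic > 0L) {
    if (cfg$anchor_targets && nsnp > 0L) {
      anchor_idx <- sample.int(nsnp, cfg$n_somatic,
                               replace = cfg$n_somatic > nsnp)
      mpos <- vapply(anchor_idx, function(i) {
        sp <- snps$pos[i]
        seg <- snps$segment[i]
        cand <- sp + c(-(10:(cfg$read_length - 1L)),
                       10:(cfg$read_length - 1L))
        cand <- cand[cand >= 1L & cand <= L &
                       segment_of(cand, cfg$segment_length) == seg &
                       !(cand %in% snps$pos)]
        if (length(cand) == 0L) sp + 1L
        else cand[sample.int(length(cand), 1L)]
      }, integer(1))
    } else {
      mpos <- sample.int(L, cfg$n_somatic)
    }
    mpos <- unique(mpos[!(mpos %in% snps$pos)])
  }
  nmut <- length(mpos)
  mref <- sample(DNA_BASES, nmut, replace = TRUE, prob = w)
  malt <- vapply(mref, function(r)
    sample(setdiff(DNA_BASES, r), 1L), character(1))
  n_nodes <- 2L^(cfg$lineage_depth + 1L) - 1L
  muts <- data.frame(chrom = rep("chr1", nmut), pos = mpos, ref = mref,
                     alt = unname(malt),
                     hap = sample(1:2, nmut, replace = TRUE),
                     origin_node = sample.int(n_nodes, nmut, replace = TRUE),
                     segment = segment_of(mpos, cfg$segment_length),
                     stringsAsFactors = FALSE)
  muts <- muts[order(muts$pos), , drop = FALSE]
  rownames(muts) <- NULL

  # cells on leaves; optional fusion cells take the union of two leaves
  leaves <- leaf_nodes(cfg$lineage_depth)
  cell_ids <- sprintf("cell%02d", seq_len(cfg$n_cells))
  leaf_assign <- rep_len(leaves, cfg$n_cells)
  is_fusion <- rep(FALSE, cfg$n_cells)
  if (!is.null(cfg$fusion)) {
    if (!all(cfg$fusion %in% seq_along(leaves)) || length(cfg$fusion) != 2L)
      stop("fusion must be a pair of leaf indices in 1..", length(leaves))
    is_fusion[seq(cfg$n_cells - cfg$n_fusion_cells + 1L, cfg$n_cells)] <- TRUE
  }
  carriers <- matrix(FALSE, cfg$n_cells, nmut,
                     dimnames = list(cell_ids, NULL))
  for (i in seq_len(cfg$n_cells)) {
    anc <- if (is_fusion[i]) {
      union(node_ancestors(leaves[cfg$fusion[1]]),
            node_ancestors(leaves[cfg$fusion[2]]))
    } else {
      node_ancestors(leaf_assign[i])
    }
    carriers[i, ] <- muts$origin_node %in% anc
  }

  dropped <- matrix(runif(cfg$n_cells * n_segments) < cfg$ado_rate,
                    cfg$n_cells, n_segments)
  lost <- matrix(sample(1:2, cfg$n_cells * n_segments, replace = TRUE),
                 cfg$n_cells, n_segments)
  dropout <- ifelse(dropped, lost, 0L)
  dimnames(dropout) <- list(cell_ids, NULL)

  structure(list(cfg = cfg, snps = snps, muts = muts,
                 cells = data.frame(cell = cell_ids, leaf = leaf_assign,
                                    is_fusion = is_fusion,
                                    stringsAsFactors = FALSE),
                 carriers = carriers, dropout = dropout,
                 n_segments = n_segments),
            class = "sim_truth")
}

# Haplotype alleles at every tracked site for one cell:
# a 2-row (haplotype) x n_sites character matrix.
cell_haplotypes <- function(truth, cell_idx) {
  snps <- truth$snps; muts <- truth$muts
  n <- nrow(snps) + nrow(muts)
  h <- matrix("", 2L, n)
  if (nrow(snps)) {
    h[1, seq_len(nrow(snps))] <- ifelse(snps$hap == 1L, snps$alt, snps$ref)
    h[2, seq_len(nrow(snps))] <- ifelse(snps$hap == 2L, snps$alt, snps$ref)
  }
  if (nrow(muts)) {
    j <- nrow(snps) + seq_len(nrow(muts))
    carry <- truth$carriers[cell_idx, ]
    h[1, j] <- ifelse(carry & muts$hap == 1L, muts$alt, muts$ref)
    h[2, j] <- ifelse(carry & muts$hap == 2L, muts$alt, muts$ref)
  }
  h
}

# All tracked sites in simulation order (SNPs first, then mutations).
tracked_sites <- function(truth) {
  snps <- truth$snps[, c("chrom", "pos", "ref", "segment")]
  snps$type <- rep("snp", nrow(snps))
  muts <- truth$muts[, c("chrom", "pos", "ref", "segment")]
  muts$type <- rep("mut", nrow(muts))
  rbind(snps, muts)
}

# Sample one pileup given per-site allele pair and lost haplotype.
sample_pileup <- function(chrom, pos, ref, a1, a2, lost, depth_mean, e, w) {
  depth <- rpois(length(pos), depth_mean)
  idx <- rep(seq_along(pos), depth)
  n_reads <- length(idx)
  hap <- integer(n_reads)
  free <- lost[idx] == 0L
  hap[free] <- sample(1:2, sum(free), replace = TRUE)
  hap[!free] <- 3L - lost[idx][!free]
  base <- ifelse(hap == 1L, a1[idx], a2[idx])
  err <- runif(n_reads) < e
  if (any(err)) {
    true_base <- base
    for (b in DNA_BASES) {
      ii <- which(err & true_base == b)
      if (length(ii)) {
        others <- setdiff(DNA_BASES, b)
        base[ii] <- sample(others, length(ii), replace = TRUE,
                           prob = w[others])
      }
    }
  }
  f <- factor(idx, levels = seq_along(pos))
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, depth = depth,
                    stringsAsFactors = FALSE)
  out$bases <- unname(split(base, f))
  out$errs <- lapply(depth, function(d) rep(e, d))
  class(out) <- c("pileup", class(out))
  out
}

#' Simulate per-cell and bulk pileups from a ground truth
#'
#' Per-site depth is Poisson; each read samples a surviving haplotype
#' uniformly, and with probability `e = 10^(-phred_q/10)` the base is
#' misread into one of the other three bases with GC-weighted
#' probabilities (the same model the genotype caller assumes). Bulks are
#' generated without dropout: the normal bulk is heterozygous at germline
#' SNPs and homozygous-reference at mutation sites; the tumor bulk carries
#' each mutation at allele fraction `carrier_fraction / 2`. Sites listed in
#' `cfg$low_normal_depth_sites` get thin normal coverage.
#'
#' @param truth A [simulate_truth()] result.
#' @return List of class `sim_reads`: `cells` (named list of `pileup` data
#'   frames covering all tracked sites), `normal_bulk`, `tumor_bulk`.
#' @export
simulate_reads <- function(truth) {
  cfg <- truth$cfg
  set.seed((cfg$seed %% 2000000000L) + 1L)
  e <- phred_to_error(cfg$phred_q)
  w <- base_comp_model(cfg$gc_content)$w
  sites <- tracked_sites(truth)
  nsnp <- nrow(truth$snps)
  cells <- vector("list", cfg$n_cells)
  names(cells) <- truth$cells$cell
  for (i in seq_len(cfg$n_cells)) {
    h <- cell_haplotypes(truth, i)
    lost <- truth$dropout[i, sites$segment]
    cells[[i]] <- sample_pileup(sites$chrom, sites$pos, sites$ref,
                                h[1, ], h[2, ], lost,
                                cfg$depth_mean, e, w)
    attr(cells[[i]], "sample_id") <- truth$cells$cell[i]
  }

  # normal bulk: germline het, no somatic mutations, no dropout
  na1 <- c(ifelse(truth$snps$hap == 1L, truth$snps$alt, truth$snps$ref),
           truth$muts$ref)
  na2 <- c(ifelse(truth$snps$hap == 2L, truth$snps$alt, truth$snps$ref),
           truth$muts$ref)
  ndepth <- rep(cfg$bulk_depth, nrow(sites))
  if (!is.null(cfg$low_normal_depth_sites))
    ndepth[sites$pos %in% cfg$low_normal_depth_sites] <- cfg$low_normal_depth
  normal <- sample_pileup_vardepth(sites, na1, na2, NULL, ndepth, e, w)
  attr(normal, "sample_id") <- "normal_bulk"

  # tumor bulk: somatic alt read probability = carrier fraction / 2
  alt_frac <- c(rep(0.5, nsnp),
                if (nrow(truth$muts)) colMeans(truth$carriers) / 2 else
                  numeric(0))
  ta1 <- c(truth$snps$ref, truth$muts$ref)
  ta2 <- c(truth$snps$alt, truth$muts$alt)
  tumor <- sample_pileup_vardepth(sites, ta1, ta2, alt_frac,
                                  rep(cfg$bulk_depth, nrow(sites)), e, w)
  attr(tumor, "sample_id") <- "tumor_bulk"

  structure(list(cells = cells, normal_bulk = normal, tumor_bulk = tumor),
            class = "sim_reads")
}

# Bulk pileup sampler: allele 2 drawn with per-site probability alt_frac
# (0.5 when NULL), Poisson depth with per-site mean.
sample_pileup_vardepth <- function(sites, a1, a2, alt_frac, depth_mean, e, w) {
  depth <- rpois(nrow(sites), depth_mean)
  idx <- rep(seq_len(nrow(sites)), depth)
  n_reads <- length(idx)
  p2 <- if (is.null(alt_frac)) rep(0.5, nrow(sites)) else alt_frac
  pick2 <- runif(n_reads) < p2[idx]
  base <- ifelse(pick2, a2[idx], a1[idx])
  err <- runif(n_reads) < e
  if (any(err)) {
    true_base <- base
    for (b in DNA_BASES) {
      ii <- which(err & true_base == b)
      if (length(ii)) {
        others <- setdiff(DNA_BASES, b)
        base[ii] <- sample(others, length(ii), replace = TRUE,
                           prob = w[others])
      }
    }
  }
  f <- factor(idx, levels = seq_len(nrow(sites)))
  out <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                    depth = depth, stringsAsFactors = FALSE)
  out$bases <- unname(split(base, f))
  out$errs <- lapply(depth, function(d) rep(e, d))
  class(out) <- c("pileup", class(out))
  out
}

#' Derive minimal variant records from a pileup via genotype calling
#'
#' Convenience bridge from simulated pileups into the record-based
#' mutation pipeline: each site is genotyped with [call_genotype()] and
#' re-expressed as a minimal VCF-style record. QUAL is the Phred-scaled
#' posterior probability that the site is *not* homozygous-reference, GQ
#' the Phred-scaled probability that the called genotype is wrong, QD is
#' QUAL/DP, and FS is 0 (no strand is simulated). Heterozygous calls
#' containing the reference map to GT `0/1`, homozygous-alternative to
#' `1/1`, homozygous-reference to `0/0` (ALT `.`), anything else to `./.`.
#'
#' @param pileup A `pileup` data frame.
#' @param prior,comp,min_depth,ratio_threshold As in [call_genotype()].
#' @return A `variant_records` data frame (see [read_vcf_min()]).
#' @export
pileup_to_records <- function(pileup,
                              prior = genotype_prior(comp),
                              comp = base_comp_model(),
                              min_depth = 5L, ratio_threshold = 1000) {
  n <- nrow(pileup)
  alt <- character(n); gt <- character(n)
  qual <- numeric(n); gq <- numeric(n)
  for (i in seq_len(n)) {
    ref <- pileup$ref[i]
    post <- genotype_posterior(pileup$bases[[i]], pileup$errs[[i]],
                               prior, comp)
    gc <- call_genotype(pileup$bases[[i]], pileup$errs[[i]], prior, comp,
                        min_depth, ratio_threshold)
    hom_ref <- genotype_name(ref, ref)
    qual[i] <- round(min(-10 * log10(max(post[[hom_ref]], 1e-30)), 300), 1)
    gq[i] <- round(min(-10 * log10(max(1 - max(post), 1e-30)), 99))
    call <- gc$call
    a <- strsplit(call, "")[[1]]
    if (identical(call, hom_ref)) {
      alt[i] <- "."; gt[i] <- "0/0"
    } else if (is_het(call) && ref %in% a) {
      alt[i] <- setdiff(a, ref); gt[i] <- "0/1"
    } else if (is_hom(call)) {
      alt[i] <- a[1]; gt[i] <- "1/1"
    } else {
      nonref <- names(sort(table(pileup$bases[[i]][
        pileup$bases[[i]] != ref]), decreasing = TRUE))
      alt[i] <- if (length(nonref)) nonref[1] else "."
      gt[i] <- "./."
    }
  }
  dp <- lengths(pileup$bases)
  out <- data.frame(chrom = pileup$chrom, pos = pileup$pos,
                    ref = pileup$ref, alt = alt, qual = qual,
                    fs = 0, qd = round(qual / pmax(dp, 1L), 2),
                    gq = gq, dp = as.numeric(dp), gt = gt,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- attr(pileup, "sample_id")
  class(out) <- c("variant_records", class(out))
  out
}
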