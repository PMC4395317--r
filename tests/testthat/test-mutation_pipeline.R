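rec <- function(qual = 25, fs = 30, qd = 2, gq = 30, dp = 6, gt = "0/1",
                chrom = "chr1", pos = 100L, ref = "G", alt = "T") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
             fs = fs, qd = qd, gq = gq, dp = dp, gt = gt,
             stringsAsFactors = FALSE)
}

test_that("record filters are strict and fail on the first violation", {
  cfg <- filter_config()
  expect_true(filter_record(rec(), cfg, "cell")$pass)
  # every threshold boundary is exclusive
  expect_equal(filter_record(rec(qual = 20), cfg, "cell")$reason, "QUAL")
  expect_equal(filter_record(rec(fs = 40), cfg, "cell")$reason, "FS")
  expect_equal(filter_record(rec(qd = 1.5), cfg, "cell")$reason, "QD")
  expect_equal(filter_record(rec(gq = 20), cfg, "cell")$reason, "GQ")
  expect_equal(filter_record(rec(dp = 5), cfg, "cell")$reason, "DP")
  # first violated criterion wins
  expect_equal(filter_record(rec(qual = 10, gq = 5), cfg, "cell")$reason,
               "QUAL")
  # role selects the depth gate: 6 reads pass for a cell, not for a bulk
  expect_true(filter_record(rec(dp = 6), cfg, "cell")$pass)
  expect_false(filter_record(rec(dp = 6), cfg, "bulk")$pass)
  expect_true(filter_record(rec(dp = 21), cfg, "bulk")$pass)
  # an absent annotation cannot satisfy a strict inequality
  expect_equal(filter_record(rec(fs = NA), cfg, "cell")$reason, "FS")
})

test_that("known-site exclusion removes exact sites, regions and common SNPs", {
  cand <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                     stringsAsFactors = FALSE)
  kept <- exclude_known_sites(
    cand,
    site_lists = list(data.frame(chrom = "chr1", pos = 200L)),
    region_lists = list(data.frame(chrom = "chr1", start = 290L,
                                   end = 310L)),
    maf_table = data.frame(chrom = "chr1", pos = c(100L, 400L),
                           maf = c(0.01, 0.05)))
  # MAF exactly 0.01 is retained (strict >); 0.05 is excluded
  expect_equal(kept$pos, 100L)
})

test_that("exclusion equals the set-difference oracle on random inputs", {
  set.seed(33)
  for (i in 1:10) {
    cand <- data.frame(chrom = "chr1",
                       pos = sample.int(500L, 60L), stringsAsFactors = FALSE)
    excl <- data.frame(chrom = "chr1", pos = sample.int(500L, 40L))
    got <- exclude_known_sites(cand, site_lists = list(excl))
    expect_setequal(got$pos, setdiff(cand$pos, excl$pos))
  }
})

test_that("binomial support threshold matches exact tail enumeration", {
  # independent oracle: direct summation of the binomial pmf
  oracle <- function(n, p, alpha) {
    for (k in 1:n) {
      if (sum(dbinom(k:n, n, p)) < alpha) return(k)
    }
    n + 1L
  }
  expect_equal(min_support_cells(80L, 0.005, 0.05),
               oracle(80L, 0.005, 0.05))
  expect_equal(min_support_cells(100L, 0.04, 0.01),
               oracle(100L, 0.04, 0.01))
  # a vanishing false-positive rate makes a single observation significant
  expect_equal(min_support_cells(80L, 1e-9, 0.05), 1L)
  # the pipeline default bypasses the model with the literal k = 3
  expect_equal(filter_config()$min_support_cells, 3L)
})

test_that("support threshold is monotone in fp_rate and alpha", {
  k <- vapply(c(0.001, 0.01, 0.05, 0.1), function(p)
    min_support_cells(60L, p, 0.05), integer(1))
  expect_true(all(diff(k) >= 0))
  k2 <- vapply(c(0.001, 0.01, 0.1), function(a)
    min_support_cells(60L, 0.02, a), integer(1))
  expect_true(all(diff(k2) <= 0))
})

test_that("mutation calling needs cell support, clean normal, mutant tumor", {
  cells <- list(
    c1 = rec(), c2 = rec(), c3 = rec(),
    c4 = rec(gt = "0/0"), c5 = rec(gt = "0/0"))
  normal <- rec(dp = 25, gt = "0/0")
  tumor <- rec(dp = 30, gt = "0/1")
  cand <- call_mutations(cells, normal, tumor)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$pos, 100L)
  expect_equal(cand$n_support, 3L)
  expect_setequal(strsplit(cand$supporting_cells, ",")[[1]],
                  c("c1", "c2", "c3"))

  # a thin normal bulk makes the site unevaluable, never a mutation
  expect_equal(nrow(call_mutations(cells, rec(dp = 15, gt = "0/0"), tumor)),
               0L)
  # a heterozygous normal marks a germline variant, excluded
  expect_equal(nrow(call_mutations(cells, rec(dp = 25, gt = "0/1"), tumor)),
               0L)
  # absent from the tumor bulk: not a tumor mutation
  expect_equal(nrow(call_mutations(cells, normal, rec(dp = 30, gt = "0/0"))),
               0L)
  # only two supporting cells: below the three-cell requirement
  expect_equal(nrow(call_mutations(cells[c(1, 2, 4, 5)], normal, tumor)), 0L)
  # no normal bulk at all is a hard error
  expect_error(call_mutations(cells, NULL, tumor), "normal bulk")
})

test_that("blacklist and target regions restrict the candidate set", {
  cells <- list(c1 = rec(), c2 = rec(), c3 = rec())
  normal <- rec(dp = 25, gt = "0/0")
  tumor <- rec(dp = 30, gt = "0/1")
  blk <- data.frame(chrom = "chr1", start = 90L, end = 110L)
  expect_equal(nrow(call_mutations(cells, normal, tumor,
                                   amplified_blacklist = blk)), 0L)
  # site at pos 100 is inside [0,50)+90bp flank but not [0,5)+flank
  tg_in <- data.frame(chrom = "chr1", start = 0L, end = 50L)
  tg_out <- data.frame(chrom = "chr1", start = 0L, end = 5L)
  expect_equal(nrow(call_mutations(cells, normal, tumor, targets = tg_in)),
               1L)
  expect_equal(nrow(call_mutations(cells, normal, tumor, targets = tg_out)),
               0L)
})

test_that("exclusion filters commute: application order never matters", {
  set.seed(34)
  cand <- data.frame(chrom = "chr1", pos = sample.int(300L, 50L))
  s1 <- data.frame(chrom = "chr1", pos = sample.int(300L, 30L))
  s2 <- data.frame(chrom = "chr1", pos = sample.int(300L, 30L))
  r1 <- data.frame(chrom = "chr1", start = 100L, end = 150L)
  a <- exclude_known_sites(cand, list(s1, s2), list(r1))
  b <- exclude_known_sites(cand, list(s2, s1), list(r1))
  c2 <- exclude_known_sites(exclude_known_sites(cand, list(s1)),
                            list(s2), list(r1))
  expect_setequal(a$pos, b$pos)
  expect_setequal(a$pos, c2$pos)
})

test_that("a thinly covered germline SNP is excluded, not miscalled somatic", {
  # the miscall mechanism: a het germline SNP looks het in every tumor
  # cell; if the normal bulk is too shallow to prove it germline, a naive
  # pipeline calls it a recurrent somatic mutation. The depth gate on the
  # normal genotype excludes the site instead.
  cfg <- sim_config(seed = 41, n_cells = 6L, genome_length = 1e5,
                    n_snps = 30L, frac_paired = 0, n_somatic = 8L,
                    ado_rate = 0, depth_mean = 40, phred_q = 40L,
                    bulk_depth = 60, lineage_depth = 1L)
  truth <- simulate_truth(cfg)
  shallow <- truth$snps$pos[1:5]
  cfg$low_normal_depth_sites <- shallow
  cfg$low_normal_depth <- 8
  truth$cfg <- cfg
  reads <- simulate_reads(truth)
  comp <- base_comp_model(cfg$gc_content)
  prior <- genotype_prior(comp)
  cell_recs <- lapply(reads$cells, pileup_to_records, prior, comp)
  normal <- pileup_to_records(reads$normal_bulk, prior, comp)
  tumor <- pileup_to_records(reads$tumor_bulk, prior, comp)
  cand <- call_mutations(cell_recs, normal, tumor,
                         filter_config(min_support_cells = 3L))
  expect_gt(nrow(cand), 0L)
  # no germline SNP site survives -- in particular not the shallow ones
  expect_false(any(cand$pos %in% truth$snps$pos))
  # and the called set contains only true simulated somatic mutations
  expect_true(all(cand$pos %in% truth$muts$pos))
})
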