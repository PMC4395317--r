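test_that("linked-pair search enforces the strict read-length bound", {
  targets <- data.frame(chrom = "chr1", pos = 100L)
  snps <- data.frame(chrom = "chr1", pos = c(150L, 200L))
  p <- find_linked_pairs(targets, snps)
  expect_equal(nrow(p), 1L)
  expect_equal(p$anchor_pos, 150L)
  expect_equal(p$distance, 50L)

  # 89 bp away is linked, 90 bp is not
  snps2 <- data.frame(chrom = "chr1", pos = c(189L, 190L))
  p2 <- find_linked_pairs(targets, snps2)
  expect_equal(p2$anchor_pos, 189L)

  # different chromosome never links
  snps3 <- data.frame(chrom = "chr2", pos = 150L)
  expect_equal(nrow(find_linked_pairs(targets, snps3)), 0L)

  expect_error(
    find_linked_pairs(data.frame(chrom = "chr1", pos = c(200L, 100L)), snps),
    "sorted")
})

test_that("linked-pair search equals the brute-force all-pairs filter", {
  set.seed(21)
  mk <- function(n) {
    s <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    pos = sample.int(5000L, n), stringsAsFactors = FALSE)
    s <- unique(s[order(s$chrom, s$pos), ]); rownames(s) <- NULL; s
  }
  targets <- mk(120L)
  snps <- mk(150L)
  got <- find_linked_pairs(targets, snps)
  want <- brute_force_pairs(targets, snps)
  o <- function(x) {
    x <- x[order(x$chrom, x$target_pos, x$anchor_pos), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(o(got), o(want))
  # symmetry up to role labels
  swapped <- find_linked_pairs(snps, targets)
  expect_setequal(paste(got$chrom, got$target_pos, got$anchor_pos),
                  paste(swapped$chrom, swapped$anchor_pos,
                        swapped$target_pos))
  expect_equal(sort(got$distance), sort(swapped$distance))
})

test_that("dropout classification is a total function of the anchor call", {
  expect_equal(classify_ado("AC"), "NO_DROPOUT")
  expect_equal(classify_ado("AA"), "DROPOUT")
  expect_equal(classify_ado("UNCERTAIN"), "UNINFORMATIVE")
  expect_equal(classify_ado(NA_character_), "UNINFORMATIVE")
  expect_equal(classify_ado(c("AG", "TT", "UNCERTAIN")),
               c("NO_DROPOUT", "DROPOUT", "UNINFORMATIVE"))
})

test_that("wild-type confirmation requires an anchor proving both alleles", {
  # hom-ref target with a no-dropout anchor: confirmed wild-type
  expect_equal(confirm_wildtype("GG", "NO_DROPOUT", "G", "T"), -1L)
  # hom-ref target but every anchor dropped out: undefined, could be a
  # hidden mutation
  expect_equal(confirm_wildtype("GG", c("DROPOUT", "DROPOUT"), "G", "T"), 0L)
  expect_equal(confirm_wildtype("GG", character(0), "G", "T"), 0L)
  # mutant het: confirmed mutation regardless of anchors
  expect_equal(confirm_wildtype("GT", "DROPOUT", "G", "T"), 1L)
  expect_equal(confirm_wildtype("GT", character(0), "G", "T"), 1L)
  # uncertain target: undefined
  expect_equal(confirm_wildtype("UNCERTAIN", "NO_DROPOUT", "G", "T"), 0L)
  # hom-alt is not a confirmed het mutation under the matrix semantics
  expect_equal(confirm_wildtype("TT", "NO_DROPOUT", "G", "T"), 0L)
  # disagreement: one informative anchor showing both alleles suffices
  expect_equal(confirm_wildtype("GG", c("DROPOUT", "NO_DROPOUT"), "G", "T"),
               -1L)
})

test_that("no confirmed wild-type is ever emitted without a NO_DROPOUT", {
  set.seed(22)
  for (i in 1:200) {
    call <- sample(c(genotypes(), "UNCERTAIN"), 1)
    verdicts <- sample(c("NO_DROPOUT", "DROPOUT", "UNINFORMATIVE"),
                       sample(0:3, 1), replace = TRUE)
    code <- confirm_wildtype(call, verdicts, "G", "T")
    if (code == -1L) expect_true("NO_DROPOUT" %in% verdicts)
    expect_true(code %in% c(-1L, 0L, 1L))
  }
})

test_that("batch confirmation matches per-case confirmation", {
  targets <- data.frame(chrom = "chr1", pos = c(100L, 500L),
                        ref = c("G", "C"), alt = c("T", "A"),
                        stringsAsFactors = FALSE)
  snps <- data.frame(chrom = "chr1", pos = c(150L, 540L))
  pairs <- find_linked_pairs(targets, snps)
  calls <- rbind(
    data.frame(cell = "c1", chrom = "chr1", pos = c(100L, 150L, 500L, 540L),
               call = c("GG", "AC", "AC", "TT")),
    data.frame(cell = "c2", chrom = "chr1", pos = c(100L, 150L, 500L, 540L),
               call = c("GG", "AA", "CC", "UNCERTAIN")))
  codes <- confirm_wildtypes(targets, pairs, calls)
  lookup <- function(cell, pos) codes$code[codes$cell == cell &
                                             codes$pos == pos]
  expect_equal(lookup("c1", 100L), -1L)  # hom-ref, anchor het
  expect_equal(lookup("c1", 500L), 1L)   # het containing the alt
  expect_equal(lookup("c2", 100L), 0L)   # anchor dropped out
  expect_equal(lookup("c2", 500L), 0L)   # hom-ref, anchor uncertain
})

test_that("pair-concordance counts both orientations per cell", {
  pairs <- data.frame(chrom = "chr1", target_pos = 100L, anchor_pos = 150L)
  calls <- rbind(
    data.frame(cell = "c1", chrom = "chr1", pos = c(100L, 150L),
               call = c("AC", "AC")),   # het/het: 2 informative, 0 discordant
    data.frame(cell = "c2", chrom = "chr1", pos = c(100L, 150L),
               call = c("AC", "AA")),   # het/hom: 1 informative, 1 discordant
    data.frame(cell = "c3", chrom = "chr1", pos = c(100L, 150L),
               call = c("AA", "GG")))   # hom/hom: nothing informative
  res <- validate_pair_concordance(pairs, calls)
  expect_equal(res$n_informative, 3L)
  expect_equal(res$n_discordant, 1L)
  expect_equal(res$error_rate, 1 / 3)
})

test_that("concordance on co-amplified SNP pairs is error-free", {
  # deep coverage, near-zero sequencing error, every pair inside one
  # amplification segment: dropout silences both members together, so an
  # informative (het) first member guarantees a het second member
  cfg <- sim_config(seed = 31, n_cells = 4L, genome_length = 2e5,
                    n_snps = 400L, frac_paired = 1, n_somatic = 0L,
                    ado_rate = 0.3, segment_length = 10000L,
                    depth_mean = 40, phred_q = 60L)
  truth <- simulate_truth(cfg)
  reads <- simulate_reads(truth)
  pairs <- find_linked_pairs(truth$snps, truth$snps)
  pairs <- pairs[pairs$target_pos < pairs$anchor_pos, , drop = FALSE]
  seg <- function(p) (p - 1L) %/% cfg$segment_length + 1L
  pairs <- pairs[seg(pairs$target_pos) == seg(pairs$anchor_pos), ,
                 drop = FALSE]
  expect_gt(nrow(pairs), 50L)
  comp <- base_comp_model(cfg$gc_content)
  calls <- sim_cell_calls(reads, comp)
  res <- validate_pair_concordance(pairs, calls)
  expect_gt(res$n_informative, 200L)
  expect_equal(res$n_discordant, 0L)
  expect_equal(res$error_rate, 0)
})

test_that("concordance with no informative cases reports NA, not zero", {
  pairs <- data.frame(chrom = "chr1", target_pos = 100L, anchor_pos = 150L)
  calls <- data.frame(cell = "c1", chrom = "chr1", pos = c(100L, 150L),
                      call = c("AA", "GG"))
  expect_true(is.na(validate_pair_concordance(pairs, calls)$error_rate))
  expect_true(is.na(concordance_summary(0L, 0L)$error_rate))
})
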