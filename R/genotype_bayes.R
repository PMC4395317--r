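# Bayesian genotype inference from pileup data.
#
# The model works on the ten unordered diploid genotypes over {A,C,G,T}.
# Each observed base b with Phred-derived error probability e contributes a
# likelihood p(b|G) = 1/2 p(b|A1) + 1/2 p(b|A2). The per-allele term is
# GC-aware: a misread does not land uniformly on the three other bases but
# proportionally to their abundance in the target region, so
#   p(b|A) = 1 - e                 when b = A
#   p(b|A) = e * w_b / (1 - w_A)   when b != A
# with composition weights w_G = w_C = gc/2, w_A = w_T = (1-gc)/2. At
# gc = 0.5 this collapses to the familiar uniform e/3 model, and at a
# GC/AT ratio of 2/3 it gives (2/7)*e for a G/C misread of an A/T allele.

GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
GT_ALLELE1 <- substr(GENOTYPES, 1, 1)
GT_ALLELE2 <- substr(GENOTYPES, 2, 2)

#' The ten unordered diploid genotypes
#'
#' @return Character vector `c("AA","AC",...,"TT")`; heterozygous genotypes
#'   are written with alleles in alphabetical order, so `{C,A}` is `"AC"`.
#' @export
genotypes <- function() GENOTYPES

#' Canonical genotype name for an allele pair
#'
#' @param a1,a2 Single bases in `{A,C,G,T}`.
#' @return The unordered genotype string, e.g. `genotype_name("T","A")` is
#'   `"AT"`.
#' @export
genotype_name <- function(a1, a2) {
  paste0(pmin(a1, a2), pmax(a1, a2))
}

#' Is a genotype call heterozygous / homozygous?
#'
#' `UNCERTAIN` and `NA` are neither.
#'
#' @param call Genotype call string(s) as produced by [call_genotype()].
#' @return Logical vector.
#' @export
is_het <- function(call) {
  !is.na(call) & call %in% GENOTYPES & substr(call, 1, 1) != substr(call, 2, 2)
}

#' @rdname is_het
#' @export
is_hom <- function(call) {
  !is.na(call) & call %in% GENOTYPES & substr(call, 1, 1) == substr(call, 2, 2)
}

#' Base-composition model for a target region
#'
#' @param gc_content Fraction of G+C in the region, in (0, 1). The exome-wide
#'   average used throughout is 0.41.
#' @return An object of class `base_comp` holding the per-base weights
#'   `w` with `w_G = w_C = gc/2`, `w_A = w_T = (1-gc)/2` (summing to 1).
#' @export
base_comp_model <- function(gc_content = 0.41) {
  if (!is.numeric(gc_content) || gc_content <= 0 || gc_content >= 1)
    stop("gc_content must be in (0, 1)")
  w <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  structure(list(gc_content = gc_content, w = w), class = "base_comp")
}

#' Probability of an observed base given a single allele
#'
#' Error mass `e` is split among the three non-allele bases proportionally
#' to their composition weights: `p(b|A) = 1 - e` for `b = A`, else
#' `e * w_b / (1 - w_A)`. The four values over `b` sum to one.
#'
#' @param b Observed base(s).
#' @param allele True allele.
#' @param e Error probability (reversed Phred quality) in `[0, 1]`.
#' @param comp A [base_comp_model()].
#' @return Probability vector, recycled over the longest argument.
#' @export
base_given_allele <- function(b, allele, e, comp = base_comp_model()) {
  stopifnot(all(e >= 0 & e <= 1))
  w <- comp$w
  ifelse(b == allele, 1 - e, e * w[b] / (1 - w[allele]))
}

#' Probability of an observed base given a diploid genotype
#'
#' The even mixture `p(b|{A1,A2}) = 1/2 p(b|A1) + 1/2 p(b|A2)`; for a
#' homozygous genotype it reduces to [base_given_allele()].
#'
#' @param b Observed base(s).
#' @param g Genotype string, e.g. `"AT"`.
#' @param e Error probability in `[0, 1]`.
#' @param comp A [base_comp_model()].
#' @return Probability vector.
#' @export
base_given_genotype <- function(b, g, e, comp = base_comp_model()) {
  a1 <- substr(g, 1, 1)
  a2 <- substr(g, 2, 2)
  0.5 * base_given_allele(b, a1, e, comp) +
    0.5 * base_given_allele(b, a2, e, comp)
}

#' Prior over the ten diploid genotypes from base composition
#'
#' Hardy-Weinberg products of the composition weights:
#' `p({A,A}) = w_A^2` and `p({A1,A2}) = 2 w_A1 w_A2` for distinct alleles.
#' This is the GC-dependent, normalized, reference-free prior; at gc = 0.5
#' every homozygote has prior 1/16 and every heterozygote 1/8.
#'
#' @param comp A [base_comp_model()].
#' @return Named numeric vector over [genotypes()], summing to 1.
#' @export
genotype_prior <- function(comp = base_comp_model()) {
  w <- comp$w
  p <- w[GT_ALLELE1] * w[GT_ALLELE2] *
    ifelse(GT_ALLELE1 == GT_ALLELE2, 1, 2)
  setNames(as.numeric(p), GENOTYPES)
}

# Log-likelihoods log p(D|G) for one pileup column, all ten genotypes.
# Products are evaluated in log space: 20+ reads at e = 1e-4 underflow a
# naive product.
genotype_loglik <- function(bases, errs, comp) {
  n <- length(bases)
  if (n == 0L) return(setNames(rep(0, 10L), GENOTYPES))
  w <- comp$w
  # P[i, a]: p(b_i | allele a)
  P <- matrix(0, n, 4L, dimnames = list(NULL, DNA_BASES))
  wb <- w[bases]
  for (a in DNA_BASES) {
    P[, a] <- ifelse(bases == a, 1 - errs, errs * wb / (1 - w[a]))
  }
  ll <- colSums(log(0.5 * (P[, GT_ALLELE1, drop = FALSE] +
                             P[, GT_ALLELE2, drop = FALSE])))
  setNames(ll, GENOTYPES)
}

#' Posterior distribution over the ten genotypes for one pileup column
#'
#' `p(G|D)` is proportional to `p(G) * prod_b p(b|G)`; the evidence `p(D)`
#' is constant over genotypes and cancels in the normalization. An empty
#' pileup returns the prior unchanged.
#'
#' @param bases Character vector of observed bases at the site.
#' @param errs Matching vector of per-base error probabilities.
#' @param prior Named prior from [genotype_prior()].
#' @param comp A [base_comp_model()].
#' @return Named numeric vector over [genotypes()], summing to 1.
#' @export
genotype_posterior <- function(bases, errs,
                               prior = genotype_prior(comp),
                               comp = base_comp_model()) {
  lp <- log(prior[GENOTYPES]) + genotype_loglik(bases, errs, comp)
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Call the genotype of one pileup column
#'
#' A genotype is assigned only when two gates pass: (i) the column carries
#' more than `min_depth` qualified reads, and (ii) the top posterior
#' probability exceeds `ratio_threshold` times the sum of the other nine
#' genotypes' posteriors. Otherwise the call is `"UNCERTAIN"` -- the data do
#' not determine the genotype.
#'
#' @param bases,errs Observed bases and error probabilities (may be empty).
#' @param prior,comp Prior and composition model, as in
#'   [genotype_posterior()].
#' @param min_depth Depth gate; the call is attempted only when the number
#'   of reads is strictly greater than this (default 5, i.e. "more than 5
#'   qualified reads"). Set `depth_at_least = TRUE` to relax the gate to
#'   `>=`.
#' @param ratio_threshold Posterior dominance required to call (default
#'   1000).
#' @param depth_at_least Interpret `min_depth` as an inclusive bound.
#' @return A list of class `genotype_call`: `call` (genotype string or
#'   `"UNCERTAIN"`), `posterior`, `dominance_ratio` (`+Inf` when the other
#'   nine posteriors are numerically zero), `depth`.
#' @export
call_genotype <- function(bases, errs,
                          prior = genotype_prior(comp),
                          comp = base_comp_model(),
                          min_depth = 5L, ratio_threshold = 1000,
                          depth_at_least = FALSE) {
  post <- genotype_posterior(bases, errs, prior, comp)
  depth <- length(bases)
  top <- which.max(post)
  tail_mass <- sum(post[-top])
  ratio <- if (tail_mass == 0) Inf else post[[top]] / tail_mass
  depth_ok <- if (depth_at_least) depth >= min_depth else depth > min_depth
  tied <- sum(post == post[[top]]) > 1L
  call <- if (depth_ok && !tied && ratio >= ratio_threshold)
    GENOTYPES[top] else "UNCERTAIN"
  structure(list(call = call, posterior = post, dominance_ratio = ratio,
                 depth = depth),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat("genotype call:", x$call,
      sprintf("(depth %d, dominance ratio %.3g)\n", x$depth,
              x$dominance_ratio))
  invisible(x)
}

#' Call genotypes for every column of a pileup
#'
#' Vectorized driver over [call_genotype()].
#'
#' @param pileup A `pileup` data frame (see [read_pileup()]).
#' @param prior,comp,min_depth,ratio_threshold,depth_at_least As in
#'   [call_genotype()].
#' @return A data frame `chrom`, `pos`, `ref`, `depth`, `call`,
#'   `dominance_ratio`; attribute `sample_id` is carried over.
#' @export
call_genotypes <- function(pileup,
                           prior = genotype_prior(comp),
                           comp = base_comp_model(),
                           min_depth = 5L, ratio_threshold = 1000,
                           depth_at_least = FALSE) {
  n <- nrow(pileup)
  call <- character(n)
  ratio <- numeric(n)
  lprior <- log(prior[GENOTYPES])
  for (i in seq_len(n)) {
    lp <- lprior + genotype_loglik(pileup$bases[[i]], pileup$errs[[i]], comp)
    lp <- lp - max(lp)
    p <- exp(lp)
    p <- p / sum(p)
    top <- which.max(p)
    tail_mass <- sum(p[-top])
    r <- if (tail_mass == 0) Inf else p[[top]] / tail_mass
    depth <- length(pileup$bases[[i]])
    depth_ok <- if (depth_at_least) depth >= min_depth else depth > min_depth
    tied <- sum(p == p[[top]]) > 1L
    call[i] <- if (depth_ok && !tied && r >= ratio_threshold)
      GENOTYPES[top] else "UNCERTAIN"
    ratio[i] <- r
  }
  out <- data.frame(chrom = pileup$chrom, pos = pileup$pos, ref = pileup$ref,
                    depth = lengths(pileup$bases), call = call,
                    dominance_ratio = ratio, stringsAsFactors = FALSE)
  attr(out, "sample_id") <- attr(pileup, "sample_id")
  out
}
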