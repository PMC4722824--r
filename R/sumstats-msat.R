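# Microsatellite summary statistics: allele counts, unbiased expected and
# observed heterozygosity, allele-size variance, and rarefied allelic
# richness.

# stacked allele vector (2 per genotyped individual) for one locus
locus_alleles <- function(gen, l) {
  a <- c(gen$a1[, l], gen$a2[, l])
  a[!is.na(a)]
}

#' Per-group microsatellite summary statistics
#'
#' A = mean alleles per locus; He = unbiased expected heterozygosity
#' (2n/(2n-1))(1 - sum p^2) averaged over loci (n = gene copies / 2
#' diploids); Ho = observed heterozygosity; V = population-convention
#' (divide by n) variance of allele sizes in repeat units; Ar = rarefied
#' allelic richness at `rarefaction_g` gene copies via hypergeometric
#' rarefaction. Monomorphic loci contribute A = 1, He = 0, V = 0.
#'
#' @param gen a [msat_genotypes()] with >= 2 genotyped individuals.
#' @param rarefaction_g rarefaction size in gene copies; NULL uses the
#'   smallest per-locus sample across loci.
#' @return list with A, He, Ho, V, Ar and per-locus vectors.
#' @export
msat_group_stats <- function(gen, rarefaction_g = NULL) {
  stopifnot(inherits(gen, "msat_genotypes"))
  L <- length(gen$loci)
  ns <- vapply(seq_len(L), function(l) length(locus_alleles(gen, l)), numeric(1))
  if (max(ns) < 4) stop("need at least 2 genotyped individuals")
  if (is.null(rarefaction_g)) rarefaction_g <- min(ns[ns > 0])
  if (rarefaction_g > min(ns[ns > 0])) {
    stop("rarefaction_g exceeds the smallest per-locus sample (",
         min(ns[ns > 0]), ")")
  }
  A <- He <- Ho <- V <- Ar <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    a <- locus_alleles(gen, l)
    n2 <- length(a)
    if (n2 < 2) next
    tab <- table(a)
    p <- as.numeric(tab) / n2
    A[l] <- length(tab)
    He[l] <- (n2 / (n2 - 1)) * (1 - sum(p^2))
    g1 <- gen$a1[, l]; g2 <- gen$a2[, l]
    typed <- !is.na(g1)
    Ho[l] <- mean(g1[typed] != g2[typed])
    V[l] <- mean((a - mean(a))^2)
    Ar[l] <- sum(1 - exp(lchoose(n2 - as.numeric(tab), rarefaction_g) -
                           lchoose(n2, rarefaction_g)))
  }
  list(A = mean(A, na.rm = TRUE), He = mean(He, na.rm = TRUE),
       Ho = mean(Ho, na.rm = TRUE), V = mean(V, na.rm = TRUE),
       Ar = mean(Ar, na.rm = TRUE), rarefaction_g = rarefaction_g,
       per_locus = list(A = A, He = He, Ho = Ho, V = V, Ar = Ar))
}

#' Weir-Cockerham theta (FST) from diploid genotypes
#'
#' Multi-allele, multi-locus variance-components estimator (Weir &
#' Cockerham 1984): theta = sum(a) / sum(a + b + c) over alleles and loci.
#'
#' @param gen a [msat_genotypes()].
#' @param pops character vector of population labels parallel to `gen$ids`.
#' @return list with theta and the summed components a, b, c.
#' @export
wc_theta <- function(gen, pops) {
  stopifnot(length(pops) == length(gen$ids))
  sum_a <- sum_b <- sum_c <- 0
  upops <- unique(pops)
  r <- length(upops)
  if (r < 2) stop("need at least 2 populations")
  pidx0 <- match(pops, upops)
  for (l in seq_along(gen$loci)) {
    g1 <- gen$a1[, l]; g2 <- gen$a2[, l]
    typed <- !is.na(g1)
    if (!any(typed)) next
    ni_all <- tabulate(pidx0[typed], r)
    if (sum(ni_all > 0) < 2) next
    use <- which(ni_all > 0)
    ni <- ni_all[use]; rl <- length(use)
    kidx <- match(pidx0, use)  # NA for unused pops
    nbar <- mean(ni)
    nc <- (rl * nbar - sum(ni^2) / (rl * nbar)) / (rl - 1)
    alleles <- sort(unique(c(g1[typed], g2[typed])))
    nA <- length(alleles)
    if (nA < 2) next
    a1c <- match(g1, alleles); a2c <- match(g2, alleles)
    # per-population allele counts and heterozygote-carrier counts,
    # accumulated as cnt[k, a] via a combined (a-1)*rl + k index
    sel_all <- typed & !is.na(kidx)
    kk <- rep(kidx[sel_all], 2)
    ac <- c(a1c[sel_all], a2c[sel_all])
    cnt <- matrix(tabulate((ac - 1L) * rl + kk, rl * nA), rl, nA)
    ishet <- rep(a1c[sel_all] != a2c[sel_all], 2)
    het <- matrix(tabulate((ac[ishet] - 1L) * rl + kk[ishet], rl * nA),
                  rl, nA)
    p_i <- cnt / (2 * ni)          # rl x nA
    h_i <- het / ni
    pbar <- colSums(ni * p_i) / (rl * nbar)
    s2 <- colSums(ni * (p_i - rep(pbar, each = rl))^2) / ((rl - 1) * nbar)
    hbar <- colSums(ni * h_i) / (rl * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (rl - 1) / rl - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (rl - 1) / rl - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    sum_a <- sum_a + sum(a); sum_b <- sum_b + sum(b); sum_c <- sum_c + sum(cc)
  }
  denom <- sum_a + sum_b + sum_c
  theta <- if (denom > 0) sum_a / denom else NA_real_
  list(theta = theta, a = sum_a, b = sum_b, c = sum_c)
}
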