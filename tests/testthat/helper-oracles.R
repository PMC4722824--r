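# Independent brute-force oracles. These deliberately re-derive each
# statistic from first principles by a different route than the package.

# TN93 closed form evaluated directly from counted proportions
oracle_tn93 <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  pool <- c(a, b)
  g <- sapply(c("A", "C", "G", "T"), function(x) mean(pool == x))
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
  n <- length(a)
  P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / n
  P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / n
  Q <- sum(a != b) / n - P1 - P2
  k1 <- 2 * g["A"] * g["G"] / gR
  k2 <- 2 * g["T"] * g["C"] / gY
  unname(-k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
           k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
           2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["T"] * g["C"] * gR / gY) *
           log(1 - Q / (2 * gR * gY)))
}

# exhaustive pairwise enumeration of sequence summaries (no NA handling)
oracle_seq_stats <- function(strs) {
  n <- length(strs)
  mats <- do.call(rbind, strsplit(strs, ""))
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(p) sum(mats[p[1], ] != mats[p[2], ]))
  hap <- match(strs, unique(strs))
  p <- as.numeric(table(hap)) / n
  list(NH = length(unique(hap)),
       h = n / (n - 1) * (1 - sum(p^2)),
       kbar = mean(diffs),
       pi = mean(diffs / ncol(mats)),
       S = sum(apply(mats, 2, function(col) length(unique(col)) > 1)))
}

# textbook Tajima's D
oracle_tajima_D <- function(strs) {
  st <- oracle_seq_stats(strs)
  n <- length(strs); S <- st$S
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (st$kbar - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Ewens P(K = k) via the unsigned-Stirling polynomial route:
# coefficients of theta * (theta+1) * ... * (theta+n-1)
oracle_ewens_pmf <- function(n, theta) {
  coefs <- 1  # polynomial "1"
  for (j in 0:(n - 1)) {
    # multiply by (theta + j): coefs_k' = coefs_{k-1} + j * coefs_k
    coefs <- c(coefs * j, 0) + c(0, coefs)
  }
  # coefs[k+1] is coefficient of theta^k, k = 0..n; P(K=k) oc coefs[k+1] theta^k
  k <- 1:n
  w <- coefs[k + 1] * theta^k
  w / sum(w)
}

oracle_fu_fs <- function(strs) {
  st <- oracle_seq_stats(strs)
  n <- length(strs)
  pk <- oracle_ewens_pmf(n, st$kbar)
  Sp <- sum(pk[st$NH:n])
  log(Sp / (1 - Sp))
}

# literal Weir-Cockerham (1984) component transcription, loops everywhere
oracle_wc_theta <- function(genos, pops) {
  # genos: list per locus of 2-column matrices of alleles (rows = indivs)
  A <- B <- C <- 0
  for (loc in genos) {
    keep <- !is.na(loc[, 1])
    loc <- loc[keep, , drop = FALSE]; pp <- pops[keep]
    r <- length(unique(pp))
    ni <- sapply(unique(pp), function(p) sum(pp == p))
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (al in unique(as.vector(loc))) {
      p_i <- h_i <- numeric(r)
      for (k in seq_len(r)) {
        rows <- pp == unique(pp)[k]
        p_i[k] <- mean(loc[rows, ] == al)
        h_i[k] <- mean(xor(loc[rows, 1] == al, loc[rows, 2] == al))
      }
      pbar <- sum(ni * p_i) / sum(ni)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / sum(ni)
      A <- A + nbar / nc * (s2 - 1 / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      B <- B + nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
        (2 * nbar - 1) / (4 * nbar) * hbar)
      C <- C + hbar / 2
    }
  }
  A / (A + B + C)
}

# direct sums-of-squares AMOVA oracle (1-level), solving the expected
# mean-square equations written out longhand
oracle_amova_1level <- function(d2, pop) {
  N <- nrow(d2); pops <- unique(pop); P <- length(pops)
  ss_tot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_tot <- ss_tot + d2[i, j]
  ss_tot <- ss_tot / N
  ss_wp <- 0
  for (p in pops) {
    idx <- which(pop == p); np <- length(idx)
    if (np > 1) {
      acc <- 0
      for (i in idx) for (j in idx) if (i < j) acc <- acc + d2[i, j]
      ss_wp <- ss_wp + acc / np
    }
  }
  ss_ap <- ss_tot - ss_wp
  sigma_w <- ss_wp / (N - P)
  nprime <- (N - sum(sapply(pops, function(p) sum(pop == p))^2) / N) / (P - 1)
  sigma_a <- (ss_ap / (P - 1) - sigma_w) / nprime
  list(ss_ap = ss_ap, ss_wp = ss_wp, sigma_a = sigma_a, sigma_w = sigma_w,
       phi_st = sigma_a / (sigma_a + sigma_w))
}

# exact pmf of segregating sites under the constant-size coalescent
# (Tavare 1984)
oracle_S_pmf <- function(n, theta, smax) {
  s <- 0:smax
  pmf <- numeric(smax + 1)
  for (i in 2:n) {
    pmf <- pmf + (-1)^i * choose(n - 1, i - 1) * (i - 1) / (theta + i - 1) *
      (theta / (theta + i - 1))^s
  }
  pmf
}

# small helpers used across test files
random_alignment <- function(n, L, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  seq_alignment(paste0("ind", seq_len(n)),
                matrix(sample(alphabet, n * L, TRUE), n, L))
}

toy_dataset <- function(seed = 42) {
  # two-group dataset with modest differentiation, both markers
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), 60, TRUE)
  mk <- function(k, shift) t(vapply(seq_len(k), function(i) {
    s <- base
    idx <- sample(60, 3 + shift)
    s[idx] <- sample(c("A", "C", "G", "T"), length(idx), TRUE)
    s
  }, character(60)))
  aln <- seq_alignment(c(paste0("A", 1:5), paste0("B", 1:5)),
                       rbind(mk(5, 0), mk(5, 4)))
  a1 <- matrix(sample(8:14, 40, TRUE), 10, 4)
  a2 <- matrix(sample(8:14, 40, TRUE), 10, 4)
  a1[6:10, ] <- a1[6:10, ] + 4L; a2[6:10, ] <- a2[6:10, ] + 4L
  gen <- msat_genotypes(aln$ids, paste0("L", 1:4), a1, a2)
  map <- data.frame(individual = aln$ids,
                    population = rep(c("pA", "pB"), each = 5),
                    group = rep(c("GA", "GB"), each = 5))
  assemble_dataset(aln, gen, map)
}
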