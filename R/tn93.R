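# Tamura-Nei (1993) pairwise distances with empirical base frequencies
# taken from the compared pair. Ambiguous sites (N, -) are excluded
# pairwise, never listwise.

# A,C,G,T -> 1..4; N and - -> NA
encode_dna <- function(seqs) {
  m <- matrix(match(seqs, c("A", "C", "G", "T")), nrow(seqs), ncol(seqs))
  rownames(m) <- rownames(seqs)
  m
}

tn93_from_counts <- function(p1, p2, q, freqs) {
  # p1: prop. A<->G transitions, p2: prop. C<->T, q: prop. transversions,
  # freqs: c(A,C,G,T) empirical for the pair
  gA <- freqs[1]; gC <- freqs[2]; gG <- freqs[3]; gT <- freqs[4]
  gR <- gA + gG; gY <- gC + gT
  if (p1 + p2 + q == 0) return(0)
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  w1 <- 1 - p1 / k1 - q / (2 * gR)
  w2 <- 1 - p2 / k2 - q / (2 * gY)
  w3 <- 1 - q / (2 * gR * gY)
  if (!is.finite(w1) || !is.finite(w2) || !is.finite(w3) ||
      w1 <= 0 || w2 <= 0 || w3 <= 0) {
    return(Inf)  # saturation: log-domain failure flagged as infinite
  }
  d <- -k1 * log(w1) - k2 * log(w2) -
    2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY) * log(w3)
  max(d, 0)
}

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Empirical base frequencies are estimated from the two sequences being
#' compared, over their mutually unambiguous sites. Saturated pairs (a
#' logarithm argument reaching zero) return `Inf`.
#'
#' @param seqA,seqB character vectors of aligned nucleotide symbols, or
#'   length-1 strings.
#' @return distance in substitutions per site.
#' @export
tn93_distance <- function(seqA, seqB) {
  if (length(seqA) == 1L && nchar(seqA[1L]) > 1L) seqA <- strsplit(toupper(seqA), "")[[1]]
  if (length(seqB) == 1L && nchar(seqB[1L]) > 1L) seqB <- strsplit(toupper(seqB), "")[[1]]
  if (length(seqA) != length(seqB)) stop("sequences must have equal length")
  a <- match(toupper(seqA), c("A", "C", "G", "T"))
  b <- match(toupper(seqB), c("A", "C", "G", "T"))
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 1L) stop("no mutually unambiguous site")
  a <- a[ok]; b <- b[ok]
  freqs <- (tabulate(a, 4L) + tabulate(b, 4L)) / (2 * n)
  diff <- a != b
  ts1 <- sum(diff & ((a == 1L & b == 3L) | (a == 3L & b == 1L))) / n
  ts2 <- sum(diff & ((a == 2L & b == 4L) | (a == 4L & b == 2L))) / n
  q <- sum(diff) / n - ts1 - ts2
  tn93_from_counts(ts1, ts2, q, freqs)
}

#' Pairwise TN93 distance matrix for an alignment
#'
#' @param aln a [seq_alignment()] or an encoded integer matrix.
#' @param scale `"per_site"` (substitutions/site) or `"per_locus"`
#'   (multiplied by the per-pair number of comparable sites, i.e. corrected
#'   numbers of differences, the AMOVA convention).
#' @return symmetric numeric matrix.
#' @export
tn93_matrix <- function(aln, scale = c("per_site", "per_locus")) {
  scale <- match.arg(scale)
  enc <- if (inherits(aln, "seq_alignment")) encode_dna(aln$seqs) else aln
  n <- nrow(enc); L <- ncol(enc)
  D <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  if (n < 2L) return(D)
  if (!anyNA(enc)) {
    # fully vectorized path: all pairwise counts as n x n matrices
    X <- lapply(1:4, function(b) (enc == b) * 1)
    cnt <- vapply(X, rowSums, numeric(n))           # n x 4 base counts
    TS1 <- X[[1]] %*% t(X[[3]]); TS1 <- TS1 + t(TS1)
    TS2 <- X[[2]] %*% t(X[[4]]); TS2 <- TS2 + t(TS2)
    SAME <- Reduce(`+`, lapply(X, function(x) x %*% t(x)))
    pairsum <- function(v) outer(v, v, "+")
    gA <- pairsum(cnt[, 1]) / (2 * L); gC <- pairsum(cnt[, 2]) / (2 * L)
    gG <- pairsum(cnt[, 3]) / (2 * L); gT <- pairsum(cnt[, 4]) / (2 * L)
    gR <- gA + gG; gY <- gC + gT
    P1 <- TS1 / L; P2 <- TS2 / L
    Q <- (L - SAME) / L - P1 - P2
    k1 <- 2 * gA * gG / gR
    k2 <- 2 * gT * gC / gY
    w1 <- 1 - P1 / k1 - Q / (2 * gR)
    w2 <- 1 - P2 / k2 - Q / (2 * gY)
    w3 <- 1 - Q / (2 * gR * gY)
    suppressWarnings(
      D <- -k1 * log(w1) - k2 * log(w2) -
        2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY) * log(w3))
    # identical pairs are 0; log-domain failures (NaN or -Inf weights)
    # flag as saturated
    D[P1 + P2 + Q == 0] <- 0
    D[is.na(D)] <- Inf
    D[D < 0 & is.finite(D)] <- 0
    if (scale == "per_locus") D <- D * L
    diag(D) <- 0
    dimnames(D) <- list(rownames(enc), rownames(enc))
  } else {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- enc[i, ]; b <- enc[j, ]
      ok <- !is.na(a) & !is.na(b)
      m <- sum(ok)
      if (m == 0L) { D[i, j] <- D[j, i] <- NA_real_; next }
      a2 <- a[ok]; b2 <- b[ok]
      freqs <- (tabulate(a2, 4L) + tabulate(b2, 4L)) / (2 * m)
      diff <- a2 != b2
      ts1 <- sum(diff & ((a2 == 1L & b2 == 3L) | (a2 == 3L & b2 == 1L))) / m
      ts2 <- sum(diff & ((a2 == 2L & b2 == 4L) | (a2 == 4L & b2 == 2L))) / m
      q <- sum(diff) / m - ts1 - ts2
      d <- tn93_from_counts(ts1, ts2, q, freqs)
      if (scale == "per_locus") d <- d * m
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# raw pairwise difference counts and per-pair comparable sites
pairwise_diff_matrix <- function(enc) {
  n <- nrow(enc); L <- ncol(enc)
  DIFF <- matrix(0, n, n); VALID <- matrix(L, n, n)
  if (n < 2L) return(list(diff = DIFF, valid = VALID))
  if (!anyNA(enc)) {
    SAME <- matrix(0, n, n)
    for (b in 1:4) {
      Xb <- (enc == b) * 1
      SAME <- SAME + Xb %*% t(Xb)
    }
    DIFF <- L - SAME
    diag(DIFF) <- 0
  } else {
    OK <- !is.na(enc)
    VALID <- (OK * 1) %*% t(OK * 1)
    SAME <- matrix(0, n, n)
    for (b in 1:4) {
      Xb <- (!is.na(enc) & enc == b) * 1
      SAME <- SAME + Xb %*% t(Xb)
    }
    DIFF <- VALID - SAME
    diag(DIFF) <- 0
  }
  list(diff = DIFF, valid = VALID)
}
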