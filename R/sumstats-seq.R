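# Sequence summary statistics: haplotype/nucleotide diversity, segregating
# sites, Tajima's D, Fu's Fs, and mismatch-distribution analysis under the
# sudden-expansion model.

# segregating sites: columns with >= 2 distinct unambiguous states
count_seg_sites <- function(enc) {
  if (!anyNA(enc)) {
    return(sum(colSums(enc != matrix(enc[1, ], nrow(enc), ncol(enc),
                                     byrow = TRUE)) > 0))
  }
  sum(apply(enc, 2, function(col) {
    u <- unique(col[!is.na(col)]); length(u) >= 2L
  }))
}

# Haplotype cluster labels. Two sequences belong to the same haplotype when
# they are identical over the sites where both are unambiguous; identity is
# closed transitively (union-find over pairwise identity).
haplotype_classes <- function(enc) {
  n <- nrow(enc)
  if (!anyNA(enc)) {
    key <- apply(enc, 1, paste, collapse = "")
    return(match(key, unique(key)))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- enc[i, ]; b <- enc[j, ]
    ok <- !is.na(a) & !is.na(b)
    if (!any(a[ok] != b[ok])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Per-group sequence summary statistics
#'
#' Computes the number of haplotypes (NH), gene diversity h with its
#' standard deviation, nucleotide diversity per site (pi) with SD,
#' segregating sites S and mean pairwise differences k-bar. Ambiguous sites
#' are excluded pairwise; h uses the unbiased estimator
#' n(1 - sum p_i^2)/(n - 1).
#'
#' @param aln a [seq_alignment()] with n >= 2 sequences.
#' @return list with N, NH, h, h_sd, pi, pi_sd, S, kbar.
#' @export
seq_group_stats <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences")
  enc <- encode_dna(aln$seqs)
  cls <- haplotype_classes(enc)
  NH <- length(unique(cls))
  p <- as.numeric(table(cls)) / n
  sp2 <- sum(p^2)
  h <- n * (1 - sp2) / (n - 1)
  # Nei (1987) eq. 8.12
  h_var <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sp2^2) + sp2 - sp2^2)
  pd <- pairwise_diff_matrix(enc)
  ut <- upper.tri(pd$diff)
  kbar <- mean(pd$diff[ut])
  pi <- mean(pd$diff[ut] / pd$valid[ut])
  S <- count_seg_sites(enc)
  # Nei (1987) eq. 10.7 (total variance of pi)
  L <- aln$length
  pi_var <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(N = n, NH = NH, h = h, h_sd = sqrt(max(h_var, 0)),
       pi = pi, pi_sd = sqrt(max(pi_var, 0)), S = S, kbar = kbar)
}

# ---- Tajima's D -----------------------------------------------------------

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_D <- function(n, S, kbar) {
  if (S == 0) return(NA_real_)
  cc <- tajima_constants(n)
  (kbar - S / cc$a1) / sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
}

# ---- Fu's Fs --------------------------------------------------------------

# P(K = k) for the Ewens sampling formula at theta, k = 1..n.
# Built by the stable recursion K_n = K_{n-1} + Bernoulli(theta/(theta+n-1)),
# equivalent to the unsigned-Stirling closed form but overflow-free.
ewens_K_pmf <- function(n, theta) {
  p <- 1
  if (n >= 2) for (j in seq_len(n - 1)) {
    q <- theta / (theta + j)
    p <- c(p * (1 - q), 0) + c(0, p * q)
  }
  p
}

fu_Fs <- function(n, NH, kbar) {
  if (kbar <= 0 || NH <= 1) return(NA_real_)
  pk <- ewens_K_pmf(n, kbar)
  Sp <- sum(pk[NH:n])  # P(K >= NH_obs)
  if (Sp <= 0 || Sp >= 1) return(NA_real_)
  log(Sp / (1 - Sp))
}

# ---- neutral coalescent simulation (constant size, infinite sites) --------

# One standard-coalescent draw at scaled theta; returns S, kbar and the
# haplotype count K under infinite sites. Time in units of 2N (pairwise
# coalescence rate 1); mutations at rate theta/2 per lineage per unit.
sim_neutral_snm <- function(n, theta) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  blen <- numeric(n_nodes)
  ndesc <- c(rep(1L, n), integer(n - 1L))
  active <- seq_len(n)
  node_time <- numeric(n_nodes)
  t <- 0; nxt <- n + 1L
  for (k in seq(n, 2L)) {
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    pick <- sample(length(active), 2L)
    ch <- active[pick]
    parent[ch] <- nxt
    node_time[nxt] <- t
    blen[ch] <- t - node_time[ch]
    ndesc[nxt] <- sum(ndesc[ch])
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  root <- n_nodes
  nmut <- stats::rpois(n_nodes, theta / 2 * blen)
  S <- sum(nmut)
  i <- ndesc[-root]
  kbar <- sum(nmut[-root] * i * (n - i)) / (n * (n - 1) / 2)
  # haplotype classes: leaves share a haplotype iff the branch sets with
  # mutations along their root paths are identical
  key <- character(n)
  for (leaf in seq_len(n)) {
    v <- leaf; ks <- integer(0)
    while (v != root) {
      if (nmut[v] > 0L) ks <- c(ks, v)
      v <- parent[v]
    }
    key[leaf] <- paste(ks, collapse = ",")
  }
  list(S = S, kbar = kbar, K = length(unique(key)))
}

#' Tajima's D and Fu's Fs with simulation p-values
#'
#' D follows Tajima (1989); Fs = ln(S'/(1-S')) with
#' S' = P(K >= NH_obs) under the Ewens sampling formula at theta = k-bar.
#' p-values are lower-tail fractions from `n_sim` constant-size neutral
#' coalescent simulations at theta = k-bar, with the (b+1)/(m+1) correction.
#'
#' @param aln a [seq_alignment()] with n >= 4 sequences.
#' @param n_sim number of neutral simulations for the p-values.
#' @param rng_seed integer seed.
#' @return list with D, p_D, Fs, p_Fs (statistics NA when undefined).
#' @export
neutrality_tests <- function(aln, n_sim = 1000L, rng_seed = 1L) {
  st <- seq_group_stats(aln)
  n <- st$N
  if (n < 4L) stop("need at least 4 sequences")
  D <- tajima_D(n, st$S, st$kbar)
  Fs <- fu_Fs(n, st$NH, st$kbar)
  p_D <- p_Fs <- NA_real_
  if (n_sim > 0L && st$kbar > 0) {
    old <- .Random.seed_store()
    set.seed(rng_seed)
    simD <- simFs <- numeric(n_sim)
    for (b in seq_len(n_sim)) {
      sm <- sim_neutral_snm(n, st$kbar)
      simD[b] <- if (sm$S > 0) tajima_D(n, sm$S, sm$kbar) else NA_real_
      fs <- fu_Fs(n, sm$K, sm$kbar)
      simFs[b] <- if (is.na(fs)) Inf else fs  # K = 1: no evidence of excess
    }
    .Random.seed_restore(old)
    if (!is.na(D)) {
      ok <- !is.na(simD)
      p_D <- (sum(simD[ok] <= D) + 1) / (sum(ok) + 1)
    }
    if (!is.na(Fs)) p_Fs <- (sum(simFs <= Fs) + 1) / (n_sim + 1)
  }
  list(D = D, p_D = p_D, Fs = Fs, p_Fs = p_Fs, S = st$S, kbar = st$kbar,
       NH = st$NH, n = n)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- mismatch distribution ------------------------------------------------

# equilibrium mismatch pmf at theta
mismatch_equilibrium <- function(theta, jmax) {
  j <- 0:jmax
  exp(j * log(theta) - (j + 1) * log(1 + theta))
}

#' Expected mismatch distribution under sudden expansion
#'
#' Li (1977) / Rogers & Harpending (1992): a population at mutation-scaled
#' size theta0 grows instantaneously to theta1 at mutational time tau before
#' the present.
#'
#' @param tau expansion time in mutational units (2ut generations).
#' @param theta0,theta1 pre-/post-expansion 2Nu (theta0 <= theta1).
#' @param jmax largest difference class.
#' @return numeric vector of expected relative frequencies for 0..jmax.
#' @export
expected_mismatch <- function(tau, theta0, theta1, jmax) {
  f1 <- mismatch_equilibrium(theta1, jmax)
  if (tau <= 0) return(mismatch_equilibrium(theta0, jmax))
  f0 <- mismatch_equilibrium(theta0, jmax)
  out <- numeric(jmax + 1)
  lpref <- -tau * (theta1 + 1) / theta1
  for (j in 0:jmax) {
    i <- 0:j
    w <- exp(lpref + i * log(tau) - lgamma(i + 1))
    out[j + 1] <- f1[j + 1] + sum(w * (f0[j - i + 1] - f1[j - i + 1]))
  }
  pmax(out, 0)
}

#' Harpending's raggedness index
#'
#' Sum of squared successive differences of the relative mismatch
#' frequencies, padded with zero classes below class 0 and above the last
#' class (so a two-class histogram (0.5, 0.5) scores 0.5).
#'
#' @param freq relative frequencies for classes 0..d.
#' @export
raggedness_index <- function(freq) {
  sum(diff(c(0, freq, 0))^2)
}

fit_sudden_expansion <- function(obs, multistart = c("full", "quick")) {
  multistart <- match.arg(multistart)
  jmax <- length(obs) - 1L
  ssd_fn <- function(par) {
    tau <- par[1]; th0 <- par[2]; th1 <- par[2] + par[3]
    sum((obs - expected_mismatch(tau, th0, th1, jmax))^2)
  }
  kb <- sum((0:jmax) * obs)
  starts <- if (multistart == "full") {
    expand.grid(tau = c(0.5, max(kb, 0.5), 2 * max(kb, 0.5) + 1),
                th0 = c(0.05, 1),
                dth = c(5, 100))
  } else {
    data.frame(tau = c(max(kb, 0.5), 1), th0 = c(0.1, 1), dth = c(10, 100))
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[s, ]), ssd_fn, method = "L-BFGS-B",
                   lower = c(0, 1e-8, 0), upper = c(200, 500, 5000),
                   control = list(factr = 1e-8 / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("sudden-expansion fit failed")
  list(tau = best$par[1], theta0 = best$par[2],
       theta1 = best$par[2] + best$par[3], SSD = best$value)
}

# haploid two-epoch coalescent in mutational units (u = 1/2 per lineage per
# generation; population size theta1 until tau generations back, theta0
# earlier), returning the relative mismatch histogram padded to jmax.
sim_expansion_mismatch <- function(n, tau, theta0, theta1) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes); blen <- numeric(n_nodes)
  ndesc <- c(rep(1L, n), integer(n - 1L))
  node_time <- numeric(n_nodes)
  active <- seq_len(n); t <- 0; nxt <- n + 1L
  theta0 <- max(theta0, 1e-6); theta1 <- max(theta1, 1e-6)
  for (k in seq(n, 2L)) {
    rate1 <- k * (k - 1) / 2 / theta1
    if (t < tau) {
      dt <- stats::rexp(1L, rate1)
      if (t + dt > tau) {
        t <- tau + stats::rexp(1L, k * (k - 1) / 2 / theta0)
      } else t <- t + dt
    } else {
      t <- t + stats::rexp(1L, k * (k - 1) / 2 / theta0)
    }
    pick <- sample(length(active), 2L)
    ch <- active[pick]
    parent[ch] <- nxt; node_time[nxt] <- t
    blen[ch] <- t - node_time[ch]
    ndesc[nxt] <- sum(ndesc[ch])
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  root <- n_nodes
  nmut <- stats::rpois(n_nodes, blen / 2)
  # pairwise differences via branch contributions
  # build per-leaf mutation paths
  sets <- vector("list", n)
  for (leaf in seq_len(n)) {
    v <- leaf; ks <- integer(0)
    while (v != root) { if (nmut[v] > 0L) ks <- c(ks, rep(v, nmut[v])); v <- parent[v] }
    sets[[leaf]] <- ks
  }
  d <- integer(n * (n - 1) / 2); idx <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    idx <- idx + 1L
    d[idx] <- length(sets[[i]]) + length(sets[[j]]) -
      2L * length(intersect_multiset(sets[[i]], sets[[j]]))
  }
  d
}

intersect_multiset <- function(a, b) {
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (!length(common)) return(integer(0))
  rep.int(1L, sum(pmin(ta[common], tb[common])))
}

#' Mismatch-distribution analysis under the sudden-expansion model
#'
#' Fits (tau, theta0, theta1) to the observed histogram of pairwise
#' difference counts by bounded nonlinear least squares (multistart),
#' reports SSD and Harpending's raggedness, and obtains p-values by
#' parametric bootstrap: data re-simulated under the fitted expansion,
#' refitted, and the statistics compared (P(stat* >= obs)).
#'
#' @param aln a [seq_alignment()] with n >= 4 sequences.
#' @param n_boot parametric bootstrap replicates.
#' @param rng_seed integer seed.
#' @return list with obs (relative frequencies 0..d_max), tau, theta0,
#'   theta1, SSD, p_SSD, Hri, p_Hri, and `stable` flag for degenerate input.
#' @export
mismatch_analysis <- function(aln, n_boot = 200L, rng_seed = 1L) {
  stopifnot(inherits(aln, "seq_alignment"))
  n <- length(aln$ids)
  if (n < 4L) stop("need at least 4 sequences")
  enc <- encode_dna(aln$seqs)
  pd <- pairwise_diff_matrix(enc)
  d <- pd$diff[upper.tri(pd$diff)]
  jmax <- max(d)
  obs <- tabulate(d + 1L, jmax + 1L) / length(d)
  if (jmax == 0L) {
    return(list(obs = obs, tau = NA_real_, theta0 = NA_real_,
                theta1 = NA_real_, SSD = NA_real_, p_SSD = NA_real_,
                Hri = raggedness_index(obs), p_Hri = NA_real_,
                stable = TRUE))
  }
  fit <- fit_sudden_expansion(obs)
  Hri <- raggedness_index(obs)
  p_SSD <- p_Hri <- NA_real_
  if (n_boot > 0L) {
    old <- .Random.seed_store()
    set.seed(rng_seed)
    bs <- bh <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      db <- sim_expansion_mismatch(n, fit$tau, fit$theta0, fit$theta1)
      jb <- max(db)
      ob <- tabulate(db + 1L, jb + 1L) / length(db)
      if (jb == 0L) { bs[b] <- 0; bh[b] <- raggedness_index(ob); next }
      fb <- fit_sudden_expansion(ob, multistart = "quick")
      bs[b] <- fb$SSD
      bh[b] <- raggedness_index(ob)
    }
    .Random.seed_restore(old)
    p_SSD <- (sum(bs >= fit$SSD) + 1) / (n_boot + 1)
    p_Hri <- (sum(bh >= Hri) + 1) / (n_boot + 1)
  }
  list(obs = obs, tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
       SSD = fit$SSD, p_SSD = p_SSD, Hri = Hri, p_Hri = p_Hri,
       stable = FALSE)
}
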