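# Hierarchical AMOVA on molecular distances, pairwise differentiation
# statistics, and the ordered ABC summary-statistic vector.

# sum over within-unit pairs of d2/n_unit, for a labelling
.ss_within <- function(d2, labels) {
  tot <- 0
  for (u in unique(labels)) {
    idx <- which(labels == u)
    if (length(idx) > 1) {
      tot <- tot + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
  }
  tot
}

amova_components <- function(d2, pop, grp = NULL) {
  N <- nrow(d2)
  ss_tot <- sum(d2[upper.tri(d2)]) / N
  np <- table(pop)
  P <- length(np)
  ss_wp <- .ss_within(d2, pop)
  if (is.null(grp)) {
    df_ap <- P - 1; df_wp <- N - P
    sigma_c <- (ss_wp) / df_wp
    nprime <- (N - sum(np^2) / N) / (P - 1)
    msd_ap <- (ss_tot - ss_wp) / df_ap
    sigma_a <- (msd_ap - sigma_c) / nprime
    comps <- c(among_pop = sigma_a, within_pop = sigma_c)
    phi <- c(F_ST = sigma_a / (sigma_a + sigma_c))
    ss <- c(among_pop = ss_tot - ss_wp, within_pop = ss_wp)
    df <- c(among_pop = df_ap, within_pop = df_wp)
  } else {
    gmap <- tapply(grp, pop, function(x) x[1])
    G <- length(unique(grp))
    ss_wg <- .ss_within(d2, grp)
    ss_ag <- ss_tot - ss_wg
    ss_apwg <- ss_wg - ss_wp
    df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
    ng <- table(grp)
    # per-group sum of squared population sizes
    sp2g <- vapply(names(ng), function(g) {
      sum(np[names(gmap)[gmap == g]]^2)
    }, numeric(1))
    n2 <- (sum(sp2g / as.numeric(ng)) - sum(np^2) / N) / df_ag
    n3 <- (N - sum(ng^2) / N) / df_ag
    sigma_c <- ss_wp / df_wp
    if (df_ap == 0) {
      # one population per group: the among-populations-within-groups
      # stratum is structurally empty
      sigma_b <- 0
    } else {
      n1 <- (N - sum(sp2g / as.numeric(ng))) / df_ap
      sigma_b <- (ss_apwg / df_ap - sigma_c) / n1
    }
    sigma_a <- (ss_ag / df_ag - sigma_c - n2 * sigma_b) / n3
    comps <- c(among_grp = sigma_a, among_pop_within_grp = sigma_b,
               within_pop = sigma_c)
    tot <- sigma_a + sigma_b + sigma_c
    phi <- c(F_CT = sigma_a / tot,
             F_SC = sigma_b / (sigma_b + sigma_c),
             F_ST = (sigma_a + sigma_b) / tot)
    ss <- c(among_grp = ss_ag, among_pop_within_grp = ss_apwg,
            within_pop = ss_wp)
    df <- c(among_grp = df_ag, among_pop_within_grp = df_ap,
            within_pop = df_wp)
  }
  list(ss = ss, df = df, components = comps, phi = phi)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Nested variance decomposition of squared molecular distances (Excoffier
#' et al. 1992) with TN93-corrected numbers of differences, one- or
#' two-level designs, and permutation p-values: F_CT permutes populations
#' among groups, F_SC permutes individuals among populations within groups,
#' F_ST permutes individuals among all populations.
#'
#' Negative variance components are reported as estimated; percentages are
#' computed after flooring components at zero (noted in the result).
#'
#' @param aln a [seq_alignment()] (or a precomputed squared-distance
#'   matrix).
#' @param map population map data.frame restricted to the aligned
#'   individuals (columns individual, population, group).
#' @param grouping `"1-level"` (populations only) or `"2-level"`
#'   (groups/populations).
#' @param n_perm permutations per fixation index.
#' @param rng_seed integer seed.
#' @return list of class `scenabc_amova`: ss, df, components, percent, phi,
#'   p_values, n_perm, floored.
#' @export
amova <- function(aln, map, grouping = c("1-level", "2-level"),
                  n_perm = 1000L, rng_seed = 1L) {
  grouping <- match.arg(grouping)
  if (inherits(aln, "seq_alignment")) {
    d2 <- tn93_matrix(aln, scale = "per_locus")
    ids <- aln$ids
  } else {
    d2 <- as.matrix(aln)
    ids <- rownames(d2)
  }
  stopifnot(all(ids %in% map$individual))
  map <- map[match(ids, map$individual), ]
  pop <- map$population
  if (length(unique(pop)) < 2) stop("need at least 2 populations")
  grp <- if (grouping == "2-level") map$group else NULL
  if (grouping == "2-level" && length(unique(grp)) < 2) {
    stop("2-level design needs at least 2 groups")
  }
  obs <- amova_components(d2, pop, grp)
  floored <- any(obs$components < 0)
  pc <- pmax(obs$components, 0)
  percent <- 100 * pc / sum(pc)
  p <- rep(NA_real_, length(obs$phi))
  names(p) <- names(obs$phi)
  if (n_perm > 0L) {
    old <- .Random.seed_store()
    set.seed(rng_seed)
    hits <- stats::setNames(numeric(length(obs$phi)), names(obs$phi))
    if (grouping == "1-level") {
      for (b in seq_len(n_perm)) {
        ph <- amova_components(d2, sample(pop))$phi
        hits["F_ST"] <- hits["F_ST"] + (ph["F_ST"] >= obs$phi["F_ST"])
      }
    } else {
      pops_u <- unique(pop)
      pop2grp <- vapply(pops_u, function(pp) grp[pop == pp][1], character(1))
      for (b in seq_len(n_perm)) {
        # F_ST: individuals among all populations
        ph <- amova_components(d2, sample(pop), grp)$phi
        hits["F_ST"] <- hits["F_ST"] + (ph["F_ST"] >= obs$phi["F_ST"])
        # F_SC: individuals among populations within their group
        pop_sc <- pop
        for (g in unique(grp)) {
          sel <- grp == g
          pop_sc[sel] <- sample(pop[sel])
        }
        ph <- amova_components(d2, pop_sc, grp)$phi
        hits["F_SC"] <- hits["F_SC"] + (ph["F_SC"] >= obs$phi["F_SC"])
        # F_CT: whole populations among groups
        g_of_pop <- sample(pop2grp)
        names(g_of_pop) <- pops_u
        ph <- amova_components(d2, pop, as.character(g_of_pop[pop]))$phi
        hits["F_CT"] <- hits["F_CT"] + (ph["F_CT"] >= obs$phi["F_CT"])
      }
    }
    .Random.seed_restore(old)
    p <- (hits + 1) / (n_perm + 1)
    p[setdiff(names(p), if (grouping == "1-level") "F_ST" else names(p))] <- NA
  }
  structure(list(ss = obs$ss, df = obs$df, components = obs$components,
                 percent = percent, phi = obs$phi, p_values = p,
                 n_perm = n_perm, floored = floored),
            class = "scenabc_amova")
}

#' @export
print.scenabc_amova <- function(x, ...) {
  cat("AMOVA\n")
  tab <- data.frame(df = x$df, SS = round(x$ss, 3),
                    sigma2 = round(x$components, 4),
                    percent = round(x$percent, 2))
  print(tab)
  cat("Fixation indices:",
      paste(names(x$phi), round(x$phi, 4), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# N_ST (Pons & Petit 1996 form): 1 - pi_S/pi_T on molecular distances,
# within-group means weighted by pair counts
nst_from_dist <- function(D, labels) {
  ut <- upper.tri(D)
  pi_T <- mean(D[ut])
  wsum <- 0; wn <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      dd <- D[idx, idx][upper.tri(D[idx, idx])]
      wsum <- wsum + sum(dd); wn <- wn + length(dd)
    }
  }
  if (pi_T <= 0) return(NA_real_)
  pi_S <- wsum / wn
  1 - pi_S / pi_T
}

#' Pairwise differentiation between two groups
#'
#' Sequence Phi_ST from a two-group AMOVA on TN93 distances, microsatellite
#' Weir-Cockerham theta, N_ST = 1 - pi_S/pi_T, plus pooled-pair combined
#' statistics (unbiased mean genic diversity and segregating sites).
#'
#' @param dataset a `multilocus_dataset`.
#' @param groupA,groupB group labels.
#' @return list of class `pair_summary`.
#' @export
pairwise_differentiation <- function(dataset, groupA, groupB) {
  out <- list(groupA = groupA, groupB = groupB,
              phi_st_seq = NA_real_, theta_msat = NA_real_,
              N_ST = NA_real_, He_combined = NA_real_,
              S_combined = NA_real_)
  if (!is.null(dataset$alignment)) {
    idsA <- group_ids(dataset, groupA, "sequence")
    idsB <- group_ids(dataset, groupB, "sequence")
    if (length(idsA) >= 2 && length(idsB) >= 2) {
      aln <- subset_alignment(dataset$alignment, c(idsA, idsB))
      labels <- rep(c(groupA, groupB), c(length(idsA), length(idsB)))
      D <- tn93_matrix(aln, scale = "per_locus")
      if (sum(D[upper.tri(D)]) > 0) {
        comp <- amova_components(D, labels)
        out$phi_st_seq <- unname(comp$phi["F_ST"])
        out$N_ST <- nst_from_dist(D, labels)
      }
      out$S_combined <- count_seg_sites(encode_dna(aln$seqs))
    }
  }
  if (!is.null(dataset$genotypes)) {
    idsA <- group_ids(dataset, groupA, "msat")
    idsB <- group_ids(dataset, groupB, "msat")
    if (length(idsA) >= 2 && length(idsB) >= 2) {
      gen <- subset_genotypes(dataset$genotypes, c(idsA, idsB))
      pops <- rep(c(groupA, groupB), c(length(idsA), length(idsB)))
      out$theta_msat <- wc_theta(gen, pops)$theta
      out$He_combined <- pooled_genic_diversity(gen)
    }
  }
  class(out) <- "pair_summary"
  out
}

#' Ordered ABC summary-statistic vector
#'
#' For k groups: per group A (mean alleles/locus), He (mean genic
#' diversity), V (mean allele-size variance), NH (haplotypes), S
#' (segregating sites), k-bar (mean pairwise differences); for each
#' unordered group pair: combined He, Weir-Cockerham FST, combined S, and
#' N_ST. Order is groups first (6 stats each, in the group order given),
#' then pairs in lexicographic index order (4 stats each): length
#' 6k + 4*choose(k,2).
#'
#' @param dataset a `multilocus_dataset` with both markers.
#' @param groups ordered character vector of group labels.
#' @return named numeric vector.
#' @export
summary_vector <- function(dataset, groups) {
  if (is.null(dataset$alignment) || is.null(dataset$genotypes)) {
    stop("summary_vector needs both sequence and microsatellite markers")
  }
  for (g in groups) {
    if (length(group_ids(dataset, g, "sequence")) < 2) {
      stop("group '", g, "' lacks sequences")
    }
    if (length(group_ids(dataset, g, "msat")) < 2) {
      stop("group '", g, "' lacks genotypes")
    }
  }
  out <- numeric(0)
  for (g in groups) {
    ss <- seq_group_stats(group_alignment(dataset, g))
    ms <- msat_group_stats(group_genotypes(dataset, g))
    v <- c(ms$A, ms$He, ms$V, ss$NH, ss$S, ss$kbar)
    names(v) <- paste(g, c("A", "He", "V", "NH", "S", "kbar"), sep = ".")
    out <- c(out, v)
  }
  k <- length(groups)
  if (k >= 2) {
    # shared pair machinery: one encoded alignment + one TN93 matrix
    seq_ids <- lapply(groups, function(g) group_ids(dataset, g, "sequence"))
    all_seq <- unlist(seq_ids)
    enc_all <- encode_dna(subset_alignment(dataset$alignment, all_seq)$seqs)
    D_all <- tn93_matrix(enc_all, scale = "per_locus")
    rownames(D_all) <- colnames(D_all) <- all_seq
    rownames(enc_all) <- all_seq
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ids <- c(seq_ids[[i]], seq_ids[[j]])
      lab <- rep(c(groups[i], groups[j]),
                 c(length(seq_ids[[i]]), length(seq_ids[[j]])))
      nst <- nst_from_dist(D_all[ids, ids], lab)
      s_comb <- count_seg_sites(enc_all[ids, , drop = FALSE])
      gidsA <- group_ids(dataset, groups[i], "msat")
      gidsB <- group_ids(dataset, groups[j], "msat")
      gen <- subset_genotypes(dataset$genotypes, c(gidsA, gidsB))
      theta <- wc_theta(gen, rep(c("A", "B"), c(length(gidsA),
                                                length(gidsB))))$theta
      hec <- pooled_genic_diversity(gen)
      v <- c(hec, theta, s_comb, nst)
      v[is.na(v)] <- 0  # undefined differentiation in monomorphic pools
      names(v) <- paste(groups[i], groups[j],
                        c("Hec", "FST", "Sc", "NST"), sep = ".")
      out <- c(out, v)
    }
  }
  out
}

# unbiased mean genic diversity of a pooled sample, averaged over loci
pooled_genic_diversity <- function(gen) {
  L <- length(gen$loci)
  He <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    a <- locus_alleles(gen, l)
    if (length(a) >= 2) {
      p <- tabulate(match(a, unique(a))) / length(a)
      He[l] <- (length(a) / (length(a) - 1)) * (1 - sum(p^2))
    }
  }
  mean(He, na.rm = TRUE)
}
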