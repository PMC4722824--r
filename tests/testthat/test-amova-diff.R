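test_that("1-level AMOVA matches the brute-force sums-of-squares oracle", {
  # 6 sequences, 3 populations
  strs <- c("AAAAAAAAAA", "AAAAAAAAAC",
            "AAAAACCCCC", "AAAAACCCCA",
            "CCCCCCCCCC", "CCCCCCCCCA")
  aln <- seq_alignment(paste0("i", 1:6), strs)
  map <- data.frame(individual = aln$ids,
                    population = rep(c("p1", "p2", "p3"), each = 2),
                    group = "g1")
  am <- amova(aln, map, "1-level", n_perm = 0)
  d2 <- tn93_matrix(aln, scale = "per_locus")
  or <- oracle_amova_1level(d2, map$population)
  expect_equal(unname(am$ss["among_pop"]), or$ss_ap, tolerance = 1e-12)
  expect_equal(unname(am$ss["within_pop"]), or$ss_wp, tolerance = 1e-12)
  expect_equal(unname(am$components["among_pop"]), or$sigma_a,
               tolerance = 1e-12)
  expect_equal(unname(am$phi["F_ST"]), or$phi_st, tolerance = 1e-12)
  # unequal sizes as well
  map2 <- map; map2$population <- c("p1", "p1", "p1", "p2", "p3", "p3")
  am2 <- amova(aln, map2, "1-level", n_perm = 0)
  or2 <- oracle_amova_1level(d2, map2$population)
  expect_equal(unname(am2$phi["F_ST"]), or2$phi_st, tolerance = 1e-12)
})

test_that("degenerate AMOVA designs behave as expected", {
  # clones everywhere: all among-components zero
  strs <- rep(c("ACGTACGTAC", "ACGTACGTAT"), 3)
  aln <- seq_alignment(paste0("i", 1:6), strs)
  map <- data.frame(individual = aln$ids,
                    population = rep(c("p1", "p2", "p3"), 2),
                    group = rep(c("g1", "g1", "g2"), 2))
  am <- amova(aln, map, "2-level", n_perm = 0)
  # among sums of squares vanish exactly; component estimates may be
  # negative, so the floored percentages attribute everything within
  expect_equal(unname(am$ss["among_grp"]), 0, tolerance = 1e-10)
  expect_equal(unname(am$ss["among_pop_within_grp"]), 0, tolerance = 1e-10)
  expect_equal(unname(am$percent["within_pop"]), 100, tolerance = 1e-8)
  # 2 groups x 1 population, fixed difference: F_CT = F_ST = 1
  strs2 <- c(rep("AAGTACGTAC", 3), rep("ACGTACGTAT", 3))
  aln2 <- seq_alignment(paste0("j", 1:6), strs2)
  map2 <- data.frame(individual = aln2$ids,
                     population = rep(c("pA", "pB"), each = 3),
                     group = rep(c("gA", "gB"), each = 3))
  am2 <- amova(aln2, map2, "2-level", n_perm = 0)
  expect_equal(unname(am2$phi["F_ST"]), 1)
  expect_equal(unname(am2$phi["F_CT"]), 1)
})

test_that("AMOVA percentages and Phi algebra are internally consistent", {
  set.seed(77)
  base <- sample(c("A", "C", "G", "T"), 40, TRUE)
  seqs <- t(vapply(1:12, function(i) {
    s <- base; idx <- sample(40, 2 + (i > 6) * 3)
    s[idx] <- sample(c("A", "C", "G", "T"), length(idx), TRUE); s
  }, character(40)))
  aln <- seq_alignment(paste0("i", 1:12), seqs)
  map <- data.frame(individual = aln$ids,
                    population = rep(c("p1", "p2", "p3", "p4"), each = 3),
                    group = rep(c("g1", "g2"), each = 6))
  am <- amova(aln, map, "2-level", n_perm = 100, rng_seed = 5)
  expect_equal(sum(am$percent), 100, tolerance = 0.1)
  sa <- am$components["among_grp"]; sb <- am$components["among_pop_within_grp"]
  sc <- am$components["within_pop"]
  expect_equal(unname(am$phi["F_CT"]), unname(sa / (sa + sb + sc)))
  expect_equal(unname(am$phi["F_SC"]), unname(sb / (sb + sc)))
  expect_equal(unname(am$phi["F_ST"]), unname((sa + sb) / (sa + sb + sc)))
  expect_true(all(am$p_values >= 0 & am$p_values <= 1, na.rm = TRUE))
})

test_that("F_ST permutation p-values are uniform under no structure", {
  # small-scale version of the calibration property: 120 unstructured
  # datasets; p-values should not deviate from uniform (KS at alpha 0.01)
  set.seed(99)
  ps <- replicate(120, {
    base <- sample(c("A", "C", "G", "T"), 30, TRUE)
    seqs <- t(vapply(1:9, function(i) {
      s <- base; idx <- sample(30, 2)
      s[idx] <- sample(c("A", "C", "G", "T"), 2, TRUE); s
    }, character(30)))
    aln <- seq_alignment(paste0("i", 1:9), seqs)
    map <- data.frame(individual = aln$ids,
                      population = rep(c("p1", "p2", "p3"), each = 3),
                      group = "g")
    am <- amova(aln, map, "1-level", n_perm = 60,
                rng_seed = sample.int(1e6, 1))
    am$p_values["F_ST"]
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("pairwise differentiation boundary cases and WC oracle", {
  ds <- toy_dataset()
  pr <- pairwise_differentiation(ds, "GA", "GB")
  expect_lte(pr$phi_st_seq, 1)
  expect_lte(pr$theta_msat, 1)
  expect_gte(pr$S_combined,
             seq_group_stats(group_alignment(ds, "GA"))$S)
  # identical haplotype composition in both groups -> ~0 (the estimator
  # has a small negative bias of order -1/(n-1) in this exact design)
  set.seed(8)
  base <- sample(c("A", "C", "G", "T"), 40, TRUE)
  haps <- vapply(1:8, function(i) {
    s <- base; idx <- sample(40, 2)
    s[idx] <- sample(c("A", "C", "G", "T"), 2, TRUE)
    paste(s, collapse = "")
  }, character(1))
  aln <- seq_alignment(paste0("i", 1:16), c(haps, haps))
  map <- data.frame(individual = aln$ids,
                    population = rep(c("pA", "pB"), each = 8),
                    group = rep(c("GA", "GB"), each = 8))
  ds2 <- assemble_dataset(alignment = aln, map = map)
  pr2 <- pairwise_differentiation(ds2, "GA", "GB")
  expect_lt(abs(pr2$phi_st_seq), 0.2)
  expect_lt(abs(pr2$N_ST), 0.2)
  # fixed difference -> phi = 1
  strs3 <- c(rep("AAGTACGTAC", 4), rep("ACGTACGTAT", 4))
  aln3 <- seq_alignment(paste0("k", 1:8), strs3)
  map3 <- data.frame(individual = aln3$ids,
                     population = rep(c("pA", "pB"), each = 4),
                     group = rep(c("GA", "GB"), each = 4))
  ds3 <- assemble_dataset(alignment = aln3, map = map3)
  pr3 <- pairwise_differentiation(ds3, "GA", "GB")
  expect_equal(pr3$phi_st_seq, 1)
  expect_gt(pr3$N_ST, 0.9)
})

test_that("summary_vector has the documented layout and invariances", {
  ds <- toy_dataset()
  sv <- summary_vector(ds, c("GA", "GB"))
  expect_length(sv, 6 * 2 + 4 * 1)
  expect_identical(names(sv)[1:6],
                   paste("GA", c("A", "He", "V", "NH", "S", "kbar"),
                         sep = "."))
  expect_identical(names(sv)[13:16],
                   paste("GA.GB", c("Hec", "FST", "Sc", "NST"), sep = "."))
  # determinism
  expect_identical(sv, summary_vector(ds, c("GA", "GB")))
  # permuting individual order within groups leaves the vector unchanged
  perm <- c(sample(1:5), sample(6:10))
  ds_p <- assemble_dataset(
    subset_alignment(ds$alignment, ds$alignment$ids[perm]),
    subset_genotypes(ds$genotypes, ds$genotypes$ids[perm]),
    ds$map[perm, ])
  expect_equal(summary_vector(ds_p, c("GA", "GB")), sv)
  # missing marker errors name the gap
  ds_noseq <- assemble_dataset(genotypes = ds$genotypes, map = ds$map)
  expect_error(summary_vector(ds_noseq, c("GA", "GB")), "both")
})
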