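test_that("generation-time and rate arithmetic reproduce known values", {
  expect_equal(round(generation_time(2, 0.52), 2), 3.08)
  expect_equal(round(generation_time(2, 0.30), 2), 2.43)
  expect_equal(generation_time(3, 0), 3)
  expect_error(generation_time(2, 1), "survival")
  expect_equal(round(geometric_mean_rate(c(0.0145, 0.007)), 6), 0.010075)
  expect_equal(geometric_mean_rate(c(0.02, 0.02)), 0.02)
  expect_equal(geometric_mean_rate(0.013), 0.013)
  expect_error(geometric_mean_rate(c(0.1, -0.1)), "positive")
  expect_equal(round(per_generation_to_per_year(2.96e-3, 2.75), 5),
               round(1.08e-3, 5))
  expect_equal(per_generation_to_per_year(5e-4, 1), 5e-4)
  mu <- per_generation_to_per_year(2.96e-3, 2.75)
  expect_equal(mu * 2.75, 2.96e-3)
  expect_error(per_generation_to_per_year(1e-3, 0), "positive")
})

test_that("prior draws are uniform, ordered and reproducible", {
  pr <- prior_spec()
  draws <- sample_priors(pr, n = 5000, rng_seed = 3)
  expect_gte(min(draws[, "N_SMO"]), 10)
  expect_lte(max(draws[, "N_SMO"]), 1e5)
  expect_gt(stats::ks.test(draws[, "N_SMO"], "punif", 10, 1e5)$p.value, 0.01)
  expect_true(all(draws[, "t1"] < draws[, "t2"] &
                    draws[, "t2"] < draws[, "t3"]))
  again <- sample_priors(pr, n = 5000, rng_seed = 3)
  expect_identical(draws, again)
  expect_error(prior_spec(list(t1 = c(5, 2))), "bad range")
  expect_error(sample_priors(prior_spec(list(t1 = c(49000, 50000),
                                             t2 = c(100, 200),
                                             t3 = c(100, 200)))),
               "infeasible|rejection")
})

test_that("pairwise coalescence times match theory for both marker classes", {
  one_pop <- demographic_scenario("const", "P1", list())
  pars <- c(N_P1 = 1000)
  set.seed(10)
  t_auto <- replicate(2000, {
    simulate_genealogy(one_pop, pars, c(P1 = 2L), "autosomal")$time[3]
  })
  expect_lt(abs(mean(t_auto) - 2000) / 2000, 0.05)
  t_mt <- replicate(2000, {
    simulate_genealogy(one_pop, pars, c(P1 = 2L), "mtDNA")$time[3]
  })
  expect_lt(abs(mean(t_mt) - 500) / 500, 0.05)
})

test_that("merge events move lineages and trees stay ultrametric/finite", {
  sc1 <- scenario_preset("Sc1")
  # huge extant sizes, tiny final ancestral size: no coalescence before t3
  pars <- c(N_TMVB = 1e8, N_SMO = 1e8, N_SMS = 1e8, N_CHIS = 1e8,
            N5 = 1e8, N6 = 1e8, N7 = 10,
            t1 = 2, t2 = 5, t3 = 10, r = 0.5)
  set.seed(2)
  tr <- simulate_genealogy(sc1, pars, c(TMVB = 3L, SMO = 3L, SMS = 3L,
                                        CHIS = 3L), "autosomal")
  internal_times <- tr$time[(tr$n_leaves + 1):(2 * tr$n_leaves - 1)]
  expect_true(all(internal_times >= 10))
  expect_true(all(is.finite(internal_times)))
  # random prior draws: finite tree heights under all three scenarios
  pr <- prior_spec()
  set.seed(4)
  for (nm in c("Sc1", "Sc2", "Sc3")) {
    sc <- scenario_preset(nm)
    for (rep in 1:30) {
      p <- sample_priors(pr)
      tr <- simulate_genealogy(sc, p, c(TMVB = 3L, SMO = 3L, SMS = 2L,
                                        CHIS = 2L), "mtDNA")
      expect_true(all(is.finite(tr$time)))
      expect_true(all(diff(tr$time[(tr$n_leaves + 1):(2 * tr$n_leaves - 1)]) >= 0))
    }
  }
  # event times must strictly increase
  bad <- pars; bad["t2"] <- 1
  expect_error(simulate_genealogy(sc1, bad, c(TMVB = 2L, SMO = 2L,
                                              SMS = 2L, CHIS = 2L),
                                  "mtDNA"), "strictly increase")
})

test_that("scenario construction is validated", {
  expect_error(demographic_scenario("x", c("A", "B"), list()),
               "exactly one population")
  expect_error(demographic_scenario("x", c("A", "B"), list(
    list(type = "merge", time = "t1", source = "C", sink = "A",
         new_size = "N5"))), "inactive")
})

test_that("HKY sequence mutation behaves per theory", {
  two_tip <- list(parent = c(3L, 3L, 0L), time = c(0, 0, 5000),
                  n_leaves = 2L, leaf_pop = c("P1", "P1"))
  # mu = 0: identical haplotypes
  s0 <- mutate_sequence(two_tip, locus_model("sequence", length = 100,
                                             mu = 0), rng_seed = 1)
  expect_identical(s0[1, ], s0[2, ])
  # mean pairwise differences ~ 2 mu L t in the small-mu limit
  mu <- 2e-7; L <- 500; t <- 5000
  set.seed(6)
  diffs <- replicate(2000, {
    s <- mutate_sequence(two_tip, locus_model("sequence", length = L, mu = mu))
    sum(s[1, ] != s[2, ])
  })
  expected <- 2 * mu * L * t
  expect_lt(abs(mean(diffs) - expected) / expected, 0.05)
  # transition:transversion ratio grows with kappa
  ratio_at <- function(kappa) {
    set.seed(20)
    ts <- tv <- 0
    for (i in 1:300) {
      s <- mutate_sequence(two_tip,
                           locus_model("sequence", length = 200, mu = 5e-7,
                                       kappa = kappa))
      d <- which(s[1, ] != s[2, ])
      for (j in d) {
        pair <- sort(s[, j])
        if (all(pair == c("A", "G")) || all(pair == c("C", "T"))) {
          ts <- ts + 1
        } else tv <- tv + 1
      }
    }
    ts / max(tv, 1)
  }
  r <- vapply(c(1, 5, 25), ratio_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("GSM steps follow the geometric step-size law", {
  set.seed(9)
  s0 <- scenabc:::gsm_steps(5000, 0)
  expect_true(all(abs(s0) == 1))
  s5 <- scenabc:::gsm_steps(10000, 0.5)
  expect_lt(abs(mean(abs(s5)) - 2) / 2, 0.05)  # E[G] = 1/(1-P)
  expect_lt(abs(mean(sign(s5))), 0.05)         # fair sign
  # mu = 0: monomorphic
  two_tip <- list(parent = c(3L, 3L, 0L), time = c(0, 0, 1000),
                  n_leaves = 2L, leaf_pop = c("P1", "P1"))
  a <- mutate_microsat(two_tip, locus_model("microsat", mu = 0), rng_seed = 2)
  expect_equal(a[1], a[2])
  expect_equal(a[1], 20L)  # range midpoint root
  # alleles stay in range under heavy mutation
  heavy <- mutate_microsat(list(parent = c(3L, 3L, 0L),
                                time = c(0, 0, 1e6), n_leaves = 2L,
                                leaf_pop = c("P1", "P1")),
                           locus_model("microsat", mu = 1e-2, P = 0.3),
                           rng_seed = 3)
  expect_true(all(heavy >= 1 & heavy <= 40))
})

test_that("folded free walk matches the sequential reflecting walk in law", {
  # sequential oracle: reflect after every step
  seq_reflect <- function(start, steps, lo, hi) {
    x <- start
    for (s in steps) {
      x <- x + s
      while (x < lo || x > hi) {
        if (x > hi) x <- 2 * hi - x
        if (x < lo) x <- 2 * lo - x
      }
    }
    x
  }
  lo <- 1L; hi <- 6L
  set.seed(33)
  n_rep <- 4000
  seq_end <- fold_end <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    steps <- scenabc:::gsm_steps(12, 0.3)
    seq_end[r] <- seq_reflect(3L, steps, lo, hi)
    steps2 <- scenabc:::gsm_steps(12, 0.3)
    fold_end[r] <- scenabc:::fold_reflect(3L + sum(steps2), lo, hi)
  }
  expect_true(all(fold_end >= lo & fold_end <= hi))
  o <- tabulate(seq_end, hi); e <- tabulate(fold_end, hi)
  pval <- stats::chisq.test(rbind(o, e))$p.value
  expect_gt(pval, 0.001)
})

test_that("segregating sites match the exact constant-size pmf", {
  # single population, n = 10, theta = 3 (mutational scale): compare the
  # simulated S distribution against the Tavare closed form
  one_pop <- demographic_scenario("const", "P1", list())
  N <- 1000; L <- 5000
  mu <- 3 / N / L  # theta = 2 * (N/2) * mu * L = 3
  set.seed(12)
  S <- replicate(800, {
    tr <- simulate_genealogy(one_pop, c(N_P1 = N), c(P1 = 10L), "mtDNA")
    seqs <- mutate_sequence(tr, locus_model("sequence", length = L, mu = mu))
    sum(colSums(seqs != matrix(seqs[1, ], nrow(seqs), L, byrow = TRUE)) > 0)
  })
  smax <- max(S, 30)
  pmf <- oracle_S_pmf(10, 3, smax)
  obs <- tabulate(S + 1L, smax + 1L)
  # pool tail bins to keep expected counts reasonable
  brk <- c(0:14, Inf)
  o <- vapply(seq_len(length(brk) - 1), function(i) {
    sum(obs[(0:smax) >= brk[i] & (0:smax) < brk[i + 1]])
  }, numeric(1))
  e <- vapply(seq_len(length(brk) - 1), function(i) {
    sum(pmf[(0:smax) >= brk[i] & (0:smax) < brk[i + 1]])
  }, numeric(1)) * 800
  pval <- stats::pchisq(sum((o - e)^2 / e), df = length(o) - 1,
                        lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("simulated datasets are valid and reach the panmixia limit", {
  sc1 <- scenario_preset("Sc1")
  cfg <- config_preset("small")
  pars <- c(N_TMVB = 5e4, N_SMO = 5e4, N_SMS = 5e4, N_CHIS = 5e4,
            N5 = 5e4, N6 = 5e4, N7 = 5e4,
            t1 = 100, t2 = 120, t3 = 150, r = 0.5,
            mu_seq = 8e-8, mu_ms = 5e-4, P_gsm = 0.2)
  ds <- simulate_dataset(sc1, pars, cfg, n_msat = 4, rng_seed = 31)
  expect_s3_class(ds, "multilocus_dataset")
  expect_equal(vapply(c("TMVB", "SMO", "SMS", "CHIS"),
                      function(g) length(scenabc:::group_ids(ds, g, "sequence")),
                      integer(1)),
               c(TMVB = 5L, SMO = 8L, SMS = 6L, CHIS = 6L))
  expect_equal(vapply(c("TMVB", "SMO", "SMS", "CHIS"),
                      function(g) length(scenabc:::group_ids(ds, g, "msat")),
                      integer(1)),
               c(TMVB = 4L, SMO = 6L, SMS = 5L, CHIS = 5L))
  # near-panmixia: splits far in the past relative to nothing -- here the
  # splits are so recent that the four groups are one population
  set.seed(41)
  phis <- replicate(50, {
    d <- simulate_dataset(sc1, pars, cfg, n_msat = 2)
    pairwise_differentiation(d, "SMO", "CHIS")$phi_st_seq
  })
  expect_lt(abs(mean(phis, na.rm = TRUE)), 0.06)
})

test_that("mtDNA diversity increases with population size", {
  one_pop <- demographic_scenario("const", "P1", list())
  set.seed(17)
  kbar_at <- function(N) {
    mean(replicate(150, {
      tr <- simulate_genealogy(one_pop, c(N_P1 = N), c(P1 = 8L), "mtDNA")
      seqs <- mutate_sequence(tr, locus_model("sequence", length = 751,
                                              mu = 5e-8))
      st <- seq_group_stats(seq_alignment(paste0("i", 1:8), seqs))
      st$kbar
    }))
  }
  k <- vapply(c(1e3, 1e4, 1e5), kbar_at, numeric(1))
  expect_true(all(diff(k) > 0))
})

test_that("reference tables have the forced layout and are reproducible", {
  scen <- lapply(c("Sc1", "Sc2", "Sc3"), scenario_preset)
  pr <- prior_spec(list(N_TMVB = c(1e4, 1e5), N_SMO = c(1e4, 1e5),
                        N_SMS = c(1e4, 1e5), N_CHIS = c(1e4, 1e5)))
  cfg <- config_preset("small")
  tab <- build_reference_table(scen, 8, pr, cfg, n_msat = 3,
                               rng_seed = 7)
  expect_equal(nrow(tab$stats), 24)
  expect_equal(ncol(tab$params), 14)
  expect_equal(ncol(tab$stats), 6 * 4 + 4 * 6)  # 48
  expect_identical(unique(tab$scenario), c("Sc1", "Sc2", "Sc3"))
  expect_false(anyNA(tab$stats))
  # determinism under the same master seed
  tab2 <- build_reference_table(scen, 8, pr, cfg, n_msat = 3,
                                rng_seed = 7)
  expect_identical(tab$stats, tab2$stats)
  expect_identical(tab$params, tab2$params)
  # CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_reference_table(tab, f)
  back <- read_reference_table(f)
  expect_equal(back$stats, tab$stats, tolerance = 1e-12)
  expect_equal(unclass(back$prior), unclass(tab$prior))
})

test_that("checkpointed builds resume to the identical table", {
  scen <- list(scenario_preset("Sc1"))
  pr <- prior_spec()
  cfg <- config_preset("small")
  ck <- withr::local_tempfile(fileext = ".csv")
  full <- build_reference_table(scen, 6, pr, cfg, n_msat = 2, rng_seed = 5)
  # write a checkpoint after 4 rows, then resume
  partial <- build_reference_table(scen, 6, pr, cfg, n_msat = 2,
                                   rng_seed = 5, checkpoint_path = ck,
                                   checkpoint_every = 4L)
  expect_true(file.exists(ck))
  resumed <- build_reference_table(scen, 6, pr, cfg, n_msat = 2,
                                   rng_seed = 5, checkpoint_path = ck,
                                   checkpoint_every = 4L)
  expect_equal(resumed$stats, full$stats, tolerance = 1e-10)
})
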