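# toy reference tables built directly (no coalescent), exercising the ABC
# machinery against analytic expectations

toy_table <- function(n_per, k = 3, shift = 0, p = 3, seed = 1,
                      scen = paste0("Sc", seq_len(k))) {
  set.seed(seed)
  stats <- do.call(rbind, lapply(seq_len(k), function(s) {
    matrix(stats::rnorm(n_per * p, mean = shift * (s - 1)), n_per, p)
  }))
  colnames(stats) <- paste0("st", seq_len(p))
  params <- matrix(stats::runif(n_per * k, 0, 10), ncol = 1,
                   dimnames = list(NULL, "t3"))
  prior <- prior_spec(list(t3 = c(0, 10)))
  structure(list(scenario = rep(scen, each = n_per), params = params,
                 stats = stats, prior = prior, seed = seed,
                 n_per_scenario = n_per, groups = NULL),
            class = "scenabc_reftable")
}

test_that("rejection step reproduces a brute-force nearest-neighbour scan", {
  tab <- toy_table(500, k = 1, p = 4, seed = 3)
  obs <- c(st1 = 0.3, st2 = -0.2, st3 = 1, st4 = 0)
  rej <- standardize_and_reject(tab, obs, delta = 0.05)
  # oracle: scale by MAD, Euclidean scan, take the 25 closest
  sc <- apply(tab$stats, 2, stats::mad)
  d <- sqrt(colSums((t(tab$stats) / sc - obs / sc)^2))
  expect_setequal(rej$index, order(d)[1:25])
  expect_equal(sort(rej$distance), sort(d[order(d)[1:25]]), tolerance = 1e-12)
  # delta = 1 accepts everything
  expect_length(standardize_and_reject(tab, obs, delta = 1)$index, 500)
  # observed equal to a table row: that row is closest with maximal weight
  obs2 <- tab$stats[42, ]
  rej2 <- standardize_and_reject(tab, obs2, delta = 0.02)
  expect_equal(rej2$index[1], 42)
  expect_equal(rej2$distance[1], 0)
  expect_equal(which.max(rej2$weight), 1L)
  expect_error(standardize_and_reject(tab, obs[1:2], delta = 0.1), "width")
})

test_that("indistinguishable scenarios give ~1/k posteriors", {
  tab <- toy_table(4000, k = 3, shift = 0, seed = 5)
  obs <- c(st1 = 0, st2 = 0, st3 = 0)
  mc <- model_choice(tab, obs, delta = 0.05)
  expect_equal(sum(mc$logistic), 1, tolerance = 1e-6)
  expect_equal(sum(mc$direct), 1, tolerance = 1e-6)
  expect_true(all(abs(mc$logistic - 1 / 3) < 0.06))
  # CIs contain the point estimate and live in [0, 1]
  expect_true(all(mc$ci_lower <= mc$logistic & mc$logistic <= mc$ci_upper))
  expect_true(all(mc$ci_lower >= 0 & mc$ci_upper <= 1))
})

test_that("separable scenarios are identified nearly certainly", {
  tab <- toy_table(1500, k = 3, shift = 8, seed = 6)
  obs <- c(st1 = 0, st2 = 0, st3 = 0)  # inside cluster 1
  mc <- model_choice(tab, obs, delta = 0.04)
  expect_gt(mc$logistic["Sc1"], 0.99)
  expect_equal(selected_scenario(mc), "Sc1")
  # moderately separated 2-scenario toy: logistic and direct agree
  tab2 <- toy_table(3000, k = 2, shift = 1.5, seed = 8)
  obs2 <- c(st1 = 0.75, st2 = 0.75, st3 = 0.75)  # between the clusters
  mc2 <- model_choice(tab2, obs2, delta = 0.05)
  expect_lt(max(abs(mc2$logistic - mc2$direct)), 0.05)
})

test_that("model choice is deterministic and continuous in delta", {
  tab <- toy_table(1000, k = 3, shift = 1, seed = 9)
  obs <- c(st1 = 0.5, st2 = 0, st3 = 0)
  a <- model_choice(tab, obs, delta = 0.02)
  b <- model_choice(tab, obs, delta = 0.02)
  expect_identical(a$logistic, b$logistic)
  for (d in c(0.005, 0.01, 0.02, 0.04, 0.08)) {
    mc <- suppressWarnings(model_choice(tab, obs, delta = d))
    expect_equal(sum(mc$logistic), 1, tolerance = 1e-6)
  }
})

test_that("local-linear adjustment collapses a noiseless identity map", {
  # one statistic equals the parameter: the posterior concentrates on the
  # observed value (up to local curvature of the range-logit link)
  set.seed(11)
  th <- stats::runif(2000, 0, 10)
  tab <- structure(list(
    scenario = rep("Sc1", 2000),
    params = matrix(th, ncol = 1, dimnames = list(NULL, "t3")),
    stats = matrix(th, ncol = 1, dimnames = list(NULL, "st1")),
    prior = prior_spec(list(t3 = c(0, 10))),
    seed = 11, n_per_scenario = 2000, groups = NULL),
    class = "scenabc_reftable")
  obs <- c(st1 = 4.2)
  pp <- estimate_parameters(tab, obs, "Sc1", delta = 0.05)
  est <- pp$estimates$t3
  expect_lt(abs(est$mean - 4.2), 0.02)
  expect_lt(est$q975 - est$q025, 0.05)
  # all adjusted values stay within the prior bounds
  expect_true(all(est$sample >= 0 & est$sample <= 10))
})

test_that("adjusted posteriors respect prior bounds on noisy toys", {
  set.seed(13)
  for (rep in 1:20) {
    th <- stats::runif(400, 0, 10)
    stats_m <- cbind(st1 = th + stats::rnorm(400, 0, 2),
                     st2 = stats::rnorm(400))
    tab <- structure(list(scenario = rep("Sc1", 400),
                          params = matrix(th, ncol = 1,
                                          dimnames = list(NULL, "t3")),
                          stats = stats_m,
                          prior = prior_spec(list(t3 = c(0, 10))),
                          seed = rep, n_per_scenario = 400, groups = NULL),
                     class = "scenabc_reftable")
    obs <- c(st1 = stats::runif(1, 0, 10), st2 = 0)
    pp <- estimate_parameters(tab, obs, "Sc1", delta = 0.2)
    expect_true(all(pp$estimates$t3$sample >= 0 &
                      pp$estimates$t3$sample <= 10))
    qs <- unlist(pp$estimates$t3[c("q025", "q050", "median", "q950", "q975")])
    expect_false(is.unsorted(qs))
  }
})

test_that("POD errors: random choice among identical scenarios, zero when separable", {
  tab <- toy_table(2000, k = 3, shift = 0, seed = 15)
  set.seed(16)
  pod_stats <- matrix(stats::rnorm(300 * 3), 300, 3,
                      dimnames = list(NULL, colnames(tab$stats)))
  pods <- list(scenario = rep(paste0("Sc", 1:3), each = 100),
               stats = pod_stats)
  ce <- suppressWarnings(
    pods_error_rates(tab, n_pods = 100, delta = 0.03, focal = "Sc1",
                     pods = pods))
  expect_lt(abs(ce$type_I - 2 / 3), 0.12)
  expect_gte(ce$type_I, 0); expect_lte(ce$type_II, 1)
  # separable case
  tab2 <- toy_table(1000, k = 3, shift = 8, seed = 17)
  set.seed(18)
  pod_stats2 <- do.call(rbind, lapply(0:2, function(s) {
    matrix(stats::rnorm(40 * 3, mean = 8 * s), 40, 3)
  }))
  colnames(pod_stats2) <- colnames(tab2$stats)
  pods2 <- list(scenario = rep(paste0("Sc", 1:3), each = 40),
                stats = pod_stats2)
  ce2 <- pods_error_rates(tab2, n_pods = 40, delta = 0.03, focal = "Sc1",
                          pods = pods2)
  expect_equal(ce2$type_I, 0)
  expect_equal(ce2$type_II, 0)
  expect_equal(sum(ce2$confusion), 120)
})

test_that("model_check projects one observed point and calibrated tails", {
  tab <- toy_table(1500, k = 1, p = 3, seed = 19)
  fake_post <- structure(list(
    scenario = "Sc1", delta = 0.1, n_accepted = 200,
    estimates = list(t3 = list(sample = stats::runif(200, 0, 10),
                               weight = rep(1, 200),
                               prior_range = c(0, 10)))),
    class = "parameter_posterior")
  sim_fn <- function(pars, seed) {
    set.seed(seed)
    stats::setNames(stats::rnorm(3), paste0("st", 1:3))
  }
  obs <- c(st1 = 0.2, st2 = -0.4, st3 = 0.1)
  ck <- model_check(tab, fake_post, obs, sim_fn, n_pp = 150, rng_seed = 20)
  expect_equal(nrow(ck$obs_proj), 1)
  expect_equal(nrow(ck$pp_proj), 150)
  expect_true(all(ck$tail_prob >= 0 & ck$tail_prob <= 1))
  # an observed vector drawn from the prior cloud projects inside the
  # first-two-PC range of the prior cloud
  obs2 <- tab$stats[7, ]
  ck2 <- model_check(tab, fake_post, obs2, sim_fn, n_pp = 100, rng_seed = 21)
  rng1 <- range(ck2$prior_proj[, 1]); rng2 <- range(ck2$prior_proj[, 2])
  expect_gte(ck2$obs_proj[1, 1], rng1[1]); expect_lte(ck2$obs_proj[1, 1], rng1[2])
  expect_gte(ck2$obs_proj[1, 2], rng2[1]); expect_lte(ck2$obs_proj[1, 2], rng2[2])
})

test_that("posterior-predictive tail probabilities are uniform when the model is true", {
  # prior-predictive calibration of the tail machinery on a cheap
  # one-statistic gaussian model
  tab <- toy_table(400, k = 1, p = 1, seed = 23)
  set.seed(24)
  tails <- replicate(150, {
    fake_post <- structure(list(
      scenario = "Sc1", delta = 1, n_accepted = 50,
      estimates = list(t3 = list(sample = stats::runif(50, 0, 10),
                                 weight = rep(1, 50),
                                 prior_range = c(0, 10)))),
      class = "parameter_posterior")
    sim_fn <- function(pars, seed) {
      set.seed(seed)
      c(st1 = stats::rnorm(1))
    }
    obs <- c(st1 = stats::rnorm(1))
    ck <- model_check(tab, fake_post, obs, sim_fn, n_pp = 120,
                      rng_seed = sample.int(1e6, 1))
    ck$tail_prob[["st1"]]
  })
  expect_gt(suppressWarnings(stats::ks.test(tails, "punif")$p.value), 0.01)
})
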