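# Backward-time structured coalescent with population splits and one
# optional admixture pulse, dual-marker mutation (HKY sequences, GSM
# microsatellites), uniform priors, and reference-table construction.

#' Define a demographic scenario
#'
#' Events are ordered backward in time and parametrized by name: a `merge`
#' moves all lineages of `source` into `sink` (the sink switching to the
#' ancestral size `new_size`); an `admix` reassigns each lineage of
#' `target` independently to `parent1` with probability `rate`, else
#' `parent2`. After the last event exactly one population must remain.
#'
#' @param name scenario id.
#' @param pops character vector of extant population labels; the effective
#'   size of population P is taken from parameter `N_<P>`.
#' @param events list of event lists with fields `type` ("merge"/"admix"),
#'   `time` (parameter name), and type-specific fields (`source`, `sink`,
#'   `new_size`; or `target`, `parent1`, `parent2`, `rate`).
#' @return object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(name, pops, events) {
  alive <- pops
  for (ev in events) {
    if (!ev$type %in% c("merge", "admix")) stop("unknown event type: ", ev$type)
    if (ev$type == "merge") {
      if (!ev$source %in% alive || !ev$sink %in% alive) {
        stop("merge references an inactive population")
      }
      alive <- setdiff(alive, ev$source)
    } else {
      if (!all(c(ev$target, ev$parent1, ev$parent2) %in% alive)) {
        stop("admixture references an inactive population")
      }
      alive <- setdiff(alive, ev$target)
    }
  }
  if (length(alive) != 1L) {
    stop("after the last event exactly one population must remain (got ",
         length(alive), ")")
  }
  structure(list(name = name, pops = pops, events = events),
            class = "demographic_scenario")
}

#' Built-in divergence scenarios
#'
#' The three competing four-population histories: Sc1 (isolation split:
#' TMVB joins SMO at t1, SMO joins SMS at t2, SMS joins CHIS at t3), Sc2
#' (SMS joins TMVB at t1, TMVB joins SMO at t2, SMO joins CHIS at t3) and
#' Sc3 (SMS is an admixture of TMVB and SMO at t1 with rate r, TMVB joins
#' SMO at t2, SMO joins CHIS at t3). Ancestral sizes are N5, N6, N7
#' (backward order); times are in generations.
#'
#' @param name "Sc1", "Sc2" or "Sc3".
#' @return a [demographic_scenario()].
#' @export
scenario_preset <- function(name = c("Sc1", "Sc2", "Sc3")) {
  name <- match.arg(name)
  pops <- c("TMVB", "SMO", "SMS", "CHIS")
  ev <- switch(name,
    Sc1 = list(
      list(type = "merge", time = "t1", source = "TMVB", sink = "SMO",  new_size = "N5"),
      list(type = "merge", time = "t2", source = "SMO",  sink = "SMS",  new_size = "N6"),
      list(type = "merge", time = "t3", source = "SMS",  sink = "CHIS", new_size = "N7")),
    Sc2 = list(
      list(type = "merge", time = "t1", source = "SMS",  sink = "TMVB", new_size = "N5"),
      list(type = "merge", time = "t2", source = "TMVB", sink = "SMO",  new_size = "N6"),
      list(type = "merge", time = "t3", source = "SMO",  sink = "CHIS", new_size = "N7")),
    Sc3 = list(
      list(type = "admix", time = "t1", target = "SMS", parent1 = "TMVB",
           parent2 = "SMO", rate = "r"),
      list(type = "merge", time = "t2", source = "TMVB", sink = "SMO",  new_size = "N5"),
      list(type = "merge", time = "t3", source = "SMO",  sink = "CHIS", new_size = "N6")))
  demographic_scenario(name, pops, ev)
}

#' Uniform prior specification
#'
#' Defaults: effective sizes uniform on [10, 100000]; split times t1, t2,
#' t3 uniform on [100, 50000] generations with t1 < t2 < t3 enforced by
#' rejection; admixture rate r uniform on (0.001, 0.999); mean sequence
#' rate per site per generation uniform on [1e-9, 1e-7]; mean
#' microsatellite rate per locus per generation uniform on [1e-4, 1e-2];
#' GSM geometric parameter P uniform on [0.1, 0.3].
#'
#' @param ranges named list of c(lower, upper) overriding defaults.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(ranges = list()) {
  def <- list(
    N_TMVB = c(10, 1e5), N_SMO = c(10, 1e5), N_SMS = c(10, 1e5),
    N_CHIS = c(10, 1e5), N5 = c(10, 1e5), N6 = c(10, 1e5), N7 = c(10, 1e5),
    t1 = c(100, 5e4), t2 = c(100, 5e4), t3 = c(100, 5e4),
    r = c(0.001, 0.999),
    mu_seq = c(1e-9, 1e-7), mu_ms = c(1e-4, 1e-2), P_gsm = c(0.1, 0.3))
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || rg[1] >= rg[2]) stop("bad range for ", nm)
    def[[nm]] <- rg
  }
  structure(def, class = "prior_spec")
}

#' Draw parameter vectors from the priors
#'
#' Each parameter is uniform in its range; the ordering constraint
#' t1 < t2 < t3 is enforced by rejection on the time triple.
#'
#' @param prior a [prior_spec()].
#' @param n number of draws.
#' @param rng_seed optional integer seed (NULL continues the current RNG
#'   stream).
#' @return named numeric vector (n = 1) or matrix with one row per draw.
#' @export
sample_priors <- function(prior, n = 1L, rng_seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  tn <- c("t1", "t2", "t3")
  if (all(tn %in% names(prior))) {
    lo <- vapply(prior[tn], `[`, numeric(1), 1)
    hi <- vapply(prior[tn], `[`, numeric(1), 2)
    if (lo[1] >= hi[2] || lo[2] >= hi[3]) {
      stop("infeasible ordering constraint t1 < t2 < t3")
    }
  }
  draw_one <- function() {
    v <- vapply(prior, function(rg) stats::runif(1, rg[1], rg[2]), numeric(1))
    if (all(tn %in% names(v))) {
      for (tries in 1:10000) {
        if (v["t1"] < v["t2"] && v["t2"] < v["t3"]) break
        v[tn] <- vapply(prior[tn], function(rg) stats::runif(1, rg[1], rg[2]),
                        numeric(1))
      }
      if (!(v["t1"] < v["t2"] && v["t2"] < v["t3"])) {
        stop("ordering constraint rejection failed")
      }
    }
    v
  }
  if (n == 1L) draw_one() else t(vapply(seq_len(n), function(i) draw_one(),
                                        numeric(length(prior))))
}

#' Per-marker sample configuration
#'
#' @param seq_copies named integer vector: sampled mtDNA gene copies per
#'   population (one per individual).
#' @param msat_indiv named integer vector: genotyped diploid individuals
#'   per population (two gene copies each).
#' @return object of class `sample_config`.
#' @export
sample_config <- function(seq_copies, msat_indiv) {
  stopifnot(all(seq_copies >= 0), all(msat_indiv >= 0))
  structure(list(seq = seq_copies, msat = msat_indiv),
            class = "sample_config")
}

#' Study-scale and test-scale sample configurations
#'
#' `"paper"`: mtDNA copies (SMO 70, TMVB 19, SMS 37, CHIS 27) and 126
#' diploids split proportionally (SMO 58, TMVB 16, SMS 30, CHIS 22).
#' `"small"`: a reduced configuration used by the scaled test suite.
#'
#' @param name preset name.
#' @export
config_preset <- function(name = c("paper", "small")) {
  name <- match.arg(name)
  switch(name,
    paper = sample_config(
      c(TMVB = 19L, SMO = 70L, SMS = 37L, CHIS = 27L),
      c(TMVB = 16L, SMO = 58L, SMS = 30L, CHIS = 22L)),
    small = sample_config(
      c(TMVB = 5L, SMO = 8L, SMS = 6L, CHIS = 6L),
      c(TMVB = 4L, SMO = 6L, SMS = 5L, CHIS = 5L)))
}

#' Sequence or microsatellite locus model
#'
#' @param kind "sequence" or "microsat".
#' @param length sites (bp), sequence loci only.
#' @param mu per-site (sequence) or per-locus (microsat) rate per
#'   generation.
#' @param kappa HKY transition/transversion rate ratio.
#' @param freqs HKY base frequencies (A, C, G, T), summing to 1.
#' @param P GSM geometric parameter, 0 <= P < 1.
#' @param range allowed allele-size range in repeat units (microsat).
#' @export
locus_model <- function(kind = c("sequence", "microsat"), length = NULL,
                        mu, kappa = 8, freqs = c(0.31, 0.30, 0.13, 0.26),
                        P = 0.22, range = c(1L, 40L)) {
  kind <- match.arg(kind)
  stopifnot(mu >= 0)
  if (kind == "sequence") {
    stopifnot(length >= 1, kappa > 0, abs(sum(freqs) - 1) < 1e-8,
              all(freqs >= 0))
  } else {
    stopifnot(P >= 0, P < 1, range[1] < range[2])
  }
  structure(list(kind = kind, length = length, mu = mu, kappa = kappa,
                 freqs = freqs, P = P, range = as.integer(range)),
            class = "locus_model")
}

# ---- structured coalescent ------------------------------------------------

#' Simulate a genealogy under a demographic scenario
#'
#' Within a population of diploid size N, any two of k lineages coalesce at
#' rate k(k-1)/2 / (2N) per generation for autosomal markers and
#' k(k-1)/2 / (N/2) for mtDNA (haploid, maternal: one quarter of the
#' autosomal copy number). Branch lengths are in generations; trees are
#' ultrametric.
#'
#' @param scenario a [demographic_scenario()].
#' @param params named numeric parameter vector covering every name the
#'   scenario references.
#' @param n_samples named integer vector: sampled gene copies per extant
#'   population.
#' @param marker_class "autosomal" or "mtDNA".
#' @param rng_seed optional integer seed.
#' @return list with `parent` (length 2n-1, 0 at root), `time` (node times,
#'   generations), `n_leaves` and `leaf_pop`.
#' @export
simulate_genealogy <- function(scenario, params, n_samples,
                               marker_class = c("autosomal", "mtDNA"),
                               rng_seed = NULL) {
  marker_class <- match.arg(marker_class)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_samples <- n_samples[n_samples > 0]
  n <- sum(n_samples)
  if (n < 2) stop("need at least 2 sampled gene copies")
  pop_names <- scenario$pops
  sizes <- unname(params[paste0("N_", pop_names)])
  if (anyNA(sizes) || any(sizes <= 0)) {
    stop("missing/invalid population size parameter")
  }
  dd <- if (marker_class == "mtDNA") 0.5 else 2  # denom = dd * N
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes); node_time <- numeric(n_nodes)
  leaf_pop <- rep(names(n_samples), n_samples)
  lin <- seq_len(n)
  lin_pop <- match(leaf_pop, pop_names)
  if (anyNA(lin_pop)) stop("samples placed in unknown population")
  counts <- tabulate(lin_pop, length(pop_names))
  nxt <- n + 1L
  t <- 0
  ev_times <- vapply(scenario$events, function(e) unname(params[[e$time]]),
                     numeric(1))
  if (anyNA(ev_times)) stop("missing event-time parameter")
  if (is.unsorted(ev_times, strictly = TRUE)) {
    stop("event times must strictly increase backward")
  }
  ev_queue <- scenario$events
  repeat {
    if (length(lin) == 1L) break
    rates <- counts * (counts - 1) / 2 / (dd * sizes)
    rates[counts < 2L] <- 0
    total <- sum(rates)
    t_next_ev <- if (length(ev_queue)) unname(params[[ev_queue[[1L]]$time]]) else Inf
    dt <- if (total > 0) stats::rexp(1L, total) else Inf
    if (t + dt >= t_next_ev) {
      if (!is.finite(t_next_ev)) {
        stop("no remaining events but multiple populations with <2 lineages")
      }
      t <- t_next_ev
      ev <- ev_queue[[1L]]; ev_queue <- ev_queue[-1L]
      if (ev$type == "merge") {
        src <- match(ev$source, pop_names); snk <- match(ev$sink, pop_names)
        lin_pop[lin_pop == src] <- snk
        counts[snk] <- counts[snk] + counts[src]; counts[src] <- 0L
        ns <- unname(params[[ev$new_size]])
        if (is.na(ns) || ns <= 0) {
          stop("missing/invalid ancestral size ", ev$new_size)
        }
        sizes[snk] <- ns
      } else {
        tgt <- match(ev$target, pop_names)
        p1 <- match(ev$parent1, pop_names); p2 <- match(ev$parent2, pop_names)
        r <- unname(params[[ev$rate]])
        if (is.na(r) || r < 0 || r > 1) stop("invalid admixture rate")
        sel <- which(lin_pop == tgt)
        to1 <- stats::runif(length(sel)) < r
        lin_pop[sel] <- ifelse(to1, p1, p2)
        counts[tgt] <- 0L
        counts[p1] <- counts[p1] + sum(to1)
        counts[p2] <- counts[p2] + sum(!to1)
      }
    } else {
      t <- t + dt
      p <- sample.int(length(pop_names), 1L, prob = rates / total)
      idx <- which(lin_pop == p)
      pick <- idx[sample.int(length(idx), 2L)]
      parent[lin[pick]] <- nxt
      node_time[nxt] <- t
      lin <- c(lin[-pick], nxt)
      lin_pop <- c(lin_pop[-pick], p)
      counts[p] <- counts[p] - 1L
      nxt <- nxt + 1L
    }
  }
  list(parent = parent, time = node_time, n_leaves = n, leaf_pop = leaf_pop)
}

# nodes in increasing time order above the leaves follow n+1 .. 2n-1 by
# construction, so parents always have larger indices than children.

#' Drop HKY mutations on a genealogy
#'
#' The root sequence is drawn from the model base frequencies; mutation
#' counts per branch are Poisson(mu * L * branch length); each mutation
#' hits a uniform site and substitutes according to the HKY kernel
#' (target base probability proportional to pi_j, scaled by kappa for
#' transitions).
#'
#' @param tree output of [simulate_genealogy()].
#' @param locus a sequence [locus_model()].
#' @param rng_seed optional integer seed.
#' @return character matrix (leaves x sites).
#' @export
mutate_sequence <- function(tree, locus, rng_seed = NULL) {
  stopifnot(locus$kind == "sequence")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- tree$n_leaves; L <- locus$length
  n_nodes <- 2L * n - 1L
  root <- n_nodes
  kernel <- matrix(0, 4, 4)
  ts_pair <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T
  for (b in 1:4) {
    w <- locus$freqs
    w[b] <- 0
    w[ts_pair[b]] <- w[ts_pair[b]] * locus$kappa
    kernel[b, ] <- w / sum(w)
  }
  seqs <- matrix(0L, n_nodes, L)
  seqs[root, ] <- sample.int(4L, L, replace = TRUE, prob = locus$freqs)
  blen <- tree$time[tree$parent[-root]] - tree$time[-root]
  for (v in seq(n_nodes - 1L, 1L)) {
    s <- seqs[tree$parent[v], ]
    nm <- stats::rpois(1L, locus$mu * L * blen[v])
    if (nm > 0L) {
      sites <- sample.int(L, nm, replace = TRUE)
      for (m in seq_len(nm)) {
        cur <- s[sites[m]]
        s[sites[m]] <- sample.int(4L, 1L, prob = kernel[cur, ])
      }
    }
    seqs[v, ] <- s
  }
  out <- matrix(c("A", "C", "G", "T")[seqs[seq_len(n), ]], n, L)
  out
}

#' Drop generalized stepwise mutations on a genealogy
#'
#' Mutations are Poisson(mu * branch length); each changes the repeat count
#' by +/- G with fair sign and G geometric: P(G = g) = (1-P) P^(g-1).
#' Steps leaving the allowed range are reflected at the boundaries. The
#' root allele is the range midpoint.
#'
#' @param tree output of [simulate_genealogy()].
#' @param locus a microsat [locus_model()].
#' @param rng_seed optional integer seed.
#' @return integer vector of allele sizes (repeat units) per sampled copy.
#' @export
mutate_microsat <- function(tree, locus, rng_seed = NULL) {
  stopifnot(locus$kind == "microsat")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- tree$n_leaves
  n_nodes <- 2L * n - 1L
  root <- n_nodes
  lo <- locus$range[1]; hi <- locus$range[2]
  blen <- tree$time[tree$parent[-root]] - tree$time[-root]
  nmut <- stats::rpois(n_nodes - 1L, locus$mu * blen)
  disp <- numeric(n_nodes - 1L)
  tot <- sum(nmut)
  if (tot > 0L) {
    steps <- gsm_steps(tot, locus$P)
    idx <- rep.int(seq_len(n_nodes - 1L), nmut)
    agg <- rowsum(steps, idx)
    disp[as.integer(rownames(agg))] <- agg[, 1]
  }
  # free-walk positions; for sign-symmetric steps the step-by-step
  # reflecting walk equals the free walk folded onto [lo, hi] in
  # distribution (method of images) -- property-tested against the
  # sequential reflecting walk
  free <- numeric(n_nodes)
  free[root] <- round((lo + hi) / 2)
  for (v in seq(n_nodes - 1L, 1L)) {
    free[v] <- free[tree$parent[v]] + disp[v]
  }
  as.integer(fold_reflect(free[seq_len(n)], lo, hi))
}

# fold x onto [lo, hi] with specular (triangle-wave) reflection
fold_reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  ifelse(y > span, 2 * span - y, y) + lo
}

# signed GSM steps: magnitude 1 + Geometric(1-P), fair sign
gsm_steps <- function(n, P) {
  (1L + stats::rgeom(n, prob = 1 - P)) *
    sample(c(-1L, 1L), n, replace = TRUE)
}

#' Simulate a joint mtDNA + microsatellite dataset
#'
#' One mtDNA genealogy produces the concatenated sequence alignment (one
#' copy per individual); each microsatellite locus gets an independent
#' autosomal genealogy, gene copies paired within individuals. Per-locus
#' microsatellite rates are drawn from a Gamma with shape 2 around the mean
#' rate `params["mu_ms"]`.
#'
#' @param scenario a [demographic_scenario()].
#' @param params named parameter vector (see [prior_spec()]).
#' @param config a [sample_config()].
#' @param n_msat number of microsatellite loci.
#' @param seq_length concatenated sequence length (bp).
#' @param rng_seed optional integer seed.
#' @param kappa,freqs HKY settings for the sequence locus.
#' @return a `multilocus_dataset`; map has one population per group.
#' @export
simulate_dataset <- function(scenario, params, config, n_msat = 8L,
                             seq_length = 751L, rng_seed = NULL,
                             kappa = 8, freqs = c(0.31, 0.30, 0.13, 0.26)) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  seq_locus <- locus_model("sequence", length = seq_length,
                           mu = unname(params[["mu_seq"]]),
                           kappa = kappa, freqs = freqs)
  tree <- simulate_genealogy(scenario, params, config$seq, "mtDNA")
  seqs <- mutate_sequence(tree, seq_locus)
  seq_ids <- paste0(tree$leaf_pop, "_s",
                    stats::ave(seq_along(tree$leaf_pop), tree$leaf_pop,
                               FUN = seq_along))
  # symbols come straight from the mutation kernel: skip revalidation
  rownames(seqs) <- seq_ids
  aln <- structure(list(ids = seq_ids, seqs = seqs, length = ncol(seqs)),
                   class = "seq_alignment")
  # microsatellites
  ms_ids <- unlist(lapply(names(config$msat), function(p) {
    if (config$msat[[p]] > 0) paste0(p, "_m", seq_len(config$msat[[p]]))
  }))
  ms_pop <- sub("_m[0-9]+$", "", ms_ids)
  copies <- 2L * config$msat
  a1 <- a2 <- matrix(NA_integer_, length(ms_ids), n_msat)
  mu_locus <- stats::rgamma(n_msat, shape = 2,
                            scale = unname(params[["mu_ms"]]) / 2)
  for (l in seq_len(n_msat)) {
    ms_locus <- locus_model("microsat", mu = mu_locus[l],
                            P = unname(params[["P_gsm"]]))
    tr <- simulate_genealogy(scenario, params, copies, "autosomal")
    al <- mutate_microsat(tr, ms_locus)
    # copies come out grouped by population in config order; pair them
    off <- 0L; row <- 0L
    for (p in names(copies)) {
      k <- copies[[p]]
      if (k == 0L) next
      idx <- which(tr$leaf_pop == p)
      for (i in seq_len(k / 2L)) {
        row <- row + 1L
        a1[row, l] <- al[idx[2L * i - 1L]]
        a2[row, l] <- al[idx[2L * i]]
      }
      off <- off + k
    }
  }
  gen <- msat_genotypes(ms_ids, paste0("L", seq_len(n_msat)), a1, a2)
  all_ids <- c(seq_ids, ms_ids)
  all_pop <- c(tree$leaf_pop, ms_pop)
  map <- data.frame(individual = all_ids,
                    population = paste0("p.", all_pop),
                    group = all_pop, stringsAsFactors = FALSE)
  assemble_dataset(alignment = aln, genotypes = gen, map = map)
}
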