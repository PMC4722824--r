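# Orchestration: one JSON run-config drives stats -> reference table ->
# model choice -> estimation -> PODs -> checking -> color, with seeds and
# a provenance manifest.

#' Read and validate a run configuration
#'
#' JSON schema (all paths relative to the config file unless absolute):
#' `inputs` (fasta, genepop, map, spectra, spectra_groups), `groups`
#' (ordered group labels), `scenarios` (preset names), `n_sims`, `delta`,
#' `n_pods`, `n_pp`, `n_msat`, `seq_length`, `seed`, `outdir`, optional
#' `prior` range overrides and `sample_config`.
#'
#' @param path JSON config path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  defaults <- list(groups = c("TMVB", "SMO", "SMS", "CHIS"),
                   scenarios = c("Sc1", "Sc2", "Sc3"),
                   n_sims = 1000L, delta = 0.05, n_pods = 0L, n_pp = 200L,
                   n_perm = 200L, n_msat = 8L, seq_length = 751L, seed = 1L,
                   outdir = file.path(base, "scenabc_out"))
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$inputs)) stop("config must declare 'inputs'")
  cfg$inputs <- lapply(cfg$inputs, function(p) {
    if (!is.null(p) && !grepl("^/", p)) file.path(base, p) else p
  })
  for (f in unlist(cfg$inputs)) {
    if (!is.null(f) && !file.exists(f)) stop("input not readable: ", f)
  }
  if (!grepl("^/", cfg$outdir)) cfg$outdir <- file.path(base, cfg$outdir)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: summary statistics (stats.csv), reference table (ref.csv),
#' model choice (choice.json), parameter estimation (params.json), POD
#' error rates (pods.json), posterior-predictive model check (check.json),
#' color analysis (color.csv), and a provenance manifest
#' (manifest.json). Stages with existing outputs are reused when
#' `resume = TRUE`; any stage failure halts with a stage-named error,
#' preserving partial outputs.
#'
#' @param config a `run_config` (or path to one).
#' @param resume reuse stage outputs already present in the output dir.
#' @return invisibly, the manifest list.
#' @export
run_full_analysis <- function(config, resume = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("scenabc")),
                   seed = config$seed, started = format(Sys.time()),
                   config = unclass(config), stages = list())
  stage <- function(name, out_file, fn) {
    path <- file.path(config$outdir, out_file)
    t0 <- Sys.time()
    if (resume && file.exists(path)) {
      manifest$stages[[name]] <<- list(file = out_file, reused = TRUE)
      return(path)
    }
    res <- tryCatch(fn(path), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      file = out_file, reused = FALSE,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      md5 = unname(tools::md5sum(path)))
    path
  }
  inp <- config$inputs
  has_gen <- !is.null(inp$genepop)
  has_seq <- !is.null(inp$fasta)
  aln <- if (has_seq) read_alignment(inp$fasta) else NULL
  gen <- if (has_gen) read_genepop(inp$genepop)$genotypes else NULL
  ds <- NULL
  if (has_seq || has_gen) {
    ds <- assemble_dataset(alignment = aln, genotypes = gen, map = inp$map)
    stage("stats", "stats.csv", function(path) {
      write_stats_csv(ds, config$groups, path,
                      n_perm = config$n_perm, rng_seed = config$seed)
    })
  }
  if (has_seq && has_gen) {
    obs <- summary_vector(ds, config$groups)
    scen <- lapply(config$scenarios, scenario_preset)
    prior <- prior_spec(if (is.null(config$prior)) list() else
                          lapply(config$prior, as.numeric))
    cfgsam <- if (is.null(config$sample_config)) {
      sample_config(
        seq_from_dataset(ds, config$groups),
        msat_from_dataset(ds, config$groups))
    } else {
      sample_config(unlist(config$sample_config$seq),
                    unlist(config$sample_config$msat))
    }
    ref_path <- stage("reftable", "ref.csv", function(path) {
      tab <- build_reference_table(scen, config$n_sims, prior, cfgsam,
                                   n_msat = config$n_msat,
                                   seq_length = config$seq_length,
                                   rng_seed = config$seed,
                                   groups = config$groups)
      write_reference_table(tab, path)
    })
    tab <- read_reference_table(ref_path)
    choice <- NULL
    stage("choice", "choice.json", function(path) {
      choice <<- model_choice(tab, obs, delta = config$delta)
      jsonlite::write_json(list(direct = as.list(choice$direct),
                                logistic = as.list(choice$logistic),
                                ci_lower = as.list(choice$ci_lower),
                                ci_upper = as.list(choice$ci_upper),
                                selected = selected_scenario(choice)),
                           path, auto_unbox = TRUE, digits = NA)
      path
    })
    if (is.null(choice)) {
      choice <- jsonlite::read_json(file.path(config$outdir, "choice.json"),
                                    simplifyVector = TRUE)
      best <- choice$selected
    } else best <- selected_scenario(choice)
    post <- NULL
    stage("estimate", "params.json", function(path) {
      post <<- estimate_parameters(tab, obs, best, delta = config$delta)
      out <- lapply(post$estimates, function(e) {
        e[c("mean", "median", "q025", "q050", "q950", "q975")]
      })
      jsonlite::write_json(list(scenario = best, estimates = out), path,
                           auto_unbox = TRUE, digits = NA)
      path
    })
    if (config$n_pods > 0) {
      stage("pods", "pods.json", function(path) {
        pe <- pods_error_rates(tab, scen, cfgsam, n_msat = config$n_msat,
                               seq_length = config$seq_length,
                               n_pods = config$n_pods, delta = config$delta,
                               focal = best, rng_seed = config$seed)
        jsonlite::write_json(list(type_I = pe$type_I, type_II = pe$type_II,
                                  confusion = as.data.frame(pe$confusion),
                                  focal = pe$focal, n_failed = pe$n_failed),
                             path, auto_unbox = TRUE, digits = NA)
        path
      })
    }
    if (config$n_pp > 0 && !is.null(post)) {
      stage("check", "check.json", function(path) {
        scen_best <- scenario_preset(best)
        sim_fn <- function(pars, seed) {
          set.seed(seed)
          dsim <- simulate_dataset(scen_best, pars, cfgsam,
                                   n_msat = config$n_msat,
                                   seq_length = config$seq_length)
          summary_vector(dsim, config$groups)
        }
        ck <- model_check(tab, post, obs, sim_fn, n_pp = config$n_pp,
                          rng_seed = config$seed)
        jsonlite::write_json(list(tail_prob = as.list(ck$tail_prob),
                                  obs_pc = as.numeric(ck$obs_proj[1, 1:2])),
                             path, auto_unbox = TRUE, digits = NA)
        path
      })
    }
  }
  if (!is.null(inp$spectra)) {
    stage("color", "color.csv", function(path) {
      color_table(inp$spectra, inp$spectra_groups, path)
    })
  }
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

seq_from_dataset <- function(ds, groups) {
  vapply(groups, function(g) length(group_ids(ds, g, "sequence")), integer(1))
}
msat_from_dataset <- function(ds, groups) {
  vapply(groups, function(g) length(group_ids(ds, g, "msat")), integer(1))
}

#' Tidy per-group / per-pair / AMOVA statistics table
#'
#' One row per group (diversity, neutrality, mismatch), per group pair
#' (differentiation) and per AMOVA term, written as CSV.
#'
#' @param dataset a `multilocus_dataset`.
#' @param groups ordered group labels.
#' @param path CSV output path.
#' @param n_perm permutations / bootstrap replicates for p-values.
#' @param rng_seed integer seed.
#' @return the path, invisibly.
#' @export
write_stats_csv <- function(dataset, groups, path, n_perm = 1000L,
                            rng_seed = 1L) {
  rows <- list()
  has_seq <- !is.null(dataset$alignment)
  has_gen <- !is.null(dataset$genotypes)
  for (g in groups) {
    row <- list(unit = "group", name = g)
    if (has_seq && length(group_ids(dataset, g, "sequence")) >= 4) {
      aln <- group_alignment(dataset, g)
      ss <- seq_group_stats(aln)
      nt <- neutrality_tests(aln, n_sim = n_perm, rng_seed = rng_seed)
      mm <- mismatch_analysis(aln, n_boot = min(n_perm, 100L),
                              rng_seed = rng_seed)
      row <- c(row, ss[c("N", "NH", "h", "h_sd", "pi", "pi_sd", "S", "kbar")],
               nt[c("D", "p_D", "Fs", "p_Fs")],
               mm[c("tau", "SSD", "p_SSD", "Hri", "p_Hri")])
    }
    if (has_gen && length(group_ids(dataset, g, "msat")) >= 2) {
      ms <- msat_group_stats(group_genotypes(dataset, g))
      row <- c(row, ms[c("A", "He", "Ho", "V", "Ar")])
    }
    rows[[length(rows) + 1L]] <- row
  }
  k <- length(groups)
  if (k >= 2) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    pr <- pairwise_differentiation(dataset, groups[i], groups[j])
    rows[[length(rows) + 1L]] <- list(
      unit = "pair", name = paste(groups[i], groups[j], sep = "-"),
      phi_st_seq = pr$phi_st_seq, theta_msat = pr$theta_msat,
      N_ST = pr$N_ST, He_combined = pr$He_combined,
      S_combined = pr$S_combined)
  }
  if (has_seq) {
    ids <- dataset$alignment$ids
    map <- dataset$map[match(ids, dataset$map$individual), ]
    am1 <- amova(dataset$alignment, map, "1-level", n_perm = n_perm,
                 rng_seed = rng_seed)
    amova_rows <- function(am, label) {
      lapply(seq_along(am$components), function(t) {
        list(unit = "amova", name = paste0(label, ":", names(am$components)[t]),
             df = unname(am$df[t]), SS = unname(am$ss[t]),
             sigma2 = unname(am$components[t]),
             percent = unname(am$percent[t]))
      })
    }
    rows <- c(rows, amova_rows(am1, "1level"))
    if (length(unique(map$group)) >= 2 &&
        length(unique(map$population)) > length(unique(map$group))) {
      am2 <- amova(dataset$alignment, map, "2-level", n_perm = n_perm,
                   rng_seed = rng_seed)
      rows <- c(rows, amova_rows(am2, "2level"))
      for (nm in names(am2$phi)) {
        rows[[length(rows) + 1L]] <- list(unit = "amova",
                                          name = paste0("2level:", nm),
                                          value = unname(am2$phi[nm]),
                                          p = unname(am2$p_values[nm]))
      }
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    as.data.frame(r[all_cols], stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-specimen color-space table
#'
#' Smooths every spectrum, extracts the dual-window hues and tetrahedral
#' color variables, and (when groups are given) appends pairwise
#' color-volume overlaps.
#'
#' @param spectra_path spectra CSV (first column wavelength).
#' @param groups_path optional TSV with columns individual, group.
#' @param path output CSV.
#' @param span loess span.
#' @param vm a [visual_model()].
#' @return the path, invisibly.
#' @export
color_table <- function(spectra_path, groups_path = NULL, path,
                        span = 0.25, vm = visual_model()) {
  specs <- read_spectra(spectra_path)
  groups <- NULL
  if (!is.null(groups_path)) {
    gtab <- utils::read.delim(groups_path, colClasses = "character")
    groups <- stats::setNames(gtab$group, gtab$individual)
  }
  rows <- lapply(names(specs), function(id) {
    sm <- smooth_spectrum(specs[[id]], span)
    hp <- hue_peaks(sm)
    cp <- tetra_point(quantum_catches(sm, vm))
    data.frame(individual = id,
               group = if (!is.null(groups)) groups[[id]] else NA,
               hue_uv = hp$argmax[1], hue_red = hp$argmax[2],
               X = cp$X, Y = cp$Y, Z = cp$Z,
               h_theta = cp$h_theta, h_phi = cp$h_phi,
               r_vec = cp$r_vec, r_max = cp$r_max,
               r_achieved = cp$r_achieved)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(groups)) {
    gl <- unique(df$group)
    if (length(gl) >= 2) {
      ov <- list()
      for (i in 1:(length(gl) - 1)) for (j in (i + 1):length(gl)) {
        A <- as.matrix(df[df$group == gl[i], c("X", "Y", "Z")])
        B <- as.matrix(df[df$group == gl[j], c("X", "Y", "Z")])
        if (nrow(A) >= 4 && nrow(B) >= 4) {
          o <- color_volume_overlap(A, B, n_mc = 2e5L)
          ov[[paste(gl[i], gl[j], sep = "-")]] <-
            list(vol_A = o$vol_A, vol_B = o$vol_B,
                 vol_intersection = o$vol_intersection,
                 frac_union = o$frac_union, frac_smaller = o$frac_smaller)
        }
      }
      jsonlite::write_json(ov, sub("\\.csv$", "_overlap.json", path),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(path)
}
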