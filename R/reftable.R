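# Reference-table construction and persistence for ABC.

# counter-based sub-seed: deterministic in (master, index), independent of
# batching; kept below 2^31 - 1
derive_subseed <- function(master, index, salt = 0L) {
  m <- .Machine$integer.max
  as.integer((as.double(master %% m) * 747796405 + as.double(index) * 2891336453 +
                as.double(salt) * 277803737) %% m)
}

#' Build an ABC reference table
#'
#' For each scenario, draws `n_per_scenario` parameter vectors from the
#' prior, simulates a dataset per draw and records its summary vector.
#' Every row uses a sub-seed derived from `rng_seed` and the global row
#' counter, so tables are bit-identical under any batching; failed
#' simulations are retried with a salted sub-seed and logged.
#'
#' @param scenarios list of [demographic_scenario()] objects.
#' @param n_per_scenario rows per scenario.
#' @param prior a [prior_spec()].
#' @param config a [sample_config()].
#' @param n_msat,seq_length locus layout passed to [simulate_dataset()].
#' @param rng_seed master integer seed.
#' @param groups group order for [summary_vector()]; defaults to the first
#'   scenario's populations.
#' @param checkpoint_path optional CSV path; completed rows are flushed
#'   there every `checkpoint_every` rows and reused on restart.
#' @param checkpoint_every checkpoint interval in rows.
#' @param progress print progress every 500 rows.
#' @return object of class `scenabc_reftable` with elements `scenario`,
#'   `params` (matrix), `stats` (matrix), `prior`, `seed`.
#' @export
build_reference_table <- function(scenarios, n_per_scenario, prior, config,
                                  n_msat = 8L, seq_length = 751L,
                                  rng_seed = 1L, groups = NULL,
                                  checkpoint_path = NULL,
                                  checkpoint_every = 500L,
                                  progress = FALSE) {
  if (inherits(scenarios, "demographic_scenario")) scenarios <- list(scenarios)
  if (is.null(groups)) groups <- scenarios[[1L]]$pops
  n_total <- length(scenarios) * n_per_scenario
  scen_names <- vapply(scenarios, function(s) s$name, character(1))
  done <- NULL
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    done <- utils::read.csv(checkpoint_path, check.names = FALSE)
  }
  rows <- vector("list", n_total)
  idx <- 0L
  for (s in seq_along(scenarios)) {
    for (i in seq_len(n_per_scenario)) {
      idx <- idx + 1L
      if (!is.null(done) && idx <= nrow(done)) next
      sub <- derive_subseed(rng_seed, idx)
      rec <- NULL
      for (attempt in 0:9) {
        rec <- tryCatch({
          set.seed(derive_subseed(sub, attempt, salt = attempt))
          pars <- sample_priors(prior)
          ds <- simulate_dataset(scenarios[[s]], pars, config,
                                 n_msat = n_msat, seq_length = seq_length)
          sv <- summary_vector(ds, groups)
          c(pars, sv)
        }, error = function(e) NULL)
        if (!is.null(rec)) break
      }
      if (is.null(rec)) stop("simulation failed repeatedly at row ", idx)
      rows[[idx]] <- rec
      if (progress && idx %% 500L == 0L) {
        message("reference table: ", idx, "/", n_total)
      }
      if (!is.null(checkpoint_path) && idx %% checkpoint_every == 0L) {
        .write_checkpoint(rows, scen_names, n_per_scenario, idx,
                          checkpoint_path, done)
      }
    }
  }
  param_names <- names(prior_spec())
  if (!is.null(done)) {
    mat_done <- as.matrix(done[, -1L, drop = FALSE])
    for (j in seq_len(nrow(done))) rows[[j]] <- mat_done[j, ]
  }
  full <- do.call(rbind, rows)
  scen_col <- rep(scen_names, each = n_per_scenario)
  params <- full[, param_names, drop = FALSE]
  stats <- full[, setdiff(colnames(full), param_names), drop = FALSE]
  structure(list(scenario = scen_col, params = params, stats = stats,
                 prior = prior, seed = rng_seed,
                 n_per_scenario = n_per_scenario, groups = groups),
            class = "scenabc_reftable")
}

.write_checkpoint <- function(rows, scen_names, n_per, upto, path, done) {
  keep <- rows[seq_len(upto)]
  if (!is.null(done)) for (j in seq_len(nrow(done))) {
    keep[[j]] <- as.matrix(done[, -1L, drop = FALSE])[j, ]
  }
  mat <- do.call(rbind, keep)
  df <- data.frame(scenario = rep(scen_names, each = n_per)[seq_len(upto)],
                   mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' @export
print.scenabc_reftable <- function(x, ...) {
  cat(sprintf("<scenabc_reftable> %d rows (%s), %d parameters, %d statistics\n",
              nrow(x$stats),
              paste(unique(x$scenario), collapse = "/"),
              ncol(x$params), ncol(x$stats)))
  invisible(x)
}

#' Write a reference table as CSV plus metadata JSON
#'
#' @param table a `scenabc_reftable`.
#' @param path CSV output path; metadata goes to `<path>.meta.json`.
#' @export
write_reference_table <- function(table, path) {
  df <- data.frame(scenario = table$scenario, table$params, table$stats,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(stat_names = colnames(table$stats),
               param_names = colnames(table$params),
               prior = lapply(unclass(table$prior), as.numeric),
               seed = table$seed, n_per_scenario = table$n_per_scenario,
               groups = table$groups)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a reference table written by [write_reference_table()]
#' @param path CSV path.
#' @export
read_reference_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  prior <- prior_spec(lapply(meta$prior, as.numeric))
  structure(list(scenario = df$scenario,
                 params = as.matrix(df[, meta$param_names, drop = FALSE]),
                 stats = as.matrix(df[, meta$stat_names, drop = FALSE]),
                 prior = prior, seed = meta$seed,
                 n_per_scenario = meta$n_per_scenario,
                 groups = meta$groups),
            class = "scenabc_reftable")
}
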