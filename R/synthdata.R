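# Truth-annotated synthetic fixtures emulating the four-group study
# layout, so every analysis stage is testable without any download.

#' Generate a synthetic population-genetic fixture
#'
#' Simulates one dataset under a scenario preset and writes FASTA
#' (concatenated 751-bp sequences, default group copies SMO 70 / TMVB 19 /
#' SMS 37 / CHIS 27), GenePop (8 loci, 126 diploids split proportionally),
#' the population map TSV and a truth JSON (scenario, parameters, seed,
#' SHA-256 manifest). Regenerating with the same seed reproduces the files
#' bit-identically.
#'
#' @param scenario a scenario name ("Sc1", "Sc2", "Sc3") or a
#'   [demographic_scenario()].
#' @param params named parameter vector, or `"draw"` to sample from
#'   `prior`.
#' @param config a [sample_config()] or preset name.
#' @param prior a [prior_spec()] used when `params = "draw"`.
#' @param rng_seed master integer seed.
#' @param outdir output directory.
#' @param force overwrite an existing directory.
#' @param n_msat,seq_length locus layout.
#' @return invisibly, the truth list (scenario, params, seed, files).
#' @export
make_popgen_fixture <- function(scenario = "Sc1", params = "draw",
                                config = "paper", prior = prior_spec(),
                                rng_seed = 1L, outdir, force = FALSE,
                                n_msat = 8L, seq_length = 751L) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  if (is.character(config)) config <- config_preset(config)
  if (dir.exists(outdir) && length(dir(outdir)) && !force) {
    stop("output directory exists and is not empty: ", outdir,
         " (use force = TRUE)")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(rng_seed)
  if (identical(params, "draw")) params <- sample_priors(prior)
  ds <- simulate_dataset(scenario, params, config, n_msat = n_msat,
                         seq_length = seq_length)
  files <- c(fasta = file.path(outdir, "sequences.fasta"),
             genepop = file.path(outdir, "genotypes.gen"),
             map = file.path(outdir, "popmap.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_alignment(ds$alignment, files["fasta"])
  pops <- stats::setNames(ds$map$population, ds$map$individual)
  write_genepop(ds$genotypes, pops[ds$genotypes$ids], files["genepop"])
  write_popmap(ds$map, files["map"])
  truth <- list(scenario = scenario$name,
                params = as.list(params),
                rng_seed = rng_seed,
                n_msat = n_msat, seq_length = seq_length,
                config = list(seq = as.list(config$seq),
                              msat = as.list(config$msat)))
  truth$manifest <- as.list(vapply(files[1:3], function(f) {
    unname(tools::md5sum(f))
  }, character(1)))
  jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE, digits = NA)
  invisible(c(truth, list(files = files, dataset = ds)))
}

#' Generate a synthetic reflectance-spectrum fixture
#'
#' Spectra are a sum of two Gaussians on a 1-nm grid over 300-1000 nm: a
#' UV/blue peak near 420 nm and a red peak at the group mean (715 nm for
#' the amethyst groups, 780 nm for the blue group), with per-specimen peak
#' jitter (SD 8 nm) and heteroscedastic noise. Writes a spectra CSV and a
#' group TSV.
#'
#' @param n_per_group specimens per group (>= 5).
#' @param group_red_peaks named numeric vector of red-peak means (nm).
#' @param uv_peak UV/blue peak mean (nm).
#' @param noise_sd baseline noise SD (percent reflectance).
#' @param rng_seed integer seed.
#' @param outdir output directory.
#' @param force overwrite.
#' @return invisibly, list with file paths and the truth table.
#' @export
make_spectra_fixture <- function(n_per_group = 10L,
                                 group_red_peaks = c(amethyst = 715,
                                                     salvini = 715,
                                                     blue = 780),
                                 uv_peak = 420, noise_sd = 0.5,
                                 rng_seed = 1L, outdir, force = FALSE) {
  if (n_per_group < 5L) stop("need at least 5 specimens per group")
  if (dir.exists(outdir) && length(dir(outdir)) && !force) {
    stop("output directory exists and is not empty: ", outdir,
         " (use force = TRUE)")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(rng_seed)
  wl <- 300:1000
  specs <- list(); rows <- list()
  for (g in names(group_red_peaks)) {
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      red_mu <- group_red_peaks[[g]] + stats::rnorm(1, 0, 8)
      uv_mu <- uv_peak + stats::rnorm(1, 0, 8)
      base <- 8 * exp(-((wl - uv_mu)^2) / (2 * 30^2)) +
        35 * exp(-((wl - red_mu)^2) / (2 * 45^2)) + 1
      noise <- stats::rnorm(length(wl), 0, noise_sd * (1 + base / 20))
      specs[[id]] <- reflectance_spectrum(wl, base + noise)
      rows[[id]] <- data.frame(individual = id, group = g,
                               red_peak_true = red_mu,
                               uv_peak_true = uv_mu)
    }
  }
  files <- c(spectra = file.path(outdir, "spectra.csv"),
             groups = file.path(outdir, "groups.tsv"),
             truth = file.path(outdir, "spectra_truth.json"))
  write_spectra(specs, files["spectra"])
  truth <- do.call(rbind, rows)
  utils::write.table(truth[, c("individual", "group")], files["groups"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(rng_seed = rng_seed, noise_sd = noise_sd,
                            truth = truth),
                       files["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(files = files, truth = truth, spectra = specs))
}
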