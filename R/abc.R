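# ABC engine: MAD-standardized rejection, logistic-regression model choice
# with delta-method confidence intervals, local-linear parameter
# adjustment, POD error rates, and posterior-predictive model checking.

#' Standardize statistics and select the closest simulations
#'
#' Each statistic is scaled by its reference median absolute deviation (SD
#' fallback when the MAD is zero; statistics constant across the table are
#' dropped with a warning when the observed value falls outside). Rows are
#' ranked by Euclidean distance to the observed vector and the
#' ceiling(delta * n) closest returned with Epanechnikov weights.
#'
#' @param table a `scenabc_reftable` (or a plain statistics matrix).
#' @param observed named numeric summary vector, same width as the table.
#' @param delta accepted fraction, 0 < delta <= 1.
#' @return list: `index` (accepted row indices), `weight`, `distance`,
#'   `scale` (per-statistic scale used), `dropped` (names of dropped
#'   statistics).
#' @export
standardize_and_reject <- function(table, observed, delta = 0.01) {
  stopifnot(delta > 0, delta <= 1)
  stats_m <- if (inherits(table, "scenabc_reftable")) table$stats else as.matrix(table)
  if (length(observed) != ncol(stats_m)) {
    stop("observed vector width ", length(observed),
         " != table width ", ncol(stats_m))
  }
  sc <- apply(stats_m, 2, stats::mad)
  sdv <- apply(stats_m, 2, stats::sd)
  sc[sc == 0] <- sdv[sc == 0]
  dropped <- character(0)
  keep <- sc > 0
  if (any(!keep)) {
    const_ok <- abs(observed[!keep] - stats_m[1, !keep]) < 1e-12
    bad <- names(which(!keep))[!const_ok]
    if (length(bad)) {
      warning("constant statistics dropped (observed outside value): ",
              paste(bad, collapse = ", "))
    }
    dropped <- names(which(!keep))
  }
  Z <- sweep(stats_m[, keep, drop = FALSE], 2, sc[keep], "/")
  zobs <- observed[keep] / sc[keep]
  d <- sqrt(rowSums(sweep(Z, 2, zobs, "-")^2))
  n_acc <- ceiling(delta * nrow(stats_m))
  ord <- order(d)[seq_len(n_acc)]
  dmax <- max(d[ord])
  w <- if (dmax > 0) 1 - (d[ord] / dmax)^2 else rep(1, n_acc)
  w[w <= 0] <- min(w[w > 0], 1e-8) / 2  # boundary row keeps a nominal weight
  list(index = ord, weight = w, distance = d[ord], scale = sc,
       dropped = dropped, keep = keep)
}

# Fisher discriminant axes (up to K-1) of class-labelled rows; ridge keeps
# the within-class scatter invertible when features are collinear
lda_axes <- function(X, y, K) {
  p <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (k in seq_len(K)) {
    Xi <- X[y == k, , drop = FALSE]
    if (nrow(Xi) == 0) next
    mk <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mk)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + nrow(Xi) * tcrossprod(mk - mu)
  }
  Sw <- Sw + diag(1e-6 * (mean(diag(Sw)) + 1), p)
  M <- solve(Sw, Sb)
  e <- eigen(M)
  ax <- Re(e$vectors[, seq_len(min(K - 1, p)), drop = FALSE])
  # normalize each axis for numerical sanity
  apply(ax, 2, function(v) v / sqrt(sum(v^2)))
}

# ---- weighted multinomial logistic regression (Newton-Raphson) -----------

# y: integer class 1..K; X: model matrix with intercept; w: weights
# returns coefficients for classes 1..K-1 (reference K) and the observed
# information inverse (covariance)
fit_multinom <- function(X, y, w, ridge = 1e-6, max_iter = 100L) {
  K <- max(y); p <- ncol(X); n <- nrow(X)
  B <- matrix(0, K - 1, p)
  w <- w / mean(w)
  loglik <- function(B) {
    eta <- X %*% t(B)
    m <- pmax(apply(eta, 1, max), 0)
    lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
    lk <- ifelse(y < K, eta[cbind(seq_len(n), pmin(y, K - 1))], 0)
    sum(w * (lk - lse)) - ridge * sum(B^2) / 2
  }
  ll_old <- loglik(B)
  for (iter in seq_len(max_iter)) {
    eta <- X %*% t(B)
    m <- pmax(apply(eta, 1, max), 0)
    den <- exp(-m) + rowSums(exp(eta - m))
    P <- exp(eta - m) / den                      # n x (K-1)
    g <- numeric((K - 1) * p)
    H <- matrix(0, (K - 1) * p, (K - 1) * p)
    for (k in seq_len(K - 1)) {
      rk <- ((k - 1) * p + 1):(k * p)
      g[rk] <- crossprod(X, w * ((y == k) - P[, k])) - ridge * B[k, ]
      for (l in seq_len(K - 1)) {
        rl <- ((l - 1) * p + 1):(l * p)
        wkl <- w * P[, k] * ((k == l) - P[, l])
        H[rk, rl] <- -crossprod(X, X * wkl)
      }
    }
    H <- H - ridge * diag((K - 1) * p)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    step_m <- matrix(step, K - 1, p, byrow = TRUE)
    lambda <- 1
    repeat {
      Bn <- B - lambda * step_m
      ll <- loglik(Bn)
      if (is.finite(ll) && ll >= ll_old - 1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    B <- Bn
    if (abs(ll - ll_old) < 1e-10 * (abs(ll_old) + 1)) { ll_old <- ll; break }
    ll_old <- ll
  }
  if (max(abs(B)) > 50) return(NULL)  # (quasi-)complete separation
  vcov <- tryCatch(solve(-H), error = function(e) NULL)
  list(B = B, vcov = vcov)
}

#' ABC model choice
#'
#' Direct estimate: weighted scenario vote share among the accepted
#' simulations. Logistic estimate: weighted multinomial logistic regression
#' of the scenario indicator on the standardized (summary - observed)
#' differences over the accepted rows, evaluated at zero offset, with 95%
#' confidence intervals by the delta method on the softmax. On complete
#' separation or a singular fit the direct estimate is returned with a
#' warning.
#'
#' @param table a `scenabc_reftable`.
#' @param observed named summary vector.
#' @param delta accepted fraction.
#' @param rng_seed unused (the procedure is deterministic); kept for
#'   interface stability.
#' @return list of class `model_choice_result`: `scenarios`, `direct`,
#'   `logistic`, `ci_lower`, `ci_upper`, `delta`, `n_accepted`, `method`.
#' @export
model_choice <- function(table, observed, delta = 0.01, rng_seed = NULL) {
  scen_all <- sort(unique(table$scenario))
  if (length(scen_all) < 2) stop("need at least 2 scenarios in the table")
  rej <- standardize_and_reject(table, observed, delta)
  scen <- table$scenario[rej$index]
  w <- rej$weight
  direct <- vapply(scen_all, function(s) sum(w[scen == s]), numeric(1))
  direct <- direct / sum(direct)
  Z <- sweep(table$stats[rej$index, rej$keep, drop = FALSE], 2,
             rej$scale[rej$keep], "/")
  zobs <- observed[rej$keep] / rej$scale[rej$keep]
  Xs <- sweep(Z, 2, zobs, "-")
  y <- match(scen, scen_all)
  # project onto the k-1 linear discriminant axes before the logistic
  # regression (the standard preprocessing for ABC model choice): with
  # dozens of statistics and a few hundred accepted rows the raw-feature
  # regression overfits and yields overconfident posteriors
  ld <- lda_axes(Xs, y, length(scen_all))
  P <- Xs %*% ld
  # unit-variance features keep the coefficient scale interpretable, so
  # the separation guard in fit_multinom does not trip on healthy fits;
  # the zero offset (the observed point) is preserved by pure scaling
  psd <- apply(P, 2, stats::sd)
  psd[psd == 0] <- 1
  X <- cbind(1, sweep(P, 2, psd, "/"))
  fit <- if (length(unique(y)) == length(scen_all)) {
    fit_multinom(X, y, w)
  } else NULL
  K <- length(scen_all)
  if (is.null(fit)) {
    warning("logistic regression unstable (separation or singular fit); ",
            "falling back to the direct estimate")
    post <- direct
    ci_l <- ci_u <- rep(NA_real_, K)
    method <- "direct"
  } else {
    b0 <- fit$B[, 1]
    e <- c(exp(b0), 1)
    post <- e / sum(e)
    names(post) <- scen_all
    ci_l <- ci_u <- rep(NA_real_, K)
    if (!is.null(fit$vcov)) {
      p <- ncol(X)
      i0 <- seq(1, by = p, length.out = K - 1)  # intercept positions
      V0 <- fit$vcov[i0, i0, drop = FALSE]
      # dp_k/db0_l = p_k (1{k=l} - p_l), l = 1..K-1
      G <- matrix(0, K, K - 1)
      for (k in seq_len(K)) for (l in seq_len(K - 1)) {
        G[k, l] <- post[k] * ((k == l) - post[l])
      }
      se <- sqrt(pmax(diag(G %*% V0 %*% t(G)), 0))
      ci_l <- pmax(post - 1.96 * se, 0)
      ci_u <- pmin(post + 1.96 * se, 1)
    }
    method <- "logistic"
  }
  names(post) <- names(direct) <- scen_all
  structure(list(scenarios = scen_all, direct = direct, logistic = post,
                 ci_lower = stats::setNames(ci_l, scen_all),
                 ci_upper = stats::setNames(ci_u, scen_all),
                 delta = delta, n_accepted = length(rej$index),
                 method = method),
            class = "model_choice_result")
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat("ABC model choice (", x$method, ", ", x$n_accepted, " accepted)\n",
      sep = "")
  tab <- data.frame(direct = round(x$direct, 4),
                    logistic = round(x$logistic, 4),
                    ci95 = sprintf("[%.4f, %.4f]", x$ci_lower, x$ci_upper))
  print(tab)
  invisible(x)
}

#' Selected scenario of a model-choice result
#'
#' Highest logistic posterior; ties broken by the direct estimate, then by
#' scenario order.
#' @param result a `model_choice_result`.
#' @export
selected_scenario <- function(result) {
  o <- order(-result$logistic, -result$direct,
             seq_along(result$scenarios))
  result$scenarios[o[1]]
}

#' ABC local-linear parameter estimation
#'
#' Restricts the table to one scenario, accepts the delta fraction closest
#' to the observed vector, logit-transforms every parameter to its prior
#' range, adjusts by weighted local-linear regression on the standardized
#' (summary - observed) differences, back-transforms and summarizes.
#' Singular regressions fall back to a ridge solve (penalty 1e-6).
#'
#' @param table a `scenabc_reftable`.
#' @param observed named summary vector.
#' @param scenario scenario id to condition on.
#' @param delta accepted fraction (of the scenario's rows).
#' @param params parameters to estimate; default all.
#' @return list of class `parameter_posterior`: per parameter the adjusted
#'   sample, mean, median and quantiles (2.5/5/95/97.5%).
#' @export
estimate_parameters <- function(table, observed, scenario, delta = 0.01,
                                params = NULL) {
  sel <- table$scenario == scenario
  if (!any(sel)) stop("scenario not present in table: ", scenario)
  sub <- list(stats = table$stats[sel, , drop = FALSE],
              params = table$params[sel, , drop = FALSE])
  rej <- standardize_and_reject(sub$stats, observed, delta)
  if (length(rej$index) < 2) stop("too few accepted rows")
  Z <- sweep(sub$stats[rej$index, rej$keep, drop = FALSE], 2,
             rej$scale[rej$keep], "/")
  zobs <- observed[rej$keep] / rej$scale[rej$keep]
  X <- cbind(1, sweep(Z, 2, zobs, "-"))
  w <- rej$weight
  if (is.null(params)) params <- colnames(sub$params)
  out <- list()
  for (pm in params) {
    rg <- table$prior[[pm]]
    th <- sub$params[rej$index, pm]
    # logit to the prior range (guard the boundaries)
    eps <- 1e-10 * (rg[2] - rg[1])
    u <- pmin(pmax((th - rg[1]) / (rg[2] - rg[1]), eps), 1 - eps)
    yv <- log(u / (1 - u))
    XtW <- t(X * w)
    A <- XtW %*% X
    beta <- tryCatch(solve(A, XtW %*% yv), error = function(e) {
      solve(A + 1e-6 * diag(ncol(X)), XtW %*% yv)
    })
    adj <- yv - X[, -1, drop = FALSE] %*% beta[-1]
    uadj <- 1 / (1 + exp(-adj))
    th_adj <- rg[1] + uadj * (rg[2] - rg[1])
    qs <- weighted_quantile(th_adj, w, c(0.025, 0.05, 0.5, 0.95, 0.975))
    out[[pm]] <- list(sample = as.numeric(th_adj), weight = w,
                      prior_range = rg,
                      mean = sum(w * th_adj) / sum(w),
                      median = qs[3], q025 = qs[1], q050 = qs[2],
                      q950 = qs[4], q975 = qs[5])
  }
  structure(list(scenario = scenario, delta = delta,
                 n_accepted = length(rej$index), estimates = out),
            class = "parameter_posterior")
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' @export
print.parameter_posterior <- function(x, ...) {
  cat("ABC parameter posterior (", x$scenario, ", ", x$n_accepted,
      " accepted)\n", sep = "")
  tab <- t(vapply(x$estimates, function(e) {
    c(mean = e$mean, median = e$median, q050 = e$q050, q950 = e$q950)
  }, numeric(4)))
  print(round(tab, 4))
  invisible(x)
}

#' POD-based scenario-choice error rates
#'
#' Simulates `n_pods` pseudo-observed datasets under each scenario (or uses
#' supplied summary vectors), classifies each with [model_choice()] against
#' the reference table, and reports for the focal scenario the Type I error
#' (focal true but not selected) and Type II error (focal selected when
#' false), plus the full confusion matrix.
#'
#' @param table a `scenabc_reftable`.
#' @param scenarios list of scenarios matching the table (ignored when
#'   `pods` given).
#' @param config,n_msat,seq_length simulation layout (ignored when `pods`
#'   given).
#' @param n_pods PODs per scenario.
#' @param delta accepted fraction for each classification.
#' @param focal focal scenario id (default first).
#' @param rng_seed master seed.
#' @param pods optional pre-computed PODs: list(scenario = character,
#'   stats = matrix) for testing or reuse.
#' @return list of class `confusion_errors`: `type_I`, `type_II`,
#'   `confusion` (true x selected counts), `n_pods`, `n_failed`.
#' @export
pods_error_rates <- function(table, scenarios = NULL, config = NULL,
                             n_msat = 8L, seq_length = 751L,
                             n_pods = 100L, delta = 0.01, focal = NULL,
                             rng_seed = 1L, pods = NULL) {
  scen_all <- sort(unique(table$scenario))
  if (is.null(focal)) focal <- scen_all[1]
  if (is.null(pods)) {
    if (is.null(scenarios) || is.null(config)) {
      stop("either `pods` or (`scenarios`, `config`) must be supplied")
    }
    names(scenarios) <- vapply(scenarios, function(s) s$name, character(1))
    truth <- rep(scen_all, each = n_pods)
    stats_l <- vector("list", length(truth))
    for (i in seq_along(truth)) {
      sub <- derive_subseed(rng_seed, i, salt = 101L)
      stats_l[[i]] <- tryCatch({
        set.seed(sub)
        pars <- sample_priors(table$prior)
        ds <- simulate_dataset(scenarios[[truth[i]]], pars, config,
                               n_msat = n_msat, seq_length = seq_length)
        summary_vector(ds, table$groups)
      }, error = function(e) NULL)
    }
    ok <- !vapply(stats_l, is.null, logical(1))
    pods <- list(scenario = truth[ok], stats = do.call(rbind, stats_l[ok]))
    n_failed <- sum(!ok)
  } else n_failed <- 0L
  sel <- character(nrow(pods$stats))
  for (i in seq_len(nrow(pods$stats))) {
    mc <- suppressWarnings(model_choice(table, pods$stats[i, ], delta))
    sel[i] <- selected_scenario(mc)
  }
  confusion <- table(true = factor(pods$scenario, scen_all),
                     selected = factor(sel, scen_all))
  is_focal_true <- pods$scenario == focal
  type_I <- mean(sel[is_focal_true] != focal)
  type_II <- mean(sel[!is_focal_true] == focal)
  structure(list(type_I = type_I, type_II = type_II, confusion = confusion,
                 focal = focal, n_pods = sum(is_focal_true),
                 n_failed = n_failed),
            class = "confusion_errors")
}

#' @export
print.confusion_errors <- function(x, ...) {
  cat(sprintf("POD errors (focal %s): Type I = %.3f, Type II = %.3f\n",
              x$focal, x$type_I, x$type_II))
  print(x$confusion)
  invisible(x)
}

#' Posterior-predictive model checking
#'
#' Simulates `n_pp` summary vectors from posterior parameter draws, fits a
#' PCA on the standardized prior-simulated statistics, projects prior,
#' posterior-predictive and observed vectors, and reports per-statistic
#' two-sided tail probabilities of the observed value under the
#' posterior-predictive distribution.
#'
#' @param table a `scenabc_reftable` (prior simulations; PCA training set).
#' @param posterior a `parameter_posterior`.
#' @param observed named summary vector.
#' @param simulate_fn function(params, rng_seed) returning a summary
#'   vector; called once per posterior-predictive draw.
#' @param n_pp number of posterior-predictive simulations (>= 100 advised).
#' @param rng_seed master seed.
#' @return list of class `model_check_report`: `pca` (prcomp fit),
#'   `prior_proj`, `pp_proj`, `obs_proj`, `tail_prob`, `pp_stats`.
#' @export
model_check <- function(table, posterior, observed, simulate_fn,
                        n_pp = 500L, rng_seed = 1L) {
  if (n_pp < 100L) warning("n_pp < 100: unstable tail probabilities")
  est <- posterior$estimates
  sample_mat <- vapply(est, function(e) e$sample, numeric(length(est[[1]]$sample)))
  w <- est[[1]]$weight
  pp <- vector("list", n_pp)
  for (i in seq_len(n_pp)) {
    set.seed(derive_subseed(rng_seed, i, salt = 202L))
    j <- sample.int(nrow(sample_mat), 1L, prob = w)
    pars <- sample_mat[j, ]
    names(pars) <- colnames(sample_mat)
    pp[[i]] <- simulate_fn(pars, derive_subseed(rng_seed, i, salt = 203L))
  }
  pp_stats <- do.call(rbind, pp)
  sc <- apply(table$stats, 2, stats::mad)
  sc[sc == 0] <- apply(table$stats, 2, stats::sd)[sc == 0]
  keep <- sc > 0
  Z <- sweep(table$stats[, keep, drop = FALSE], 2, sc[keep], "/")
  pca <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  proj <- function(m) {
    zz <- sweep(m[, keep, drop = FALSE], 2, sc[keep], "/")
    stats::predict(pca, zz)
  }
  tail_prob <- vapply(seq_along(observed), function(j) {
    v <- pp_stats[, j]
    lo <- (sum(v <= observed[j]) + 1) / (length(v) + 1)
    hi <- (sum(v >= observed[j]) + 1) / (length(v) + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  names(tail_prob) <- names(observed)
  structure(list(pca = pca, prior_proj = stats::predict(pca, Z),
                 pp_proj = proj(pp_stats),
                 obs_proj = proj(matrix(observed, 1,
                                        dimnames = list(NULL, names(observed)))),
                 tail_prob = tail_prob, pp_stats = pp_stats),
            class = "model_check_report")
}
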