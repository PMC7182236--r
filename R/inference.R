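#' MCMC sampling plan and priors
#'
#' Defaults reproduce the reported analysis: Gaussian likelihood,
#' Normal(0, 3) priors on the cell means, half-Student-t(3, 0, 2) on the
#' participant and residual standard deviations, and 8 chains of 8,000
#' iterations with 4,000 warmup and thinning 2, retaining
#' `chains * (iterations - warmup) / thin = 16,000` draws per parameter.
#'
#' @param chains,iterations,warmup,thin Sampling plan.
#' @param prior_beta_sd SD of the normal prior on cell means.
#' @param prior_sd_scale,prior_sd_df Scale and df of the half-Student-t
#'   prior on standard deviations.
#' @return A list of class `fpvs_model_spec`.
#' @export
model_spec <- function(chains = 8, iterations = 8000, warmup = 4000,
                       thin = 2, prior_beta_sd = 3, prior_sd_scale = 2,
                       prior_sd_df = 3) {
  stopifnot(chains >= 1, warmup < iterations, thin >= 1)
  structure(list(chains = chains, iterations = iterations, warmup = warmup,
                 thin = thin, prior_beta_sd = prior_beta_sd,
                 prior_sd_scale = prior_sd_scale, prior_sd_df = prior_sd_df,
                 retained = chains * (iterations - warmup) %/% thin),
            class = "fpvs_model_spec")
}

jags_model_string <- function() {
  # participant effects use the multiplicative parameter expansion
  # b = xi * u: with xi ~ N(0, scale^2) and tau_u ~ Gamma(df/2, df/2)
  # the implied sd_b = |xi| / sqrt(tau_u) has exactly the half-Student-t
  # prior, and the Gibbs sampler mixes far better than the direct form
  "model {
    for (i in 1:N) {
      y[i] ~ dnorm(mu[cell[i]] + xi * u[subj[i]], tau)
    }
    for (c in 1:C) { mu[c] ~ dnorm(0, prec_beta) }
    for (s in 1:S) { u[s] ~ dnorm(0, tau_u) }
    xi ~ dnorm(0, prec_sd)
    tau_u ~ dgamma(df_sd / 2, df_sd / 2)
    sd_b <- abs(xi) / sqrt(tau_u)
    sigma ~ dt(0, prec_sd, df_sd) T(0,)
    tau <- pow(sigma, -2)
  }"
}

# cell label for a CS table row: the condition factors that are present
# and actually vary
cs_cells <- function(table) {
  fac <- intersect(c("orientation", "regularity", "variability"), names(table))
  fac <- fac[purrr::map_lgl(fac, ~ length(unique(table[[.x]])) > 1 ||
                              !all(table[[.x]] %in% "none"))]
  if (!length(fac)) abort("No condition factors found in the CS table.")
  do.call(paste, c(table[fac], sep = "."))
}

#' Fit the Bayesian multilevel model to a CS table
#'
#' Cell-means parameterization of the condition effects with
#' participant-varying intercepts, fitted by MCMC (JAGS) under the priors
#' and sampling plan of [model_spec()]. Convergence diagnostics
#' (split-chain R-hat, effective-sample ratio, Monte Carlo standard
#' error) are computed for every parameter; the fit is flagged (with a
#' warning) when any R-hat exceeds 1.05 or any effective-sample ratio
#' falls below 0.1.
#'
#' @param table A tibble with columns `participant`, `cs`, and the
#'   condition factors (`orientation`, `regularity`, optionally
#'   `variability`); one row per participant and cell.
#' @param spec A [model_spec()].
#' @param seed Optional integer seed (drives all chains).
#' @return An object of class `fpvs_fit`.
#' @export
fit_cs_model <- function(table, spec = model_spec(), seed = NULL) {
  stopifnot(all(c("participant", "cs") %in% names(table)))
  if (!all(is.finite(table$cs))) abort("CS values must be finite.")
  cell <- factor(cs_cells(table))
  subj <- factor(table$participant)
  if (nlevels(subj) < 2) abort("Need at least 2 participants.")
  counts <- table(subj, cell)
  if (any(counts == 0)) {
    abort("Design incomplete: every participant needs every cell.",
          class = "fpvs_design_error")
  }
  data <- list(y = table$cs, cell = as.integer(cell),
               subj = as.integer(subj), N = nrow(table),
               C = nlevels(cell), S = nlevels(subj),
               prec_beta = 1 / spec$prior_beta_sd^2,
               prec_sd = 1 / spec$prior_sd_scale^2,
               df_sd = spec$prior_sd_df)
  seeds <- child_seeds(if (is.null(seed)) 1L else seed, spec$chains)
  inits <- purrr::map(seq_len(spec$chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seeds[[i]]))
  })
  n_adapt <- min(1000L, spec$warmup)
  jm <- rjags::jags.model(textConnection(jags_model_string()), data = data,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (spec$warmup > n_adapt) update(jm, spec$warmup - n_adapt, progress.bar = "none")
  draws <- rjags::coda.samples(jm, c("mu", "sd_b", "sigma"),
                               n.iter = spec$iterations - spec$warmup,
                               thin = spec$thin, progress.bar = "none")
  pars <- coda::varnames(draws)
  labels <- pars
  labels[grep("^mu\\[", pars)] <- levels(cell)[
    as.integer(gsub("^mu\\[(\\d+)\\]$", "\\1", grep("^mu\\[", pars, value = TRUE)))]
  labels[pars == "sd_b"] <- "sd_participant"
  total <- spec$chains * niter_kept(draws)
  rhat <- tryCatch(
    coda::gelman.diag(draws, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, length(pars)))
  ess <- coda::effectiveSize(draws)
  mat <- as.matrix(draws)
  ess_v <- unname(ess[pars])
  sd_v <- unname(apply(mat, 2, sd)[pars])
  diag_tbl <- tibble(
    term = labels,
    rhat = unname(rhat[pars]),
    ess = ess_v,
    ess_ratio = ess_v / total,
    mcse = sd_v / sqrt(ess_v)
  )
  converged <- all(diag_tbl$rhat <= 1.05, na.rm = TRUE) &&
    all(diag_tbl$ess_ratio >= 0.1, na.rm = TRUE)
  if (!converged) {
    warn("Fit flagged: R-hat > 1.05 or effective-sample ratio < 0.1.")
  }
  colnames(mat) <- labels
  structure(list(draws = mat, mcmc = draws, cells = levels(cell),
                 diagnostics = diag_tbl, converged = converged,
                 spec = spec, data = table, n_retained = total),
            class = "fpvs_fit")
}

niter_kept <- function(draws) nrow(draws[[1]])

#' @export
print.fpvs_fit <- function(x, ...) {
  cat(sprintf("<fpvs_fit> %d cells, %d participants, %d retained draws%s\n",
              length(x$cells), length(unique(x$data$participant)),
              x$n_retained,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(tidy(x))
  invisible(x)
}

#' Narrowest highest-density interval
#'
#' The shortest window over the sorted draws containing a `prob` mass.
#'
#' @param x Numeric draws.
#' @param prob Interval mass (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.95) {
  s <- sort(x)
  n <- length(s)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(s[1], s[n]))
  width <- s[(k + 1):n] - s[1:(n - k)]
  i <- which.min(width)
  c(s[i], s[i + k])
}

#' Evidence ratio for a directional hypothesis
#'
#' The ratio of posterior draws on the hypothesised side of zero to
#' those on the other side. `Inf` when every draw supports the
#' hypothesis, 0 when none does.
#'
#' @param d Difference draws.
#' @param direction `"greater"` (d > 0), `"less"`, or `"auto"` (the side
#'   of the posterior mean).
#' @return A non-negative (possibly infinite) ratio.
#' @export
evidence_ratio <- function(d, direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  if (direction == "auto") direction <- if (mean(d) >= 0) "greater" else "less"
  p <- mean(d > 0); q <- mean(d < 0)
  num <- if (direction == "greater") p else q
  den <- if (direction == "greater") q else p
  if (den == 0) {
    if (num == 0) NaN else Inf
  } else num / den
}

#' Interpretive band of an evidence ratio
#'
#' `"inconclusive"` below 3, `"anecdotal"` in `[3, 10)`, `"strong"` from
#' 10, `"very strong"` when the posterior lies entirely on one side
#' (`ER = Inf`). Boundary values go to the higher band.
#'
#' @param er Evidence ratio(s), non-negative or infinite.
#' @return Character band(s).
#' @examples
#' classify_er(c(2.5, 25.02, Inf))
#' @export
classify_er <- function(er) {
  if (any(is.na(er)) || any(er < 0)) {
    abort("Evidence ratios must be non-negative.", class = "fpvs_domain_error")
  }
  dplyr::case_when(is.infinite(er) ~ "very strong",
                   er >= 10 ~ "strong",
                   er >= 3 ~ "anecdotal",
                   TRUE ~ "inconclusive")
}

#' Posterior contrast between two condition cells
#'
#' Difference draws `d = A - B` summarised by their mean, the 95%
#' highest-density interval, the evidence ratio for the stated direction
#' and its interpretive band. Contrasts between two irregular cells are
#' marked uninterpretable (the spatial filter can overfit noise in the
#' absence of a regularity response, so comparing two such fits is
#' meaningless).
#'
#' @param fit An `fpvs_fit`.
#' @param cell_a,cell_b Cell labels (see `fit$cells`).
#' @param direction Direction for the evidence ratio, as in
#'   [evidence_ratio()].
#' @param prob HDI mass.
#' @return One-row tibble: `contrast`, `mean`, `hdi_lower`, `hdi_upper`,
#'   `er`, `band`, `interpretable`.
#' @export
contrast <- function(fit, cell_a, cell_b, direction = "auto", prob = 0.95) {
  for (cl in c(cell_a, cell_b)) {
    if (!cl %in% fit$cells) {
      abort(paste0("Unknown cell '", cl, "'. Cells: ",
                   paste(fit$cells, collapse = ", ")))
    }
  }
  d <- fit$draws[, cell_a] - fit$draws[, cell_b]
  er <- evidence_ratio(d, direction)
  h <- hdi(d, prob)
  both_irregular <- grepl("irregular", cell_a) && grepl("irregular", cell_b)
  tibble(contrast = paste(cell_a, "vs.", cell_b),
         mean = mean(d), hdi_lower = h[1], hdi_upper = h[2],
         er = er, band = classify_er(er),
         interpretable = !both_irregular)
}

#' All pairwise cell contrasts
#'
#' @param fit An `fpvs_fit`.
#' @param direction,prob Passed to [contrast()].
#' @return A tibble with one row per unordered cell pair.
#' @export
contrast_all <- function(fit, direction = "auto", prob = 0.95) {
  pairs <- utils::combn(fit$cells, 2, simplify = FALSE)
  dplyr::bind_rows(purrr::map(pairs, ~ contrast(fit, .x[1], .x[2],
                                                direction, prob)))
}

#' @export
tidy.fpvs_fit <- function(x, conf.level = 0.95, ...) {
  dplyr::bind_cols(
    tibble(term = colnames(x$draws),
           estimate = colMeans(x$draws),
           std.error = apply(x$draws, 2, sd),
           conf.low = apply(x$draws, 2, function(d) hdi(d, conf.level)[1]),
           conf.high = apply(x$draws, 2, function(d) hdi(d, conf.level)[2])),
    x$diagnostics[match(colnames(x$draws), x$diagnostics$term),
                  c("rhat", "ess_ratio", "mcse")])
}

#' @export
glance.fpvs_fit <- function(x, ...) {
  tibble(nobs = nrow(x$data),
         n_participants = length(unique(x$data$participant)),
         n_cells = length(x$cells),
         chains = x$spec$chains,
         retained_draws = x$n_retained,
         max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
         min_ess_ratio = min(x$diagnostics$ess_ratio, na.rm = TRUE),
         converged = x$converged)
}

#' Write a condition-summary CS table (TSV)
#'
#' One row per experiment cell with the mean CS and a 95% interval
#' across participants.
#'
#' @param cs_table Tibble of per-participant CS values.
#' @param path Output path.
#' @return The summary tibble, invisibly written.
#' @export
write_cs_summary <- function(cs_table, path) {
  fac <- intersect(c("experiment", "variability", "orientation", "regularity",
                     "frequency"), names(cs_table))
  out <- dplyr::summarise(
    dplyr::group_by(cs_table, dplyr::across(dplyr::all_of(fac))),
    n = dplyr::n(), cs_mean = mean(.data$cs),
    ci_lower = mean(.data$cs) - 1.96 * sd(.data$cs) / sqrt(dplyr::n()),
    ci_upper = mean(.data$cs) + 1.96 * sd(.data$cs) / sqrt(dplyr::n()),
    .groups = "drop")
  readr::write_tsv(out, path)
  invisible(out)
}

#' Write a contrast table (TSV)
#'
#' @param contrasts Tibble from [contrast()] / [contrast_all()].
#' @param path Output path.
#' @return The contrasts, invisibly.
#' @export
write_contrast_table <- function(contrasts, path) {
  readr::write_tsv(contrasts, path)
  invisible(contrasts)
}

#' Write model diagnostics as JSON
#'
#' @param fit An `fpvs_fit`.
#' @param path Output path.
#' @return The fit, invisibly.
#' @export
write_diagnostics <- function(fit, path) {
  jsonlite::write_json(list(converged = fit$converged,
                            retained_draws = fit$n_retained,
                            parameters = fit$diagnostics),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
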