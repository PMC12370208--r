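#' Sampling ranges for initial guesses and optimizer bounds
#'
#' Per-parameter `(low, high)` boxes used both to draw log-uniform initial
#' guesses and as the optimizer's box constraints. Defaults span the
#' literature-scale ranges for protein synthesis, transport and degradation:
#' `alpha` in (1e3, 1e7) #/cell/h, `beta`, `gamma`, `delta`, `epsilon`,
#' `kappa` in (1e-3, 10) 1/h, and `tau` in (0.25, 4) h.
#'
#' @param ... Named length-2 numeric vectors overriding defaults, e.g.
#'   `sampling_ranges(delta = c(0.01, 1))`.
#' @return A tibble with columns `parameter`, `low`, `high`.
#' @export
sampling_ranges <- function(...) {
  defaults <- list(alpha = c(1e3, 1e7), beta = c(1e-3, 10),
                   gamma = c(1e-3, 10), delta = c(1e-3, 10),
                   tau = c(0.25, 4), epsilon = c(1e-3, 10),
                   kappa = c(1e-3, 10))
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  defaults[names(overrides)] <- overrides
  out <- tibble::tibble(parameter = names(defaults),
                        low = vapply(defaults, `[`, numeric(1), 1),
                        high = vapply(defaults, `[`, numeric(1), 2))
  if (any(out$low <= 0) || any(out$high <= out$low)) {
    stop("ranges must satisfy 0 < low < high", call. = FALSE)
  }
  out
}

free_param_names <- function(config) {
  c("alpha", "beta", "gamma", "delta",
    if (config$include_delay) "tau",
    if (config$include_internalization) "epsilon",
    if (config$include_production_decay) "kappa")
}

params_from_free <- function(free, config) {
  full <- c(alpha = 0, beta = 0, gamma = 0, delta = 0, tau = 0,
            epsilon = 0, kappa = 0)
  full[names(free)] <- free
  do.call(sflt_params, as.list(full))
}

#' Draw log-uniform initial parameter guesses
#'
#' Independent log-uniform draws per free parameter of the model structure,
#' within the sampling ranges; reproducible under a fixed seed.
#'
#' @param config A [model_config()] (decides which parameters are free).
#' @param ranges A [sampling_ranges()] tibble.
#' @param n Number of guesses.
#' @param seed Integer seed.
#' @return A tibble with `n` rows and one column per free parameter.
#' @export
sample_initial_guesses <- function(config, ranges = sampling_ranges(), n = 100,
                                   seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  free <- free_param_names(config)
  rg <- ranges[match(free, ranges$parameter), ]
  if (anyNA(rg$parameter)) {
    stop("ranges must cover parameters: ", paste(free, collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(seed, {
    draws <- purrr::map2(rg$low, rg$high, function(lo, hi) {
      10 ^ stats::runif(n, log10(lo), log10(hi))
    })
    names(draws) <- free
    tibble::as_tibble(draws)
  })
}

# simulate every scenario a collection needs, once, and return residuals
# over retained points (prediction - observation, or relative variant)
cost_residuals <- function(config, p, data, units, settings,
                           relative_residuals = FALSE) {
  settings <- resolve_settings(settings, p)
  sims <- list()
  if (any(data$scenario == "constitutive")) {
    sub <- data[data$scenario == "constitutive", ]
    dur <- max(sub$time_h, sub$normalization_ref_time, na.rm = TRUE)
    raw <- constitutive_raw(config, p, p, dur, settings)
    sims$constitutive <- list(time_h = raw$times, I = pmax(raw$I, 0),
                              X = pmax(raw$X, 0))
  }
  if (any(data$scenario == "pulse_chase")) {
    sub <- data[data$scenario == "pulse_chase", ]
    chase_h <- max(10, sub$time_h, sub$normalization_ref_time, na.rm = TRUE)
    raw <- pulse_chase_raw(config, p, settings, chase_h = chase_h)
    sims$pulse_chase <- list(time_h = raw$times, I = pmax(raw$I, 0),
                             X = pmax(raw$X, 0))
  }
  kept <- data[!data$omit_flag, ]
  groups <- split(kept, interaction(kept$study_id, kept$scenario,
                                    kept$species, drop = TRUE))
  res <- purrr::map(groups, function(ds) {
    pred <- predict_on_dataset(sims[[ds$scenario[1]]], ds, units)$predicted
    if (relative_residuals) {
      # zero-valued observations cannot be divided through; floor the
      # denominator at a small fraction of the dataset's scale
      denom <- pmax(abs(ds$value), 1e-8 * max(abs(ds$value), 1))
      (pred - ds$value) / denom
    } else {
      pred - ds$value
    }
  })
  unlist(res, use.names = FALSE)
}

#' Sum-of-squares cost of a parameter set against a dataset collection
#'
#' Simulates each scenario the collection requires once, maps predictions
#' onto every dataset's observation scale via [predict_on_dataset()], and
#' returns the unweighted sum of squared residuals over all retained points.
#' With `relative_residuals = TRUE` the residuals are divided by the
#' observed values first (an alternative weighting kept for comparison; the
#' default plain squared differences is the operational definition used for
#' scoring).
#'
#' @param config A [model_config()].
#' @param p An [sflt_params()] set.
#' @param data An [sflt_data()] collection.
#' @param units A [unit_map()].
#' @param settings Optional [solver_settings()].
#' @param relative_residuals Use relative instead of absolute residuals.
#' @return The scalar cost.
#' @export
sflt_cost <- function(config, p, data, units = unit_map(), settings = NULL,
                      relative_residuals = FALSE) {
  stopifnot(inherits(config, "sflt_config"), inherits(p, "sflt_params"))
  if (nrow(data) == 0) stop("dataset collection is empty", call. = FALSE)
  sum(cost_residuals(config, p, data, units, settings,
                     relative_residuals) ^ 2)
}

#' Fit a candidate model to a dataset collection
#'
#' Box-constrained nonlinear least squares (Levenberg-Marquardt via
#' \code{minpack.lm::nls.lm}) on the log10-transformed free parameters of
#' the model structure; the log scale conditions the search across the
#' orders-of-magnitude parameter ranges and keeps all rates positive.
#' Simulation failures during the search contribute a large finite residual
#' (1e6 per point) instead of raising, so a multistart batch always runs to
#' completion.
#'
#' @inheritParams sflt_cost
#' @param guess Initial [sflt_params()] (or named vector of free
#'   parameters) within the bounds.
#' @param ranges A [sampling_ranges()] tibble providing box constraints.
#' @param max_iter Optimizer iteration cap.
#' @return An `sflt_fit` object: list with the model `config`, `start` and
#'   optimized `params`, `cost`, `converged`, `n_obs`, optimizer `info` and
#'   `message`.
#' @export
sflt_fit <- function(config, data, units = unit_map(), guess,
                     ranges = sampling_ranges(), settings = NULL,
                     relative_residuals = FALSE, max_iter = 100) {
  stopifnot(inherits(config, "sflt_config"))
  free <- free_param_names(config)
  g <- if (inherits(guess, "sflt_params")) unlist(guess)[free]
       else unlist(guess)[free]
  if (anyNA(g)) stop("guess must supply parameters: ",
                     paste(free, collapse = ", "), call. = FALSE)
  rg <- ranges[match(free, ranges$parameter), ]
  if (any(g < rg$low - 1e-12) || any(g > rg$high + 1e-12)) {
    stop("initial guess outside the sampling ranges", call. = FALSE)
  }
  n_obs <- n_observations(data)
  fail_res <- rep(1e6, n_obs)
  resid_fn <- function(logp) {
    p <- params_from_free(stats::setNames(10 ^ logp, free), config)
    tryCatch(
      cost_residuals(config, p, data, units, settings, relative_residuals),
      error = function(e) fail_res)
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = log10(g), lower = log10(rg$low), upper = log10(rg$high),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         maxfev = 100 * (length(g) + 2))))
  opt <- params_from_free(stats::setNames(10 ^ fit$par, free), config)
  cost <- sum(fit$fvec ^ 2)
  converged <- fit$info %in% 1:4 && is.finite(cost) &&
    !identical(unname(fit$fvec), unname(fail_res))
  structure(list(config = config,
                 start = params_from_free(stats::setNames(g, free), config),
                 params = opt, cost = cost, converged = converged,
                 n_obs = n_obs, info = fit$info, message = fit$message,
                 n_iter = fit$niter),
            class = "sflt_fit")
}

#' @export
print.sflt_fit <- function(x, ...) {
  cat("<sflt_fit> ", x$config$label, ": cost ", signif(x$cost, 5),
      if (x$converged) " (converged)\n" else " (not converged)\n", sep = "")
  print(unlist(x$params))
  invisible(x)
}

#' Tidy/glance methods for fitted models
#'
#' `tidy()` returns one row per free parameter with start and optimized
#' values; `glance()` returns a one-row model summary including the AICc.
#'
#' @param x An `sflt_fit`.
#' @param ... Unused.
#' @method tidy sflt_fit
#' @export
tidy.sflt_fit <- function(x, ...) {
  free <- free_param_names(x$config)
  tibble::tibble(parameter = free,
                 start = unlist(x$start)[free],
                 estimate = unlist(x$params)[free])
}

#' @rdname tidy.sflt_fit
#' @method glance sflt_fit
#' @export
glance.sflt_fit <- function(x, ...) {
  k <- x$config$k_params + 1L
  tibble::tibble(model = x$config$label, cost = x$cost,
                 converged = x$converged, n_obs = x$n_obs, k = k,
                 AICc = if (x$cost > 0 && x$n_obs - k - 1 > 0)
                   aicc(x$cost, x$n_obs, k) else NA_real_,
                 n_iter = x$n_iter)
}

#' Multistart calibration of one candidate model
#'
#' Draws `n_starts` log-uniform initial guesses and fits each; one tibble
#' row per run with the initial and optimized parameters, cost and
#' convergence flag. Deterministic under a fixed seed; ties in downstream
#' best-fit selection break by earliest run.
#'
#' @inheritParams sflt_fit
#' @param n_starts Number of starts.
#' @param seed Seed for guess sampling.
#' @return A tibble of class `sflt_fits` with attributes `config` and
#'   `n_obs`.
#' @export
multistart_fit <- function(config, data, units = unit_map(), n_starts = 100,
                           seed = 1L, ranges = sampling_ranges(),
                           settings = NULL, relative_residuals = FALSE,
                           max_iter = 100) {
  guesses <- sample_initial_guesses(config, ranges, n_starts, seed)
  rows <- purrr::map(seq_len(n_starts), function(i) {
    f <- sflt_fit(config, data, units, guess = unlist(guesses[i, ]),
                  ranges = ranges, settings = settings,
                  relative_residuals = relative_residuals,
                  max_iter = max_iter)
    init <- f$start
    opt <- f$params
    tibble::tibble(model = config$label, run = i,
                   init_alpha = init$alpha, init_beta = init$beta,
                   init_gamma = init$gamma, init_delta = init$delta,
                   init_tau = init$tau, init_epsilon = init$epsilon,
                   init_kappa = init$kappa,
                   alpha = opt$alpha, beta = opt$beta,
                   gamma = opt$gamma, delta = opt$delta,
                   tau = opt$tau, epsilon = opt$epsilon,
                   kappa = opt$kappa,
                   cost = f$cost, converged = f$converged)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sflt_fits", class(out))
  attr(out, "config") <- config
  attr(out, "n_obs") <- n_observations(data)
  out
}

#' Filter a multistart ensemble by cost
#'
#' Retains converged runs whose cost is within `tolerance` of the minimum
#' cost (cost <= (1 + tolerance) * min), preserving run order.
#'
#' @param fits An `sflt_fits` tibble.
#' @param tolerance Fraction above the minimum cost (default 10%).
#' @return The retained subset (same class and attributes).
#' @export
filter_fits <- function(fits, tolerance = 0.10) {
  conv <- fits[fits$converged & is.finite(fits$cost), ]
  if (nrow(conv) == 0) {
    stop("empty ensemble: no converged fits to filter", call. = FALSE)
  }
  out <- conv[conv$cost <= (1 + tolerance) * min(conv$cost), ]
  attr(out, "config") <- attr(fits, "config")
  attr(out, "n_obs") <- attr(fits, "n_obs")
  out
}

#' Corrected Akaike Information Criterion
#'
#' `AICc = n log(C / n) + 2k + 2k(k + 1) / (n - k - 1)` with the natural
#' logarithm, where `C` is the least-squares cost, `n` the number of
#' retained observations, and `k` the degrees of freedom (free parameter
#' count + 1, the extra one for the assumed-constant residual variance).
#' The last term corrects for small samples (`n/k < 40`).
#'
#' @param cost Positive least-squares cost.
#' @param n_obs Number of observations.
#' @param k Degrees of freedom.
#' @return The AICc score.
#' @examples
#' aicc(26, 26, 6)
#' @export
aicc <- function(cost, n_obs, k) {
  if (cost <= 0) stop("AICc undefined for cost <= 0", call. = FALSE)
  if (n_obs - k - 1 <= 0) {
    stop("AICc correction undefined: need n_obs - k - 1 > 0", call. = FALSE)
  }
  n_obs * log(cost / n_obs) + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Score the candidate model family by AICc
#'
#' Runs a multistart calibration for each candidate structure, takes each
#' model's minimum converged cost, and scores it with that model's degrees
#' of freedom. Models with no converged fit are flagged and left unranked.
#'
#' @inheritParams multistart_fit
#' @param models Labels of the candidates to score (default all eight).
#' @return A tibble sorted by AICc: `model`, `k`, `min_cost`, `AICc`,
#'   `n_converged`, `n_starts`.
#' @export
score_model_family <- function(data, units = unit_map(), n_starts = 100,
                               seed = 1L, ranges = sampling_ranges(),
                               settings = NULL, models = paste0("M", 1:8),
                               relative_residuals = FALSE, max_iter = 100) {
  n_obs <- n_observations(data)
  rows <- purrr::map(models, function(label) {
    config <- model_config(label)
    fits <- multistart_fit(config, data, units, n_starts = n_starts,
                           seed = seed, ranges = ranges, settings = settings,
                           relative_residuals = relative_residuals,
                           max_iter = max_iter)
    conv <- fits[fits$converged & is.finite(fits$cost), ]
    k <- config$k_params + 1L
    if (nrow(conv) == 0) {
      tibble::tibble(model = label, k = k, min_cost = NA_real_,
                     AICc = NA_real_, n_converged = 0L, n_starts = n_starts)
    } else {
      mc <- min(conv$cost)
      tibble::tibble(model = label, k = k, min_cost = mc,
                     AICc = aicc(mc, n_obs, k), n_converged = nrow(conv),
                     n_starts = n_starts)
    }
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$AICc)
}

#' Serialize a fit ensemble to delimited text
#'
#' One row per optimization run (model, run index, initial and optimized
#' parameters, cost, convergence flag), tab-separated.
#'
#' @param fits An `sflt_fits` tibble.
#' @param path File path.
#' @export
write_fits <- function(fits, path) {
  readr::write_tsv(fits, path)
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  class(out) <- c("sflt_fits", class(out))
  out
}
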