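#' Kinetic parameter set for the sFLT1 secretion models
#'
#' Bundles the kinetic constants of one model instance. All rates are in
#' hours and molecules per cell: `alpha` is the zeroth-order production rate
#' (#/cell/h), `beta` the first-order secretion rate constant (1/h), `gamma`
#' the intracellular degradation rate constant (1/h), `delta` the
#' extracellular degradation rate constant (1/h), `tau` the maturation delay
#' (h) between synthesis and eligibility for secretion or degradation,
#' `epsilon` the internalization rate constant (1/h) and `kappa` the
#' production decay rate constant (1/h) acting during the chase phase of a
#' pulse-chase experiment. Absent processes are encoded as exact zeros of
#' `tau`, `epsilon` or `kappa` rather than structurally different equations.
#'
#' @param alpha,beta,gamma,delta Core rate constants (non-negative).
#' @param tau Maturation delay in hours; 0 when the model has no delay.
#' @param epsilon Internalization rate constant; 0 when absent.
#' @param kappa Production decay rate constant; 0 when absent.
#' @return An object of class `sflt_params` (a named list).
#' @examples
#' p <- sflt_params(alpha = 1e4, beta = 0.1, gamma = 0.1, delta = 0.1)
#' steady_state(p)
#' @export
sflt_params <- function(alpha, beta, gamma, delta, tau = 0, epsilon = 0,
                        kappa = 0) {
  p <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
            tau = tau, epsilon = epsilon, kappa = kappa)
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    stop("all kinetic parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("kinetic parameters must be non-negative; got ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  }
  structure(p, class = "sflt_params")
}

#' @export
print.sflt_params <- function(x, ...) {
  cat("<sflt_params>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
as.data.frame.sflt_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

#' Tidy a parameter set into a long tibble
#' @param x An `sflt_params` object.
#' @param ... Unused.
#' @method tidy sflt_params
#' @export
tidy.sflt_params <- function(x, ...) {
  tibble::tibble(parameter = names(unclass(x)),
                 value = unname(unlist(x)))
}

param_names <- function() {
  c("alpha", "beta", "gamma", "delta", "tau", "epsilon", "kappa")
}

#' Candidate model configuration
#'
#' The candidate family crosses three optional processes — maturation delay
#' (`tau`), internalization of extracellular protein (`epsilon`) and decay of
#' labeled production during the chase (`kappa`) — giving eight structures
#' M1..M8. M1 has all three absent (the plain ODE model) and M2 has the
#' maturation delay only (the base DDE model). Parameter count is 4 core
#' rates plus one per included process.
#'
#' @param label One of `"M1"`..`"M8"`, or `NULL` to build from flags.
#' @param include_delay,include_internalization,include_production_decay
#'   Logical flags; ignored when `label` is given.
#' @return An object of class `sflt_config`.
#' @examples
#' model_config("M2")
#' model_family()
#' @export
model_config <- function(label = NULL, include_delay = FALSE,
                         include_internalization = FALSE,
                         include_production_decay = FALSE) {
  fam <- model_family()
  if (!is.null(label)) {
    row <- fam[fam$label == label, ]
    if (nrow(row) != 1) {
      stop("unknown model label: ", label, call. = FALSE)
    }
    include_delay <- row$include_delay
    include_internalization <- row$include_internalization
    include_production_decay <- row$include_production_decay
  } else {
    row <- fam[fam$include_delay == include_delay &
               fam$include_internalization == include_internalization &
               fam$include_production_decay == include_production_decay, ]
    label <- row$label
  }
  structure(list(label = label,
                 include_delay = include_delay,
                 include_internalization = include_internalization,
                 include_production_decay = include_production_decay,
                 k_params = 4L + include_delay + include_internalization +
                   include_production_decay),
            class = "sflt_config")
}

#' @export
print.sflt_config <- function(x, ...) {
  proc <- c(if (x$include_delay) "maturation delay (tau)",
            if (x$include_internalization) "internalization (epsilon)",
            if (x$include_production_decay) "production decay (kappa)")
  cat("<sflt_config> ", x$label, ": ",
      if (length(proc)) paste(proc, collapse = ", ") else "core processes only",
      " [", x$k_params, " parameters]\n", sep = "")
  invisible(x)
}

#' Enumerate the eight candidate model structures
#'
#' @return A tibble with one row per candidate model: `label`, the three
#'   inclusion flags, and the free-parameter count `k_params`.
#' @export
model_family <- function() {
  tibble::tibble(
    label = paste0("M", 1:8),
    include_delay            = c(FALSE, TRUE,  FALSE, FALSE, TRUE,  TRUE,  FALSE, TRUE),
    include_internalization  = c(FALSE, FALSE, FALSE, TRUE,  FALSE, TRUE,  TRUE,  TRUE),
    include_production_decay = c(FALSE, FALSE, TRUE,  FALSE, TRUE,  FALSE, TRUE,  TRUE)
  ) |>
    dplyr::mutate(k_params = 4L + .data$include_delay +
                    .data$include_internalization + .data$include_production_decay)
}

# check that zero-valued optional parameters match the config flags
check_params_config <- function(p, config) {
  if (!config$include_delay && p$tau != 0)
    stop("model ", config$label, " excludes the maturation delay but tau != 0",
         call. = FALSE)
  if (!config$include_internalization && p$epsilon != 0)
    stop("model ", config$label, " excludes internalization but epsilon != 0",
         call. = FALSE)
  if (!config$include_production_decay && p$kappa != 0)
    stop("model ", config$label, " excludes production decay but kappa != 0",
         call. = FALSE)
  invisible(TRUE)
}

#' Closed-form steady state of the secretion model
#'
#' At steady state the intracellular pool is `I_ss = alpha / (beta + gamma)`
#' and the extracellular pool is `X_ss = (beta / delta) * I_ss`. Because
#' `I(t - tau) = I(t)` at steady state, the delay model shares these values
#' with the ODE model.
#'
#' @param p An [sflt_params()] set with `beta + gamma > 0` and `delta > 0`.
#' @return A tibble with columns `I_ss` and `X_ss` (#/cell).
#' @examples
#' steady_state(sflt_params(1e4, 0.1, 0.1, 0.1))
#' @export
steady_state <- function(p) {
  stopifnot(inherits(p, "sflt_params"))
  if (p$beta + p$gamma <= 0 || p$delta <= 0) {
    stop("no steady state: requires beta + gamma > 0 and delta > 0",
         call. = FALSE)
  }
  I_ss <- p$alpha / (p$beta + p$gamma)
  tibble::tibble(I_ss = I_ss, X_ss = (p$beta / p$delta) * I_ss)
}

#' Characteristic times to half-maximal concentration
#'
#' With first-order clearance the intracellular pool approaches steady state
#' with half-time `ln(2) / (beta + gamma)` and the extracellular pool with
#' half-time `ln(2) / delta`.
#'
#' @inheritParams steady_state
#' @return A tibble with columns `T50_I` and `T50_X` (hours).
#' @export
characteristic_times <- function(p) {
  stopifnot(inherits(p, "sflt_params"))
  if (p$beta + p$gamma <= 0 || p$delta <= 0) {
    stop("no steady state: requires beta + gamma > 0 and delta > 0",
         call. = FALSE)
  }
  tibble::tibble(T50_I = log(2) / (p$beta + p$gamma),
                 T50_X = log(2) / p$delta)
}

#' Compound constants c1 = alpha * beta and c2 = beta + gamma
#'
#' Temporal secretion data pin down the product `c1 = alpha * beta` and the
#' sum `c2 = beta + gamma` even when `alpha`, `beta` and `gamma` are
#' individually unidentifiable; together with `delta` and `tau` they leave
#' the model a single degree of freedom.
#'
#' @inheritParams steady_state
#' @return A tibble with columns `c1` (#/cell/h^2) and `c2` (1/h).
#' @export
compound_constants <- function(p) {
  stopifnot(inherits(p, "sflt_params"))
  tibble::tibble(c1 = p$alpha * p$beta, c2 = p$beta + p$gamma)
}

#' Reconstruct a parameter set from the compound constants and a chosen beta
#'
#' Inverts [compound_constants()] along the model's one remaining degree of
#' freedom: given `c1`, `c2` and a secretion rate constant
#' `0 < beta <= c2`, sets `alpha = c1 / beta` and `gamma = c2 - beta`;
#' `delta` and `tau` are supplied from a reference set.
#'
#' @param c1,c2 Compound constants (both > 0).
#' @param beta Secretion rate constant, in `(0, c2]`.
#' @param delta,tau Reference values for the remaining parameters.
#' @return An [sflt_params()] set satisfying both constraints exactly.
#' @export
parameters_from_beta <- function(c1, c2, beta, delta, tau = 0) {
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive", call. = FALSE)
  if (beta <= 0) stop("infeasible: beta = 0 leaves alpha undefined",
                      call. = FALSE)
  if (beta > c2) stop("infeasible: beta > c2 implies negative gamma",
                      call. = FALSE)
  sflt_params(alpha = c1 / beta, beta = beta, gamma = c2 - beta,
              delta = delta, tau = tau)
}

#' Median calibrated parameter set for the delay model
#'
#' The median of the filtered multistart calibration of the maturation-delay
#' model (M2) to the compiled HUVEC secretion time courses; used as the
#' baseline for sensitivity and inhibition analyses and as the ground truth
#' of the synthetic study generator.
#'
#' @return An [sflt_params()] set.
#' @export
sflt_median_params <- function() {
  sflt_params(alpha = 1.419e5, beta = 5.123e-2, gamma = 1.215e-1,
              delta = 5.743e-2, tau = 1.958)
}

#' Write or read a parameter set as a flat key-value file
#'
#' Plain-text serialization, one `key = value` pair per line, with keys
#' `alpha`, `beta`, `gamma`, `delta`, `tau`, `epsilon`, `kappa` and
#' optionally `model_label`.
#'
#' @param p An [sflt_params()] set.
#' @param path File path.
#' @param config Optional [model_config()] whose label is stored alongside.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a list with elements `params` and (possibly `NULL`) `config`.
#' @export
write_params <- function(p, path, config = NULL) {
  stopifnot(inherits(p, "sflt_params"))
  lines <- sprintf("%s = %.17g", param_names(), unlist(p)[param_names()])
  if (!is.null(config)) lines <- c(lines, sprintf("model_label = %s", config$label))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(x[2]), character(1))
  config <- NULL
  if ("model_label" %in% keys) {
    config <- model_config(vals[keys == "model_label"])
    vals <- vals[keys != "model_label"]
    keys <- keys[keys != "model_label"]
  }
  num <- as.numeric(vals)
  names(num) <- keys
  missing <- setdiff(param_names(), keys)
  if (length(missing)) {
    stop("parameter file missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  list(params = do.call(sflt_params, as.list(num[param_names()])),
       config = config)
}
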