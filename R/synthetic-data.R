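# Synthetic inputs with known ground truth for every pipeline stage:
# drug-like Abraham descriptor sets, log Pe datasets generated from a
# known coefficient vector plus Gaussian noise, and forward-simulated
# PAMPA plate reads.  All generators are pure functions of their
# configuration (the seed is part of the config).

# run code under a transient RNG state so generators are pure
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.default_ranges <- list(E = c(0, 2), S = c(0, 2.5), A = c(0, 1.5),
                        B = c(0, 2), V = c(0.5, 2.5))

#' Configuration for the synthetic-data generators
#'
#' @param seed integer RNG seed; the same config always yields the same
#'   output.
#' @param n_compounds number of solutes to generate.
#' @param descriptor_ranges named list of `c(min, max)` per descriptor;
#'   defaults span drug-like Abraham space
#'   (E in 0-2, S in 0-2.5, A in 0-1.5, B in 0-2, V in 0.5-2.5).
#' @param noise_sd Gaussian residual SD on generated log Pe (log units).
#' @param true_coefficients one-row system data frame (with intercept)
#'   used as ground truth; defaults to the skin-PAMPA certramide
#'   equation.
#' @param geometry a [pampa_geometry()].
#' @param retention_range `c(min, max)` for simulated membrane
#'   retention.
#' @param ionizable_fraction fraction of compounds assigned a pKa (to
#'   exercise the neutral-species filter); pKa ~ U(3, 11), acid/base
#'   assigned with equal probability, measurement pH 7.4.
#' @param concentration_cv coefficient of variation of multiplicative
#'   log-normal noise applied to simulated concentrations (0 = exact).
#' @param descriptor_correlation optional 5x5 positive-definite
#'   correlation matrix; when supplied, descriptors are drawn from a
#'   Gaussian copula with this correlation before scaling to the
#'   ranges.  Default `NULL` (independent draws).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_compounds = 45L,
                             descriptor_ranges = .default_ranges,
                             noise_sd = 0.15,
                             true_coefficients = certramide_truth(),
                             geometry = pampa_geometry(),
                             retention_range = c(0, 0.4),
                             ionizable_fraction = 0,
                             concentration_cv = 0,
                             descriptor_correlation = NULL) {
  for (nm in c("E", "S", "A", "B", "V")) {
    r <- descriptor_ranges[[nm]]
    if (is.null(r) || length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
      stop("degenerate range for descriptor '", nm, "'", call. = FALSE)
    }
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_compounds < 0) stop("n_compounds must be >= 0", call. = FALSE)
  if (retention_range[1] < 0 || retention_range[2] >= 1 ||
      retention_range[1] > retention_range[2]) {
    stop("retention_range must lie within [0, 1)", call. = FALSE)
  }
  if (ionizable_fraction < 0 || ionizable_fraction > 1) {
    stop("ionizable_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(descriptor_correlation)) {
    stopifnot(is.matrix(descriptor_correlation),
              all(dim(descriptor_correlation) == 5L))
    if (any(eigen(descriptor_correlation, symmetric = TRUE,
                  only.values = TRUE)$values <= 0)) {
      stop("descriptor_correlation must be positive definite", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
                 descriptor_ranges = descriptor_ranges, noise_sd = noise_sd,
                 true_coefficients = validate_systems(true_coefficients,
                                                      require_intercept = TRUE),
                 geometry = geometry, retention_range = retention_range,
                 ionizable_fraction = ionizable_fraction,
                 concentration_cv = concentration_cv,
                 descriptor_correlation = descriptor_correlation),
            class = "generator_config")
}

#' Ground-truth coefficients of the skin-PAMPA certramide system
#'
#' Convenience default for simulations: the certramide-membrane
#' equation (intercept included).
#'
#' @return One-row system data frame.
#' @export
certramide_truth <- function() {
  system_coefficients("truth", c = -4.181, e = 0.064, s = -0.594,
                      a = -1.038, b = -2.269, v = 1.730)
}

#' Generate drug-like Abraham descriptor sets
#'
#' Uniform draws within the configured ranges (independent by default;
#' through a Gaussian copula when `descriptor_correlation` is set).
#'
#' @param cfg a [generator_config()].
#' @return Data frame with columns `E, S, A, B, V`.
#' @export
generate_descriptors <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_compounds
  nms <- c("E", "S", "A", "B", "V")
  with_seed(cfg$seed, {
    if (n == 0L) {
      u <- matrix(numeric(0), nrow = 0, ncol = 5)
    } else if (is.null(cfg$descriptor_correlation)) {
      u <- matrix(stats::runif(n * 5), ncol = 5)
    } else {
      z <- matrix(stats::rnorm(n * 5), ncol = 5) %*%
        chol(cfg$descriptor_correlation)
      u <- stats::pnorm(z)
    }
    colnames(u) <- nms
    out <- as.data.frame(u)
    for (nm in nms) {
      r <- cfg$descriptor_ranges[[nm]]
      out[[nm]] <- r[1] + (r[2] - r[1]) * out[[nm]]
    }
    out
  })
}

#' Generate a solute dataset from a known coefficient vector
#'
#' Descriptors are drawn as in [generate_descriptors()]; log Pe is the
#' solvation-parameter prediction of the configured true coefficients
#' plus Gaussian noise of SD `noise_sd`.  A configured fraction of
#' compounds receives a pKa (uniform in 3-11, acid or base with equal
#' probability) at measurement pH 7.4, to exercise the ionization
#' filter.
#'
#' @param cfg a [generator_config()].
#' @return Data frame with columns
#'   `name, E, S, A, B, V, log_pe, pKa, acid_base, pH` plus the
#'   noise-free `log_pe_true`.
#' @export
generate_lfer_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  d <- generate_descriptors(cfg)
  n <- nrow(d)
  truth <- cfg$true_coefficients
  log_pe_true <- if (n > 0) predict_log_sp(truth, d) else numeric(0)
  with_seed(cfg$seed + 1L, {
    noise <- stats::rnorm(n, 0, cfg$noise_sd)
    pKa <- rep(NA_real_, n)
    acid_base <- rep(NA_character_, n)
    if (cfg$ionizable_fraction > 0 && n > 0) {
      n_ion <- round(cfg$ionizable_fraction * n)
      idx <- sample.int(n, n_ion)
      pKa[idx] <- stats::runif(n_ion, 3, 11)
      acid_base[idx] <- sample(c("acid", "base"), n_ion, replace = TRUE)
    }
    data.frame(name = sprintf("cmpd_%03d", seq_len(n)),
               d,
               log_pe = log_pe_true + noise,
               log_pe_true = log_pe_true,
               pKa = pKa, acid_base = acid_base,
               pH = rep(7.4, n),
               stringsAsFactors = FALSE)
  })
}

#' Forward-simulate an iso-/gradient-pH PAMPA experiment pair
#'
#' Wraps [forward_simulate()] at the standard 4 h incubation
#' (t = 14400 s): the iso-pH record carries `pe_ad` in both directions
#' (pH 7.4/7.4) and the gradient record the directional pair.  Membrane
#' retention is drawn from the configured range.  Optional
#' multiplicative log-normal noise (CV `concentration_cv`) emulates
#' quantification error on each measured concentration.
#'
#' @param cfg a [generator_config()].
#' @param pe_da donor-to-acceptor permeability (cm/s) of the gradient
#'   experiment.
#' @param pe_ad acceptor-to-donor permeability (cm/s); also the iso-pH
#'   permeability.
#' @param t incubation time (s).
#' @return A list with elements `iso` and `gradient`
#'   ([concentration_record()]s) and the drawn `RM`.
#' @export
generate_pampa_experiments <- function(cfg, pe_da, pe_ad, t = 14400) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 2L, {
    rm_ <- stats::runif(1, cfg$retention_range[1], cfg$retention_range[2])
    iso <- forward_simulate(Pe_DA = pe_ad, Pe_AD = pe_ad, RM = rm_,
                            geom = cfg$geometry, t = t,
                            pH_donor = 7.4, pH_acceptor = 7.4)
    grad <- forward_simulate(Pe_DA = pe_da, Pe_AD = pe_ad, RM = rm_,
                             geom = cfg$geometry, t = t,
                             pH_donor = 5.0, pH_acceptor = 7.4)
    if (cfg$concentration_cv > 0) {
      iso <- jitter_record(iso, cfg$concentration_cv)
      grad <- jitter_record(grad, cfg$concentration_cv)
    }
    list(iso = iso, gradient = grad, RM = rm_)
  })
}

# multiplicative log-normal noise with the given CV on each measured
# concentration (C_D0 is the prepared solution, also re-quantified)
jitter_record <- function(rec, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  fac <- stats::rlnorm(3, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  concentration_record(C_D0 = rec$C_D0 * fac[1],
                       C_Dt = min(rec$C_Dt * fac[2], rec$C_D0 * fac[1]),
                       C_At = rec$C_At * fac[3],
                       t = rec$t,
                       pH_donor = rec$pH_donor,
                       pH_acceptor = rec$pH_acceptor)
}
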