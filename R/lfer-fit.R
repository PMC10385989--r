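# Fitting the solvation parameter equation to a measured solute set.
#
# The equation applies to neutral species, so compounds appreciably
# ionized at their measurement pH are excluded before the regression
# (default cutoff: ionized fraction 0.02).  The fit itself is ordinary
# least squares of log Pe on (1, E, S, A, B, V); diagnostics follow the
# conventions of the field: residual df = N - 6, SD the residual
# standard error, F = (R^2/5) / ((1 - R^2)/(N - 6)).

#' Ionized fraction at a given pH
#'
#' Henderson-Hasselbalch degree of ionization for a monoprotic site.
#'
#' @param pKa acid dissociation constant (vectorized).
#' @param pH measurement pH (vectorized).
#' @param kind `"acid"` or `"base"`.
#' @return Fraction ionized, in [0, 1].
#' @examples
#' ionized_fraction(9, 7, "acid")    # ~0.0099
#' ionized_fraction(5, 7.4, "base")  # ~0.0040
#' @export
ionized_fraction <- function(pKa, pH, kind) {
  if (any(!is.finite(pKa)) || any(!is.finite(pH))) {
    stop("pKa and pH must be finite", call. = FALSE)
  }
  kind <- rep_len(as.character(kind), length.out = max(length(pKa), length(pH)))
  if (!all(kind %in% c("acid", "base"))) {
    stop("kind must be 'acid' or 'base'", call. = FALSE)
  }
  ifelse(kind == "acid",
         1 / (1 + 10^(pKa - pH)),
         1 / (1 + 10^(pH - pKa)))
}

# maximum ionized fraction over a compound's sites; pKa/kind may be
# ";"-separated strings (multiprotic) or plain numerics
max_ionized_fraction <- function(pKa, kind, pH) {
  if (is.na(pKa) || (is.character(pKa) && !nzchar(pKa))) return(NA_real_)
  vals <- as.numeric(strsplit(as.character(pKa), ";", fixed = TRUE)[[1]])
  kinds <- trimws(strsplit(as.character(kind), ";", fixed = TRUE)[[1]])
  if (length(kinds) == 1L) kinds <- rep(kinds, length(vals))
  if (length(kinds) != length(vals)) {
    stop("pKa and acid/base type lists have different lengths", call. = FALSE)
  }
  max(ionized_fraction(vals, pH, kinds))
}

#' Exclude ionized compounds from a solute dataset
#'
#' Retains compounds whose ionized fraction at their measurement pH does
#' not exceed `threshold` (default 0.02, the neutral-species rule).
#' Compounds without pKa information are treated as neutral and
#' retained.  Multiprotic compounds use the maximum ionized fraction
#' over their sites (`pKa`/`acid_base` as `";"`-separated lists).
#'
#' @param records data frame of solutes with columns
#'   `name, E, S, A, B, V, log_pe` and optionally `pKa, acid_base, pH`.
#' @param threshold ionization cutoff in (0, 1].
#' @return A list of class `neutral_filter`: `retained` and `excluded`
#'   subsets plus a per-compound `report` with the computed fractions.
#' @export
filter_neutral <- function(records, threshold = 0.02) {
  if (!is.data.frame(records)) stop("records must be a data frame", call. = FALSE)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(records)
  has_pka <- "pKa" %in% names(records)
  frac <- rep(NA_real_, n)
  if (has_pka && n > 0) {
    ph <- if ("pH" %in% names(records)) records$pH else rep(7.4, n)
    for (i in seq_len(n)) {
      if (!is.na(records$pKa[i]) &&
          !(is.character(records$pKa) && !nzchar(records$pKa[i]))) {
        if (is.na(ph[i])) {
          stop("record '", records$name[i],
               "' has pKa but no measurement pH", call. = FALSE)
        }
        frac[i] <- max_ionized_fraction(records$pKa[i],
                                        records$acid_base[i], ph[i])
      }
    }
  }
  keep <- is.na(frac) | frac <= threshold
  report <- data.frame(name = records$name,
                       ionized_fraction = frac,
                       retained = keep,
                       stringsAsFactors = FALSE)
  structure(list(retained = records[keep, , drop = FALSE],
                 excluded = records[!keep, , drop = FALSE],
                 report = report, threshold = threshold),
            class = "neutral_filter")
}

#' @export
print.neutral_filter <- function(x, ...) {
  cat(sprintf("Neutral-species filter (ionized fraction <= %g):\n",
              x$threshold))
  cat(sprintf("  retained %d of %d compounds (%d excluded, %d without pKa)\n",
              nrow(x$retained), nrow(x$report), nrow(x$excluded),
              sum(is.na(x$report$ionized_fraction))))
  invisible(x)
}

#' Fit the solvation parameter equation by multiple linear regression
#'
#' Ordinary least squares of `log_pe` on the five Abraham descriptors
#' with intercept.  Reports the coefficient vector with standard errors,
#' N, the residual standard deviation SD = sqrt(RSS/(N-6)), R^2, the
#' Fisher statistic F = (R^2/5)/((1-R^2)/(N-6)), and per-coefficient
#' significance at the 95% level (two-sided t test, N-6 df).
#'
#' @param records data frame with columns `E, S, A, B, V, log_pe`
#'   (typically the `retained` element of [filter_neutral()]).
#' @param system_id label attached to the fitted coefficients.
#' @return A list of class `lfer_fit`: `coefficients` (one-row system
#'   data frame), `std_errors`, `N`, `SD`, `R2`, `F`, `significant_95`,
#'   and the underlying `lm` object as `model`.
#' @export
fit_lfer <- function(records, system_id = "fitted") {
  validate_descriptors(records)
  if (!"log_pe" %in% names(records)) {
    stop("records must contain a 'log_pe' column", call. = FALSE)
  }
  if (any(!is.finite(records$log_pe))) {
    stop("'log_pe' contains non-finite values", call. = FALSE)
  }
  n <- nrow(records)
  if (n < 7L) {
    stop("need at least 7 compounds (N - 6 residual df >= 1); got ", n,
         call. = FALSE)
  }
  X <- stats::model.matrix(~ E + S + A + B + V, data = records)
  qrx <- qr(X, LAPACK = FALSE)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("descriptor matrix is rank deficient (linearly dependent column: ",
         paste(unique(dep), collapse = ", "), ")", call. = FALSE)
  }
  fit <- stats::lm(log_pe ~ E + S + A + B + V, data = records)
  beta <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((records$log_pe - mean(records$log_pe))^2)
  sd_res <- sqrt(rss / (n - 6))
  r2 <- 1 - rss / tss
  f_stat <- (r2 / 5) / ((1 - r2) / (n - 6))
  se <- sqrt(diag(sd_res^2 * chol2inv(qr.R(qr(X)))))
  tcrit <- stats::qt(0.975, df = n - 6)
  sig <- abs(beta / se) > tcrit
  names(beta) <- names(se) <- names(sig) <-
    c("c", "e", "s", "a", "b", "v")
  coeffs <- system_coefficients(system_id,
                                c = beta[["c"]], e = beta[["e"]],
                                s = beta[["s"]], a = beta[["a"]],
                                b = beta[["b"]], v = beta[["v"]],
                                n = n, sd = sd_res, r2 = r2, f = f_stat)
  structure(list(coefficients = coeffs, std_errors = se,
                 N = n, SD = sd_res, R2 = r2, F = f_stat,
                 significant_95 = sig, model = fit),
            class = "lfer_fit")
}

#' F statistic from printed regression summaries
#'
#' Recovers the Fisher statistic of a five-descriptor solvation
#' parameter fit from its determination coefficient and sample size:
#' F = (R^2/5) / ((1 - R^2)/(N - 6)).
#'
#' @param r2 determination coefficient in [0, 1).
#' @param n number of compounds (>= 7).
#' @return F statistic.
#' @examples
#' fisher_f(0.835, 27) # 21.3
#' @export
fisher_f <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)", call. = FALSE)
  if (any(n < 7)) stop("n must be >= 7", call. = FALSE)
  (r2 / 5) / ((1 - r2) / (n - 6))
}

#' Format a fitted equation in the conventional text layout
#'
#' Renders `log Pe = c (se) + e (se) E + ...` with standard errors in
#' parentheses, followed by the N/SD/R^2/F line.
#'
#' @param fit an [fit_lfer()] result.
#' @param digits coefficient digits.
#' @return A character string.
#' @export
format_lfer_equation <- function(fit, digits = 3) {
  stopifnot(inherits(fit, "lfer_fit"))
  co <- as_coef(fit$coefficients, need = c("c", "e", "s", "a", "b", "v"))
  se <- fit$std_errors
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  terms <- c("", " E", " S", " A", " B", " V")
  parts <- character(6)
  for (i in seq_len(6)) {
    val <- co[[i]]
    sign <- if (i == 1) "" else if (val >= 0) " + " else " - "
    parts[i] <- sprintf("%s%s (%s)%s", sign, fmt(abs(val)), fmt(se[[i]]),
                        terms[i])
  }
  if (co[[1]] < 0) parts[1] <- paste0("-", parts[1])
  paste0("log Pe = ", paste(parts, collapse = ""),
         sprintf("\nN = %d; SD = %.3f; R2 = %.3f; F = %.1f",
                 fit$N, fit$SD, fit$R2, fit$F))
}

#' @export
print.lfer_fit <- function(x, ...) {
  cat(format_lfer_equation(x), "\n")
  ns <- names(x$significant_95)[!x$significant_95]
  if (length(ns) > 0) {
    cat("not significant at the 95% level:", paste(ns, collapse = ", "), "\n")
  }
  invisible(x)
}
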