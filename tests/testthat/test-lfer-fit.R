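test_that("ionized fraction follows Henderson-Hasselbalch", {
  expect_equal(ionized_fraction(7, 7, "acid"), 0.5)
  expect_equal(ionized_fraction(7, 7, "base"), 0.5)
  expect_equal(ionized_fraction(9, 7, "acid"), 1 / (1 + 10^2))
  expect_equal(ionized_fraction(5, 7.4, "base"), 1 / (1 + 10^2.4))
  expect_error(ionized_fraction(7, 7, "zwitterion"), "acid")
})

test_that("the neutral-species filter excludes ionized compounds", {
  # 31 compounds, 4 constructed with ionized fraction > 0.02 at pH 7.4
  n <- 31
  base <- data.frame(name = paste0("c", 1:n),
                     E = runif(n), S = runif(n), A = runif(n),
                     B = runif(n), V = runif(n, 0.5, 2),
                     log_pe = rnorm(n),
                     pKa = NA_real_, acid_base = NA_character_,
                     pH = 7.4, stringsAsFactors = FALSE)
  ion <- c(3, 11, 20, 28)
  base$pKa[ion] <- c(7.0, 6.5, 8.2, 7.4)           # acids near pH 7.4
  base$acid_base[ion] <- "acid"
  neutral_pka <- c(5, 15)
  base$pKa[neutral_pka] <- 10.5                    # acid 3 units above pH
  base$acid_base[neutral_pka] <- "acid"

  flt <- filter_neutral(base, threshold = 0.02)
  expect_equal(nrow(flt$retained), 27L)
  expect_setequal(flt$excluded$name, paste0("c", ion))
  # threshold 1 retains everything
  expect_equal(nrow(filter_neutral(base, threshold = 1)$retained), n)
  # compounds without pKa are treated as neutral
  expect_true(all(is.na(flt$report$ionized_fraction[-c(ion, neutral_pka)])))

  # multiprotic compounds use the worst site
  multi <- base[1, ]
  multi$pKa <- "10.5;6.0"; multi$acid_base <- "acid;base"
  expect_equal(nrow(filter_neutral(multi, 0.02)$retained), 0L)
  expect_equal(filter_neutral(multi, 0.05)$report$ionized_fraction,
               1 / (1 + 10^(7.4 - 6.0)))
})

test_that("zero-noise data is recovered exactly by the regression", {
  cfg <- generator_config(seed = 9, n_compounds = 20, noise_sd = 0)
  dat <- generate_lfer_dataset(cfg)
  fit <- fit_lfer(dat)
  truth <- as.numeric(cfg$true_coefficients[, c("c", "e", "s", "a", "b", "v")])
  est <- as.numeric(fit$coefficients[, c("c", "e", "s", "a", "b", "v")])
  expect_equal(est, truth, tolerance = 1e-8)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  expect_equal(fit$SD, 0, tolerance = 1e-8)
})

test_that("diagnostics agree with the standard linear-model summary", {
  cfg <- generator_config(seed = 10, n_compounds = 30, noise_sd = 0.2)
  dat <- generate_lfer_dataset(cfg)
  fit <- fit_lfer(dat)
  sm <- summary(fit$model)
  expect_equal(unname(fit$std_errors), unname(sm$coefficients[, 2]))
  expect_equal(fit$SD, sm$sigma)
  expect_equal(fit$R2, sm$r.squared)
  expect_equal(fit$F, unname(sm$fstatistic[1]))
  # residual orthogonality X' r = 0
  X <- model.matrix(fit$model)
  expect_lt(max(abs(t(X) %*% residuals(fit$model))), 1e-9)
  # significance flags match the two-sided t rule at N - 6 df
  tval <- sm$coefficients[, 3]
  expect_equal(unname(fit$significant_95),
               unname(abs(tval) > qt(0.975, fit$N - 6)))
})

test_that("the F formula reproduces both printed regression summaries", {
  # published diagnostics line 1: R2 = 0.835, N = 27 -> F = 21.3
  expect_equal(round(fisher_f(0.835, 27), 1), 21.3)
  # published diagnostics line 2: R2 = 0.964, N = 45 -> F = 210.6
  # within the rounding of the printed R2 (0.9635 <= R2 < 0.9645)
  expect_gte(210.6, fisher_f(0.9635, 45))
  expect_lte(210.6, fisher_f(0.9645, 45))
})

test_that("a near-zero e coefficient is flagged non-significant", {
  # data generated from the certramide-like truth (e = 0.064, close to
  # zero relative to its spread) with realistic noise
  cfg <- generator_config(seed = 21, n_compounds = 45, noise_sd = 0.15)
  fit <- fit_lfer(generate_lfer_dataset(cfg))
  expect_false(fit$significant_95[["e"]])
  # the large-magnitude coefficients remain significant
  expect_true(all(fit$significant_95[c("b", "v")]))
})

test_that("ill-posed designs are rejected with informative errors", {
  cfg <- generator_config(seed = 12, n_compounds = 10, noise_sd = 0.1)
  dat <- generate_lfer_dataset(cfg)
  expect_error(fit_lfer(dat[1:6, ]), "at least 7")
  dep <- dat; dep$B <- 2 * dep$A          # collinear descriptor
  expect_error(fit_lfer(dep), "rank deficient")
  expect_error(fit_lfer(dat[, setdiff(names(dat), "log_pe")]), "log_pe")
})
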