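# Abraham solvation parameter model:
#   log SP = c + e*E + s*S + a*A + b*B + v*V
# and the D' similarity distance between two characterized systems.

.lfer_coef_names <- c("c", "e", "s", "a", "b", "v")
.lfer_desc_names <- c("E", "S", "A", "B", "V")

#' Solute descriptors for the solvation parameter model
#'
#' Builds a validated data frame of Abraham solute descriptors.
#'
#' @param E excess molar refractivity (cm^3 mol^-1 / 10).
#' @param S dipolarity/polarizability (dimensionless).
#' @param A hydrogen-bond acidity (dimensionless).
#' @param B hydrogen-bond basicity (dimensionless).
#' @param V McGowan characteristic volume (cm^3 mol^-1 / 100); must be
#'   strictly positive for any real molecule.
#'
#' @return A data frame with columns `E`, `S`, `A`, `B`, `V`.
#' @examples
#' solute_descriptors(E = 0.82, S = 1.2, A = 0.3, B = 0.9, V = 1.3)
#' @export
solute_descriptors <- function(E, S, A, B, V) {
  d <- data.frame(E = E, S = S, A = A, B = B, V = V)
  validate_descriptors(d)
  d
}

validate_descriptors <- function(d, positive_V = TRUE) {
  missing_cols <- setdiff(.lfer_desc_names, names(d))
  if (length(missing_cols) > 0L) {
    stop("missing descriptor column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (nm in .lfer_desc_names) {
    x <- d[[nm]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      stop("descriptor '", nm, "' contains non-finite or non-numeric values",
           call. = FALSE)
    }
  }
  if (positive_V && any(d$V <= 0)) {
    stop("descriptor 'V' must be strictly positive (McGowan volume)",
         call. = FALSE)
  }
  invisible(d)
}

#' System coefficients of a solvation parameter equation
#'
#' One row per characterized system, holding the fitted coefficients of
#' the linear free-energy relationship plus optional fit diagnostics.
#' The intercept `c` may be `NA` for systems compiled from the
#' literature without a published intercept; such systems can still be
#' compared through [dprime()], which uses only `e, s, a, b, v`.
#'
#' @param system_id unique label for the system.
#' @param e,s,a,b,v LFER coefficients acting on log SP (dimensionless).
#' @param c intercept of the equation; `NA` if unknown.
#' @param category `"pampa"` or `"biological"`.
#' @param n,sd,r2,f optional fit diagnostics: number of compounds,
#'   residual standard deviation, determination coefficient, Fisher F.
#'
#' @return A data frame with one row per system.
#' @export
system_coefficients <- function(system_id, e, s, a, b, v, c = NA_real_,
                                category = "pampa",
                                n = NA_real_, sd = NA_real_,
                                r2 = NA_real_, f = NA_real_) {
  out <- data.frame(system_id = as.character(system_id),
                    category = category,
                    c = c, e = e, s = s, a = a, b = b, v = v,
                    n = n, sd = sd, r2 = r2, f = f,
                    stringsAsFactors = FALSE)
  validate_systems(out)
  out
}

validate_systems <- function(systems, require_intercept = FALSE) {
  needed <- c("system_id", "e", "s", "a", "b", "v")
  if (require_intercept) needed <- c(needed, "c")
  missing_cols <- setdiff(needed, names(systems))
  if (length(missing_cols) > 0L) {
    stop("missing system column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (nm in intersect(c("e", "s", "a", "b", "v"), names(systems))) {
    if (any(!is.finite(systems[[nm]]))) {
      stop("coefficient '", nm, "' contains non-finite values", call. = FALSE)
    }
  }
  if (require_intercept && any(!is.finite(systems$c))) {
    stop("coefficient 'c' contains non-finite values (intercept required ",
         "for prediction but absent for this system)", call. = FALSE)
  }
  if (anyDuplicated(systems$system_id)) {
    stop("duplicate system_id values: ",
         paste(unique(systems$system_id[duplicated(systems$system_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(systems$n) && any(!is.na(systems$n) & systems$n < 7)) {
    stop("diagnostic 'n' must be >= 7 (one more observation than parameters)",
         call. = FALSE)
  }
  if (!is.null(systems$r2) &&
      any(!is.na(systems$r2) & (systems$r2 < 0 | systems$r2 > 1))) {
    stop("diagnostic 'r2' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(systems$sd) && any(!is.na(systems$sd) & systems$sd < 0)) {
    stop("diagnostic 'sd' must be non-negative", call. = FALSE)
  }
  invisible(systems)
}

# coerce a one-row system (data frame, list or named vector) to a named
# numeric vector of coefficients; `need` lists the fields that must be finite
as_coef <- function(x, need = c("e", "s", "a", "b", "v")) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single system (one row)", call. = FALSE)
    x <- as.list(x)
  }
  x <- unlist(x[intersect(.lfer_coef_names, names(x))])
  missing_f <- setdiff(need, names(x))
  if (length(missing_f) > 0L) {
    stop("missing coefficient(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) {
    if (!is.finite(x[[nm]])) {
      stop("coefficient '", nm, "' is not finite", call. = FALSE)
    }
  }
  x
}

#' Predict log SP from system coefficients and solute descriptors
#'
#' Evaluates the solvation parameter equation
#' \deqn{\log SP = c + eE + sS + aA + bB + vV}
#' for one system over one or more solutes.  For PAMPA systems log SP is
#' the log10 intrinsic permeability in log(cm/s).
#'
#' @param coeffs a one-row system (see [system_coefficients()]) or a
#'   named vector with elements `c, e, s, a, b, v`.
#' @param descriptors a data frame with columns `E, S, A, B, V`
#'   (see [solute_descriptors()]).
#'
#' @return Numeric vector of predicted log SP values, one per solute.
#' @examples
#' certramide <- system_coefficients("certramide", c = -4.181,
#'   e = 0.064, s = -0.594, a = -1.038, b = -2.269, v = 1.730)
#' predict_log_sp(certramide, solute_descriptors(0.8, 1.0, 0.2, 0.8, 1.2))
#' @export
predict_log_sp <- function(coeffs, descriptors) {
  co <- as_coef(coeffs, need = .lfer_coef_names)
  if (is.numeric(descriptors) && !is.null(names(descriptors))) {
    descriptors <- as.data.frame(as.list(descriptors))
  }
  # V = 0 is allowed here (pure-intercept evaluation); the constructor
  # enforces V > 0 for real molecules
  validate_descriptors(descriptors, positive_V = FALSE)
  X <- as.matrix(descriptors[.lfer_desc_names])
  drop(co[["c"]] + X %*% co[c("e", "s", "a", "b", "v")])
}

#' D' distance between two characterized systems
#'
#' The Euclidean distance between the `(e, s, a, b, v)` coefficient
#' vectors of two systems characterized by the same solvation parameter
#' model.  The intercept `c` is excluded by construction.  Small D'
#' (conventionally at or below 1) indicates that one system can emulate
#' the other.
#'
#' @param i,j systems as one-row data frames or named coefficient vectors.
#' @return Non-negative numeric scalar.
#' @examples
#' sys <- pampa_systems()
#' dprime(sys[sys$system_id == "2", ], sys[sys$system_id == "10", ]) # 0.60
#' @export
dprime <- function(i, j) {
  ci <- as_coef(i)
  cj <- as_coef(j)
  k <- c("e", "s", "a", "b", "v")
  sqrt(sum((ci[k] - cj[k])^2))
}

#' D' distance matrix over a set of systems
#'
#' @param systems data frame of systems with unique `system_id` and
#'   finite `e, s, a, b, v` columns (at least two rows).
#' @return Symmetric numeric matrix with zero diagonal; row and column
#'   names are the system ids.
#' @examples
#' dprime_matrix(pampa_systems()[1:3, ])
#' @export
dprime_matrix <- function(systems) {
  validate_systems(systems)
  if (nrow(systems) < 2L) stop("need at least 2 systems", call. = FALSE)
  X <- as.matrix(systems[, c("e", "s", "a", "b", "v")])
  rownames(X) <- as.character(systems$system_id)
  m <- as.matrix(stats::dist(X, method = "euclidean"))
  m
}
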