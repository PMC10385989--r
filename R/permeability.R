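# Effective permeability from PAMPA plate reads.
#
# The donor/acceptor mass balance gives the membrane retention RM; the
# log-depletion equation converts the donor decay over the incubation
# (minus the lag time) into an effective permeability P_e (cm/s).  Under
# iso-pH the aqueous volume ratio r_v = V_D/V_A enters the equation;
# under gradient-pH the two directions differ and the volume ratio is
# replaced by the asymmetry ratio r_a = (V_D/V_A) * Pe(A->D)/Pe(D->A),
# which must be solved iteratively because it depends on Pe(D->A) itself.

#' PAMPA plate geometry
#'
#' Well geometry of a PAMPA sandwich.  Defaults are the skin-PAMPA
#' plate: 180 uL donor (after the stirring bar), 200 uL acceptor,
#' 0.3 cm^2 filter area, apparent porosity 0.76.
#'
#' @param V_D donor volume (cm^3).
#' @param V_A acceptor volume (cm^3).
#' @param area membrane area (cm^2).
#' @param porosity apparent membrane porosity (0, 1].
#' @return A list of class `pampa_geometry`.
#' @export
pampa_geometry <- function(V_D = 0.18, V_A = 0.2, area = 0.3,
                           porosity = 0.76) {
  vals <- c(V_D = V_D, V_A = V_A, area = area, porosity = porosity)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry parameters must be positive and finite", call. = FALSE)
  }
  if (porosity > 1) stop("porosity must be <= 1", call. = FALSE)
  structure(list(V_D = V_D, V_A = V_A, area = area, porosity = porosity),
            class = "pampa_geometry")
}

#' One PAMPA well experiment
#'
#' Concentrations are volume-normalized (mol cm^-3); time in seconds.
#'
#' @param C_D0 initial donor concentration.
#' @param C_Dt donor concentration at time `t`.
#' @param C_At acceptor concentration at time `t`.
#' @param t incubation time (s), > 0.
#' @param pH_donor,pH_acceptor compartment pH values.
#' @return A list of class `concentration_record`.
#' @export
concentration_record <- function(C_D0, C_Dt, C_At, t,
                                 pH_donor = 7.4, pH_acceptor = 7.4) {
  if (any(!is.finite(c(C_D0, C_Dt, C_At, t, pH_donor, pH_acceptor)))) {
    stop("all record fields must be finite", call. = FALSE)
  }
  if (C_D0 <= 0) stop("C_D0 must be > 0", call. = FALSE)
  if (C_Dt < 0 || C_At < 0) stop("concentrations must be >= 0", call. = FALSE)
  if (C_Dt > C_D0) stop("C_Dt exceeds C_D0 (donor gained mass)", call. = FALSE)
  if (t <= 0) stop("t must be > 0", call. = FALSE)
  structure(list(C_D0 = C_D0, C_Dt = C_Dt, C_At = C_At, t = t,
                 pH_donor = pH_donor, pH_acceptor = pH_acceptor),
            class = "concentration_record")
}

#' Membrane retention factor
#'
#' Mass-balance fraction of solute retained in the membrane:
#' \deqn{R_M = 1 - C_D(t)/C_D(0) - (V_A/V_D) \, C_A(t)/C_D(0)}
#'
#' Small negative values (|RM| below `clamp_tol`) arise from measurement
#' noise and are clamped to zero with a warning; larger violations, or
#' RM >= 1, indicate an inconsistent record and are rejected.
#'
#' @param rec a [concentration_record()].
#' @param geom a [pampa_geometry()].
#' @param clamp_tol tolerance for clamping slightly negative RM.
#' @return RM as a fraction in [0, 1).
#' @export
membrane_retention <- function(rec, geom = pampa_geometry(),
                               clamp_tol = 0.02) {
  stopifnot(inherits(rec, "concentration_record"),
            inherits(geom, "pampa_geometry"))
  rm_ <- 1 - rec$C_Dt / rec$C_D0 -
    (geom$V_A / geom$V_D) * rec$C_At / rec$C_D0
  if (rm_ < 0) {
    if (abs(rm_) < 1e-12) {
      # rounding error at RM = 0, not measurement noise
      rm_ <- 0
    } else if (abs(rm_) < clamp_tol) {
      warning(sprintf("RM = %.4f slightly negative; clamped to 0", rm_),
              call. = FALSE)
      rm_ <- 0
    } else {
      stop(sprintf("inconsistent record: RM = %.4f < 0 (mass creation)", rm_),
           call. = FALSE)
    }
  }
  if (rm_ >= 1) {
    stop(sprintf("inconsistent record: RM = %.4f >= 1", rm_), call. = FALSE)
  }
  rm_
}

#' Lag time before steady-state flux
#'
#' Empirical lag time as a function of membrane retention.  The adopted
#' form is affine, t_ss = ((5/4) RM + 1) * 60 s; an alternative
#' reciprocal reading, t_ss = 5/(4 RM + 1) * 60 s, can be selected
#' should a different plate calibration require it.
#'
#' @param RM membrane retention fraction in [0, 1).
#' @param form `"affine"` (default) or `"reciprocal"`.
#' @return Lag time in seconds.
#' @export
lag_time <- function(RM, form = c("affine", "reciprocal")) {
  form <- match.arg(form)
  if (any(!is.finite(RM)) || any(RM < 0) || any(RM >= 1)) {
    stop("RM must lie in [0, 1)", call. = FALSE)
  }
  switch(form,
         affine = ((5 / 4) * RM + 1) * 60,
         reciprocal = 5 / (4 * RM + 1) * 60)
}

# core log-depletion inversion shared by the iso- and gradient-pH paths;
# r is r_v (iso) or r_a (gradient)
pe_from_record <- function(rec, geom, r, lag_form = "affine") {
  rm_ <- membrane_retention(rec, geom)
  tss <- lag_time(rm_, form = lag_form)
  if (rec$t <= tss) {
    stop(sprintf("incubation shorter than lag time (t = %.0f s <= t_ss = %.0f s)",
                 rec$t, tss), call. = FALSE)
  }
  arg <- -r + (1 + r) / (1 - rm_) * rec$C_Dt / rec$C_D0
  if (arg <= 0) {
    stop("at/beyond equilibrium, P_e not determinable (log argument <= 0)",
         call. = FALSE)
  }
  pe <- -log(10) * geom$V_D /
    (geom$area * (rec$t - tss) * geom$porosity) *
    (1 / (1 + r)) * log10(arg)
  list(Pe = pe, RM = rm_, t_ss = tss)
}

#' Effective permeability under iso-pH conditions
#'
#' Inverts the donor-depletion equation with the aqueous volume ratio
#' r_v = V_D/V_A.  Membrane retention and lag time are computed
#' internally from the record.
#'
#' @inheritParams membrane_retention
#' @param lag_form passed to [lag_time()].
#' @return A list with elements `Pe` (cm/s), `RM` and `t_ss` (s).
#' @export
pe_iso <- function(rec, geom = pampa_geometry(), lag_form = "affine") {
  stopifnot(inherits(rec, "concentration_record"))
  r_v <- geom$V_D / geom$V_A
  pe_from_record(rec, geom, r = r_v, lag_form = lag_form)
}

#' Directional permeabilities under gradient-pH conditions
#'
#' Under a pH gradient, permeability differs by direction and the
#' asymmetry ratio r_a = (V_D/V_A) Pe(A->D)/Pe(D->A) couples the
#' depletion equation to its own solution.  Pe(A->D) is fixed by the
#' companion iso-pH experiment (where the two directions coincide);
#' Pe(D->A) is then iterated: starting from r_a = r_v, each pass
#' re-solves the gradient record and updates r_a from the new Pe(D->A),
#' until successive Pe(D->A) values agree to the relative tolerance.
#'
#' @param iso_rec iso-pH [concentration_record()] (equal pH both sides).
#' @param grad_rec gradient-pH record for the same compound.
#' @param geom a [pampa_geometry()].
#' @param tol relative convergence tolerance on Pe(D->A).
#' @param max_iter iteration cap.
#' @param lag_form passed to [lag_time()].
#' @return A list of class `permeability_result` with elements `Pe_DA`,
#'   `Pe_AD` (cm/s), `RM`, `t_ss` (s), `r_a`, `iterations`, `converged`
#'   and the iteration `trace` of Pe(D->A) values.
#' @export
pe_gradient <- function(iso_rec, grad_rec, geom = pampa_geometry(),
                        tol = 1e-3, max_iter = 100L, lag_form = "affine") {
  stopifnot(inherits(iso_rec, "concentration_record"),
            inherits(grad_rec, "concentration_record"))
  if (abs(iso_rec$pH_donor - iso_rec$pH_acceptor) > 1e-9) {
    stop("iso_rec must have equal donor and acceptor pH", call. = FALSE)
  }
  pe_ad <- pe_iso(iso_rec, geom, lag_form = lag_form)$Pe
  r_v <- geom$V_D / geom$V_A

  r_a <- r_v
  trace <- numeric(0)
  pe_da <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sol <- pe_from_record(grad_rec, geom, r = r_a, lag_form = lag_form)
    pe_new <- sol$Pe
    trace <- c(trace, pe_new)
    if (pe_new <= 0) {
      stop("gradient record yields non-positive Pe(D->A)", call. = FALSE)
    }
    if (it > 1L && abs(pe_new - pe_da) <= tol * abs(pe_da)) {
      pe_da <- pe_new
      converged <- TRUE
      break
    }
    pe_da <- pe_new
    r_a <- r_v * pe_ad / pe_da
  }
  if (!converged) {
    warning(sprintf("pe_gradient did not converge in %d iterations; last Pe(D->A) = %.6g",
                    max_iter, pe_da), call. = FALSE)
  }
  structure(list(Pe_DA = pe_da, Pe_AD = pe_ad,
                 RM = sol$RM, t_ss = sol$t_ss,
                 r_a = r_v * pe_ad / pe_da,
                 iterations = length(trace), converged = converged,
                 trace = trace),
            class = "permeability_result")
}

#' Forward-simulate a PAMPA concentration record
#'
#' Closed-form inversion of the depletion equations: given directional
#' permeabilities, retention and geometry, produces the well
#' concentrations that the permeability calculation should invert back
#' to the inputs.  This is the independent oracle for all round-trip
#' tests.
#'
#' With r = r_a (gradient) or r = r_v (iso, when `Pe_AD == Pe_DA`):
#' \deqn{C_D(t)/C_D(0) = (1 - R_M)\,(r + 10^{-k})/(1 + r)}
#' where \eqn{k = P_e A \epsilon_a (t - t_{ss})(1 + r)/(2.303 V_D)}, and
#' C_A(t) follows from the retention mass balance.
#'
#' @param Pe_DA donor-to-acceptor permeability (cm/s).
#' @param Pe_AD acceptor-to-donor permeability (cm/s); equal to `Pe_DA`
#'   for an iso-pH experiment.
#' @param RM membrane retention fraction in [0, 1).
#' @param geom a [pampa_geometry()].
#' @param t incubation time (s); must exceed the lag time.
#' @param C_D0 initial donor concentration (mol cm^-3); default 5e-8
#'   (50 uM).
#' @param pH_donor,pH_acceptor pH labels carried on the record.
#' @param lag_form passed to [lag_time()].
#' @return A [concentration_record()].
#' @export
forward_simulate <- function(Pe_DA, Pe_AD = Pe_DA, RM = 0,
                             geom = pampa_geometry(), t = 14400,
                             C_D0 = 5e-8,
                             pH_donor = 7.4, pH_acceptor = 7.4,
                             lag_form = "affine") {
  if (Pe_DA <= 0 || Pe_AD <= 0) stop("permeabilities must be > 0", call. = FALSE)
  if (RM < 0 || RM >= 1) stop("RM must lie in [0, 1)", call. = FALSE)
  tss <- lag_time(RM, form = lag_form)
  if (t <= tss) stop("t must exceed the lag time", call. = FALSE)
  r_v <- geom$V_D / geom$V_A
  r <- r_v * Pe_AD / Pe_DA
  k <- Pe_DA * geom$area * geom$porosity * (t - tss) * (1 + r) /
    (log(10) * geom$V_D)
  ratio_d <- (1 - RM) * (r + 10^(-k)) / (1 + r)
  C_Dt <- ratio_d * C_D0
  # retention mass balance fixes the acceptor concentration
  C_At <- (geom$V_D / geom$V_A) * (1 - RM - ratio_d) * C_D0
  concentration_record(C_D0 = C_D0, C_Dt = C_Dt, C_At = C_At, t = t,
                       pH_donor = pH_donor, pH_acceptor = pH_acceptor)
}

#' @export
print.permeability_result <- function(x, ...) {
  cat("PAMPA permeability result\n")
  cat(sprintf("  Pe(D->A) = %.6g cm/s\n", x$Pe_DA))
  cat(sprintf("  Pe(A->D) = %.6g cm/s\n", x$Pe_AD))
  cat(sprintf("  RM = %.4f, t_ss = %.1f s, r_a = %.4f\n",
              x$RM, x$t_ss, x$r_a))
  cat(sprintf("  %d iteration(s), converged: %s\n",
              x$iterations, x$converged))
  invisible(x)
}
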