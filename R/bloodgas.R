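#' Blood gas chemistry
#'
#' Evaluates the blood buffer system at given carbon dioxide tension, oxygen
#' tension and bicarbonate concentration: arterial pH by the
#' Henderson-Hasselbalch equation, hemoglobin oxygen saturation by a Hill
#' curve with a Bohr shift of P50, and whole-blood CO2 content by an in vivo
#' dissociation relation with a Haldane correction (content rises as
#' saturation falls).
#'
#' @param PCO2 carbon dioxide tension, mmHg (> 0).
#' @param PO2 oxygen tension, mmHg (> 0).
#' @param HCO3 bicarbonate concentration, mEq/l (> 0).
#' @param params parameter list from [default_parameters()].
#' @return list with components \code{PH} (pH units), \code{SO2} (fraction
#'   in [0, 1]), \code{CCO2} (blood CO2 content, l STPD per l blood) and
#'   \code{P50} (the Bohr-shifted half-saturation tension, mmHg).
#' @export
#' @examples
#' p <- default_parameters()
#' blood_gas_chemistry(40, 99, 24, p)$PH   # about 7.4
blood_gas_chemistry <- function(PCO2, PO2, HCO3, params = default_parameters()) {
  p <- params
  if (!all(is.finite(c(PCO2, PO2, HCO3))) || PCO2 <= 0 || PO2 <= 0 ||
      HCO3 <= 0)
    stop("blood_gas_chemistry: PCO2, PO2 and HCO3 must be positive and ",
         "finite (logarithm undefined otherwise)")
  PH  <- p$PKHH + log10(HCO3 / (p$SCO2 * PCO2))
  P50 <- p$P500 * 10^(p$BOHR * (p$PHA0 - PH))
  r   <- (PO2 / P50)^p$HILLN
  SO2 <- r / (1 + r)
  CCO2 <- p$CO2CNV * (HCO3 + p$SCO2 * PCO2) * (1 + p$HALD * (1 - SO2))
  list(PH = PH, SO2 = SO2, CCO2 = CCO2, P50 = P50)
}

#' Solve arterial pH from buffer base and PCO2
#'
#' The ECF acid-base state is carried as a buffer-base store; at any instant
#' the arterial pH is the unique root of
#' \deqn{S \cdot PCO2 \cdot 10^{pH - pK} + \beta (pH - 7.4) = A}
#' where the first term is bicarbonate (Henderson-Hasselbalch), \eqn{\beta}
#' is the non-bicarbonate buffer value of the extracellular fluid and
#' \eqn{A} is the buffer base per liter ECF. Solved by damped Newton
#' iteration (the left side is smooth, convex and strictly increasing).
#'
#' @param A buffer base concentration, mEq/l.
#' @param PCO2 carbon dioxide tension, mmHg.
#' @param params parameter list.
#' @param tol convergence tolerance on the residual, mEq/l.
#' @return pH (scalar).
#' @export
solve_ph <- function(A, PCO2, params = default_parameters(), tol = 1e-10) {
  p <- params
  PCO2 <- max(PCO2, p$PHEPS)
  x <- p$PHA0
  for (i in 1:100) {
    hco3 <- p$SCO2 * PCO2 * 10^(x - p$PKHH)
    f  <- hco3 + p$BUFB * (x - p$PHA0) - A
    if (abs(f) < tol) break
    fp <- log(10) * hco3 + p$BUFB
    step <- f / fp
    ## keep the iterate inside the physical bracket
    x <- min(max(x - step, p$PHLO), p$PHHI)
  }
  if (abs(f) >= 1e-6)
    stop("solve_ph: Newton iteration failed to converge (A = ", A,
         ", PCO2 = ", PCO2, ")")
  x
}

#' Standard bicarbonate
#'
#' Bicarbonate concentration the extracellular fluid would have after
#' re-equilibration to a PCO2 of 40 mmHg at constant buffer base, i.e. the
#' metabolic component of the acid-base state, referenced to pH 7.4.
#'
#' @param A buffer base concentration, mEq/l.
#' @param params parameter list.
#' @return standard bicarbonate, mEq/l.
#' @export
standard_bicarbonate <- function(A, params = default_parameters()) {
  p <- params
  ph40 <- solve_ph(A, p$PCOA0, p)
  A - p$BUFB * (ph40 - p$PHA0)
}
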