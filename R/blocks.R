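#' Ventilation controller
#'
#' Alveolar ventilation as a function of arterial pH, alveolar CO2 tension
#' and alveolar O2 tension: an additive chemoreflex with a linear central
#' CO2 term, a linear pH (acidemia) term and an exponential peripheral
#' hypoxic term, normalized so that the controller returns exactly the
#' baseline ventilation at the baseline operating point.
#'
#' @param PHA arterial pH.
#' @param PCOA alveolar CO2 tension, mmHg.
#' @param PO2A alveolar O2 tension, mmHg.
#' @param params parameter list.
#' @return alveolar ventilation VI, l/min (never negative).
#' @export
#' @examples
#' p <- default_parameters()
#' ventilation_controller(p$PHA0, p$PCOA0, p$PO2A0, p)  # baseline, 5 l/min
ventilation_controller <- function(PHA, PCOA, PO2A,
                                   params = default_parameters()) {
  p <- params
  stopifnot(is.finite(PHA), is.finite(PCOA), is.finite(PO2A),
            PCOA > 0, PO2A > 0)
  hyp  <- function(P) exp(-(P - p$PHYP0) / p$KHYP)
  drv  <- 1 +
    p$GVCO2 * (PCOA - p$PCOA0) +
    p$GVPH  * (p$PHA0 - PHA) +
    p$GVO2  * (hyp(PO2A) - hyp(p$PO2A0))
  max(0, p$VI0 * drv)
}

#' Circulation steady state
#'
#' The circulatory block is reduced to its settled steady state: systemic
#' arterial pressure and cardiac output are monotone functions of plasma
#' volume (volume loading raises venous return, cardiac output and
#' pressure).
#'
#' @param state state vector (uses VEC to derive plasma volume) or a list
#'   with element \code{VP}.
#' @param params parameter list.
#' @return list with \code{PAS} (mmHg), \code{QCO} (l/min), \code{VP} (l)
#'   and blood volume \code{VB} (l).
#' @export
circulation_steady_state <- function(state, params = default_parameters()) {
  p <- params
  VP <- if (!is.null(names(state)) && "VEC" %in% names(state))
    p$VP0 + p$FVP * (state[["VEC"]] - p$VEC0)
  else state$VP
  if (!is.finite(VP) || VP <= 0) stop("circulation: non-positive plasma volume")
  rel <- VP / p$VP0
  list(PAS = p$PAS0 * rel^p$KPAS,
       QCO = p$QCO0 * rel^p$KQCO,
       VP  = VP,
       VB  = VP / (1 - p$HCT0))
}

#' Fluid compartments and solute concentrations
#'
#' Partitions extracellular volume into plasma and interstitium, forms all
#' compartmental concentrations from the solute stores, and evaluates plasma
#' osmolality from sodium, potassium, glucose, urea and mannitol (urea is
#' treated as a permeant osmole: it contributes to measured osmolality but
#' not to the transcellular osmotic gradient).
#'
#' @param state state vector.
#' @param params parameter list.
#' @return list of volumes (VP, VIF, VEC, VIC, TBW, l), ECF concentrations
#'   (XNE, XKE, XCLE mEq/l; XGLE mg/dl; XUR mg/dl; XMN mOsm/l; XCAE, XMGE,
#'   XPO4E, XOAE mEq/l), ICF potassium XKI (mEq/l), osmolalities OSMP
#'   (measured), OSME and OSMIC (effective extracellular/intracellular,
#'   mOsm/l), and the transcellular water flux QSIC (l/min, positive into
#'   the cells).
#' @export
fluid_compartments <- function(state, params = default_parameters()) {
  p <- params
  s <- as.list(state)
  if (!is.finite(s$VEC) || !is.finite(s$VIC) || s$VEC <= 0 || s$VIC <= 0)
    stop("fluid_compartments: degenerate (non-positive) compartment volume")
  VP  <- p$VP0 + p$FVP * (s$VEC - p$VEC0)
  VIF <- s$VEC - VP
  XNE  <- s$YNE  / s$VEC
  XKE  <- s$YKE  / s$VEC
  XCLE <- s$YCLE / s$VEC
  XGLE <- s$YGLE / (s$VEC * 10)             # mg per dl
  XMN  <- s$YMN  / s$VEC
  XCAE <- s$YCAE / s$VEC
  XMGE <- s$YMGE / s$VEC
  XPO4 <- s$YPO4E / s$VEC
  XOAE <- s$YOAE / s$VEC
  TBW  <- s$VEC + s$VIC
  XUR  <- s$YUREA / (TBW * 10)              # mg per dl, distributes in TBW
  XKI  <- s$YKI / s$VIC
  ## osmolality: measured (includes urea) and effective (excludes urea)
  OSNA <- p$OSMCF * (XNE + XKE)
  OSGL <- XGLE / 18
  OSUR <- XUR / 6
  OSME <- OSNA + OSGL + XMN + p$OSMR
  OSMP <- OSME + OSUR
  ## effective ICF osmoles: a fixed regulated pool (cell-volume regulation
  ## holds the intracellular impermeant-osmole content constant)
  SIC0 <- (p$OSMCF * (p$XNE0 + p$XKE0) + p$XGLE0 / 18 + p$OSMR) * p$VIC0
  OSMIC <- SIC0 / s$VIC
  QSIC <- p$KOSM * (OSMIC - OSME)           # water follows osmoles into ICF
  list(VP = VP, VIF = VIF, VEC = s$VEC, VIC = s$VIC, TBW = TBW,
       XNE = XNE, XKE = XKE, XCLE = XCLE, XGLE = XGLE, XUR = XUR,
       XMN = XMN, XCAE = XCAE, XMGE = XMGE, XPO4E = XPO4, XOAE = XOAE,
       XKI = XKI, OSNA = OSNA, OSGL = OSGL, OSUR = OSUR,
       OSMP = OSMP, OSME = OSME, OSMIC = OSMIC, QSIC = QSIC)
}

#' Hormone controllers
#'
#' Target (secretion-driven) levels of the three hormone effect variables.
#' ADH rises with plasma osmolality and falls with plasma-volume expansion;
#' aldosterone (a reduced renin-angiotensin-aldosterone transfer function)
#' rises with ECF potassium and falls with arterial pressure and ECF volume
#' expansion; insulin rises with ECF glucose. The dynamic states relax
#' toward these targets with first-order time constants.
#'
#' @param snap list with elements OSMP, VP, VEC, XKE, PAS, XGLE (a full
#'   [snapshot()] works).
#' @param state state vector (unused fields ignored; kept for signature
#'   symmetry with the other blocks).
#' @param params parameter list.
#' @return list with targets \code{ADHT}, \code{ALDT}, \code{INST} and the
#'   individual stimulus components.
#' @export
hormone_controllers <- function(snap, state = NULL,
                                params = default_parameters()) {
  p <- params
  ADHOS <- p$GADHO * (snap$OSMP - p$OSMP0)           # osmotic stimulus
  ADHVL <- -p$GADHV * (snap$VP / p$VP0 - 1)          # volume-receptor signal
  ADHT  <- min(max(1 + ADHOS + ADHVL, p$ADHMN), p$ADHMX)
  ALDKF <- p$GALDK * (snap$XKE - p$XKE0)             # potassium stimulus
  ALDPF <- -p$GALDP * (snap$PAS - p$PAS0)            # pressure suppression
  ALDVF <- -p$GALDV * (snap$VEC / p$VEC0 - 1)        # volume suppression
  ALDT  <- min(max(1 + ALDKF + ALDPF + ALDVF, p$ALDMN), p$ALDMX)
  INST  <- min(max((max(snap$XGLE, p$PHEPS) / p$XGLE0)^p$KINS,
                   p$INSMN), p$INSMX)
  list(ADHT = ADHT, ALDT = ALDT, INST = INST,
       ADHOS = ADHOS, ADHVL = ADHVL,
       ALDKF = ALDKF, ALDPF = ALDPF, ALDVF = ALDVF)
}

#' Glucose metabolism
#'
#' Cellular glucose uptake and endogenous (hepatic) production. Uptake has
#' an insulin-independent and an insulin-dependent component, both
#' proportional to the glucose concentration; production is inhibited by
#' glucose and insulin. Disorders of glucose metabolism are modelled by
#' varying CGL1 (insulin-independent uptake), CGL2 (insulin-dependent
#' uptake) and CGL3 (endogenous production).
#'
#' @param XGLE ECF glucose concentration, mg/dl (>= 0).
#' @param INS insulin effect level (baseline 1).
#' @param params parameter list.
#' @return list with \code{UGL} (uptake, mg/min), \code{HGL} (production,
#'   mg/min) and the transcellular potassium flux \code{QKIC_factor}
#'   components used by the assembled model.
#' @export
glucose_metabolism <- function(XGLE, INS, params = default_parameters()) {
  p <- params
  stopifnot(XGLE >= 0, INS >= 0)
  rel <- XGLE / p$XGLE0
  UGL <- (p$CGL1 + p$CGL2 * INS) * rel
  HGL <- if (p$CGL3 == 0) 0 else
    p$CGL3 * (1 / max(rel, p$PHEPS))^p$KHGL * max(INS, p$PHEPS)^(-p$KHGLI)
  list(UGL = UGL, HGL = HGL)
}

#' Renal block
#'
#' Glomerular filtration and tubular handling of water and every tracked
#' solute. GFR is a sigmoid (saturating) function of arterial pressure,
#' scaled by extracellular volume and modulated by ADH, ALD and the
#' proximal control signal THDF. THDF (volume expansion / pressure
#' diuresis) rises with ECF volume and arterial pressure and depresses
#' proximal fractional reabsorption. Distal sodium excretion is inhibited
#' by aldosterone; potassium secretion is stimulated by aldosterone, ECF
#' potassium and distal flow; water excretion is governed by ADH. Glucose
#' is reabsorbed up to a tubular maximum. Urinary acid excretion comprises
#' ammonium (slowly adapting), titratable acid and a bicarbonate spill
#' limited by a PCO2-dependent reabsorption capacity.
#'
#' @param snap list with fields PAS, VEC, XNE, XKE, XCLE, XGLE, XCO3, XUR,
#'   XMN, XCAE, XMGE, XPO4E, XOAE, PHA, PCOA (a full [snapshot()] works).
#' @param hormones list with ADH, ALD effect levels and the adapted
#'   ammonium capacity ANH4 (mEq/min).
#' @param params parameter list.
#' @return list of all renal variables: GFR and its factors, THDF, per-
#'   solute filtered loads (FIL*), distal deliveries (DL*), excretion rates
#'   (QWU l/min; YNU, YKU, YCLU, YHC3U, YNH4U, YTAU, YCAU, YMGU, YPO4U,
#'   YOAU, YMNU mEq/min; YGLU, YURU mg/min), net acid excretion NAE, urine
#'   concentrations (U*), urine pH (UPH) and osmolality (UOSM).
#' @export
kidney <- function(snap, hormones, params = default_parameters()) {
  p   <- params
  ADH <- hormones$ADH
  ALD <- hormones$ALD
  ## --- proximal control signal: volume expansion / pressure diuresis ------
  THDF <- min(max((snap$VEC / p$VEC0)^p$KTHV * (snap$PAS / p$PAS0)^p$KTHP,
                  p$THMN), p$THMX)
  ## --- glomerular filtration ----------------------------------------------
  sig   <- function(P) 1 / (1 + exp(-(P - p$GFP50) / p$GFSL))
  GFRS  <- sig(snap$PAS) / sig(p$PAS0)                # pressure sigmoid
  GFRV  <- (snap$VEC / p$VEC0)^p$KGFV                 # ECF volume control
  GFRH  <- (1 + p$KGFA * (1 - ADH)) * (1 + p$KGFL * (1 - ALD))
  GFRT  <- THDF^p$KGFT
  GFR   <- p$GFR0 * GFRS * GFRV * GFRH * GFRT         # ml/min
  QFIL  <- GFR / 1000                                 # l/min
  ## --- filtered loads -------------------------------------------------------
  FILNA <- QFIL * snap$XNE
  FILK  <- QFIL * snap$XKE
  FILCL <- QFIL * snap$XCLE
  FILC3 <- QFIL * snap$XCO3
  FILGL <- (GFR / 100) * snap$XGLE                    # mg/min (dl/min * mg/dl)
  FILUR <- (GFR / 100) * snap$XUR
  FILMN <- QFIL * snap$XMN
  ## --- proximal tubule -------------------------------------------------------
  FPROX <- min(max(p$FPROX0 * THDF^(-p$KPROX), p$FPROMN), p$FPROMX)
  DLW   <- QFIL  * (1 - FPROX)
  DLNA  <- FILNA * (1 - FPROX)
  DLK   <- FILK  * (1 - FPROX)
  DLCL  <- FILCL * (1 - FPROX)
  ## --- distal tubule and collecting duct -------------------------------------
  AMNA  <- ALD^(-p$KNAALD)                            # ALD: Na retention
  FNAX  <- (snap$XNE / p$XNE0)^p$KNAX                 # osmotic natriuresis
  YNU   <- min(DLNA * p$EXNA0 * AMNA * FNAX, DLNA)
  AMK   <- ALD^p$KKALD                                # ALD: K secretion
  YKU   <- p$YKU0 * (snap$XKE / p$XKE0)^p$KKXK * AMK *
    (DLNA / p$DLNA0)^p$KKFL
  YCLU  <- p$YCLU0 * (snap$XCLE / p$XCLE0)^p$KCLX *
    (max(YNU, p$PHEPS) / p$YNU0)^p$KCLNA
  FWE   <- min(max(p$FWE0 * ADH^(-p$KWADH) * THDF^p$KWTH, p$FWEMN), p$FWEMX)
  QWU   <- DLW * FWE
  ## --- glucose: tubular maximum ----------------------------------------------
  YGLU  <- max(0, FILGL - p$TMG)
  ## --- urea, mannitol, minor ions ---------------------------------------------
  YURU  <- p$FUREA * FILUR
  YMNU  <- FILMN                                      # freely filtered, no reab
  YCAU  <- p$YCAIN  * (snap$XCAE / p$XCAE0)^p$KEXCA * (GFR / p$GFR0)
  YMGU  <- p$YMGIN  * (snap$XMGE / p$XMGE0)^p$KEXCA * (GFR / p$GFR0)
  YPO4U <- p$YPO4IN * (snap$XPO4E / p$XPO4E0)^p$KEXCA * (GFR / p$GFR0)
  YOAU  <- p$YOAIN  * (snap$XOAE / p$XOAE0)^p$KEXCA * (GFR / p$GFR0)
  ## --- acid excretion ------------------------------------------------------------
  TRC3  <- p$TRC30 * (snap$PCOA / p$PCOA0)^p$KTRC3 * THDF^(-p$KTHC3)
  YHC3U <- min(max(0, FILC3 - TRC3), p$UC3MX * QWU)
  YNH4U <- hormones$ANH4
  YTAU  <- p$YTA0 * min(max(exp(p$KTA * (p$PHA0 - snap$PHA)), p$FTAMN),
                        p$FTAMX)
  NAE   <- YNH4U + YTAU - YHC3U
  ## --- urine composition -----------------------------------------------------------
  UNA  <- YNU  / QWU
  UK   <- YKU  / QWU
  UCL  <- YCLU / QWU
  UC3  <- YHC3U / QWU
  UGLC <- YGLU / QWU                                   # mg/l
  UURC <- YURU / QWU
  UPH  <- p$PKHH + log10(max(UC3, p$UC3MN) /
                           (p$SCO2 * (snap$PCOA + p$UPCO2D)))
  UOSM <- (YNU + YKU + YCLU + YHC3U + YNH4U + YTAU + YCAU + YMGU + YPO4U +
             YOAU + YMNU + YGLU / 180 + YURU / 60) / QWU
  list(THDF = THDF, GFR = GFR, GFRS = GFRS, GFRV = GFRV, GFRH = GFRH,
       GFRT = GFRT, QFIL = QFIL,
       FILNA = FILNA, FILK = FILK, FILCL = FILCL, FILC3 = FILC3,
       FILGL = FILGL, FILUR = FILUR, FILMN = FILMN,
       FPROX = FPROX, DLW = DLW, DLNA = DLNA, DLK = DLK, DLCL = DLCL,
       AMNA = AMNA, AMK = AMK, FWE = FWE,
       QWU = QWU, YNU = YNU, YKU = YKU, YCLU = YCLU, YGLU = YGLU,
       YURU = YURU, YMNU = YMNU, YCAU = YCAU, YMGU = YMGU, YPO4U = YPO4U,
       YOAU = YOAU, TRC3 = TRC3, YHC3U = YHC3U, YNH4U = YNH4U, YTAU = YTAU,
       NAE = NAE, UNA = UNA, UK = UK, UCL = UCL, UC3 = UC3, UGLC = UGLC,
       UURC = UURC, UPH = UPH, UOSM = UOSM)
}
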