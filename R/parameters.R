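#' Default model parameters
#'
#' Returns the full constant set of the whole-body model, calibrated for a
#' healthy adult male of approximately 55 kg body weight. All constants keep
#' the uppercase mnemonic style of the classic model family (volumes in
#' liters, solutes in mEq or mg, pressures in mmHg, time in minutes).
#'
#' The parameter list is normalized so that the nominal baseline state
#' returned by [initial_state()] is an exact fixed point of
#' [derivatives()] under the baseline external inputs: every regulated flux
#' is written as \code{baseline_value * (dimensionless factors that equal 1
#' at baseline)}.
#'
#' @param ... named overrides of individual parameters, e.g.
#'   \code{default_parameters(CGL1 = 0)}.
#' @return A named list of model constants. Derived constants (metabolic
#'   rates, baseline concentrations products, normalization factors) are
#'   computed from the primary ones so that overriding a primary constant
#'   keeps the set self-consistent.
#' @export
#' @examples
#' p <- default_parameters()
#' p$VI0    # baseline alveolar ventilation, l/min
default_parameters <- function(...) {
  p <- list(
    ## ---- body composition -------------------------------------------------
    BWT    = 55,     # body weight, kg (informational)
    VEC0   = 11.0,   # baseline extracellular fluid volume, l
    VIC0   = 22.0,   # baseline intracellular fluid volume, l
    VP0    = 2.75,   # baseline plasma volume, l
    FVP    = 0.25,   # fraction of ECF volume change appearing in plasma
    HCT0   = 0.45,   # hematocrit (blood volume bookkeeping only)

    ## ---- circulation (settled steady state) ------------------------------
    PAS0   = 100,    # baseline systemic arterial pressure, mmHg
    KPAS   = 1.2,    # PAS ~ (VP/VP0)^KPAS
    QCO0   = 5.0,    # baseline cardiac output, l/min
    KQCO   = 1.5,    # QCO ~ (VP/VP0)^KQCO

    ## ---- baseline external inputs ----------------------------------------
    QIN    = 0.001,  # oral water intake, l/min
    QVIN   = 0,      # intravenous water, l/min
    YNIN   = 0.12,   # sodium intake, mEq/min
    YCLI   = 0.1328, # chloride intake, mEq/min
    YGLI   = 0,      # glucose intake, mg/min
    FCOI   = 0,      # volume fraction CO2 in dry inspired gas
    YKIN   = 0.06,   # potassium intake, mEq/min (fixed dietary rate)
    YMNIN  = 0,      # mannitol infusion, mOsm/min
    QMW    = 3e-4,   # metabolic water production, l/min
    QIWL   = 3e-4,   # insensible water loss, l/min

    ## ---- ECF / ICF composition -------------------------------------------
    XNE0   = 142,    # ECF sodium, mEq/l
    XKE0   = 4.5,    # ECF potassium, mEq/l
    XKI0   = 150,    # ICF potassium, mEq/l
    XCLE0  = 104,    # ECF chloride, mEq/l
    XGLE0  = 90,     # ECF glucose, mg/dl
    XUR0   = 30,     # plasma/total-body-water urea, mg/dl
    XCAE0  = 5,      # ECF calcium, mEq/l
    XMGE0  = 2,      # ECF magnesium, mEq/l
    XPO4E0 = 2,      # ECF inorganic phosphate, mEq/l
    XOAE0  = 4,      # ECF organic acids, mEq/l
    YCAIN  = 0.004,  # calcium intake, mEq/min
    YMGIN  = 0.002,  # magnesium intake, mEq/min
    YPO4IN = 0.02,   # phosphate intake, mEq/min
    YOAIN  = 0.03,   # organic acid production+intake, mEq/min

    ## ---- osmolality -------------------------------------------------------
    OSMCF  = 1.86,   # osmotic coefficient applied to (Na + K) with anions
    OSMR   = 4.5,    # residual osmoles (Ca, Mg, PO4, proteins...), mOsm/l
    KOSM   = 0.05,   # transcellular water conductance, l/min per (mOsm/l)

    ## ---- acid-base ---------------------------------------------------------
    PKHH   = 6.1,    # Henderson-Hasselbalch pK of the CO2/HCO3 system
    SCO2   = 0.03,   # CO2 solubility, mEq/l per mmHg
    BUFB   = 22,     # non-bicarbonate buffer value of ECF, mEq/l per pH unit
    PHA0   = 7.4,    # reference arterial pH
    PCOA0  = 40,     # baseline alveolar (= arterial) PCO2, mmHg
    MAP0   = 0.05,   # metabolic fixed-acid production, mEq/min
    ANH40  = 0.03,   # baseline urinary ammonium excretion, mEq/min
    KNH4   = 6,      # ammoniagenesis pH sensitivity, per pH unit
    ANH4MX = 0.09,   # ammonium excretion ceiling (adaptation limit), mEq/min
    ANH4MN = 0.005,  # ammonium excretion floor, mEq/min
    TAUNH4 = 600,    # ammoniagenesis adaptation time constant, min
    YTA0   = 0.022,  # baseline titratable acid excretion, mEq/min
    KTA    = 2,      # titratable-acid pH sensitivity, per pH unit
    FTAMN  = 0.3,    # titratable-acid lower factor bound (buffer-limited)
    FTAMX  = 1.5,    # titratable-acid upper factor bound
    YHC3U0 = 0.002,  # baseline urinary bicarbonate excretion, mEq/min
    KTRC3  = 1.0,    # PCO2 sensitivity of tubular HCO3 reabsorption capacity
    KTHC3  = 0.3,    # THDF inhibition of HCO3 reabsorption capacity
    UC3MX  = 40,     # maximum achievable urine HCO3 concentration, mEq/l
    UPCO2D = 20,     # urine PCO2 exceeds alveolar PCO2 by this much, mmHg
    UC3MN  = 0.05,   # urine HCO3 concentration floor for urine pH, mEq/l

    ## ---- respiration -------------------------------------------------------
    PB     = 760,    # barometric pressure, mmHg
    PH2O   = 47,     # saturated water vapor pressure at 37 C, mmHg
    FIO2   = 0.2093, # O2 fraction of dry inspired air
    VI0    = 5.0,    # baseline alveolar ventilation, l/min
    RQ     = 0.8,    # respiratory quotient
    VALCO2 = 3.0,    # effective alveolar CO2 storage volume, l
    VALO2  = 2.5,    # effective alveolar O2 storage volume, l
    VTCO2D = 36,     # body CO2 store distribution volume, l blood-equivalent
    VTO2D  = 6,      # body O2 store distribution volume, l blood-equivalent
    SLCO2  = 0.0078, # in vivo blood CO2 content slope, (l/l)/mmHg
    GVCO2  = 0.08,   # central chemoreflex gain on PCO2, per mmHg
    GVPH   = 30,     # chemoreflex gain on arterial pH, per pH unit
    GVO2   = 15,     # peripheral hypoxic gain, dimensionless
    KHYP   = 25,     # hypoxic drive shape, mmHg
    PHYP0  = 30,     # hypoxic drive offset, mmHg
    P500   = 26.8,   # hemoglobin P50 at pH 7.4, mmHg
    HILLN  = 2.7,    # Hill coefficient of the O2 saturation curve
    BOHR   = 0.48,   # Bohr coefficient, d log10(P50)/d pH
    O2CAP  = 0.201,  # hemoglobin O2 capacity, l STPD per l blood
    O2SOL  = 3e-5,   # dissolved O2, l STPD per l blood per mmHg
    CO2CNV = 0.0223, # l STPD per mmol of CO2
    HALD   = 0.045,  # Haldane coefficient (content gain per unit desaturation)
    VDRAT  = 0.3,    # dead-space fraction of total ventilation
    RR0    = 12,     # baseline respiratory rate, breaths/min

    ## ---- hormone controllers ----------------------------------------------
    TAUADH = 15,     # ADH effect time constant, min
    TAUALD = 45,     # aldosterone effect time constant, min
    TAUINS = 12,     # insulin effect time constant, min
    GADHO  = 0.12,   # ADH gain on plasma osmolality, per mOsm/l
    GADHV  = 10,     # ADH suppression per fractional plasma-volume expansion
    ADHMN  = 0.1,    # ADH effect floor
    ADHMX  = 4,      # ADH effect ceiling
    GALDK  = 1.5,    # ALD gain on ECF potassium, per mEq/l
    GALDP  = 0.04,   # ALD suppression per mmHg arterial pressure rise
    GALDV  = 5,      # ALD suppression per fractional ECF expansion
    ALDMN  = 0.2,    # ALD effect floor
    ALDMX  = 5,      # ALD effect ceiling
    KINS   = 1.8,    # insulin secretion exponent on (XGLE/XGLE0)
    INSMN  = 0.05,   # insulin effect floor
    INSMX  = 12,     # insulin effect ceiling

    ## ---- glucose metabolism -----------------------------------------------
    CGL1   = 70,     # insulin-independent glucose uptake at baseline, mg/min
    CGL2   = 70,     # insulin-dependent glucose uptake at baseline, mg/min
    CGL3   = 140,    # endogenous (hepatic) glucose production, mg/min
    KHGL   = 0.5,    # production inhibition exponent on (XGLE/XGLE0)
    KHGLI  = 0.3,    # production inhibition exponent on insulin
    TMG    = 220,    # tubular maximum for glucose reabsorption, mg/min
    QKIC0  = 3.0,    # transcellular potassium exchange conductance, mEq/min
    KINSK  = 0.06,   # insulin stimulation of cellular K uptake

    ## ---- urea ---------------------------------------------------------------
    PUR    = 15,     # urea production, mg/min
    FUREA  = 0.5,    # fractional urea excretion (urea clearance / GFR)

    ## ---- kidney -------------------------------------------------------------
    GFR0   = 100,    # baseline glomerular filtration rate, ml/min
    GFP50  = 70,     # arterial pressure at half-maximal GFR sigmoid, mmHg
    GFSL   = 8,      # GFR sigmoid slope, mmHg
    KGFV   = 0.6,    # GFR sensitivity to ECF volume
    KGFA   = 0.05,   # GFR modulation by ADH
    KGFL   = 0.03,   # GFR modulation by ALD
    KGFT   = 0.1,    # GFR modulation by THDF
    KTHV   = 3,      # THDF exponent on ECF volume expansion
    KTHP   = 1.5,    # THDF exponent on arterial pressure (pressure diuresis)
    THMN   = 0.2,    # THDF floor
    THMX   = 5,      # THDF ceiling
    FPROX0 = 0.75,   # baseline proximal fractional reabsorption
    KPROX  = 0.4,    # THDF inhibition exponent of proximal reabsorption
    FPROMN = 0.3,    # proximal fractional reabsorption floor
    FPROMX = 0.95,   # proximal fractional reabsorption ceiling
    KNAALD = 1,      # ALD exponent on distal sodium excretion (inhibitory)
    KNAX   = 8,      # osmotic-natriuresis exponent on (XNE/XNE0)
    FWE0   = 0.04,   # baseline fractional excretion of distal water delivery
    KWADH  = 2,      # ADH exponent on fractional water excretion (inhibitory)
    KWTH   = 1.5,    # THDF exponent on fractional water excretion
    FWEMX  = 0.8,    # maximal fractional distal water excretion
    FWEMN  = 1e-4,   # minimal fractional distal water excretion
    KKXK   = 6,      # potassium secretion exponent on (XKE/XKE0)
    KKALD  = 2,      # ALD exponent on potassium secretion (stimulatory)
    KKFL   = 0.5,    # flow (distal Na delivery) exponent on K secretion
    KCLX   = 8,      # chloride excretion exponent on (XCLE/XCLE0)
    KCLNA  = 0.5,    # chloride excretion exponent on (YNU/YNU0)
    KEXCA  = 2,      # Ca/Mg/PO4/OA excretion exponent on concentration

    ## ---- numerics -----------------------------------------------------------
    PHEPS  = 1e-9,   # positive floor applied before logarithms
    PHLO   = 6.0,    # pH solver bracket, lower
    PHHI   = 8.5     # pH solver bracket, upper
  )

  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }

  ## ---- derived, self-consistent constants ---------------------------------
  p$XCO30  <- p$SCO2 * p$PCOA0 * 10^(p$PHA0 - p$PKHH)  # baseline ECF HCO3
  p$MRCO2  <- p$VI0 * p$PCOA0 / 863                    # CO2 production, l/min
  p$MRO2   <- p$MRCO2 / p$RQ                           # O2 consumption, l/min
  p$PIO20  <- p$FIO2 * (p$PB - p$PH2O)                 # baseline inspired PO2
  p$PO2A0  <- p$PIO20 - 863 * p$MRO2 / p$VI0           # baseline alveolar PO2
  p$OSMP0  <- p$OSMCF * (p$XNE0 + p$XKE0) + p$XGLE0 / 18 + p$XUR0 / 6 + p$OSMR
  ## distal sodium delivery and its calibrated fractional excretion
  p$DLNA0  <- (p$GFR0 / 1000) * p$XNE0 * (1 - p$FPROX0)
  p$EXNA0  <- p$YNIN / p$DLNA0
  p$YKU0   <- p$YKIN
  p$YCLU0  <- p$YCLI
  p$YNU0   <- p$YNIN
  ## tubular HCO3 reabsorption capacity leaves the baseline spill YHC3U0
  p$TRC30  <- (p$GFR0 / 1000) * p$XCO30 - p$YHC3U0
  p
}

#' Baseline external inputs
#'
#' The external-input vector of the model at rest: oral water intake,
#' intravenous water, sodium/chloride/glucose intake, inspired CO2 fraction,
#' plus the fixed dietary rates carried in the parameter set.
#'
#' @param params parameter list from [default_parameters()].
#' @return Named numeric vector with elements QIN, QVIN, YNIN, YCLI, YGLI,
#'   FCOI, YKIN, YMNIN.
#' @export
baseline_inputs <- function(params = default_parameters()) {
  c(QIN  = params$QIN,  QVIN  = params$QVIN, YNIN = params$YNIN,
    YCLI = params$YCLI, YGLI  = params$YGLI, FCOI = params$FCOI,
    YKIN = params$YKIN, YMNIN = params$YMNIN)
}

## names of external inputs a protocol may override
input_names <- function() {
  c("QIN", "QVIN", "YNIN", "YCLI", "YGLI", "FCOI", "YKIN", "YMNIN")
}

## algebraic variables a protocol may clamp
clampable_names <- function() c("VI", "GFR", "ADHX", "ALDX")

#' Baseline (nominal) state vector
#'
#' The differential state of the model at its calibrated resting point.
#' Entries are the integrated variables only; every other physiological
#' quantity is algebraic and computed by [snapshot()].
#'
#' State entries: fluid volumes VEC, VIC (l); electrolyte stores YNE, YKE,
#' YKI, YCLE (mEq); glucose store YGLE (mg); urea store YUREA (mg); mannitol
#' store YMN (mOsm); ECF buffer-base store YBBE (mEq); adapted ammonium
#' excretion capacity ANH4 (mEq/min); alveolar gas tensions PCOA, PO2A
#' (mmHg); body gas stores YCO2V, YO2V (l STPD); hormone effect states ADH,
#' ALD, INS (dimensionless); minor-ion stores YCAE, YMGE, YPO4E, YOAE (mEq);
#' and cumulative intake/output bookkeeping integrals CWIN..CGLOUT used by
#' the mass-balance audit.
#'
#' @param params parameter list from [default_parameters()].
#' @return Named numeric state vector; an exact fixed point of
#'   [derivatives()] under [baseline_inputs()].
#' @export
initial_state <- function(params = default_parameters()) {
  p <- params
  TBWdl <- (p$VEC0 + p$VIC0) * 10          # total body water in dl
  ## baseline blood gas contents, consistent with the algebra
  bg <- blood_gas_chemistry(p$PCOA0, p$PO2A0, p$XCO30, p)
  CACO2 <- bg$CCO2
  CAO2  <- p$O2CAP * bg$SO2 + p$O2SOL * p$PO2A0
  CVCO2 <- CACO2 + p$MRCO2 / p$QCO0
  CVO2  <- CAO2 - p$MRO2 / p$QCO0
  c(VEC   = p$VEC0,
    VIC   = p$VIC0,
    YNE   = p$XNE0 * p$VEC0,
    YKE   = p$XKE0 * p$VEC0,
    YKI   = p$XKI0 * p$VIC0,
    YCLE  = p$XCLE0 * p$VEC0,
    YGLE  = p$XGLE0 * (p$VEC0 * 10),
    YUREA = p$XUR0 * TBWdl,
    YMN   = 0,
    YBBE  = p$XCO30 * p$VEC0,
    ANH4  = p$ANH40,
    PCOA  = p$PCOA0,
    PO2A  = p$PO2A0,
    YCO2V = CVCO2 * p$VTCO2D,
    YO2V  = CVO2 * p$VTO2D,
    ADH   = 1,
    ALD   = 1,
    INS   = 1,
    YCAE  = p$XCAE0 * p$VEC0,
    YMGE  = p$XMGE0 * p$VEC0,
    YPO4E = p$XPO4E0 * p$VEC0,
    YOAE  = p$XOAE0 * p$VEC0,
    CWIN  = 0, CWOUT = 0,
    CNAIN = 0, CNAOUT = 0,
    CKIN  = 0, CKOUT  = 0,
    CCLIN = 0, CCLOUT = 0,
    CGLIN = 0, CGLOUT = 0)
}

#' Units registry
#'
#' Maps every state and algebraic mnemonic to a unit string, used for output
#' metadata headers.
#'
#' @param params parameter list.
#' @return Named character vector of unit strings.
#' @export
variable_units <- function(params = default_parameters()) {
  s  <- initial_state(params)
  sn <- snapshot(s, baseline_inputs(params), params)
  u <- c(VEC = "l", VIC = "l", YNE = "mEq", YKE = "mEq", YKI = "mEq",
         YCLE = "mEq", YGLE = "mg", YUREA = "mg", YMN = "mOsm",
         YBBE = "mEq", ANH4 = "mEq/min", PCOA = "mmHg", PO2A = "mmHg",
         YCO2V = "l STPD", YO2V = "l STPD", ADH = "effect units",
         ALD = "effect units", INS = "effect units", YCAE = "mEq",
         YMGE = "mEq", YPO4E = "mEq", YOAE = "mEq",
         CWIN = "l", CWOUT = "l", CNAIN = "mEq", CNAOUT = "mEq",
         CKIN = "mEq", CKOUT = "mEq", CCLIN = "mEq", CCLOUT = "mEq",
         CGLIN = "mg", CGLOUT = "mg",
         time = "min", PAS = "mmHg", QCO = "l/min", VB = "l", VP = "l",
         VIF = "l", TBW = "l", OSMP = "mOsm/l", OSME = "mOsm/l",
         OSMIC = "mOsm/l", QSIC = "l/min", VI = "l/min", VINAT = "l/min",
         VE = "l/min", RR = "1/min", VT = "l", PHA = "pH", PHV = "pH",
         XCO3 = "mEq/l", STBC = "mEq/l", BEB = "mEq/l", SAO2 = "fraction",
         SVO2 = "fraction", P50A = "mmHg", PCOV = "mmHg", PO2V = "mmHg",
         PICO2 = "mmHg", PIO2 = "mmHg", GFR = "ml/min",
         THDF = "dimensionless", QWU = "l/min", UPH = "pH",
         UOSM = "mOsm/l", XGLE = "mg/dl", XUR = "mg/dl")
  excr <- c("YNU", "YKU", "YCLU", "YHC3U", "YNH4U", "YTAU", "NAE", "YCAU",
            "YMGU", "YPO4U", "YOAU", "YMNU")
  u[excr] <- "mEq/min"
  u[c("YGLU", "YURU", "UGL", "HGL")] <- c("mg/min", "mg/min", "mg/min",
                                          "mg/min")
  miss <- setdiff(c(names(s), names(sn)), names(u))
  u[miss] <- "dimensionless or native"
  u
}
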