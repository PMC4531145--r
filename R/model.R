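## Assembled model: one pass computing every algebraic variable and every
## state derivative from (t, state, inputs, params, clamps). All block
## functions are pure; the evaluation order below resolves the algebraic
## dependencies (fluids -> circulation -> acid-base/gas -> ventilation ->
## hormones -> metabolism -> kidney -> gas exchange -> derivatives) without
## any residual loop: the only implicit equation is the scalar buffer-base
## pH relation, solved by Newton iteration in solve_ph().
model_algebra <- function(t, state, inputs, params, clamps = list()) {
  p  <- params
  s  <- as.list(state)
  inp <- as.list(inputs)
  cl <- clamps

  ## ---- block 1/3/4: body fluids and circulation ---------------------------
  fc   <- fluid_compartments(state, p)
  circ <- circulation_steady_state(state, p)
  PAS  <- circ$PAS; QCO <- circ$QCO
  TPR  <- PAS / QCO

  ## ---- acid-base state of the ECF -----------------------------------------
  ABASE <- s$YBBE / s$VEC                       # buffer base, mEq/l
  PHA   <- solve_ph(ABASE, s$PCOA, p)
  XCO3  <- max(p$SCO2 * s$PCOA * 10^(PHA - p$PKHH), p$PHEPS)
  bg    <- blood_gas_chemistry(s$PCOA, s$PO2A, XCO3, p)
  SAO2  <- bg$SO2
  P50A  <- bg$P50
  CACO2 <- bg$CCO2
  CHBO2 <- p$O2CAP * SAO2
  CDISS <- p$O2SOL * s$PO2A
  CAO2  <- CHBO2 + CDISS
  CVCO2 <- s$YCO2V / p$VTCO2D
  CVO2  <- s$YO2V  / p$VTO2D
  SVO2  <- min(max(CVO2 / p$O2CAP, 1e-6), 0.999)
  PO2V  <- P50A * (SVO2 / (1 - SVO2))^(1 / p$HILLN)
  PCOV  <- s$PCOA + (CVCO2 - CACO2) / p$SLCO2
  PHV   <- p$PKHH + log10(XCO3 / (p$SCO2 * max(PCOV, p$PHEPS)))
  STBC  <- standard_bicarbonate(ABASE, p)
  BEB   <- ABASE - p$XCO30                      # base excess, mEq/l
  TCO2A <- CACO2 / p$CO2CNV                     # total CO2, mmol/l
  TCO2V <- CVCO2 / p$CO2CNV
  BUN   <- fc$XUR * 28 / 60                     # blood urea nitrogen, mg/dl

  ## ---- block 2: respiration ------------------------------------------------
  vd    <- ventilation_controller(PHA, s$PCOA, s$PO2A, p)
  hyp   <- function(P) exp(-(P - p$PHYP0) / p$KHYP)
  DVCO2 <- p$GVCO2 * (s$PCOA - p$PCOA0)
  DVPH  <- p$GVPH * (p$PHA0 - PHA)
  DVO2  <- p$GVO2 * (hyp(s$PO2A) - hyp(p$PO2A0))
  VINAT <- vd
  VI    <- if (!is.null(cl$VI)) cl$VI else VINAT
  VE    <- VI / (1 - p$VDRAT)                   # total ventilation
  VD    <- VE - VI                              # dead-space ventilation
  ## breathing-pattern bookkeeping (guarded against transient apnea)
  RR    <- p$RR0 * (max(VE, p$PHEPS) / (p$VI0 / (1 - p$VDRAT)))^0.7
  VT    <- VE / RR                              # tidal volume, l

  ## inspired gas
  PICO2 <- inp$FCOI * (p$PB - p$PH2O)
  FO2I  <- p$FIO2 * (1 - inp$FCOI)
  PIO2  <- FO2I * (p$PB - p$PH2O)
  FACO2 <- s$PCOA / (p$PB - p$PH2O)
  FAO2  <- s$PO2A / (p$PB - p$PH2O)

  ## ---- hormone controllers ---------------------------------------------------
  ADH <- if (!is.null(cl$ADH)) cl$ADH else s$ADH
  ALD <- if (!is.null(cl$ALD)) cl$ALD else s$ALD
  INS <- s$INS
  hc  <- hormone_controllers(list(OSMP = fc$OSMP, VP = fc$VP, VEC = s$VEC,
                                  XKE = fc$XKE, PAS = PAS, XGLE = fc$XGLE),
                             state, p)

  ## ---- glucose metabolism and potassium shift ---------------------------------
  gm    <- glucose_metabolism(fc$XGLE, INS, p)
  FINSK <- 1 + p$KINSK * (INS - 1)
  JKIN  <- p$QKIC0 * (fc$XKE / p$XKE0) * FINSK
  JKOUT <- p$QKIC0 * (fc$XKI / p$XKI0)
  QKIC  <- JKIN - JKOUT

  ## ---- blocks 5-7: kidney ------------------------------------------------------
  ANH4T <- min(max(p$ANH40 * exp(p$KNH4 * (p$PHA0 - PHA)), p$ANH4MN),
               p$ANH4MX)
  kd <- kidney(list(PAS = PAS, VEC = s$VEC, XNE = fc$XNE, XKE = fc$XKE,
                    XCLE = fc$XCLE, XGLE = fc$XGLE, XCO3 = XCO3,
                    XUR = fc$XUR, XMN = fc$XMN, XCAE = fc$XCAE,
                    XMGE = fc$XMGE, XPO4E = fc$XPO4E, XOAE = fc$XOAE,
                    PHA = PHA, PCOA = s$PCOA),
               list(ADH = ADH, ALD = ALD, ANH4 = s$ANH4), p)
  if (!is.null(cl$GFR)) {
    ## clamped GFR: re-evaluate the renal block at the imposed filtration
    sc <- cl$GFR / kd$GFR
    kd <- kidney(list(PAS = PAS, VEC = s$VEC, XNE = fc$XNE, XKE = fc$XKE,
                      XCLE = fc$XCLE, XGLE = fc$XGLE, XCO3 = XCO3,
                      XUR = fc$XUR, XMN = fc$XMN, XCAE = fc$XCAE,
                      XMGE = fc$XMGE, XPO4E = fc$XPO4E, XOAE = fc$XOAE,
                      PHA = PHA, PCOA = s$PCOA),
                 list(ADH = ADH, ALD = ALD, ANH4 = s$ANH4),
                 within(p, GFR0 <- GFR0 * sc))
  }

  ## derived renal indices
  RBF  <- 0.2 * QCO                              # renal blood flow, l/min
  RPF  <- RBF * (1 - p$HCT0)                     # renal plasma flow, l/min
  FF   <- kd$QFIL / RPF                          # filtration fraction
  RPW  <- kd$QFIL - kd$DLW                       # proximal water reabsorption
  RPNA <- kd$FILNA - kd$DLNA
  RPK  <- kd$FILK - kd$DLK
  RPCL <- kd$FILCL - kd$DLCL
  RDNA <- kd$DLNA - kd$YNU                       # distal Na reabsorption
  RDW  <- kd$DLW - kd$QWU
  SECK <- kd$YKU - kd$DLK                        # net distal K secretion
  RGLU <- min(kd$FILGL, p$TMG)
  FEW  <- kd$QWU / kd$QFIL
  FENA <- kd$YNU / max(kd$FILNA, p$PHEPS)
  FEK  <- kd$YKU / max(kd$FILK, p$PHEPS)
  FECL <- kd$YCLU / max(kd$FILCL, p$PHEPS)
  FEC3 <- kd$YHC3U / max(kd$FILC3, p$PHEPS)
  FEGL <- kd$YGLU / max(kd$FILGL, p$PHEPS)
  FEUR <- kd$YURU / max(kd$FILUR, p$PHEPS)
  CLUR <- 100 * kd$YURU / max(fc$XUR, p$PHEPS)   # urea clearance, ml/min
  CLOSM <- kd$UOSM * kd$QWU / fc$OSMP            # osmolar clearance, l/min
  CLH2O <- kd$QWU - CLOSM                        # free-water clearance
  UNH4 <- kd$YNH4U / kd$QWU
  UTA  <- kd$YTAU / kd$QWU
  UCAC <- kd$YCAU / kd$QWU
  UMGC <- kd$YMGU / kd$QWU
  UPO4C <- kd$YPO4U / kd$QWU
  UOAC <- kd$YOAU / kd$QWU
  UMNC <- kd$YMNU / kd$QWU

  ## ---- gas exchange fluxes ---------------------------------------------------
  QXCO2 <- VI * (s$PCOA - PICO2) / 863           # alveolar CO2 output, l/min
  QTCO2 <- QCO * (CVCO2 - CACO2)                 # tissue-to-lung CO2 transport
  QXO2  <- VI * (PIO2 - s$PO2A) / 863            # alveolar O2 uptake
  QTO2  <- QCO * (CAO2 - CVO2)                   # lung-to-tissue O2 transport
  RER   <- QXCO2 / max(QXO2, p$PHEPS)

  ## ---- water throughput ---------------------------------------------------------
  QWIN  <- inp$QIN + inp$QVIN + p$QMW
  QWOUT <- kd$QWU + p$QIWL
  THVF  <- (s$VEC / p$VEC0)^p$KTHV
  THPF  <- (PAS / p$PAS0)^p$KTHP

  ## ---- derivatives ------------------------------------------------------------
  der <- c(
    VEC   = QWIN - QWOUT - fc$QSIC,
    VIC   = fc$QSIC,
    YNE   = inp$YNIN - kd$YNU,
    YKE   = inp$YKIN - kd$YKU - QKIC,
    YKI   = QKIC,
    YCLE  = inp$YCLI - kd$YCLU,
    YGLE  = inp$YGLI + gm$HGL - gm$UGL - kd$YGLU,
    YUREA = p$PUR - kd$YURU,
    YMN   = inp$YMNIN - kd$YMNU,
    YBBE  = kd$NAE - p$MAP0,
    ANH4  = (ANH4T - s$ANH4) / p$TAUNH4,
    PCOA  = 863 * (QTCO2 - QXCO2) / p$VALCO2,
    PO2A  = 863 * (QXO2 - QTO2) / p$VALO2,
    YCO2V = p$MRCO2 - QTCO2,
    YO2V  = QTO2 - p$MRO2,
    ADH   = if (!is.null(cl$ADH)) 0 else (hc$ADHT - s$ADH) / p$TAUADH,
    ALD   = if (!is.null(cl$ALD)) 0 else (hc$ALDT - s$ALD) / p$TAUALD,
    INS   = (hc$INST - s$INS) / p$TAUINS,
    YCAE  = p$YCAIN - kd$YCAU,
    YMGE  = p$YMGIN - kd$YMGU,
    YPO4E = p$YPO4IN - kd$YPO4U,
    YOAE  = p$YOAIN - kd$YOAU,
    CWIN  = QWIN,  CWOUT = QWOUT,
    CNAIN = inp$YNIN, CNAOUT = kd$YNU,
    CKIN  = inp$YKIN, CKOUT = kd$YKU,
    CCLIN = inp$YCLI, CCLOUT = kd$YCLU,
    CGLIN = inp$YGLI + gm$HGL, CGLOUT = gm$UGL + kd$YGLU)

  BALW  <- der[["VEC"]] + der[["VIC"]]
  BALNA <- der[["YNE"]]
  BALK  <- der[["YKE"]] + der[["YKI"]]
  BALCL <- der[["YCLE"]]
  BALGL <- der[["YGLE"]]

  alg <- c(
    ## fluids
    VP = fc$VP, VIF = fc$VIF, TBW = fc$TBW,
    XNE = fc$XNE, XKE = fc$XKE, XCLE = fc$XCLE, XGLE = fc$XGLE,
    XUR = fc$XUR, XMN = fc$XMN, XCAE = fc$XCAE, XMGE = fc$XMGE,
    XPO4E = fc$XPO4E, XOAE = fc$XOAE, XKI = fc$XKI,
    OSNA = fc$OSNA, OSGL = fc$OSGL, OSUR = fc$OSUR,
    OSMP = fc$OSMP, OSME = fc$OSME, OSMIC = fc$OSMIC, QSIC = fc$QSIC,
    ## circulation
    PAS = PAS, QCO = QCO, VB = circ$VB, TPR = TPR,
    RBF = RBF, RPF = RPF, FF = FF,
    ## acid-base and blood gases
    ABASE = ABASE, PHA = PHA, XCO3 = XCO3, STBC = STBC, BEB = BEB,
    P50A = P50A, SAO2 = SAO2, SVO2 = SVO2, CHBO2 = CHBO2, CDISS = CDISS,
    CACO2 = CACO2, CAO2 = CAO2, CVCO2 = CVCO2, CVO2 = CVO2,
    TCO2A = TCO2A, TCO2V = TCO2V, PCOV = PCOV, PO2V = PO2V, PHV = PHV,
    BUN = BUN,
    ## respiration
    VI = VI, VINAT = VINAT, DVCO2 = DVCO2, DVPH = DVPH, DVO2 = DVO2,
    VE = VE, VD = VD, RR = RR, VT = VT,
    PICO2 = PICO2, PIO2 = PIO2, FO2I = FO2I, FACO2 = FACO2, FAO2 = FAO2,
    QXCO2 = QXCO2, QTCO2 = QTCO2, QXO2 = QXO2, QTO2 = QTO2, RER = RER,
    ## hormones
    ADHX = ADH, ALDX = ALD, INSX = INS,
    ADHT = hc$ADHT, ALDT = hc$ALDT, INST = hc$INST,
    ADHOS = hc$ADHOS, ADHVL = hc$ADHVL,
    ALDKF = hc$ALDKF, ALDPF = hc$ALDPF, ALDVF = hc$ALDVF,
    ANH4T = ANH4T,
    ## metabolism
    UGL = gm$UGL, HGL = gm$HGL, FINSK = FINSK, JKIN = JKIN, JKOUT = JKOUT,
    QKIC = QKIC,
    ## kidney
    THDF = kd$THDF, THVF = THVF, THPF = THPF,
    GFR = kd$GFR, GFRS = kd$GFRS, GFRV = kd$GFRV, GFRH = kd$GFRH,
    GFRT = kd$GFRT, QFIL = kd$QFIL,
    FILNA = kd$FILNA, FILK = kd$FILK, FILCL = kd$FILCL, FILC3 = kd$FILC3,
    FILGL = kd$FILGL, FILUR = kd$FILUR, FILMN = kd$FILMN,
    FPROX = kd$FPROX, DLW = kd$DLW, DLNA = kd$DLNA, DLK = kd$DLK,
    DLCL = kd$DLCL,
    RPW = RPW, RPNA = RPNA, RPK = RPK, RPCL = RPCL,
    RDNA = RDNA, RDW = RDW, SECK = SECK, RGLU = RGLU,
    AMNA = kd$AMNA, AMK = kd$AMK, FWE = kd$FWE,
    QWU = kd$QWU, YNU = kd$YNU, YKU = kd$YKU, YCLU = kd$YCLU,
    YGLU = kd$YGLU, YURU = kd$YURU, YMNU = kd$YMNU,
    YCAU = kd$YCAU, YMGU = kd$YMGU, YPO4U = kd$YPO4U, YOAU = kd$YOAU,
    TRC3 = kd$TRC3, YHC3U = kd$YHC3U, YNH4U = kd$YNH4U, YTAU = kd$YTAU,
    NAE = kd$NAE,
    FEW = FEW, FENA = FENA, FEK = FEK, FECL = FECL, FEC3 = FEC3,
    FEGL = FEGL, FEUR = FEUR, CLUR = CLUR, CLOSM = CLOSM, CLH2O = CLH2O,
    UNA = kd$UNA, UK = kd$UK, UCL = kd$UCL, UC3 = kd$UC3, UGLC = kd$UGLC,
    UURC = kd$UURC, UNH4 = UNH4, UTA = UTA, UCAC = UCAC, UMGC = UMGC,
    UPO4C = UPO4C, UOAC = UOAC, UMNC = UMNC,
    UPH = kd$UPH, UOSM = kd$UOSM,
    ## external inputs in force
    QIN = inp$QIN, QVIN = inp$QVIN, YNIN = inp$YNIN, YCLI = inp$YCLI,
    YGLI = inp$YGLI, FCOI = inp$FCOI, YKIN = inp$YKIN, YMNIN = inp$YMNIN,
    QMW = p$QMW, QIWL = p$QIWL, QWIN = QWIN, QWOUT = QWOUT,
    ## net balances
    BALW = BALW, BALNA = BALNA, BALK = BALK, BALCL = BALCL, BALGL = BALGL)

  if (any(!is.finite(der))) {
    bad <- names(der)[!is.finite(der)][1]
    stop("non-finite derivative for state variable ", bad, " at t = ", t)
  }
  if (any(!is.finite(alg))) {
    bad <- names(alg)[!is.finite(alg)][1]
    stop("non-finite algebraic value for ", bad, " at t = ", t)
  }
  list(alg = alg, der = der)
}

#' Algebraic snapshot of the model
#'
#' Evaluates every derived physiological quantity at an instant: pressures,
#' concentrations, pH, osmolality, ventilation, hormone effects, renal
#' fluxes and urine composition. Purely a function of its arguments
#' (deterministic); contains every variable reported in the built-in
#' scenarios (QWU, VP, VEC, VIC, OSMP, VIF, PAS, STBC, ADH, ALD, VI, PCOA,
#' PO2A, XCO3, XGLE, XKE, YGLU, YKU, PHA, ...).
#'
#' @param state state vector, see [initial_state()].
#' @param inputs external inputs, see [baseline_inputs()].
#' @param params parameter list.
#' @param clamps named list of active clamps (e.g. \code{list(VI = 15)}).
#' @return named numeric vector of algebraic variables.
#' @export
#' @examples
#' p <- default_parameters()
#' sn <- snapshot(initial_state(p), baseline_inputs(p), p)
#' sn[c("PHA", "PCOA", "OSMP", "VI")]
snapshot <- function(state, inputs = baseline_inputs(params),
                     params = default_parameters(), clamps = list()) {
  a <- model_algebra(0, state, inputs, params, clamps)$alg
  ## state entries that scenario reports refer to directly join the snapshot
  c(a,
    PCOA = unname(state[["PCOA"]]), PO2A = unname(state[["PO2A"]]),
    VEC = unname(state[["VEC"]]), VIC = unname(state[["VIC"]]),
    ADH = unname(if (!is.null(clamps$ADH)) clamps$ADH else state[["ADH"]]),
    ALD = unname(if (!is.null(clamps$ALD)) clamps$ALD else state[["ALD"]]),
    INS = unname(state[["INS"]]))
}

#' State derivatives
#'
#' Time derivative of every integrated variable: water, electrolyte, glucose,
#' urea, mannitol and buffer-base balances, alveolar and body gas stores,
#' hormone effect relaxation, ammonium adaptation, and the cumulative
#' intake/output bookkeeping integrals. Purely a function of
#' \code{(t, state, inputs, params)}.
#'
#' @inheritParams snapshot
#' @param t time, min (the model is autonomous; kept for solver interfaces).
#' @return named numeric vector of derivatives, one entry per state entry.
#' @export
derivatives <- function(t, state, inputs = baseline_inputs(params),
                        params = default_parameters(), clamps = list()) {
  model_algebra(t, state, inputs, params, clamps)$der
}
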