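# Shared fixtures and independent oracles, built in code at test time.

# A minimal valid compound with unit partitioning everywhere: with bpr = 1 and
# all Kp = 1 the whole body behaves (in the fast-flow limit) as one
# well-stirred volume, which the Bateman closed form describes exactly.
toyRecord <- function(clApp = 5, giKa = 0.8, bpr = 1, fup = 0.5, mw = 300,
                      kpScaler = 1, kp = setNames(rep(1, 11), kpTissues())) {
  compoundRecord("toy", "C", mw = mw, fup = fup, bpr = bpr, giKa = giKa,
                 clApp = clApp, vssPerKg = 1, kp = kp, kpScaler = kpScaler,
                 ic50Cyp11b1 = 100, ic50Cyp11b2 = 10)
}

# Reference subject with all regional flows inflated so tissue equilibration
# is much faster than absorption/elimination: the one-compartment collapse.
collapsedSubject <- function(factor = 1000) {
  base <- referenceSubject()
  tt <- tissueTable(base)
  ov <- lapply(which(tt$name != "lung"), function(i)
    list(flow_L_per_h = tt$blood_flow[i] * factor))
  names(ov) <- tt$name[tt$name != "lung"]
  referenceSubject(overrides = ov)
}

# Analytic oral one-compartment (Bateman) plasma concentration, ng/mL.
batemanConc <- function(t, dose, ka, ke, vol) {
  dose * ka / (vol * (ka - ke)) * (exp(-ke * t) - exp(-ka * t)) * 1000
}

# Wrap a bare concentration vector as a ConcentrationTimeSeries so the NCA
# functions can be exercised on synthetic curves.
syntheticSeries <- function(times, conc) {
  comps <- c("depot", pbpkTissues(), "venous", "arterial", "eliminated")
  amt <- matrix(0, length(times), length(comps),
                dimnames = list(NULL, comps))
  amt[, "venous"] <- conc  # placeholder amounts; NCA reads plasmaConc
  methods::new("ConcentrationTimeSeries", times = times,
               plasmaConc = conc, amounts = amt)
}
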