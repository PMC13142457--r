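# Shared synthetic fixtures, built once per test run. Sizes are kept small:
# pairwise decoding and the geometry/encoding analyses saturate well below
# these trial counts at the default generator SNR.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

inv3 <- c("K", "N", "SH")

set27 <- function() fixture("set27", function() buildFullFactorial(inv3, 3))

# standard compositional session: 27 conditions x 8 repeats, 64 features
sesStd <- function() fixture("sesStd", function() {
  set <- set27()
  cfg <- generatorConfig(nFeatures = 64L, snr = 2)
  code <- makeGroundTruthCode(set, cfg, alignment = 0.6, seed = 101)
  plan <- makeTrialPlan(set, 8L, seed = 102)
  list(set = set, cfg = cfg, code = code, plan = plan,
       session = zscoreSession(simulateSession(code, plan, set, cfg, seed = 103)))
})

# noiseless session (exact linear function of the labels)
sesNoiseless <- function() fixture("sesNoiseless", function() {
  set <- set27()
  cfg <- generatorConfig(nFeatures = 64L, snr = Inf)
  code <- makeGroundTruthCode(set, cfg, alignment = 0.6, seed = 111)
  plan <- makeTrialPlan(set, 3L, seed = 112)
  list(set = set, cfg = cfg, code = code, plan = plan,
       session = simulateSession(code, plan, set, cfg, seed = 113))
})

# mixed-length set (CV / CVCV / CVCVC-style, 1-3 consonant slots)
setMixed <- function() fixture("setMixed", function()
  combineConditionSets(
    buildFullFactorial(inv3, 1L, shape = "CV"),
    buildFullFactorial(inv3, 2L, shape = "CV"),
    buildFullFactorial(inv3, 3L, shape = "CVC")))

prepWin <- function(len = 0.7) epochWindow("go_cue", -len, 0)
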