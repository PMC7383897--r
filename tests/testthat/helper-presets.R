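# Shared fixtures built in code.

# A preset with widely separated class distributions, for tests that need
# near-perfect gating: areas many SDs apart, DNA channels non-overlapping.
separablePreset <- function() {
  makeDonorPreset("separable",
    fractions = c(enucleated = 0.4, nucleated = 0.35, nucleus = 0.25),
    params = list(
      enucleated = list(area = c(50, 6), deformability = c(0.045, 0.01),
                        cd235a = c(6, 0.4), dna = c(7, 0.3)),
      nucleated  = list(area = c(100, 6), deformability = c(0.020, 0.006),
                        cd235a = c(6.2, 0.4), dna = c(7, 0.3)),
      nucleus    = list(area = c(25, 3), deformability = c(0.012, 0.004),
                        cd235a = c(4.8, 0.5), dna = c(7, 0.3))),
    dnaBackground = c(3, 0.4), debrisFraction = 0)
}

# Preset variant without debris, for count oracles.
noDebris <- function(preset) {
  preset@debrisFraction <- 0
  preset
}

# All (flow rate, class pair) combinations present in a focusing model.
modelPairs <- function(model) {
  e <- model@entries
  out <- list()
  for (q in unique(e$flow_rate)) {
    cls <- e$class[abs(e$flow_rate - q) < 1e-9]
    if (length(cls) < 2) next
    cmb <- utils::combn(sort(cls), 2)
    for (j in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <- list(flow = q, a = cmb[1, j], b = cmb[2, j])
  }
  out
}
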