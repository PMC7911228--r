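# Internal helpers shared across modules.

# let data.table syntax ([, .N, by=]) dispatch correctly from this namespace
.datatable.aware <- TRUE

# Deterministic derived seeds, kept inside 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 7919) %% 2147483647)
}

# Quantize a spike time onto the dt grid: a spike occurring inside a step is
# recorded at that step's end boundary (no within-step interpolation).
quantizeTime <- function(t, dt) dt * ceiling(t / dt - 1e-9)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
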