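# Shared fixtures are generated once per test run and memoised here; all are
# built from seeded generators, nothing is stored on disk.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (!exists(key, envir = .fixtures))
        assign(key, force(expr), envir = .fixtures)
    get(key, envir = .fixtures)
}

relErr <- function(x, ref) abs(x - ref) / abs(ref)

# Small video with the default embedding, for tests that only need a
# working recording rather than the full study conditions.
smallSubject <- function(seed, durationS = 60, frameShape = c(24, 24), ...) {
    synthSubject(seed = seed, durationS = durationS,
                 frameShape = frameShape, ...)
}

# Brute-force popcount, independent of the bitplane code under test.
popcount <- function(v) sum(floor(v / 2^(0:7)) %% 2)

# Poincare oracle: rotate the (RR_n, RR_{n+1}) cloud by 45 degrees and take
# sample SDs along the rotated axes.
poincareProjectionOracle <- function(rri) {
    n <- length(rri)
    x <- rri[-n]
    y <- rri[-1]
    u <- (y - x) / sqrt(2)   # perpendicular to the identity line
    v <- (x + y) / sqrt(2)   # along the identity line
    c(sd1 = stats::sd(u), sd2 = stats::sd(v))
}
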