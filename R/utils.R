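# Internal helpers shared across modules.

#' @importFrom utils head tail
NULL

# Order chromosome labels numerically where possible ("1" < "2" < "10"),
# non-numeric labels (e.g. "unknown") last, alphabetically.
.chromRank <- function(chrom) {
    num <- suppressWarnings(as.numeric(chrom))
    order(is.na(num), num, chrom)
}

.chromLevels <- function(chrom) unique(chrom[.chromRank(chrom)])

# 0-based half-open bin index of 1-based positions.
.binIndex <- function(position_bp, binSizeBp) {
    as.integer((position_bp - 1L) %/% binSizeBp)
}

# Run a block with a deterministic RNG state, restoring the caller's state.
.withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

# Derive a stream of sub-seeds from one seed, staying within 32-bit range.
.subSeeds <- function(seed, n) {
    .withSeed(seed, sample.int(.Machine$integer.max, n))
}

.checkFreqs <- function(freqs, tol = 1e-9) {
    if (any(freqs < -tol) || abs(sum(freqs) - 1) > tol)
        stop("allele frequencies must be non-negative and sum to 1")
    invisible(freqs)
}
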