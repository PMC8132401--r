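# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulator calls do
#' not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
.withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    expr
}

# Derive a stage-specific seed from a run seed; keeps values inside the
# 32-bit integer range whatever the run seed is.
.stageSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

.DNA_BASES <- c("A", "C", "G", "T")

# Row-wise min/mean over a small integer matrix without extra dependencies.
.rowMins <- function(m) {
    stopifnot(ncol(m) >= 1L)
    Reduce(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

.checkScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a single number", name), call. = FALSE)
    if (x < lower || (strict_lower && x <= lower) || x > upper)
        stop(sprintf("'%s' out of range", name), call. = FALSE)
    invisible(x)
}
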