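# Run code under a temporary RNG seed, restoring the caller's stream.
.withSeed <- function(seed, fn) {
    if (is.null(seed))
        return(fn())
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    fn()
}

# Diagnostics go to stderr so file/stdout output stays machine-readable.
.log <- function(...) message("[taxenrich] ", ...)
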