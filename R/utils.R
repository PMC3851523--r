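# Run an expression under a local, seeded RNG stream, restoring the
# caller's RNG state afterwards; keeps package functions from perturbing
# user code.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed %% 2147483647))
    expr
}

.zeroPad <- function(i, width) formatC(i, width = width, flag = "0")
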