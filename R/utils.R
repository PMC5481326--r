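## Internal helpers.

## Evaluate expr under a local, seeded RNG stream, restoring the caller's
## RNG state afterwards so generators never perturb user code.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

## Derive a child seed from a base seed; stays well below 2^31.
.childSeed <- function(seed, k) {
    (as.numeric(seed) * 1103L + as.numeric(k) * 12345L) %% 2147483629
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a finite numeric scalar", name),
             call. = FALSE)
    if (positive && x <= 0)
        stop(sprintf("'%s' must be positive", name), call. = FALSE)
    invisible(x)
}

## Channel of the epoch covering each time point (times in [0, total)).
.epochIndexAt <- function(schedule, times) {
    e <- epochs(schedule)
    idx <- findInterval(times, e$start_s, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    idx[idx > nrow(e)] <- nrow(e)
    idx
}

## For dark epochs, the channel governing the dive response: the adjacent
## lit epoch (next if present, else previous). Vector over epochs.
.governingChannel <- function(schedule) {
    e <- epochs(schedule)
    ch <- e$channel
    gov <- ch
    lit <- which(ch != "dark")
    for (i in which(ch == "dark")) {
        nxt <- lit[lit > i]
        prv <- lit[lit < i]
        if (length(nxt)) gov[i] <- ch[nxt[1L]]
        else if (length(prv)) gov[i] <- ch[prv[length(prv)]]
        else gov[i] <- "dark"
    }
    gov
}
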