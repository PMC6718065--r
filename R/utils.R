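# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the ambient RNG stream".
withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = .GlobalEnv)
        else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(seed)
    force(code)
}

# format numbers so integers print without decimals and others keep full
# precision (used by the VOC writer and detections CSV)
.fmtNum <- function(v) {
    ifelse(is.finite(v) & v == round(v),
           sprintf("%d", as.integer(round(v))),
           sprintf("%.17g", v))
}

# split a detection frame into a list of frames by image id, preserving order
.splitByImage <- function(df) {
    if (!nrow(df)) return(list())
    split(df, factor(df$image_id, levels = unique(df$image_id)))
}
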