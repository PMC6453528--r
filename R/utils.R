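# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_unknown_gene <- function(symbol, context = "matrix index") {
  stop(sprintf("unknown gene symbol '%s' (not present in %s)", symbol, context),
       call. = FALSE)
}
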