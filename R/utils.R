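# internal helpers shared across modules

# classed error so pipelines can branch on failure modes
# (e.g. "phosphofit_saturation_error", "phosphofit_kinetics_too_fast")
.stop_classed <- function(class, message, ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

.warn_classed <- function(class, message, ...) {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# run an expression with a locally-seeded RNG, restoring global state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
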