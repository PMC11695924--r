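# internal helpers

# Run code under a fixed RNG seed and restore the caller's RNG state.
# Mersenne-Twister is pinned so identical spec + seed give identical
# output across platforms and sessions.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# run manifest emitted next to CLI outputs so any artifact is reconstructible
run_manifest <- function(command, params) {
  list(
    package = "conformalpr",
    version = as.character(utils::packageVersion("conformalpr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    command = command,
    parameters = params,
    rng = "Mersenne-Twister/Inversion",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}
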