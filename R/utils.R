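# Internal helpers.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

check_newick_safe <- function(labels) {
  bad <- grepl("[,;:()\\[\\]'\" \t]", labels)
  if (any(bad)) {
    stop("labels not usable in Newick output: ",
         paste(labels[bad], collapse = ", "))
  }
  invisible(labels)
}
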