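# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards
# so that package functions are deterministic without clobbering user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Coerce the various matrix-bearing objects to a plain numeric matrix of
# coordinates (cells/points in rows).
as_coords <- function(x) {
  if (inherits(x, "expression_matrix")) {
    return(x$values)
  }
  if (inherits(x, "embedding2d")) {
    return(cbind(x = x$x, y = x$y))
  }
  if (is.data.frame(x)) {
    return(as.matrix(x[vapply(x, is.numeric, logical(1))]))
  }
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  abort("cannot interpret input as a coordinate matrix")
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    abort(paste0(what, " contains non-finite values"))
  }
  invisible(x)
}

# Stable content fingerprint for provenance records.
fingerprint <- function(x) {
  rlang::hash(x)
}

stage_log <- function(stage, t0, extra = NULL) {
  msg <- sprintf(
    "[embedbench] %-12s %7.2fs%s",
    stage, as.numeric(proc.time()[["elapsed"]]) - t0,
    if (is.null(extra)) "" else paste0("  ", extra)
  )
  inform(msg)
}
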