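## small internal helpers

## evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## named per-modality numeric vector from a scalar or (partially) named input
per_modality <- function(x, what, default) {
  out <- stats::setNames(rep(default, length(MODALITIES)), MODALITIES)
  if (is.null(x)) return(out)
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", what))
  if (is.null(names(x))) {
    if (length(x) == 1L) out[] <- x
    else if (length(x) == length(MODALITIES)) out[] <- x
    else stop(sprintf("%s must be a scalar or named by modality", what))
  } else {
    bad <- setdiff(names(x), MODALITIES)
    if (length(bad)) stop(sprintf("unknown modality in %s: %s", what,
                                  paste(bad, collapse = ", ")))
    out[names(x)] <- x
  }
  out
}

## stable md5 of an R object (used for config hashes in sidecar metadata)
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
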