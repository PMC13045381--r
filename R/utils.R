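# Internal: an isolated RNG stream. Draws never disturb (and are never
# disturbed by) the caller's global RNG state; the stream is fully determined
# by `seed`.
local_rng <- function(seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("an explicit integer seed is required for every stochastic operation")
  }
  state <- NULL
  run <- function(f, ...) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(state)) {
      set.seed(as.integer(seed))
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    on.exit({
      state <<- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    f(...)
  }
  list(
    rnorm  = function(...) run(stats::rnorm, ...),
    runif  = function(...) run(stats::runif, ...),
    sample = function(...) run(base::sample, ...),
    sample_int = function(...) run(base::sample.int, ...)
  )
}

stopifnot_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    stop(sprintf("%s must be a positive integer", name))
  }
  invisible(as.integer(x))
}

# Internal: md5 of an R object via its serialisation, used for the pipeline
# summary checksums.
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
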