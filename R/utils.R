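# internal helpers shared across modules

# 90% confidence level multiplier used throughout: published survey MOEs are
# half-widths of 90% intervals, so SE = MOE / 1.645. One constant, no
# alternative conventions.
Z90 <- 1.645

`%||%` <- function(x, y) if (is.null(x)) y else x

# sample() interprets a length-1 numeric vector as 1:n; these wrappers never do
sample_one <- function(v) v[sample.int(length(v), 1L)]
shuffle <- function(v) v[sample.int(length(v))]

# run `code` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_cvr <- function(msg, class) {
  stop(structure(
    class = c(class, "cvregion_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_numeric_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_cvr(paste0(what, " must be numeric and non-missing"), "cvr_domain_error")
  }
  invisible(x)
}
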