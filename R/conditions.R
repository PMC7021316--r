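# Structured error conditions: config errors (bad parameters, bad config
# files) versus data errors (inputs that fail preconditions at run time).
# The CLI maps these to distinct exit codes.

abort_config <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("duplexish_config_error", "duplexish_error"),
                      call = call))
}

abort_data <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("duplexish_data_error", "duplexish_error"),
                      call = call))
}

# Evaluate `code` under a fixed RNG state without clobbering the caller's
# stream; seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
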