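# Classed conditions so callers (and the CLI) can distinguish failure modes:
#   mimicprep_io_error        - unreadable/missing files
#   mimicprep_parse_error     - malformed file content or selection query
#   mimicprep_usage_error     - bad arguments / missing required inputs
#   mimicprep_chemistry_error - unresolved elements, unsaturated valences
# All inherit from "mimicprep_error".

stop_mimicprep <- function(msg, class, call. = FALSE, ...) {
  cond <- structure(
    class = c(class, "mimicprep_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

stop_io <- function(msg, ...) stop_mimicprep(msg, "mimicprep_io_error", ...)
stop_parse <- function(msg, ...) stop_mimicprep(msg, "mimicprep_parse_error", ...)
stop_usage <- function(msg, ...) stop_mimicprep(msg, "mimicprep_usage_error", ...)
stop_chem <- function(msg, ...) stop_mimicprep(msg, "mimicprep_chemistry_error", ...)

# Save/restore .Random.seed so fixture generators are deterministic without
# clobbering the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
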