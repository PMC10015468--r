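# Minimal leveled logging. Verbosity is controlled by
# options(mimicprep.verbose = 0/1/2): 0 = warnings and summaries only (the
# default), 1 = informational messages, 2 = debug.

verbosity <- function() getOption("mimicprep.verbose", 0L)

log_info <- function(...) {
  if (verbosity() >= 1) message("[mimicprep] ", ...)
}

log_debug <- function(...) {
  if (verbosity() >= 2) message("[mimicprep:debug] ", ...)
}
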