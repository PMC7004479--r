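# Classed conditions used across the package. Every reader error that can be
# traced to an input row carries the offending row number(s) in its `rows`
# field so problems are addressable in the source file.

dcxError <- function(class, msg, ..., rows = NULL, call = sys.call(-1)) {
  stop(errorCondition(
    msg,
    class = c(class, "decomplexR_error"),
    rows = rows,
    ...,
    call = call
  ))
}

dcxWarn <- function(class, msg, ...) {
  warning(warningCondition(msg, class = c(class, "decomplexR_warning"), ...))
}
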