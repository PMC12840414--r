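#' @keywords internal
tf_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "toothface_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
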