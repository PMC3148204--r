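# Internal condition helpers.  Three classes so callers (and the CLI) can
# distinguish bad data, out-of-range parameters, and bad configuration.

stop_input <- function(...) {
  stop(structure(
    class = c("nb_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_domain <- function(...) {
  stop(structure(
    class = c("nb_domain_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_config <- function(...) {
  stop(structure(
    class = c("nb_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

log_msg <- function(level = c("info", "warning", "error"), ...,
                    min_level = getOption("netbenefit.log_level", "info")) {
  level <- match.arg(level)
  ranks <- c(info = 1L, warning = 2L, error = 3L)
  if (ranks[[level]] >= ranks[[match.arg(min_level, names(ranks))]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}
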