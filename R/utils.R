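#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## random stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_input <- function(...) {
  stop(structure(class = c("isletsync_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("isletsync_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_undefined <- function(...) {
  stop(structure(class = c("isletsync_undefined_result", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
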