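# Classed conditions used throughout the package. Tests match on class,
# user code can distinguish bad inputs (validation/config) from broken
# files (format/integrity) and violated call contracts.

stop_megnet <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "megnet_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' @noRd
abort_validation <- function(msg) stop_megnet(msg, "megnet_validation_error")

#' @noRd
abort_config <- function(msg) stop_megnet(msg, "megnet_config_error")

#' @noRd
abort_contract <- function(msg) stop_megnet(msg, "megnet_contract_error")

#' @noRd
abort_format <- function(msg) stop_megnet(msg, "megnet_format_error")

#' @noRd
abort_integrity <- function(msg) stop_megnet(msg, "megnet_integrity_error")

# Run code with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
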