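# internal helpers: error signalling, seed derivation, file access

stop_config <- function(msg, ...) abort(msg, class = "ctdosim_config_error", ...)
stop_validation <- function(msg, ...) abort(msg, class = "ctdosim_validation_error", ...)
stop_format <- function(msg, ...) abort(msg, class = "ctdosim_format_error", ...)
stop_consistency <- function(msg, ...) abort(msg, class = "ctdosim_consistency_error", ...)
stop_reconstruction <- function(msg, ...) abort(msg, class = "ctdosim_reconstruction_error", ...)
stop_elicitation <- function(msg, ...) abort(msg, class = "ctdosim_elicitation_error", ...)

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "ctdosim")
  if (!nzchar(p)) stop_config(paste0("bundled data file not found: ", file))
  p
}

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Stable 31-bit hash (FNV-1a folded) mixing a master seed with an arbitrary
#' character key. Used to give every scoped random draw (group x parameter x
#' realization, Monte Carlo table cell, ...) its own reproducible sub-stream,
#' independent of evaluation order.
#'
#' @param master_seed integer master seed.
#' @param ... character/numeric components of the key; concatenated with "|".
#' @return integer in 0..2^31-1.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(format(master_seed, scientific = FALSE), ...), collapse = "|")
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1
  cpp_hash_seed(key)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_choice <- function(x, choices, what, error = stop_validation) {
  if (!(is.character(x) && length(x) == 1L && x %in% choices)) {
    error(paste0("invalid ", what, ": '", paste(x, collapse = ","),
                 "' (expected one of ", paste(choices, collapse = ", "), ")"))
  }
  invisible(x)
}
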