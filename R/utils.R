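#' @keywords internal
"_PACKAGE"

#' @useDynLib beaconrecon, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rbinom runif rgamma quantile
#' @importFrom utils read.delim write.table
NULL

# round half away from zero; base round() is round-half-even, which is the
# wrong convention for carrier counts (2.5 carriers of 5 must mean 3 rows)
round_half_up <- function(x) floor(x + 0.5)

# derive a module-level seed from a master seed by a fixed offset, staying
# inside the 32-bit integer range R requires of set.seed()
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 48271 + offset * 10007) %% 2147483629L)
}

# run code with a locally-set RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "becn_error_validation", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = c("becn_error_format", "becn_error_validation"), ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = c("becn_error_config", "becn_error_validation"), ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = "becn_error_io", ...)
}

stop_numeric <- function(msg, ...) {
  abort(msg, class = "becn_error_numeric", ...)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
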