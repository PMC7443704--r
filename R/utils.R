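#' @importFrom rlang abort warn .data := %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

consat_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("consat_error_", class), "consat_error"), ...)
}

consat_warn <- function(message, class) {
  warn(message, class = c(paste0("consat_warning_", class), "consat_warning"))
}

#' Run code under a stage-specific seed derived from a master seed
#'
#' Every stochastic stage of the package draws from its own stream, derived
#' deterministically from a master seed, so stages can be re-run independently
#' without disturbing one another or the caller's RNG state.
#'
#' @param master_seed integer master seed.
#' @param stage character stage tag.
#' @param code code to evaluate.
#' @keywords internal
with_stage_seed <- function(master_seed, stage, code) {
  withr::with_seed(stage_seed(master_seed, stage), code)
}

# Deterministic 31-bit sub-seed from (master seed, stage tag); a small string
# hash keeps streams distinct across stages without any RNG use here.
stage_seed <- function(master_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647L
  as.integer((as.numeric(master_seed) * 2654435761 + h) %% 2147483647)
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

# stop at first failure with a uniform error class
check_that <- function(ok, message, class) {
  if (!isTRUE(ok)) consat_abort(message, class)
  invisible(TRUE)
}
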