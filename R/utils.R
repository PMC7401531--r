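#' @importFrom rlang .data abort warn
#' @importFrom stats sd optimize qt pt quantile rnorm rpois rnbinom setNames
#' @importFrom utils head
NULL

# geometric mean of strictly positive values
geo_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ncountr <- function(msg, class) {
  rlang::abort(msg, class = c(class, "ncountr_error"))
}

# deterministic 32-bit sub-seed for per-lane RNG streams
lane_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69621 + as.numeric(index) * 104729) %%
               2147483647)
}
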