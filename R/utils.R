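#' @keywords internal
"_PACKAGE"

## NULL-coalescing helper used throughout
`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

## Deterministic sub-seed derivation: independent of how many other units
## exist, so adding prefectures never perturbs existing ones. Kept < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483587) + 1L
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)

## stable key for (prefecture, year) pairs
py_key <- function(prefecture_id, year) paste(prefecture_id, year, sep = "\r")
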