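#' @keywords internal
"_PACKAGE"

## Collapsed label alphabet used throughout the package.
.LBL_FUN <- "functional"
.LBL_NON <- "nonfunctional"
.LBL_UNK <- "unknown"
.LBL_AMB <- "ambiguous"
.LBL_SYNC <- "sync"

collapsedLevels <- function() c(.LBL_FUN, .LBL_NON, .LBL_UNK)

#' Derive a child seed from a master seed and a key
#'
#' Deterministic 31-bit hash of the master seed plus an arbitrary string key,
#' so that independent simulation stages draw from decorrelated streams while
#' the whole run stays reproducible from one master seed.
#'
#' @param seed master integer seed.
#' @param ... character/numeric key components.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h) + 1L
}

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG state is restored afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## population variance (divide by n); block length is fixed so the convention
## only needs to be stated once
popVar <- function(x) mean((x - mean(x))^2)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
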