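#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm qnorm pt qchisq cov prcomp dist median coef lm runif
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream. seed = NULL leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    .stopf("'seed' must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## 32-bit FNV-1a over a character scalar; used to stamp outputs with a
## configuration fingerprint without external hashing dependencies.
fnv1aHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    ## xor only touches the low byte since b < 256
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    ## 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    hi <- h %/% 65536
    lo16 <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo16 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## canonical serialization of a flat config list for hashing
.configString <- function(config) {
  ## paths and presentation flags do not affect the computation
  keys <- setdiff(sort(names(config)), c("out_dir", "timestamp", "input"))
  paste(vapply(keys, function(k) {
    v <- config[[k]]
    paste0(k, "=", paste(format(v, digits = 15), collapse = ","))
  }, character(1)), collapse = ";")
}

.isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && x == round(x)

.groupLevels <- c("air_only", "durian_uninfested", "durian_infested")
.phaseLevels <- c("reset", "sampling", "rest", "room_air", "sample_air")
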