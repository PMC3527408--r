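#' @importFrom stats rnorm runif sd var cor t.test p.adjust quantile median
#' @importFrom utils write.table read.table modifyList
NULL

utils::globalVariables(c("snr_db", "sai", "se", "scheme"))

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
# All seeded operations in the package go through this so that a given
# seed yields identical output regardless of surrounding RNG use.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000003 + as.double(stream) * 7919) %% 2147483647L)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_param("`%s` must be a finite scalar in [%g, %g]", name, lower, upper)
  }
  x
}

row_norms <- function(m) sqrt(rowSums(m^2))

normalize_rows <- function(m) m / pmax(row_norms(m), .Machine$double.eps)

# Row-wise cross product of two n x 3 matrices.
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

sym <- function(m) (m + t(m)) / 2

# Tiny dependency-free FNV-1a hash of a character scalar, for manifests.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
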