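#' Add-one empirical p-value against a reference sample
#'
#' One-tailed empirical p-value of each observation against a reference
#' vector, using the add-one convention `(r + 1) / (n + 1)` so that no
#' p-value is exactly zero. Ties count as "as or more extreme".
#'
#' @param x numeric vector of observed statistics.
#' @param ref numeric reference sample (the null distribution).
#' @param tail `"upper"` tests for unusually large values (p small when `x`
#'   exceeds the reference), `"lower"` for unusually small values.
#' @return numeric vector of p-values in `(0, 1]`, same length as `x`.
#' @examples
#' empirical_p(10, ref = 1:19, tail = "upper")  # 1/20
#' @export
empirical_p <- function(x, ref, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(is.numeric(x), is.numeric(ref), length(ref) >= 1L)
  n <- length(ref)
  r <- if (tail == "upper") {
    vapply(x, function(v) sum(ref >= v), numeric(1))
  } else {
    vapply(x, function(v) sum(ref <= v), numeric(1))
  }
  (r + 1) / (n + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as a
#' named seam so every module corrects p-values through one code path.
#'
#' @param p numeric vector (or matrix) of p-values; matrices are adjusted
#'   jointly over all entries and returned in the original shape.
#' @return adjusted q-values, same shape as `p`.
#' @export
bh_adjust <- function(p) {
  q <- stats::p.adjust(as.vector(p), method = "BH")
  if (is.matrix(p)) {
    q <- matrix(q, nrow = nrow(p), dimnames = dimnames(p))
  }
  q
}

# deterministic RNG scope: evaluates `code` under `seed` without disturbing
# the caller's RNG stream
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
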