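# internal helpers shared across modules

#' @useDynLib drdifc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm sd mad setNames approx
#' @importFrom utils read.csv write.csv head tail
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# near-integer check for extent/voxel compatibility
divides_evenly <- function(extent, voxel, tol = 1e-9) {
  ratio <- extent / voxel
  all(abs(ratio - round(ratio)) < tol * pmax(1, ratio))
}
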