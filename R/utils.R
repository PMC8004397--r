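#' @importFrom methods as is
#' @importFrom stats cor dnorm fisher.test median p.adjust phyper prcomp
#'   quantile rbinom rnbinom rpois runif sd t.test wilcox.test setNames
#'   complete.cases approx
#' @importFrom utils head read.delim write.table
NULL

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# scalar checks used by constructors
assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# genes x cells matrix coercion (dense numeric), preserving dimnames
as_expr_matrix <- function(x) {
  if (is(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' The five cell-cycle phase names
#'
#' Canonical ordering of the expression-program-defined cell-cycle phases
#' used throughout the package, from G1/S entry to mitotic exit.
#'
#' @return Character vector `c("G1/S", "S", "G2/M", "M", "M/G1")`.
#' @export
phase_names <- function() c("G1/S", "S", "G2/M", "M", "M/G1")
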