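#' @useDynLib aerotype, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Solve a small dense linear program
#'
#' Minimises `obj %*% x` subject to `A x (dir) b` and `x >= 0`, using a
#' dense two-phase simplex with Bland's rule. Intended for the small,
#' degenerate LPs that arise from the coarse metabolic network; not a
#' general-purpose LP interface.
#'
#' @param obj numeric objective coefficients (length `ncol(A)`).
#' @param A dense constraint matrix.
#' @param b right-hand sides.
#' @param dir per-row direction: `"<="`, `"=="` or `">="`.
#' @param maxit simplex iteration cap.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxit"`), solution `x`, objective `value` and iteration count.
#' @keywords internal
lp_solve <- function(obj, A, b, dir, maxit = 20000L) {
  stopifnot(is.matrix(A), length(obj) == ncol(A), length(b) == nrow(A),
            length(dir) == nrow(A))
  dcode <- match(dir, c("<=", "==", ">=")) - 2L
  if (anyNA(dcode)) stop("dir must be one of '<=', '==', '>='")
  # row equilibration: constraint rows mix stoichiometric coefficients
  # (order 1-100) with enzyme costs (order 1e-4); scaling each row by its
  # largest entry keeps the pivot tolerances meaningful
  scale <- pmax(apply(abs(A), 1, max), 1e-12)
  A <- A / scale
  b <- as.numeric(b) / scale
  res <- cpp_simplex(as.numeric(obj), A, b,
                     as.integer(dcode), as.integer(maxit))
  res$status <- c("optimal", "infeasible", "unbounded", "maxit")[res$status + 1L]
  res
}
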