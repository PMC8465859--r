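#' Truncated multivariate monomial basis
#'
#' Enumerates all monomials of total degree at most `m` in `n` variables, in
#' the package's canonical "last-variable-major" order, together with the
#' scale factor attached to each monomial. The ordering is: index 1 is the
#' constant 1; then, for each leading variable \eqn{x_i} (the nonzero variable
#' of highest index), monomials are listed by ascending exponent of
#' \eqn{x_i}, and within that by recursively applying the same ordering to
#' the residual monomial in \eqn{x_1,\dots,x_{i-1}}. For the quadratic case
#' (`m = 2`) this gives, per variable, the block
#' \eqn{[x_i,\; x_1 x_i,\dots,x_{i-1} x_i,\; \tfrac12 x_i^2]}, so that e.g.
#' for `n = 3` index 5 is \eqn{x_1 x_2}, index 7 is \eqn{x_3} and index 10 is
#' \eqn{\tfrac12 x_3^2}. All printed coefficient indices in the worked
#' examples refer to this ordering.
#'
#' Each monomial carries the scale \eqn{1/\prod_i a_i!} for exponents
#' \eqn{a_i}, i.e. pure k-th powers are divided by \eqn{k!} and cross terms
#' are unscaled, matching the per-variable expansion
#' \eqn{[1, x_i, \tfrac12 x_i^2, \dots, \tfrac1{m!}x_i^m]}.
#'
#' @param n state dimension (positive integer).
#' @param m maximum total degree (positive integer), default 2.
#' @return An object of class `monomial_basis`: a list with elements `n`,
#'   `m`, `exps` (size-by-n integer matrix of exponents), `scale` (numeric
#'   vector of per-monomial scale factors), `size`, and `ordering` (the
#'   ordering version string, `"tdlvm-1"`).
#' @examples
#' b <- monomial_basis(3, 2)
#' b$size                    # 10
#' basis_labels(b)[c(5, 7)]  # "x1*x2", "x3"
#' @export
monomial_basis <- function(n, m = 2) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("`m` must be a positive integer")
  n <- as.integer(n); m <- as.integer(m)
  exps <- enumerate_exponents(n, m)
  scale <- 1 / apply(exps, 1L, function(e) prod(factorial(e)))
  structure(
    list(n = n, m = m, exps = exps, scale = scale,
         size = nrow(exps), ordering = "tdlvm-1"),
    class = "monomial_basis"
  )
}

# Recursive enumeration: monomials in x_1..x_n of total degree <= m, ordered
# last-variable-major (constant first, then blocks by leading variable).
enumerate_exponents <- function(n, m) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  out <- matrix(0L, nrow = 1L, ncol = n)  # the constant
  for (i in seq_len(n)) {
    for (k in seq_len(m)) {
      rest <- enumerate_exponents(i - 1L, m - k)
      block <- cbind(rest,
                     matrix(0L, nrow(rest), n - i + 1L))
      block[, i] <- k
      out <- rbind(out, block)
    }
  }
  out
}

#' @export
print.monomial_basis <- function(x, ...) {
  cat(sprintf("Monomial basis: n = %d, max degree m = %d, %d monomials (%s)\n",
              x$n, x$m, x$size, x$ordering))
  cat(" ", paste(basis_labels(x), collapse = ", "), "\n")
  invisible(x)
}

#' Human-readable labels for basis monomials
#'
#' @param basis a `monomial_basis`.
#' @return Character vector of labels such as `"1"`, `"x2"`, `"(1/2)x3^2"`.
#' @export
basis_labels <- function(basis) {
  apply(basis$exps, 1L, function(e) {
    if (all(e == 0L)) return("1")
    parts <- vapply(which(e > 0L), function(i) {
      if (e[i] == 1L) paste0("x", i) else paste0("x", i, "^", e[i])
    }, character(1))
    s <- prod(factorial(e))
    pre <- if (s == 1) "" else paste0("(1/", s, ")")
    paste0(pre, paste(parts, collapse = "*"))
  })
}

check_point <- function(basis, point) {
  if (!is.numeric(point) || length(point) != basis$n)
    stop(sprintf("`point` must be a numeric vector of length %d", basis$n))
  as.numeric(point)
}

#' Evaluate the basis at a state-space point
#'
#' Element `k` of the result is the k-th monomial (including its scale
#' factor) evaluated at `point`, so that a potential parameterised as
#' \eqn{\Im(x) = x \cdot h} is `sum(eval_basis(basis, point) * h)`.
#'
#' @param basis a `monomial_basis`.
#' @param point numeric state vector of length `basis$n`.
#' @return Numeric vector of length `basis$size`.
#' @export
eval_basis <- function(basis, point) {
  point <- check_point(basis, point)
  drop(eval_basis_matrix(basis, matrix(point, ncol = 1L)))
}

#' Evaluate the basis at many points at once
#'
#' @param basis a `monomial_basis`.
#' @param X numeric matrix of points, one column per point (`basis$n` rows).
#' @return `basis$size` by `ncol(X)` matrix of basis values.
#' @export
eval_basis_matrix <- function(basis, X) {
  if (!is.matrix(X) || nrow(X) != basis$n)
    stop(sprintf("`X` must be a matrix with %d rows", basis$n))
  out <- matrix(1, basis$size, ncol(X))
  for (k in seq_len(basis$size)) {
    e <- basis$exps[k, ]
    for (i in which(e > 0L)) out[k, ] <- out[k, ] * X[i, ]^e[i]
    out[k, ] <- out[k, ] * basis$scale[k]
  }
  out
}

#' Exact first and second derivatives of the basis
#'
#' Differentiation is carried out on the closed-form monomials, not
#' numerically. The gradient of a potential \eqn{x \cdot h} is
#' `t(D$first) %*% h` and its Hessian is assembled from `D$second`.
#'
#' @param basis a `monomial_basis`.
#' @param point numeric state vector of length `basis$n`.
#' @return A list with `first` (size-by-n matrix, entry (k,i) is the partial
#'   derivative of monomial k with respect to \eqn{x_i}) and `second`
#'   (size-by-n-by-n array of second partials, symmetric in its trailing
#'   dimensions).
#' @export
basis_derivatives <- function(basis, point) {
  point <- check_point(basis, point)
  n <- basis$n; N <- basis$size
  D1 <- matrix(0, N, n)
  D2 <- array(0, c(N, n, n))
  for (k in seq_len(N)) {
    e <- basis$exps[k, ]
    sc <- basis$scale[k]
    for (i in seq_len(n)) {
      if (e[i] == 0L) next
      D1[k, i] <- sc * e[i] * safe_pow(point[i], e[i] - 1L) *
        prod_rest(point, e, i)
      if (e[i] >= 2L)
        D2[k, i, i] <- sc * e[i] * (e[i] - 1L) *
          safe_pow(point[i], e[i] - 2L) * prod_rest(point, e, i)
      if (i < n) for (j in seq((i + 1L), n)) {
        if (e[j] == 0L) next
        val <- sc * e[i] * e[j] *
          safe_pow(point[i], e[i] - 1L) * safe_pow(point[j], e[j] - 1L) *
          prod_rest(point, e, c(i, j))
        D2[k, i, j] <- val
        D2[k, j, i] <- val
      }
    }
  }
  list(first = D1, second = D2)
}

# x^p with the 0^0 = 1 convention used throughout polynomial evaluation
safe_pow <- function(x, p) if (p == 0L) 1 else x^p

prod_rest <- function(point, e, drop_idx) {
  keep <- setdiff(which(e > 0L), drop_idx)
  if (length(keep) == 0L) return(1)
  prod(point[keep]^e[keep])
}

#' Locate the flat basis index of a given monomial
#'
#' Convenience for addressing coefficients by content rather than position,
#' e.g. `basis_index(b, c(1, 1, 0))` is 5 for `n = 3, m = 2` (the
#' \eqn{x_1 x_2} slot).
#'
#' @param basis a `monomial_basis`.
#' @param exponents integer vector of exponents, length `basis$n`.
#' @return The 1-based index, or an error if the monomial is not in the basis.
#' @export
basis_index <- function(basis, exponents) {
  if (length(exponents) != basis$n) stop("wrong exponent vector length")
  hit <- which(apply(basis$exps, 1L, function(e) all(e == exponents)))
  if (length(hit) != 1L) stop("monomial not present in this basis")
  hit
}

# Serialisable description of the basis (ordered exponent tuples + scales).
basis_to_list <- function(basis) {
  list(n = basis$n, m = basis$m, ordering = basis$ordering,
       exponents = apply(basis$exps, 1L, identity, simplify = FALSE),
       scale = basis$scale)
}
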