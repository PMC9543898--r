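#' Sparse polynomials with exact rational coefficients
#'
#' The season accounting is carried out symbolically in the lifecycle
#' parameters: brood size `n`, help per helper `b`, and second-generation
#' brood size `n2`. Every table cell and weighted mean is a polynomial in
#' these variables with rational coefficients (e.g. `3n/4 + nb/8`), so the
#' published algebra can be asserted as exact symbolic equality rather than
#' at sampled numeric points. A `qpoly` is a sum of terms, each an exact
#' rational coefficient times a monomial in `n`, `b`, `n2`.
#'
#' `qp_const()` wraps a rational (or integer-valued numeric) constant;
#' `qp_var()` names a variable. Arithmetic (`+`, `-`, `*`, `==`) is available
#' through the usual operators, mixing `qpoly`, `rational` and integer
#' numerics freely.
#'
#' @param x a `rational` or integer-valued numeric constant.
#' @return a `qpoly`.
#' @examples
#' n <- qp_var("n"); b <- qp_var("b")
#' x <- n * rational(2, 3) + n * b * rational(1, 6)
#' qp_value(qp_eval(x, n = 1, b = 3))   # 7/6
#' @export
qp_const <- function(x) {
  r <- as_rational(x)
  stopifnot(length(r) == 1L)
  .qp_new(list(list(coef = r, exp = .qp_exp0())))
}

.QP_VARS <- c("n", "b", "n2")

.qp_exp0 <- function() c(n = 0, b = 0, n2 = 0)

#' @rdname qp_const
#' @param name one of `"n"`, `"b"`, `"n2"`.
#' @export
qp_var <- function(name) {
  name <- match.arg(name, .QP_VARS)
  e <- .qp_exp0()
  e[name] <- 1
  .qp_new(list(list(coef = rational(1), exp = e)))
}

# canonicalize: merge identical monomials, drop zeros, order by degree then vars
.qp_new <- function(terms) {
  keys <- vapply(terms, function(t) paste(t$exp, collapse = ","), "")
  merged <- list()
  for (i in seq_along(terms)) {
    k <- keys[i]
    if (is.null(merged[[k]])) {
      merged[[k]] <- terms[[i]]
    } else {
      merged[[k]]$coef <- merged[[k]]$coef + terms[[i]]$coef
    }
  }
  merged <- Filter(function(t) t$coef != 0, merged)
  if (length(merged)) {
    ord <- order(vapply(merged, function(t) sum(t$exp), 0),
                 vapply(merged, function(t) paste(sprintf("%02d", t$exp),
                                                  collapse = ""), ""))
    merged <- merged[ord]
  }
  structure(list(terms = unname(merged)), class = "qpoly")
}

.as_qpoly <- function(x) {
  if (inherits(x, "qpoly")) return(x)
  qp_const(x)
}

# group-generic body shared with Ops.rational (see rational.R)
.qp_ops_unary <- function(.Generic, e1) {
  if (.Generic == "-") {
    e1$terms <- lapply(e1$terms, function(t) { t$coef <- -t$coef; t })
    return(.qp_new(e1$terms))
  }
  if (.Generic == "+") return(e1)
  stop("unary ", .Generic, " not defined for qpoly", call. = FALSE)
}

.qp_ops <- function(.Generic, e1, e2) {
  a <- .as_qpoly(e1)
  b <- .as_qpoly(e2)
  switch(.Generic,
    "+" = .qp_new(c(a$terms, b$terms)),
    "-" = .qp_new(c(a$terms, lapply(b$terms, function(t) {
      t$coef <- -t$coef; t
    }))),
    "*" = {
      out <- list()
      for (ta in a$terms) for (tb in b$terms) {
        out[[length(out) + 1L]] <- list(coef = ta$coef * tb$coef,
                                        exp = ta$exp + tb$exp)
      }
      .qp_new(out)
    },
    "==" = qp_is_zero(a - b),
    "!=" = !qp_is_zero(a - b),
    stop(.Generic, " not defined for qpoly", call. = FALSE)
  )
}

#' Test a polynomial for identical zero
#' @param p a `qpoly`.
#' @return logical scalar.
#' @export
qp_is_zero <- function(p) length(.as_qpoly(p)$terms) == 0L

#' Symbolic equality of two polynomials
#' @param a,b `qpoly` (or coercible) operands.
#' @return logical scalar: `TRUE` iff all coefficients agree exactly.
#' @export
qp_equal <- function(a, b) qp_is_zero(.as_qpoly(a) - .as_qpoly(b))

#' Evaluate or partially evaluate a polynomial
#'
#' Substitutes exact rational values for any subset of the variables; the
#' result is again a `qpoly` (a constant one if all variables were supplied).
#' Use [qp_value()] to extract the rational from a constant polynomial, and
#' [qp_eval_num()] for fast floating-point evaluation at arbitrary numerics.
#'
#' @param p a `qpoly`.
#' @param n,b,n2 `rational` or integer-valued numeric values, or `NULL` to
#'   leave the variable symbolic.
#' @return a `qpoly`.
#' @export
qp_eval <- function(p, n = NULL, b = NULL, n2 = NULL) {
  p <- .as_qpoly(p)
  vals <- list(n = n, b = b, n2 = n2)
  vals <- Filter(Negate(is.null), vals)
  vals <- lapply(vals, as_rational)
  terms <- lapply(p$terms, function(t) {
    for (v in names(vals)) {
      k <- t$exp[[v]]
      if (k > 0) {
        t$coef <- t$coef * vals[[v]]^k
        t$exp[[v]] <- 0
      }
    }
    t
  })
  .qp_new(terms)
}

#' @rdname qp_eval
#' @export
qp_value <- function(p) {
  p <- .as_qpoly(p)
  if (length(p$terms) == 0L) return(rational(0))
  if (length(p$terms) > 1L || any(p$terms[[1L]]$exp != 0)) {
    stop("qp_value() requires a constant polynomial; got ", format(p),
         call. = FALSE)
  }
  p$terms[[1L]]$coef
}

#' @rdname qp_eval
#' @export
qp_eval_num <- function(p, n = NA_real_, b = NA_real_, n2 = NA_real_) {
  p <- .as_qpoly(p)
  vals <- c(n = n, b = b, n2 = n2)
  out <- 0
  for (t in p$terms) {
    used <- names(t$exp)[t$exp > 0]
    if (any(is.na(vals[used]))) {
      stop("qp_eval_num(): missing value for variable(s) ",
           paste(used[is.na(vals[used])], collapse = ", "), call. = FALSE)
    }
    out <- out + as.numeric(t$coef) * prod(vals[used]^t$exp[used])
  }
  out
}

#' Coefficients of a polynomial viewed as a polynomial in `b`
#'
#' @param p a `qpoly`.
#' @return a list of `qpoly` (in `n`, `n2` only) indexed by `b`-degree + 1.
#' @export
qp_coefs_b <- function(p) {
  p <- .as_qpoly(p)
  if (length(p$terms) == 0L) return(list(qp_const(0)))
  dmax <- max(vapply(p$terms, function(t) t$exp[["b"]], 0))
  out <- vector("list", dmax + 1L)
  for (d in 0:dmax) {
    sel <- Filter(function(t) t$exp[["b"]] == d, p$terms)
    sel <- lapply(sel, function(t) { t$exp[["b"]] <- 0; t })
    out[[d + 1L]] <- .qp_new(sel)
  }
  out
}

#' Exact division by a single-term polynomial
#'
#' Divides `p` by a monomial divisor (single term), failing if any quotient
#' exponent would be negative. Sufficient for the threshold algebra, where
#' the `b`-coefficient of the copy surplus is always a monomial in `n`.
#'
#' @param p a `qpoly` dividend.
#' @param d a single-term `qpoly` divisor.
#' @return a `qpoly`.
#' @export
qp_div_term <- function(p, d) {
  p <- .as_qpoly(p)
  d <- .as_qpoly(d)
  if (length(d$terms) != 1L) {
    stop("qp_div_term() divisor must have exactly one term", call. = FALSE)
  }
  td <- d$terms[[1L]]
  terms <- lapply(p$terms, function(t) {
    e <- t$exp - td$exp
    if (any(e < 0)) {
      stop("qp_div_term(): dividend not divisible by divisor", call. = FALSE)
    }
    list(coef = t$coef / td$coef, exp = e)
  })
  .qp_new(terms)
}

#' @export
format.qpoly <- function(x, ...) {
  if (length(x$terms) == 0L) return("0")
  pieces <- vapply(x$terms, function(t) {
    mono <- names(t$exp)[t$exp > 0]
    mono <- vapply(mono, function(v) {
      if (t$exp[[v]] == 1) v else paste0(v, "^", t$exp[[v]])
    }, "")
    mono <- paste(mono, collapse = "*")
    cf <- t$coef
    if (!nzchar(mono)) return(format(cf))
    if (cf == 1) return(mono)
    if (cf == -1) return(paste0("-", mono))
    if (cf$den == 1) return(paste0(format(cf), "*", mono))
    paste0("(", format(cf), ")*", mono)
  }, "")
  out <- pieces[1L]
  for (p in pieces[-1L]) {
    if (startsWith(p, "-")) out <- paste0(out, " - ", sub("^-", "", p))
    else out <- paste0(out, " + ", p)
  }
  out
}

#' @export
print.qpoly <- function(x, ...) {
  cat("<qpoly> ", format(x), "\n", sep = "")
  invisible(x)
}
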