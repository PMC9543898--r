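#' Exact rational numbers
#'
#' Vectorized exact rational arithmetic on integer-valued numerators and
#' denominators. Every probability, proportion and allele-copy count in the
#' invasion accounting is an exact rational: the published thresholds
#' (\code{b > 2}, \code{b > 7/5}, \code{b > 7 n2/10}) are exact rationals and
#' floating point would blur the equality \code{x == x_neutral} that defines
#' them. Floating point enters only at the reporting boundary and in the
#' time-course and stochastic modules.
#'
#' Values are stored as doubles holding exact integers; arithmetic aborts if a
#' numerator or denominator leaves the exactly-representable integer range
#' (2^52), which for this model's quantities never happens.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), non-zero. Recycled against `num`.
#' @return an object of class `"rational"`.
#' @examples
#' rational(7, 5) + rational(3, 5)   # 2
#' rational(1, 3) * 3 == 1           # TRUE
#' @export
rational <- function(num, den = 1) {
  num <- as.double(num)
  den <- as.double(den)
  if (length(num) == 0L || length(den) == 0L) {
    stop("rational() requires at least one value", call. = FALSE)
  }
  k <- max(length(num), length(den))
  num <- rep_len(num, k)
  den <- rep_len(den, k)
  if (any(!is.finite(num)) || any(!is.finite(den))) {
    stop("rational() requires finite values", call. = FALSE)
  }
  if (any(num != trunc(num)) || any(den != trunc(den))) {
    stop("rational() requires integer-valued numerator and denominator",
         call. = FALSE)
  }
  if (any(den == 0)) stop("rational() denominator must be non-zero", call. = FALSE)
  if (any(abs(num) > 2^52) || any(abs(den) > 2^52)) {
    stop("rational overflow: values exceed exactly representable range",
         call. = FALSE)
  }
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- .r_gcd(abs(num), den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

# vectorized Euclid on non-negative integer-valued doubles
.r_gcd <- function(a, b) {
  while (any(b != 0)) {
    nz <- b != 0
    tmp <- b[nz]
    b[nz] <- a[nz] %% b[nz]
    a[nz] <- tmp
  }
  a
}

#' Coerce to rational
#'
#' Accepts `rational` objects and integer-valued numerics. Non-integral
#' doubles are rejected: construct them explicitly with [rational()] so the
#' intended fraction is unambiguous.
#'
#' @param x object to coerce.
#' @return a `rational`.
#' @export
as_rational <- function(x) {
  if (is_rational(x)) return(x)
  if (is.numeric(x)) {
    if (any(!is.finite(x)) || any(x != trunc(x))) {
      stop("cannot coerce non-integral numeric to rational; use rational(num, den)",
           call. = FALSE)
    }
    return(rational(x))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to rational", call. = FALSE)
}

#' @rdname as_rational
#' @export
is_rational <- function(x) inherits(x, "rational")

# Ops.rational and Ops.qpoly are the same closure so that R's group-generic
# dispatch treats mixed rational/qpoly expressions as compatible; the shared
# body routes to polynomial arithmetic when either operand is a qpoly.
#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    if (inherits(e1, "qpoly")) return(.qp_ops_unary(.Generic, e1))
    if (.Generic == "-") return(rational(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rational", call. = FALSE)
  }
  if (inherits(e1, "qpoly") || inherits(e2, "qpoly")) {
    return(.qp_ops(.Generic, e1, e2))
  }
  .rational_ops(.Generic, e1, e2)
}

#' @export
#' @method Ops qpoly
Ops.qpoly <- Ops.rational

.rational_ops <- function(.Generic, e1, e2) {
  if (.Generic == "^") {
    p <- as.double(e2)
    if (length(p) != 1L || p != trunc(p)) {
      stop("rational exponent must be a single integer", call. = FALSE)
    }
    a <- as_rational(e1)
    if (p < 0) return(rational(a$den^(-p), a$num^(-p)))
    return(rational(a$num^p, a$den^p))
  }
  a <- as_rational(e1)
  b <- as_rational(e2)
  switch(.Generic,
    "+" = rational(a$num * b$den + b$num * a$den, a$den * b$den),
    "-" = rational(a$num * b$den - b$num * a$den, a$den * b$den),
    "*" = rational(a$num * b$num, a$den * b$den),
    "/" = {
      if (any(b$num == 0)) stop("division by zero rational", call. = FALSE)
      rational(a$num * b$den, a$den * b$num)
    },
    "==" = a$num * b$den == b$num * a$den,
    "!=" = a$num * b$den != b$num * a$den,
    "<"  = a$num * b$den <  b$num * a$den,
    "<=" = a$num * b$den <= b$num * a$den,
    ">"  = a$num * b$den >  b$num * a$den,
    ">=" = a$num * b$den >= b$num * a$den,
    stop(.Generic, " not defined for rational", call. = FALSE)
  )
}

#' @export
Summary.rational <- function(..., na.rm = FALSE) {
  args <- lapply(list(...), as_rational)
  x <- do.call(c, args)
  switch(.Generic,
    sum = {
      out <- rational(0)
      for (i in seq_along(x)) out <- out + x[i]
      out
    },
    prod = {
      out <- rational(1)
      for (i in seq_along(x)) out <- out * x[i]
      out
    },
    max = x[which.max(as.numeric(x))],
    min = x[which.min(as.numeric(x))],
    range = c(min(x), max(x)),
    stop(.Generic, " not defined for rational", call. = FALSE)
  )
}

#' @export
Math.rational <- function(x, ...) {
  switch(.Generic,
    abs = rational(abs(x$num), x$den),
    sign = rational(sign(x$num)),
    stop(.Generic, " not defined for rational", call. = FALSE)
  )
}

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) rational(x$num[i], x$den[i])

#' @export
`[<-.rational` <- function(x, i, value) {
  value <- as_rational(value)
  num <- x$num; den <- x$den
  num[i] <- value$num
  den[i] <- value$den
  rational(num, den)
}

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), as_rational)
  rational(unlist(lapply(parts, `[[`, "num")),
           unlist(lapply(parts, `[[`, "den")))
}

#' @export
rep.rational <- function(x, ...) rational(rep(x$num, ...), rep(x$den, ...))

#' @export
as.numeric.rational <- function(x, ...) x$num / x$den

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
format.rational <- function(x, ...) {
  ifelse(x$den == 1, format(x$num, scientific = FALSE),
         paste0(format(x$num, scientific = FALSE), "/",
                format(x$den, scientific = FALSE)))
}

#' @export
as.character.rational <- function(x, ...) format(x)

#' @export
print.rational <- function(x, ...) {
  cat("<rational> ", paste(format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}
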