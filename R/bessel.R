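# Bessel J0/J1 evaluation and J0 zeros.
#
# Base R's besselJ() loses its asymptotic range near x ~ 1e5 ("value out of
# range"), while the Hankel sum needs J1 at roots up to ~1.6e5 (n = 50,000).
# For large arguments we therefore switch to the Hankel asymptotic expansion
# J_nu(x) ~ sqrt(2/(pi x)) [P cos(chi) - Q sin(chi)], chi = x - (2 nu + 1) pi/4,
# whose truncated series is accurate to ~1e-16 absolute for x >= 50.

BESSEL_ASYMPTOTIC_CUTOFF <- 50

# Coefficients a_m(nu) = prod_{j=1..m} (4 nu^2 - (2j-1)^2) / (8 m!) split into
# even (P) and odd (Q) parts; 13 terms suffice at the cutoff.
bessel_asym_coefs <- function(nu, m_max = 13) {
  a <- numeric(m_max + 1)
  a[1] <- 1
  for (m in seq_len(m_max))
    a[m + 1] <- a[m] * (4 * nu^2 - (2 * m - 1)^2) / (8 * m)
  a
}
.J0_ASYM <- bessel_asym_coefs(0)
.J1_ASYM <- bessel_asym_coefs(1)

bessel_asym <- function(x, nu, a) {
  chi <- x - (2 * nu + 1) * pi / 4
  inv2 <- 1 / (x * x)
  m_max <- length(a) - 1
  p <- rep(a[1], length(x))
  q <- rep(a[2], length(x)) / x
  pow_e <- rep(1, length(x))
  pow_o <- 1 / x
  sgn <- 1
  for (k in seq_len(m_max %/% 2)) {
    sgn <- -sgn
    pow_e <- pow_e * inv2
    pow_o <- pow_o * inv2
    p <- p + sgn * a[2 * k + 1] * pow_e
    if (2 * k + 2 <= length(a)) q <- q + sgn * a[2 * k + 2] * pow_o
  }
  sqrt(2 / (pi * x)) * (p * cos(chi) - q * sin(chi))
}

check_bessel_arg <- function(x) {
  if (!is.numeric(x) || any(is.nan(x)) || any(x < 0))
    abort("Bessel argument must be numeric, non-negative and not NaN.",
          class = "layerfluence_domain_error")
  invisible(x)
}

#' Bessel functions of the first kind, orders 0 and 1
#'
#' Thin evaluators used by the finite Hankel transform. Small arguments go
#' through base R's `besselJ()`; arguments above 50 use the Hankel asymptotic
#' expansion, which stays accurate where `besselJ()` runs out of range
#' (x above roughly 1e5).
#'
#' @param x Non-negative finite numeric vector.
#' @return Numeric vector of function values.
#' @export
#' @examples
#' bessel_j0(0)          # 1
#' bessel_j1(0)          # 0
#' bessel_j0(2.404825557695773)  # ~0 (first zero of J0)
bessel_j0 <- function(x) {
  check_bessel_arg(x)
  out <- numeric(length(x))
  small <- x < BESSEL_ASYMPTOTIC_CUTOFF
  if (any(small)) out[small] <- besselJ(x[small], 0)
  if (any(!small)) out[!small] <- bessel_asym(x[!small], 0, .J0_ASYM)
  out
}

#' @rdname bessel_j0
#' @export
bessel_j1 <- function(x) {
  check_bessel_arg(x)
  out <- numeric(length(x))
  small <- x < BESSEL_ASYMPTOTIC_CUTOFF
  if (any(small)) out[small] <- besselJ(x[small], 1)
  if (any(!small)) out[!small] <- bessel_asym(x[!small], 1, .J1_ASYM)
  out
}

# McMahon asymptotic guess for the n-th positive zero of J0.
mcmahon_j0_zero <- function(n) {
  b <- (n - 0.25) * pi
  b + 1 / (8 * b) - 124 / (3 * (8 * b)^3) + 120928 / (15 * (8 * b)^5) -
    401743168 / (105 * (8 * b)^7)
}

#' Zeros of the Bessel function J0
#'
#' Computes the first `n_max` positive zeros of `J0` together with the Hankel
#' weights `1 / J1(root)^2` used by the inverse finite Hankel transform.
#' Roots come from a McMahon asymptotic initial guess polished by Newton
#' iteration (`J0' = -J1`), which scales to tens of thousands of roots.
#'
#' At `precision_bits = 53` everything is done in double precision in R. For
#' higher working precision (e.g. 113 for quadruple, 237 for octuple) the
#' roots are refined by the arbitrary-precision backend (see
#' [hp_available()]) and returned both as doubles and as full-precision
#' decimal strings in the `root_str` column.
#'
#' Tables are cached in memory per `(n_max, precision_bits)`;
#' [write_root_table()] / [read_root_table()] persist them as plain text.
#'
#' @param n_max Number of roots (>= 1).
#' @param precision_bits Working precision of the root computation. Default 53
#'   (IEEE double).
#' @return A tibble of class `root_table` with columns `n`, `root`, `weight`
#'   (and `root_str` when `precision_bits > 53`), plus attributes `n_max`
#'   and `precision_bits`.
#' @export
#' @examples
#' rt <- j0_zeros(5)
#' rt$root[1]  # 2.404825...
j0_zeros <- function(n_max, precision_bits = 53) {
  stopifnot(length(n_max) == 1, n_max >= 1)
  n_max <- as.integer(n_max)
  key <- sprintf("%d_%d", n_max, precision_bits)
  hit <- .lf_cache$roots[[key]]
  if (!is.null(hit)) return(hit)

  # Reuse the longest cached double table rather than recomputing.
  if (precision_bits == 53) {
    for (k in names(.lf_cache$roots)) {
      parts <- as.integer(strsplit(k, "_")[[1]])
      if (parts[2] == 53 && parts[1] >= n_max) {
        out <- .lf_cache$roots[[k]][seq_len(n_max), ]
        attr(out, "n_max") <- n_max
        attr(out, "precision_bits") <- 53
        .lf_cache$roots[[key]] <- out
        return(out)
      }
    }
  }

  n <- seq_len(n_max)
  x <- mcmahon_j0_zero(n)
  for (it in 1:3) x <- x + bessel_j0(x) / bessel_j1(x)

  if (precision_bits > 53) {
    ref <- hp_refine_roots(n_max, precision_bits)
    out <- tibble(n = n, root = ref$root, weight = 1 / bessel_j1(ref$root)^2,
                  root_str = ref$root_str)
  } else {
    out <- tibble(n = n, root = x, weight = 1 / bessel_j1(x)^2)
  }
  class(out) <- c("root_table", class(out))
  attr(out, "n_max") <- n_max
  attr(out, "precision_bits") <- precision_bits
  .lf_cache$roots[[key]] <- out
  out
}

#' Persist or load a root table as plain text
#'
#' The format is one root per line in full precision, preceded by a header
#' line `n_max precision_bits`.
#'
#' @param table A `root_table` from [j0_zeros()].
#' @param path File path.
#' @return `write_root_table()` returns `path` invisibly; `read_root_table()`
#'   returns a `root_table`.
#' @export
write_root_table <- function(table, path) {
  stopifnot(inherits(table, "root_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", attr(table, "n_max"), attr(table, "precision_bits")), con)
  if ("root_str" %in% names(table)) {
    writeLines(table[["root_str"]], con)
  } else {
    writeLines(formatC(table$root, digits = 17, format = "g"), con)
  }
  invisible(path)
}

#' @rdname write_root_table
#' @export
read_root_table <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]])
  n_max <- hdr[[1]]
  precision_bits <- hdr[[2]]
  vals <- lines[-1]
  root <- as.numeric(vals)
  out <- tibble(n = seq_len(n_max), root = root, weight = 1 / bessel_j1(root)^2)
  if (precision_bits > 53) out$root_str <- vals
  class(out) <- c("root_table", class(out))
  attr(out, "n_max") <- n_max
  attr(out, "precision_bits") <- precision_bits
  out
}
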