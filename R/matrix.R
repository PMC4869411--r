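#' Build the 3-stage annual projection matrix
#'
#' The annual life cycle has three stages — 1 = seed, 2 = cotyledonous
#' plant, 3 = flowering plant — and exactly four demographic transitions:
#' seed dormancy/mortality `d` (seed -> seed), germination `g`
#' (seed -> cotyledon), survival to flowering `s` (cotyledon -> flowering),
#' and fecundity `f` (flowering -> seed). The matrix is
#' \deqn{A = \begin{pmatrix} d & 0 & f \\ g & 0 & 0 \\ 0 & s & 0
#'   \end{pmatrix}}
#' so the population vector (seeds, cotyledons, flowerers) is projected one
#' year ahead by `A %*% n`.
#'
#' @param rates a `vital_rates` object (see [estimate_vital_rates()]), or a
#'   list with elements `d`, `g`, `s`, `f`.
#' @param labels optional named list of design labels (`biotype`,
#'   `selection`, `replicate`, `population_id`, or a pooled-level tag);
#'   taken from `rates$labels` when present.
#' @return a 3x3 matrix of class `projection_matrix` with stage dimnames
#'   and a `labels` attribute.
#' @examples
#' A <- build_matrix(list(d = 0, g = 0.5, s = 0.8, f = 312.5))
#' lambda1(A)  # 5, since (0.5 * 0.8 * 312.5)^(1/3) = 5
#' @export
build_matrix <- function(rates, labels = NULL) {
  d <- rates$d; g <- rates$g; s <- rates$s; f <- rates$f
  stopifnot(is.numeric(d), is.numeric(g), is.numeric(s), is.numeric(f))
  if (any(c(d, g, s, f) < 0)) stop("vital rates must be nonnegative")
  if (any(c(d, g, s) > 1 + 1e-12))
    stop("d, g, s are probabilities and must be <= 1")
  if (d + g > 1 + 1e-12)
    stop("infeasible rates: d + g = ", d + g, " exceeds 1 ",
         "(seeds cannot both stay and leave with total probability > 1)")
  A <- matrix(c(d, g, 0,
                0, 0, s,
                f, 0, 0), nrow = 3, ncol = 3,
              dimnames = list(STAGES, STAGES))
  if (is.null(labels) && !is.null(rates$labels)) labels <- rates$labels
  attr(A, "labels") <- labels
  class(A) <- c("projection_matrix", class(A))
  A
}

#' @export
print.projection_matrix <- function(x, ...) {
  lb <- attr(x, "labels")
  if (!is.null(lb))
    cat("Projection matrix [", paste(unlist(lb), collapse = " / "), "]\n",
        sep = "")
  print(unclass_matrix(x), ...)
  invisible(x)
}

unclass_matrix <- function(A) {
  attr(A, "labels") <- NULL
  class(A) <- "matrix"
  A
}

# TRUE when A has (at most) the canonical 4-transition skeleton
has_skeleton <- function(A) {
  structural <- matrix(FALSE, 3, 3)
  structural[1, 1] <- structural[2, 1] <- structural[3, 2] <-
    structural[1, 3] <- TRUE
  nrow(A) == 3 && ncol(A) == 3 && all(A[!structural] == 0)
}

skeleton_rates <- function(A) {
  list(d = A[1, 1], g = A[2, 1], s = A[3, 2], f = A[1, 3])
}

# Real positive dominant root of lambda^3 - d lambda^2 - g s f = 0,
# the characteristic polynomial of the 4-transition skeleton.
lambda_cubic <- function(d, g, s, f) {
  k <- g * s * f
  if (k == 0) return(d)
  roots <- polyroot(c(-k, 0, -d, 1))
  re <- Re(roots)[abs(Im(roots)) < 1e-8 * max(1, Mod(roots))]
  cand <- re[re > 0]
  if (length(cand) == 0L) stop("no real positive root of characteristic cubic")
  lam <- max(cand)
  # one Newton polish: p(x) = x^3 - d x^2 - k
  for (i in 1:3) lam <- lam - (lam^3 - d * lam^2 - k) / (3 * lam^2 - 2 * d * lam)
  lam
}

#' Dominant eigenvalue, stable stage distribution, reproductive values
#'
#' Computes the eigen-triple of a nonnegative projection matrix: the
#' dominant eigenvalue `lambda` (the asymptotic annual growth multiplier),
#' the right eigenvector `w` normalized to sum to 1 (the stable stage
#' distribution), and the left eigenvector `v` scaled so that the scalar
#' product `<w, v> = 1` (stage-specific reproductive values).
#'
#' For the canonical 4-transition skeleton the authoritative `lambda` is
#' the real positive root of the characteristic cubic
#' \eqn{\lambda^3 - d\lambda^2 - gsf = 0} and the eigenvectors have closed
#' forms (`w` proportional to `(1, g/lambda, gs/lambda^2)`, `v`
#' proportional to `(1, sf/lambda^2, f/lambda)`). The skeleton with `d = 0`
#' is imprimitive — it has complex eigenvalues of the same modulus as the
#' dominant root — which is why the real cubic root is used rather than a
#' naive spectral-radius pick. For general nonnegative matrices a numeric
#' eigendecomposition is used, with the residual
#' \eqn{\|Aw - \lambda w\|_\infty} checked against `tol`.
#'
#' A reducible matrix with `g = 0` or `f = 0` (the life cycle cannot loop)
#' yields `lambda = d` with a reducibility warning.
#'
#' @param A a `projection_matrix` or any square nonnegative matrix.
#' @param tol eigen residual tolerance (default `1e-9`).
#' @return object of class `eigen_triple`: list with `lambda`, `w`, `v`,
#'   `A`, and `reducible` flag.
#' @export
eigen_analyze <- function(A, tol = 1e-9) {
  A_ <- unclass_matrix(as.matrix(A))
  if (nrow(A_) != ncol(A_)) stop("matrix must be square")
  if (any(A_ < 0)) stop("projection matrix must be nonnegative")

  reducible <- FALSE
  if (has_skeleton(A_)) {
    r <- skeleton_rates(A_)
    lam <- lambda_cubic(r$d, r$g, r$s, r$f)
    if (r$g * r$s * r$f == 0) {
      reducible <- TRUE
      warning("reducible life cycle (g, s or f is zero): lambda = d = ", lam)
    }
    if (lam > 0) {
      # closed forms hold for the skeleton whenever lambda > 0
      w <- c(1, r$g / lam, r$g * r$s / lam^2)
      v <- c(1, r$s * r$f / lam^2, r$f / lam)
    } else {
      w <- c(1, 0, 0)
      v <- c(1, 0, 0)
    }
  } else {
    e <- eigen(A_)
    mod <- Mod(e$values)
    real_ok <- abs(Im(e$values)) < 1e-8 * max(1, max(mod)) &
      Re(e$values) >= -1e-12
    if (!any(real_ok)) stop("no real nonnegative eigenvalue found")
    i <- which(real_ok)[which.max(Re(e$values)[real_ok])]
    lam <- Re(e$values[i])
    w <- Re(e$vectors[, i])
    if (sum(w) < 0) w <- -w
    et <- eigen(t(A_))
    j <- which.min(abs(et$values - lam))
    v <- Re(et$vectors[, j])
    if (sum(v) < 0) v <- -v
    resid <- max(abs(A_ %*% w - lam * w))
    if (resid > tol * max(1, lam)) {
      stop("eigen residual ", format(resid), " exceeds tolerance")
    }
  }
  w <- w / sum(w)
  sc <- sum(w * v)
  if (abs(sc) > 0) v <- v / sc
  structure(list(lambda = lam, w = w, v = v, A = A_, reducible = reducible),
            class = "eigen_triple")
}

#' @export
print.eigen_triple <- function(x, digits = 4, ...) {
  cat("Eigenanalysis of projection matrix\n")
  cat("  lambda =", format(x$lambda, digits = digits), "\n")
  cat("  stable stage distribution w:",
      paste(format(x$w, digits = digits), collapse = "  "), "\n")
  cat("  reproductive values v:     ",
      paste(format(x$v, digits = digits), collapse = "  "), "\n")
  if (x$reducible) cat("  [reducible life cycle]\n")
  invisible(x)
}

#' Population growth rate lambda
#'
#' Dominant-eigenvalue accessor. For a `vital_rates` or `projection_matrix`
#' argument the full eigenanalysis is performed internally.
#'
#' @param x a `projection_matrix`, `eigen_triple`, `vital_rates`, or plain
#'   nonnegative matrix.
#' @return numeric scalar, the asymptotic per-year growth multiplier.
#' @export
lambda1 <- function(x) {
  if (inherits(x, "eigen_triple")) return(x$lambda)
  if (inherits(x, "vital_rates")) x <- build_matrix(x)
  suppressWarnings(eigen_analyze(x)$lambda)
}

#' Sensitivity and elasticity matrices
#'
#' The sensitivity of lambda to matrix element \eqn{a_{ij}} is
#' \eqn{s_{ij} = \partial\lambda/\partial a_{ij} = v_i w_j / \langle
#' w, v\rangle} where `w` and `v` are the dominant right and left
#' eigenvectors. Elasticities are proportional sensitivities,
#' \eqn{e_{ij} = (a_{ij}/\lambda) s_{ij}}; they are zero wherever
#' \eqn{a_{ij} = 0} and sum to 1 over the structural nonzeros.
#'
#' @param A a `projection_matrix` (or square nonnegative matrix); ignored
#'   when `e` is supplied.
#' @param e optionally, a precomputed [eigen_analyze()] result.
#' @return object of class `perturbation`: list with `S` (full sensitivity
#'   matrix, defined on every entry including structural zeros), `E`
#'   (elasticity matrix), and `lambda`.
#' @export
perturbation <- function(A = NULL, e = NULL) {
  if (is.null(e)) e <- eigen_analyze(A)
  if (e$lambda == 0) stop("lambda = 0: elasticities undefined")
  S <- outer(e$v, e$w) / sum(e$w * e$v)
  E <- (e$A / e$lambda) * S
  dimnames(S) <- dimnames(E) <-
    if (nrow(e$A) == 3) list(STAGES, STAGES) else NULL
  structure(list(S = S, E = E, lambda = e$lambda), class = "perturbation")
}

#' @export
print.perturbation <- function(x, digits = 4, ...) {
  cat("Sensitivities (d lambda / d a_ij), lambda =",
      format(x$lambda, digits = digits), "\n")
  print(round(x$S, digits))
  cat("Elasticities (sum to 1 over nonzero transitions)\n")
  print(round(x$E, digits))
  invisible(x)
}

#' Write / read a projection matrix as plain text
#'
#' Row-major whitespace-delimited 3x3 values preceded by one `#` header
#' line carrying the design labels, so archived matrices can be transcribed
#' by hand.
#'
#' @param A a `projection_matrix`.
#' @param path file path.
#' @export
write_matrix <- function(A, path) {
  lb <- attr(A, "labels")
  header <- paste("#", if (is.null(lb)) "unlabelled" else
    paste(names(lb), unlist(lb), sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(unclass_matrix(A), digits = 15), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @param path file path of a matrix written by [write_matrix()] (or
#'   transcribed in the same layout).
#' @return `read_matrix`: a `projection_matrix`.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- lines[startsWith(trimws(lines), "#")][1]
  body <- lines[!startsWith(trimws(lines), "#")]
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) != 9L) stop("expected 9 matrix values in ", path)
  A <- matrix(vals, nrow = 3, byrow = TRUE, dimnames = list(STAGES, STAGES))
  labels <- NULL
  if (!is.na(header)) {
    toks <- strsplit(trimws(sub("^#\\s*", "", header)), "\\s+")[[1]]
    kv <- strsplit(toks, "=", fixed = TRUE)
    kv <- kv[vapply(kv, length, integer(1)) == 2L]
    if (length(kv) > 0L) {
      labels <- stats::setNames(
        lapply(kv, `[[`, 2L), vapply(kv, `[[`, 1L, FUN.VALUE = character(1)))
      if (!is.null(labels$replicate))
        labels$replicate <- as.integer(labels$replicate)
    }
  }
  attr(A, "labels") <- labels
  class(A) <- c("projection_matrix", class(A))
  A
}

#' Long-format view of a projection matrix
#'
#' @param A a `projection_matrix`.
#' @return data frame with columns `i`, `j`, `from`, `to`, `value`.
#' @export
matrix_to_long <- function(A) {
  M <- unclass_matrix(A)
  data.frame(i = rep(1:3, times = 3), j = rep(1:3, each = 3),
             from = rep(STAGES, each = 3), to = rep(STAGES, times = 3),
             value = as.vector(M), stringsAsFactors = FALSE)
}
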