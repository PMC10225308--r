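#' Column-standardize a matrix
#'
#' Centers each column to mean 0 and scales it to SD 1 (denominator `N - 1`).
#' Canonical correlations are invariant to the denominator convention; the
#' sample (`N - 1`) convention is used throughout.
#'
#' @param x Numeric matrix or data frame of numeric columns.
#' @return A numeric matrix with standardized columns.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  const <- !is.finite(sds) | sds < .Machine$double.eps^0.5
  if (any(const)) {
    nm <- colnames(x)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
    stop("constant column(s) cannot be standardized: ",
         paste(nm[const], collapse = ", "), call. = FALSE)
  }
  scale(x)
}

# symmetric inverse square root, with optional ridge and pseudo-inverse
# fallback for rank-deficient correlation matrices
inv_sqrt_sym <- function(S, ridge = 0, pseudo_inverse = FALSE, label = "x") {
  if (ridge > 0) S <- S + diag(ridge, nrow(S))
  ee <- eigen(S, symmetric = TRUE)
  tol <- max(ee$values) * 1e-10
  keep <- ee$values > tol
  if (!all(keep) && !pseudo_inverse)
    stop(sprintf(paste0("within-set correlation matrix of the %s set is ",
                        "singular; enable pseudo_inverse = TRUE or set a ",
                        "small ridge"), label), call. = FALSE)
  v <- ee$vectors[, keep, drop = FALSE]
  v %*% diag(1 / sqrt(ee$values[keep]), sum(keep)) %*% t(v)
}

#' Canonical correlation analysis with dimension-reduction tests
#'
#' Fits a canonical correlation analysis between a predictor set `x` (e.g.
#' age and regional dopamine D2-like binding potentials) and a criterion set
#' `y` (e.g. the five behavioral error measures). Both sets are standardized;
#' the canonical correlations and weights come from the singular value
#' decomposition of \eqn{R_{xx}^{-1/2} R_{xy} R_{yy}^{-1/2}}. Standardized
#' coefficients are the weights applied to the z-scored variables (each
#' canonical variate has unit variance); structure coefficients are the
#' correlations of each observed variable with its own set's variate. Signs
#' are fixed so the criterion variable with the largest absolute structure
#' coefficient loads positively on every function (see [orient_signs()]).
#'
#' Sequential dimension-reduction tests (Wilks' lambda with Rao's F
#' approximation) for roots `k..s` are computed with
#' [wilks_dimension_tests()].
#'
#' @param x Predictor matrix or data frame (N x p), numeric, no missing
#'   values.
#' @param y Criterion matrix or data frame (N x q).
#' @param ridge Non-negative ridge added to the within-set correlation
#'   matrices before inversion (default 0).
#' @param pseudo_inverse Use a pseudo-inverse when a within-set correlation
#'   matrix is rank deficient (default `FALSE`: rank deficiency is an error).
#' @param permutations If positive, also compute a permutation p-value for
#'   the full model by freely permuting the rows of `y` and recomputing the
#'   full-model Wilks lambda (small-sample diagnostic; off by default).
#'
#' @return An object of class `dopacca` with elements
#'   `cancor` (canonical correlations), `r_squared`, `xcoef`/`ycoef`
#'   (standardized coefficients, one column per function),
#'   `xstructure`/`ystructure` (structure coefficients), `scores_x`/`scores_y`
#'   (canonical variate scores), `dimension_tests` (data frame: roots, wilks,
#'   F, df1, df2, p_value), `perm_p` (if requested), and the inputs' labels.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3)
#' y <- cbind(x[, 1] + rnorm(20, 0, 0.5), rnorm(20))
#' fit <- dopacca(x, y)
#' fit
#' @export
dopacca <- function(x, y, ridge = 0, pseudo_inverse = FALSE,
                    permutations = 0) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  if (nrow(x) != nrow(y))
    stop("'x' and 'y' must have the same number of rows", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values must be excluded before fitting", call. = FALSE)
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (n <= max(p, q) + 1L)
    stop("need N > max(p, q) + 1 observations", call. = FALSE)

  zx <- standardize(x)
  zy <- standardize(y)
  fit <- cca_core(zx, zy, ridge = ridge, pseudo_inverse = pseudo_inverse)

  out <- list(
    cancor = fit$cancor,
    r_squared = fit$cancor^2,
    xcoef = fit$xcoef, ycoef = fit$ycoef,
    xstructure = fit$xstructure, ystructure = fit$ystructure,
    scores_x = zx %*% fit$xcoef,
    scores_y = zy %*% fit$ycoef,
    n = n, p = p, q = q,
    x_names = colnames(x), y_names = colnames(y),
    call = match.call()
  )
  class(out) <- "dopacca"
  out <- orient_signs(out)
  # guard against exactly-unit correlations (e.g. duplicated sets): the Wilks
  # statistic degenerates to 0 there, so clamp just inside the open interval
  out$dimension_tests <-
    wilks_dimension_tests(pmin(out$r_squared, 1 - 1e-12), n, p, q)

  if (permutations > 0) {
    lam_obs <- prod(1 - out$r_squared)
    lam_perm <- vapply(seq_len(permutations), function(i) {
      zyp <- zy[sample.int(n), , drop = FALSE]
      prod(1 - cca_core(zx, zyp, ridge = ridge,
                        pseudo_inverse = pseudo_inverse)$cancor^2)
    }, numeric(1))
    out$perm_p <- (1 + sum(lam_perm <= lam_obs)) / (permutations + 1)
    out$permutations <- permutations
  }
  out
}

# decomposition on already-standardized matrices
cca_core <- function(zx, zy, ridge = 0, pseudo_inverse = FALSE) {
  n <- nrow(zx)
  rxx <- crossprod(zx) / (n - 1)
  ryy <- crossprod(zy) / (n - 1)
  rxy <- crossprod(zx, zy) / (n - 1)
  rxx_is <- inv_sqrt_sym(rxx, ridge, pseudo_inverse, "predictor")
  ryy_is <- inv_sqrt_sym(ryy, ridge, pseudo_inverse, "criterion")
  sv <- svd(rxx_is %*% rxy %*% ryy_is)
  s <- min(ncol(zx), ncol(zy))
  d <- pmin(pmax(sv$d[seq_len(s)], 0), 1)
  a <- rxx_is %*% sv$u[, seq_len(s), drop = FALSE]
  b <- ryy_is %*% sv$v[, seq_len(s), drop = FALSE]
  dimnames(a) <- list(colnames(zx), paste0("F", seq_len(s)))
  dimnames(b) <- list(colnames(zy), paste0("F", seq_len(s)))
  list(cancor = d, xcoef = a, ycoef = b,
       xstructure = rxx %*% a, ystructure = ryy %*% b)
}

#' Fix the sign indeterminacy of canonical variates
#'
#' Canonical variate pairs are determined only up to a joint sign flip. For
#' each function, both variates are flipped together so that the criterion
#' variable with the largest absolute structure coefficient loads positively;
#' the canonical correlations are unchanged. If the largest loading is
#' exactly zero the first-listed criterion variable's sign is used instead
#' (and a message is emitted).
#'
#' @param fit A `dopacca` object.
#' @return The same object with deterministically oriented signs.
#' @export
orient_signs <- function(fit) {
  stopifnot(inherits(fit, "dopacca"))
  for (j in seq_along(fit$cancor)) {
    loads <- fit$ystructure[, j]
    top <- which.max(abs(loads))
    ref <- loads[top]
    if (ref == 0) {
      message("orient_signs: all criterion loadings are zero for function ",
              j, "; using the first-listed variable's coefficient sign")
      ref <- fit$ycoef[1L, j]
    }
    if (ref < 0) {
      fit$xcoef[, j] <- -fit$xcoef[, j]
      fit$ycoef[, j] <- -fit$ycoef[, j]
      fit$xstructure[, j] <- -fit$xstructure[, j]
      fit$ystructure[, j] <- -fit$ystructure[, j]
      if (!is.null(fit$scores_x)) {
        fit$scores_x[, j] <- -fit$scores_x[, j]
        fit$scores_y[, j] <- -fit$scores_y[, j]
      }
    }
  }
  fit
}

#' Sequential Wilks-lambda dimension-reduction tests (Rao's F)
#'
#' For each starting root `k = 1..s` (s = min(p, q)), tests whether canonical
#' functions `k` through `s` jointly carry shared variance. The statistic is
#' \eqn{\Lambda_k = \prod_{i \ge k} (1 - R^2_{c,i})}, transformed to an
#' approximately F-distributed quantity by Rao's approximation with deflated
#' set sizes \eqn{p_k = p - k + 1}, \eqn{q_k = q - k + 1}:
#' \deqn{t_k = \sqrt{\frac{p_k^2 q_k^2 - 4}{p_k^2 + q_k^2 - 5}}, \quad
#'   df_1 = p_k q_k, \quad df_2 = m\,t_k - p_k q_k / 2 + 1, \quad
#'   F = \frac{1 - \Lambda_k^{1/t_k}}{\Lambda_k^{1/t_k}}
#'       \cdot \frac{df_2}{df_1}}
#' where \eqn{m = N - 3/2 - (p + q)/2} is held at the ORIGINAL set sizes for
#' every k, and \eqn{t_k = 1} when \eqn{p_k^2 + q_k^2 - 5 \le 0} (the
#' terminal 1 x 1 case). With N = 35 and p = q = 5 this convention yields
#' df2 = 94.373, 80.07, 65.86, 56.00, 29.00 for the five roots.
#'
#' @param r_squared Squared canonical correlations, descending, in `[0, 1)`.
#' @param n Number of observations (must exceed `p + q`).
#' @param p,q Number of variables in the predictor and criterion sets.
#'
#' @return Data frame with columns `roots` (label `"k to s"`), `wilks`, `F`,
#'   `df1`, `df2`, `p_value`.
#' @examples
#' wilks_dimension_tests(c(0.581, 0.351, 0.072, 0.028, 0.005), 35, 5, 5)
#' @export
wilks_dimension_tests <- function(r_squared, n, p, q) {
  s <- min(p, q)
  if (length(r_squared) != s)
    stop("expected ", s, " squared canonical correlations", call. = FALSE)
  if (any(r_squared < 0 | r_squared >= 1))
    stop("squared canonical correlations must lie in [0, 1)", call. = FALSE)
  if (n <= p + q)
    stop("N must exceed p + q for Rao's approximation (df2 would be ",
         "nonpositive)", call. = FALSE)
  m <- n - 3 / 2 - (p + q) / 2
  rows <- lapply(seq_len(s), function(k) {
    pk <- p - k + 1
    qk <- q - k + 1
    lambda <- prod(1 - r_squared[k:s])
    tk <- if (pk^2 + qk^2 - 5 > 0)
      sqrt((pk^2 * qk^2 - 4) / (pk^2 + qk^2 - 5)) else 1
    df1 <- pk * qk
    df2 <- m * tk - pk * qk / 2 + 1
    lam_t <- lambda^(1 / tk)
    Fstat <- (1 - lam_t) / lam_t * (df2 / df1)
    data.frame(roots = paste(k, "to", s), wilks = lambda, F = Fstat,
               df1 = df1, df2 = df2,
               p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regress age out of both variable sets
#'
#' Replaces every column of `x` (age itself is dropped) and `y` by the
#' residuals of its least-squares regression on age (with intercept), for the
#' robustness variant of the analysis in which age is removed as an
#' individual variable and instead partialled out of all variables.
#'
#' @param x Predictor matrix/data frame containing an `age` column (or pass
#'   `age` separately and no such column).
#' @param y Criterion matrix/data frame.
#' @param age Numeric age vector; defaults to `x[, "age"]`.
#'
#' @return List with residualized matrices `x` (age column removed) and `y`.
#' @export
residualize_age <- function(x, y, age = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(age)) {
    if (!"age" %in% colnames(x))
      stop("no 'age' column in 'x' and no 'age' argument given",
           call. = FALSE)
    age <- x[, "age"]
    x <- x[, setdiff(colnames(x), "age"), drop = FALSE]
  }
  if (stats::sd(age) < .Machine$double.eps^0.5)
    stop("age is constant; cannot residualize", call. = FALSE)
  resid_on_age <- function(mat) {
    d <- cbind(1, age)
    res <- mat - d %*% solve(crossprod(d), crossprod(d, mat))
    sds <- apply(res, 2L, stats::sd)
    flat <- sds < .Machine$double.eps^0.5 * pmax(apply(abs(mat), 2L, max), 1)
    if (any(flat))
      warning("residualized column(s) are (near-)constant: ",
              paste(colnames(mat)[flat], collapse = ", "), call. = FALSE)
    res
  }
  list(x = resid_on_age(x), y = resid_on_age(y))
}

#' @export
print.dopacca <- function(x, digits = 3, ...) {
  cat("Canonical correlation analysis (", x$p, " predictor vs ",
      x$q, " criterion variables, N = ", x$n, ")\n\n", sep = "")
  cat("Canonical correlations:\n")
  print(round(x$cancor, digits))
  cat("\nDimension reduction tests (Wilks' lambda, Rao's F):\n")
  dt <- x$dimension_tests
  dt$wilks <- round(dt$wilks, digits)
  dt$F <- round(dt$F, digits)
  dt$df2 <- round(dt$df2, 2)
  dt$p_value <- signif(dt$p_value, digits)
  print(dt, row.names = FALSE)
  if (!is.null(x$perm_p))
    cat("\nPermutation p (full model, ", x$permutations, " permutations): ",
        signif(x$perm_p, digits), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dopacca <- function(object, ...) {
  structure(list(fit = object), class = "summary.dopacca")
}

#' @export
print.summary.dopacca <- function(x, digits = 2, ...) {
  fit <- x$fit
  print(fit)
  for (j in seq_along(fit$cancor)) {
    cat("\nFunction ", j, " (r = ", round(fit$cancor[j], 2),
        "): Coef, r_s, r_s^2\n", sep = "")
    tab <- rbind(
      data.frame(set = "predictor", variable = fit$x_names,
                 Coef = fit$xcoef[, j], r_s = fit$xstructure[, j]),
      data.frame(set = "criterion", variable = fit$y_names,
                 Coef = fit$ycoef[, j], r_s = fit$ystructure[, j])
    )
    tab$r_s_sq <- tab$r_s^2
    tab$Coef <- round(tab$Coef, digits)
    tab$r_s <- round(tab$r_s, digits)
    tab$r_s_sq <- round(tab$r_s_sq, digits)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Extract canonical coefficients
#'
#' @param object A `dopacca` fit.
#' @param set `"x"` (predictor) or `"y"` (criterion) set.
#' @param type `"standardized"` weights or `"structure"` correlations.
#' @param ... Unused.
#' @return Matrix, one column per canonical function.
#' @export
coef.dopacca <- function(object, set = c("x", "y"),
                         type = c("standardized", "structure"), ...) {
  set <- match.arg(set); type <- match.arg(type)
  slot <- paste0(set, if (type == "standardized") "coef" else "structure")
  object[[slot]]
}

#' Plot the first canonical variate pair
#'
#' Scatter plot of the criterion variate against the predictor variate for
#' one canonical function, with the canonical correlation in the title.
#'
#' @param x A `dopacca` fit.
#' @param which Function index to plot (default 1).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dopacca <- function(x, which = 1L, ...) {
  graphics::plot(x$scores_x[, which], x$scores_y[, which],
                 xlab = sprintf("Predictor variate %d", which),
                 ylab = sprintf("Criterion variate %d", which),
                 main = sprintf("Canonical function %d (r = %.2f)", which,
                                x$cancor[which]), ...)
  graphics::abline(stats::lm(x$scores_y[, which] ~ x$scores_x[, which]),
                   lty = 2)
  invisible(x)
}
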