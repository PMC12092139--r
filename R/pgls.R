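#' Brownian-motion covariance matrix from a phylogeny
#'
#' Under Brownian trait evolution at unit rate, the covariance between
#' two tips equals the branch length shared on their root-to-tip paths
#' (the depth of their most recent common ancestor); the variance of a
#' tip is its root-to-tip distance. Non-ultrametric trees are accepted
#' as given.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return Species x species covariance matrix (tip-label dimnames).
#' @export
brownian_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  C <- ape::vcv.phylo(tree)
  if (all(C == 0)) stop("zero-length tree gives a singular covariance")
  C
}

#' Generalized least squares with a known error covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 C)`, by the GLS normal
#' equations `beta-hat = (X' C^-1 X)^-1 X' C^-1 y`, solved through the
#' Cholesky factorisation of `C` (never an explicit inverse): the model
#' is whitened by the factor and fitted by QR. Coefficient standard
#' errors use the residual variance estimate with `n - p` degrees of
#' freedom; p-values are two-sided t-tests.
#'
#' @param y Response vector.
#' @param X Design matrix (include the intercept column explicitly, or
#'   use [fit_all_metrics()] which builds it).
#' @param C Symmetric positive-definite covariance (e.g. from
#'   [brownian_covariance()]); row order must match `y`.
#' @param rcond_tol Reciprocal-condition threshold below which `X'C^-1X`
#'   is declared singular (default `1e-12`).
#' @return A `"pgls_fit"` list: `coefficients` data frame (`estimate`,
#'   `se`, `t`, `p`), `sigma2`, `df_residual`, `logdet_C`.
#' @export
pgls_fit <- function(y, X, C, rcond_tol = 1e-12) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n)
  if (n <= p) stop("need more observations than coefficients")
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C))) stop("C must be symmetric")
  R <- tryCatch(chol(C), error = function(e)
    stop("C is not positive definite: ", conditionMessage(e)))
  wy <- backsolve(R, y, transpose = TRUE)   # whiten: solve(t(R), .)
  wX <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(wX)
  if (rcond(XtX) < rcond_tol)
    stop("singular design: rank(X' C^-1 X) deficient (rcond = ",
         format(rcond(XtX)), ")")
  qrX <- qr(wX)
  beta <- qr.coef(qrX, wy)
  resid <- wy - wX %*% beta
  sigma2 <- sum(resid^2) / (n - p)
  cov_beta <- sigma2 * chol2inv(chol(XtX))
  se <- sqrt(diag(cov_beta))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  structure(list(
    coefficients = data.frame(
      term = colnames(X) %||% paste0("b", seq_len(p)),
      estimate = as.numeric(beta), se = se, t = as.numeric(tval),
      p = as.numeric(pval)),
    sigma2 = sigma2, df_residual = n - p,
    logdet_C = 2 * sum(log(diag(R)))), class = "pgls_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit (Brownian covariance)\n")
  print(x$coefficients, row.names = FALSE)
  cat("residual variance:", format(x$sigma2),
      " df:", x$df_residual, "\n")
  invisible(x)
}

#' PGLS of every syndrome metric on the selfing indicator
#'
#' For each numeric metric column, fits
#' `metric ~ intercept + selfing` by [pgls_fit()] with the Brownian
#' covariance of the supplied tree. Species rows are aligned to tip
#' labels; the fit is invariant to consistent relabelling. Metrics are
#' fitted independently; no multiple-testing correction is applied, and
#' the output flags this.
#'
#' @param traits Data frame with columns `species`, `selfing` (0/1) and
#'   one or more numeric metric columns (species means).
#' @param tree Rooted `phylo` whose tip labels equal `traits$species`.
#' @param metrics_cols Metric columns to fit (default: every numeric
#'   column except `selfing`).
#' @return Data frame with one row per metric: `metric`,
#'   `selfing_estimate`, `se`, `t`, `p`, `sign` (direction of the selfing
#'   effect) and attribute `"note"` on multiple testing.
#' @export
fit_all_metrics <- function(traits, tree, metrics_cols = NULL) {
  stopifnot(all(c("species", "selfing") %in% names(traits)))
  if (!setequal(tree$tip.label, traits$species))
    stop("tree tips and trait species must match")
  traits <- traits[match(tree$tip.label, traits$species), , drop = FALSE]
  if (anyNA(traits$selfing)) stop("missing selfing indicator")
  if (is.null(metrics_cols)) {
    metrics_cols <- setdiff(names(traits)[vapply(traits, is.numeric,
                                                 logical(1))], "selfing")
  }
  if (length(metrics_cols) < 1) stop("no metric columns to fit")
  C <- brownian_covariance(tree)
  X <- cbind(intercept = 1, selfing = as.numeric(traits$selfing))
  rows <- lapply(metrics_cols, function(mc) {
    fit <- pgls_fit(traits[[mc]], X, C)
    cf <- fit$coefficients[fit$coefficients$term == "selfing", ]
    data.frame(metric = mc, selfing_estimate = cf$estimate, se = cf$se,
               t = cf$t, p = cf$p, sign = sign(cf$estimate))
  })
  out <- do.call(rbind, rows)
  attr(out, "note") <- "per-metric fits; no multiple-testing correction applied"
  out
}
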