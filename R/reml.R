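#' Fit a Gaussian mixed model with arbitrary covariance structures by REML
#'
#' Restricted maximum likelihood for
#' `y = X beta + sum_k u_k + e`, `u_k ~ N(0, s2_k K_k)`,
#' `e ~ N(0, s2_e I)`, where each `K_k` is a known symmetric PSD matrix
#' (pedigree relationship, position-wise IBD, ...).  This is the Gaussian
#' linear-mixed-model reading of a hierarchical model with correlated
#' random effects, fitted by maximizing the restricted (residual)
#' log-likelihood over variance components on the log scale, with
#' boundary handling at zero.
#'
#' The likelihood is evaluated block-wise over the connected components of
#' the combined relatedness graph (pairs with a nonzero entry in any
#' `K_k`), which is exact and fast for family-structured data.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (full column rank), or `NULL` for
#'   an intercept.
#' @param structures Named list of `n x n` symmetric PSD matrices.
#' @param start Optional starting variances (length `m + 1`, structures
#'   then residual).
#' @param tol Convergence tolerance on the restricted log-likelihood
#'   (default 1e-8).
#' @param max_eval Evaluation cap for the optimizer (default 2000).
#' @param check_psd Verify each structure is PSD via a ridged Cholesky
#'   (default `TRUE`; scans switch it off after checking once).
#' @return Object of class `vc_fit`: `sigma2` (named estimates, structures
#'   plus `"residual"`; components below `1e-8 * total` are snapped to the
#'   zero boundary), `beta`, `loglik` (restricted), `converged`, `n`, `p`.
#' @export
fit_vc_model <- function(y, X = NULL, structures, start = NULL,
                         tol = 1e-8, max_eval = 2000, check_psd = TRUE) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y dimensions disagree")
  if (qr(X)$rank < ncol(X)) stop("X is not of full column rank")
  if (!length(structures)) stop("at least one covariance structure needed")
  if (is.null(names(structures)))
    names(structures) <- paste0("K", seq_along(structures))
  for (nm in names(structures)) {
    K <- structures[[nm]]
    if (!is.matrix(K) || any(dim(K) != n))
      stop("structure ", nm, " has wrong dimension")
    if (max(abs(K - t(K))) > 1e-8) stop("structure ", nm, " is not symmetric")
    if (check_psd && inherits(try(chol(K + diag(1e-7 * max(1, max(abs(K))),
                                                n)), silent = TRUE),
                              "try-error"))
      stop("structure ", nm, " is not positive semi-definite")
  }
  blocks <- vc_blocks(structures)
  prep <- vc_split(y, X, structures, blocks)
  fit <- vc_optim(prep, n, ncol(X), m = length(structures),
                  start = start, scale = stats::var(y), tol = tol,
                  max_eval = max_eval)
  info <- .vc_fit_info(log(pmax(fit$sigma2, 1e-300)), prep, n, ncol(X))
  structure(list(
    sigma2 = stats::setNames(fit$sigma2,
                             c(names(structures), "residual")),
    beta = stats::setNames(drop(info$beta), colnames(X)),
    loglik = info$loglik, converged = fit$converged,
    n = n, p = ncol(X)), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("REML variance components (restricted loglik ",
      sprintf("%.4f", x$loglik), "):\n", sep = "")
  print(round(x$sigma2, 6))
  cat("fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

# connected components of the union sparsity pattern of the structures
vc_blocks <- function(structures) {
  n <- nrow(structures[[1]])
  adj <- Reduce(`|`, lapply(structures, function(K) abs(K) > 1e-12))
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(seq_len(n), comp)
}

# split data into independent blocks for the C++ evaluator
vc_split <- function(y, X, structures, blocks) {
  lapply(blocks, function(ix) {
    list(y = y[ix], X = X[ix, , drop = FALSE],
         K = lapply(structures, function(K) K[ix, ix, drop = FALSE]))
  })
}

# log-scale Nelder-Mead over variance components, multi-start
vc_optim <- function(prep, n, p, m, start, scale, tol, max_eval) {
  starts <- list(log(rep(scale / (m + 1), m + 1)))
  if (!is.null(start))
    starts <- c(list(log(pmax(start, scale * 1e-8))), starts)
  best <- NULL
  objective <- function(par) .vc_nll(par, prep, n, p)
  for (s0 in starts) {
    opt <- stats::optim(s0, objective, method = "Nelder-Mead",
                        control = list(reltol = tol / 100,
                                       maxit = max_eval))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  sigma2 <- exp(best$par)
  sigma2[sigma2 < 1e-8 * sum(sigma2)] <- 0
  list(sigma2 = sigma2, converged = best$convergence == 0,
       loglik = -best$value)
}

#' Narrow-sense heritability from fitted variance components
#'
#' `h2 = s2_polygenic / (s2_polygenic + s2_qtl + s2_residual)`; the QTL
#' term enters the denominator when the fit includes one.  Fixed effects
#' (e.g., strain) are not part of the phenotypic variance here.
#'
#' @param fit A `vc_fit` whose structures include `"polygenic"` (and
#'   optionally `"qtl"`).
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!"polygenic" %in% names(fit$sigma2))
    stop("fit has no 'polygenic' component")
  tot <- sum(fit$sigma2)
  if (tot <= 0) stop("all variance components are zero")
  unname(fit$sigma2["polygenic"] / tot)
}

#' QTL variance as a fraction of genetic and of total variance
#'
#' @param fit A `vc_fit` with components named `"polygenic"` and `"qtl"`.
#' @return Named numeric: `fraction_of_genetic =
#'   s2_q / (s2_q + s2_a)` and `fraction_of_total =
#'   s2_q / (s2_q + s2_a + s2_e)`.
#' @export
qtl_variance_fractions <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!all(c("polygenic", "qtl") %in% names(fit$sigma2)))
    stop("fit must include 'polygenic' and 'qtl' components")
  s2a <- fit$sigma2[["polygenic"]]
  s2q <- fit$sigma2[["qtl"]]
  s2e <- fit$sigma2[["residual"]]
  if (s2a + s2q + s2e <= 0) stop("zero total variance")
  g <- if (s2q + s2a > 0) s2q / (s2q + s2a) else 0
  c(fraction_of_genetic = g,
    fraction_of_total = s2q / (s2q + s2a + s2e))
}
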