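#' SNP heritability by average-information REML
#'
#' Fits the single-GRM animal model y = X beta + g + e with
#' g ~ N(0, K sigma_g^2) and e ~ N(0, I sigma_e^2) by AI-REML. The kinship
#' matrix is eigendecomposed once, so each iteration works with a diagonal
#' covariance; updates use the average-information matrix with step-halving
#' to keep the restricted log-likelihood non-decreasing, and variance
#' components are truncated at a small positive bound (1e-6 x var(y)).
#' The standard error of h^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2) comes
#' from the delta method on the inverse AI matrix at convergence.
#'
#' @param y Phenotype vector (complete).
#' @param K Kinship matrix from \code{\link{compute_grm}}.
#' @param X Fixed-effect design matrix (default intercept only).
#' @param max_iter Maximum AI iterations (default 100).
#' @param tol_param Convergence tolerance on the relative parameter change
#'   (default 1e-8).
#' @param tol_loglik Convergence tolerance on the log-likelihood change
#'   (default 1e-10).
#' @return Object of class \code{heritability_fit}: \code{sigma_g2},
#'   \code{sigma_e2}, \code{h2}, \code{se_h2},
#'   \code{log_restricted_likelihood}, \code{n_iterations},
#'   \code{converged}, \code{loglik_trace}.
#' @export
reml_h2 <- function(y, K, X = NULL, max_iter = 100, tol_param = 1e-8,
                    tol_loglik = 1e-10) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (anyNA(y)) stop("phenotype vector must be complete")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)

  # normalize the relationship matrix to unit mean diagonal so sigma_g^2 is
  # on the phenotypic scale and h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2) is
  # the genetic fraction of phenotypic variance
  cbar <- mean(diag(as.matrix(K)))
  if (cbar <= 0) stop("kinship matrix has non-positive mean diagonal")
  eig <- eigen(unclass(K) / cbar, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  if (stats::sd(d) < 1e-10 * max(mean(abs(d)), 1e-12)) {
    warning("kinship matrix is (numerically) proportional to the identity; ",
            "sigma_g^2 and sigma_e^2 are not separable")
    return(structure(list(sigma_g2 = NA_real_, sigma_e2 = NA_real_,
                          h2 = NA_real_, se_h2 = NA_real_,
                          log_restricted_likelihood = NA_real_,
                          n_iterations = 0L, converged = FALSE,
                          loglik_trace = numeric(0)),
                     class = "heritability_fit"))
  }
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  p <- ncol(X)

  vary <- stats::var(y)
  bound <- 1e-6 * vary

  # REML pieces at (sg, se), with V = sg*d + se (diagonal in eigenspace)
  eval_state <- function(sg, se) {
    v <- sg * d + se
    w <- 1 / v
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    XtWX_inv <- solve(XtWX)
    XtWy <- drop(crossprod(XtW, yt))
    beta <- drop(XtWX_inv %*% XtWy)
    Py <- w * (yt - drop(Xt %*% beta))
    ll <- -0.5 * (sum(log(v)) + determinant(XtWX)$modulus[1] +
                    sum(yt * Py))
    list(v = v, w = w, XtW = XtW, XtWX_inv = XtWX_inv, Py = Py, ll = ll)
  }
  # quadratic form t' P s for vectors in eigenspace
  Pdot <- function(st, t_vec, s_vec) {
    wt <- st$w * t_vec
    ws <- st$w * s_vec
    sum(t_vec * ws) - drop(crossprod(crossprod(st$XtW, t_vec),
                                     st$XtWX_inv %*%
                                       crossprod(st$XtW, s_vec)))
  }

  sg <- se <- vary / 2
  st <- eval_state(sg, se)
  trace <- st$ll
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    # tr(P D) and tr(P): tr(V^-1 A) - tr((X'V^-1X)^-1 X'V^-1 A V^-1 X)
    M <- st$XtWX_inv %*% crossprod(st$XtW, st$XtW * d)
    trPD <- sum(st$w * d) - sum(diag(M))
    M2 <- st$XtWX_inv %*% crossprod(st$XtW, st$XtW)
    trP <- sum(st$w) - sum(diag(M2))
    # y' P V_g P y = (Py)' D (Py), y' P P y = (Py)'(Py)
    DPy <- d * st$Py
    score <- c(-0.5 * (trPD - sum(DPy * st$Py)),
               -0.5 * (trP - sum(st$Py * st$Py)))

    AI <- matrix(0, 2, 2)
    AI[1, 1] <- 0.5 * Pdot(st, DPy, DPy)
    AI[1, 2] <- AI[2, 1] <- 0.5 * Pdot(st, DPy, st$Py)
    AI[2, 2] <- 0.5 * Pdot(st, st$Py, st$Py)

    delta <- tryCatch(solve(AI, score), error = function(e) score / max(trP, 1))
    step <- 1
    repeat {
      sg_new <- max(sg + step * delta[1], bound)
      se_new <- max(se + step * delta[2], bound)
      st_new <- eval_state(sg_new, se_new)
      if (st_new$ll >= st$ll - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    dll <- st_new$ll - st$ll
    dpar <- max(abs(c(sg_new - sg, se_new - se))) / vary
    sg <- sg_new
    se <- se_new
    st <- st_new
    trace <- c(trace, st$ll)
    if (dpar < tol_param || abs(dll) < tol_loglik) {
      converged <- TRUE
      break
    }
  }

  h2 <- sg / (sg + se)
  # delta-method SE from the inverse AI matrix at the optimum
  se_h2 <- NA_real_
  AI <- matrix(0, 2, 2)
  DPy <- d * st$Py
  AI[1, 1] <- 0.5 * Pdot(st, DPy, DPy)
  AI[1, 2] <- AI[2, 1] <- 0.5 * Pdot(st, DPy, st$Py)
  AI[2, 2] <- 0.5 * Pdot(st, st$Py, st$Py)
  cov_par <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(cov_par)) {
    grad <- c(se, -sg) / (sg + se)^2
    v <- drop(t(grad) %*% cov_par %*% grad)
    if (is.finite(v) && v >= 0) se_h2 <- sqrt(v)
  }

  structure(list(sigma_g2 = sg, sigma_e2 = se, h2 = h2, se_h2 = se_h2,
                 log_restricted_likelihood = st$ll,
                 n_iterations = iter, converged = converged,
                 loglik_trace = trace),
            class = "heritability_fit")
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf("AI-REML heritability fit (%s, %d iterations)\n",
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_iterations))
  cat(sprintf("  sigma_g^2 = %.5f, sigma_e^2 = %.5f\n",
              x$sigma_g2, x$sigma_e2))
  cat(sprintf("  h^2 = %.3f +/- %.3f\n", x$h2, x$se_h2))
  invisible(x)
}
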