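#' Principal component analysis of assessment items with varimax rotation
#'
#' Runs PCA on the item correlation matrix, retains the leading
#' \code{n_components} components, and applies Kaiser-normalized varimax
#' rotation. Components are labelled by the item group with the largest mean
#' absolute rotated loading (stranger-approach items -> SF, treat/play items
#' -> FM, novel-object items -> NSF, umbrella items -> SR), and each
#' component is signed so that its defining items load positively, i.e. a
#' higher component score means a more confident, less fearful dog.
#'
#' @param behavior Data frame of item scores (an \code{id} column is ignored).
#' @param n_components Components to retain (default 4).
#' @param item_groups Named list mapping component labels to item names; the
#'   default is the standard approach-test + reactivity-test layout.
#' @return An object of class \code{component_result} with \code{loadings}
#'   (unrotated), \code{rotated_loadings}, \code{rotation} (orthonormal
#'   matrix), \code{explained_variance} and \code{cumulative_variance}
#'   fractions, \code{kmo}, \code{scores} (regression-method component
#'   scores, mean 0), \code{labels}, and the item correlation matrix.
#' @export
fit_pca_varimax <- function(behavior, n_components = 4,
                            item_groups = .item_groups()) {
  items <- .item_matrix(behavior)
  sds <- apply(items, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant assessment item(s): ",
         paste(colnames(items)[sds == 0], collapse = ", "))
  }
  if (ncol(items) < 2 || n_components > ncol(items)) {
    stop("need at least 2 items and n_components <= number of items")
  }
  R <- stats::cor(items)
  eig <- eigen(R, symmetric = TRUE)
  if (eig$values[n_components] <= 1e-10) {
    stop("item correlation matrix has fewer than n_components ",
         "non-degenerate dimensions")
  }
  loadings <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(n_components)]), n_components)
  rownames(loadings) <- colnames(items)

  rot <- stats::varimax(loadings, normalize = TRUE, eps = 1e-10)
  rotated <- loadings %*% rot$rotmat

  labels <- .label_components(rotated, item_groups)
  # sign convention: defining (confident-scored) items load positively
  for (k in seq_len(n_components)) {
    grp <- item_groups[[labels[k]]]
    grp <- intersect(grp, rownames(rotated))
    if (length(grp) > 0 && sum(rotated[grp, k]) < 0) {
      rotated[, k] <- -rotated[, k]
      rot$rotmat[, k] <- -rot$rotmat[, k]
    }
  }
  colnames(rotated) <- labels
  colnames(loadings) <- paste0("PC", seq_len(n_components))

  expl <- colSums(rotated^2) / ncol(items)
  Z <- scale(items)
  scores <- Z %*% solve(R, rotated)
  scores <- sweep(scores, 2, colMeans(scores))
  rownames(scores) <- rownames(items)

  structure(list(loadings = loadings,
                 rotated_loadings = rotated,
                 rotation = rot$rotmat,
                 explained_variance = expl,
                 cumulative_variance = cumsum(sort(expl, decreasing = TRUE)),
                 kmo = compute_kmo(behavior),
                 scores = scores,
                 labels = labels,
                 correlation = R,
                 item_groups = item_groups),
            class = "component_result")
}

.item_matrix <- function(behavior) {
  df <- behavior[, setdiff(colnames(behavior), "id"), drop = FALSE]
  as.matrix(df)
}

.label_components <- function(rotated, item_groups) {
  n_components <- ncol(rotated)
  score <- sapply(item_groups, function(grp) {
    grp <- intersect(grp, rownames(rotated))
    if (length(grp) == 0) return(rep(-Inf, n_components))
    colMeans(abs(rotated[grp, , drop = FALSE]))
  })  # components x groups
  score <- matrix(score, nrow = n_components,
                  dimnames = list(NULL, names(item_groups)))
  labels <- character(n_components)
  taken <- character(0)
  # assign greedily by strongest remaining (component, group) affinity
  for (step in seq_len(n_components)) {
    sc <- score
    sc[, taken] <- -Inf
    sc[labels != "", ] <- -Inf
    best <- which(sc == max(sc), arr.ind = TRUE)[1, ]
    labels[best[1]] <- colnames(score)[best[2]]
    taken <- c(taken, colnames(score)[best[2]])
  }
  labels
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO = sum of squared off-diagonal correlations divided by that sum plus
#' the sum of squared off-diagonal anti-image partial correlations
#' q_ij = -P_ij / sqrt(P_ii P_jj), where P is the inverse of the item
#' correlation matrix. The two-item case reduces to r^2 / (r^2 + q^2) with q
#' the (degenerate) partial correlation, which the same formula covers.
#'
#' @param behavior Data frame of item scores.
#' @return KMO in \[0, 1\].
#' @export
compute_kmo <- function(behavior) {
  items <- .item_matrix(behavior)
  R <- stats::cor(items)
  P <- tryCatch(solve(R), error = function(e) {
    stop("item correlation matrix is singular; KMO undefined")
  })
  d <- 1 / sqrt(diag(P))
  Q <- -P * outer(d, d)
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Regression-method component scores
#'
#' Computes S = Z R^{-1} Lambda for standardized items Z, item correlation
#' matrix R, and rotated loading matrix Lambda, then centers each column.
#'
#' @param result A fitted \code{\link{fit_pca_varimax}} object.
#' @param behavior Item scores for the dogs to score (columns must match the
#'   items the result was fitted on).
#' @return Dogs x components score matrix with column means 0.
#' @export
component_scores <- function(result, behavior) {
  items <- .item_matrix(behavior)
  if (!identical(colnames(items), rownames(result$rotated_loadings))) {
    stop("item columns do not match the fitted loading matrix")
  }
  Z <- scale(items)
  S <- Z %*% solve(result$correlation, result$rotated_loadings)
  sweep(S, 2, colMeans(S))
}

#' Adjust a behavioral phenotype for significant fixed effects
#'
#' Screens each candidate fixed effect (facility, sex, size class, age, and
#' the first two principal components of the variance-standardized genomic
#' relationship matrix) one at a time in a linear model; candidates with a
#' marginal F-test p-value below \code{alpha} are retained and the phenotype
#' is regressed on all of them jointly. The residuals of that joint fit are
#' the adjusted phenotype. When no candidate is significant the adjusted
#' phenotype is the mean-centered raw score. Factor levels observed exactly
#' once are dropped (with a warning) before testing.
#'
#' @param scores Numeric vector, one phenotype value per dog.
#' @param samples Sample table with any of \code{facility}, \code{sex},
#'   \code{size_class}, \code{age}.
#' @param grm_pcs Optional n x >=2 matrix of GRM principal components.
#' @param alpha Retention threshold for the marginal screen (default 0.05).
#' @return An object of class \code{adjusted_phenotype}: \code{residuals},
#'   \code{report} (candidate, p-value, retained flag), \code{retained},
#'   \code{n_dropped_rows}.
#' @export
adjust_phenotype <- function(scores, samples, grm_pcs = NULL, alpha = 0.05) {
  scores <- as.numeric(scores)
  stopifnot(length(scores) == nrow(samples))
  dat <- data.frame(y = scores)
  for (v in intersect(c("facility", "sex", "size_class"), names(samples))) {
    f <- factor(samples[[v]])
    singles <- names(which(table(f) == 1L))
    if (length(singles) > 0) {
      warning("dropping single-observation level(s) of ", v, ": ",
              paste(singles, collapse = ", "))
      f[f %in% singles] <- NA
    }
    dat[[v]] <- droplevels(f)
  }
  if ("age" %in% names(samples)) dat$age <- samples$age
  if (!is.null(grm_pcs)) {
    dat$PC1 <- grm_pcs[, 1]
    if (ncol(grm_pcs) >= 2) dat$PC2 <- grm_pcs[, 2]
  }

  candidates <- setdiff(names(dat), "y")
  # a candidate with a single observed level/value carries no contrast
  informative <- vapply(candidates, function(v) {
    length(unique(dat[[v]][!is.na(dat[[v]])])) >= 2
  }, logical(1))
  candidates <- candidates[informative]
  pvals <- vapply(candidates, function(v) {
    fit <- stats::lm(stats::reformulate(v, "y"), data = dat)
    an <- stats::anova(fit)
    an[v, "Pr(>F)"]
  }, numeric(1))
  retained <- candidates[pvals < alpha]

  cc <- rep(TRUE, nrow(dat))
  if (length(retained) > 0) {
    cc <- stats::complete.cases(dat[, c("y", retained), drop = FALSE])
    fit <- stats::lm(stats::reformulate(retained, "y"),
                     data = dat[cc, , drop = FALSE])
    resid_full <- rep(NA_real_, nrow(dat))
    resid_full[cc] <- stats::residuals(fit)
  } else {
    resid_full <- scores - mean(scores)
    fit <- NULL
  }

  structure(list(residuals = resid_full,
                 report = data.frame(candidate = candidates,
                                     p_value = pvals,
                                     retained = candidates %in% retained,
                                     row.names = NULL),
                 retained = retained,
                 model = fit,
                 n_dropped_rows = sum(!cc)),
            class = "adjusted_phenotype")
}

#' @export
print.adjusted_phenotype <- function(x, ...) {
  cat("Fixed-effect adjustment\n")
  cat("  retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
                     else "(none; centered raw scores)", "\n")
  print(x$report, digits = 4)
  invisible(x)
}
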