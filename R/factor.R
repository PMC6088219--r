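#' Extract the psychological problems profile from its three indicators
#'
#' Standardizes the distress, anxiety and depression columns, takes the
#' dominant eigenvector of their 3 x 3 correlation matrix, and returns
#' unit-variance factor scores together with the percentage of total
#' variance the factor explains. The factor sign is fixed so all loadings
#' are positive: a higher profile score means worse mental health.
#'
#' @param psych_indicators Data frame or matrix with 3 complete numeric
#'   columns (distress, anxiety, depression).
#' @return A `factor_solution` list: `eigenvalues`, `n_factors`, `loadings`,
#'   `variance_explained` (percent), `communalities`, `factor_scores`
#'   (mean 0, variance 1), `assignment`.
#' @export
extract_profile <- function(psych_indicators) {
  Y <- as.matrix(psych_indicators)
  if (ncol(Y) != 3L) stop("exactly 3 indicator columns required", call. = FALSE)
  if (anyNA(Y)) stop("complete cases required", call. = FALSE)
  if (any(apply(Y, 2, stats::sd) == 0)) {
    stop("constant indicator column", call. = FALSE)
  }
  Z <- scale(Y)
  R <- stats::cor(Y)
  eig <- eigen(R, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  if (any(v1 < 0)) v1 <- abs(v1) * sign(sum(v1))  # degenerate sign mix guard
  scores <- as.numeric(Z %*% v1)
  scores <- (scores - mean(scores)) / stats::sd(scores)
  loadings <- matrix(v1 * sqrt(eig$values[1]), ncol = 1,
                     dimnames = list(colnames(Y), "profile"))
  structure(list(
    eigenvalues = eig$values,
    n_factors = 1L,
    loadings = loadings,
    variance_explained = 100 * eig$values[1] / 3,
    communalities = as.numeric(loadings^2),
    factor_scores = matrix(scores, ncol = 1,
                           dimnames = list(NULL, "profile")),
    assignment = stats::setNames(rep(1L, 3), colnames(Y))
  ), class = "factor_solution")
}

#' Varimax criterion of a loading matrix
#'
#' Sum over factors of the variance of the squared loadings (raw,
#' unnormalized form). Orthogonal rotation toward simple structure
#' maximizes this quantity.
#'
#' @param loadings Numeric matrix (indicators x factors).
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  L2 <- loadings^2
  sum(apply(L2, 2, function(col) mean(col^2) - mean(col)^2))
}

#' Varimax rotation
#'
#' Orthogonally rotates a loading matrix to maximize the varimax criterion
#' by cyclic planar (Kaiser) rotations: each factor pair is rotated by the
#' closed-form optimal angle `atan2(num, den) / 4`, and sweeps repeat
#' until every pairwise angle falls below `tol`. The `atan2` form resolves
#' the balanced-loadings saddle point at which gradient-style updates
#' stall. Orthogonality of the accumulated rotation is verified to `tol`;
#' the criterion is nondecreasing across sweeps.
#'
#' @param loadings Numeric matrix with at least 2 columns.
#' @param tol Convergence / orthogonality tolerance.
#' @param max_iter Maximum number of sweeps over all factor pairs.
#' @param normalize Kaiser-normalize rows (divide by the square root of the
#'   communality) before rotation, default `TRUE`.
#' @return List with `loadings` (rotated matrix), `rotmat`, `iterations`
#'   and `trajectory` (criterion value after each sweep).
#' @export
varimax_rotate <- function(loadings, tol = 1e-10, max_iter = 1000L,
                           normalize = TRUE) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k < 2L) stop("at least 2 factors required", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be positive", call. = FALSE)
  n <- nrow(L)
  comm <- sqrt(rowSums(L^2))
  W <- if (normalize) L / pmax(comm, 1e-12) else L
  R <- diag(k)
  trajectory <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    max_phi <- 0
    for (p in seq_len(k - 1)) {
      for (q in (p + 1):k) {
        x <- W[, p]; y <- W[, q]
        u <- x^2 - y^2; v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        num <- 2 * sum(u * v) - 2 * A * B / n
        den <- sum(u^2 - v^2) - (A^2 - B^2) / n
        if (abs(num) < 1e-300 && abs(den) < 1e-300) next
        phi <- atan2(num, den) / 4
        max_phi <- max(max_phi, abs(phi))
        if (abs(phi) > 1e-15) {
          G <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
          W[, c(p, q)] <- W[, c(p, q)] %*% G
          R[, c(p, q)] <- R[, c(p, q)] %*% G
        }
      }
    }
    trajectory <- c(trajectory, varimax_criterion(W))
    if (max_phi < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf(
      "varimax did not converge in %d sweeps; criterion trajectory: %s",
      max_iter,
      paste(signif(utils::tail(trajectory, 5), 6), collapse = " -> ")))
  }
  Lr <- L %*% R
  ortho_err <- max(abs(crossprod(R) - diag(k)))
  if (ortho_err > max(tol, 1e-8)) {
    warning(sprintf("rotation matrix orthogonality error %.2e", ortho_err))
  }
  list(loadings = Lr, rotmat = R, iterations = length(trajectory),
       trajectory = trajectory)
}

#' Exploratory factor analysis of the 11 stressor domains
#'
#' Computes the correlation matrix of the domain scores, extracts
#' `n_factors` principal components (with `"auto"`, the eigenvalue > 1
#' rule, reported alongside the scree data), varimax-rotates the loadings,
#' and assigns each domain to the factor carrying its larger absolute
#' rotated loading. Variance explained is the cumulative percentage of
#' total variance carried by the retained components, invariant to column
#' scaling (correlation-based) and to the rotation.
#'
#' @param domain_scores Data frame or matrix of 11 numeric columns.
#' @param n_factors Integer, or `"auto"` for the eigenvalue > 1 rule.
#' @return A `factor_solution` list; `loadings` are rotated when 2 or more
#'   factors are retained, `assignment` maps domain to factor index (factors
#'   ordered by rotated sum of squared loadings), and `scree` holds the
#'   eigenvalues for plotting.
#' @export
efa_stressors <- function(domain_scores, n_factors = "auto") {
  Y <- as.matrix(domain_scores)
  if (anyNA(Y)) stop("complete cases required", call. = FALSE)
  p <- ncol(Y)
  R <- stats::cor(Y)
  kappa_R <- kappa(R, exact = TRUE)
  if (!all(is.finite(R)) || kappa_R > 1e12) {
    stop(sprintf("correlation matrix is singular (condition number %.3e)",
                 kappa_R), call. = FALSE)
  }
  eig <- eigen(R, symmetric = TRUE)
  auto_degenerate <- FALSE
  if (identical(n_factors, "auto")) {
    n_factors <- sum(eig$values > 1)
    if (n_factors == 0L || max(eig$values) - min(eig$values) < 1e-8) {
      auto_degenerate <- TRUE
      n_factors <- max(n_factors, 1L)
    }
  }
  n_factors <- as.integer(n_factors)
  stopifnot(n_factors >= 1L, n_factors <= p)

  L <- eig$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(n_factors)]), n_factors)
  rownames(L) <- colnames(Y)
  rotmat <- diag(n_factors)
  if (n_factors >= 2L) {
    rot <- varimax_rotate(L)
    L <- rot$loadings
    rotmat <- rot$rotmat
    ord <- order(colSums(L^2), decreasing = TRUE)
    L <- L[, ord, drop = FALSE]
    # fix each factor's sign so its dominant loadings are positive
    for (k in seq_len(ncol(L))) if (sum(L[, k]^3) < 0) L[, k] <- -L[, k]
  }
  colnames(L) <- paste0("factor", seq_len(n_factors))

  scores <- scale(Y) %*% solve(R, L)  # regression (Thurstone) method
  colnames(scores) <- colnames(L)

  structure(list(
    eigenvalues = eig$values,
    n_factors = n_factors,
    loadings = L,
    rotmat = rotmat,
    variance_explained = 100 * sum(eig$values[seq_len(n_factors)]) / p,
    communalities = rowSums(L^2),
    factor_scores = scores,
    assignment = stats::setNames(apply(abs(L), 1, which.max), colnames(Y)),
    scree = data.frame(component = seq_len(p), eigenvalue = eig$values),
    auto_degenerate = auto_degenerate
  ), class = "factor_solution")
}

#' Descriptive comparison across quartiles of the profile score
#'
#' Splits the sample at the sample quartiles of the profile scores (ties go
#' to the lower quartile) and tabulates mean (SD) for quantitative
#' variables or n (\%) for categorical ones in each quartile group, with a
#' one-way ANOVA or chi-square p-value per variable.
#'
#' @param scored Data frame of participant variables.
#' @param profile_scores Numeric vector, one score per row of `scored`.
#' @param variables Columns of `scored` to summarize; default all.
#' @return List with `table` (long-format data frame: variable, level,
#'   Q1--Q4 cells, test, p_value) and `quartile` (the group index per
#'   participant).
#' @export
quartile_descriptives <- function(scored, profile_scores,
                                  variables = names(scored)) {
  stopifnot(nrow(scored) == length(profile_scores),
            !anyNA(profile_scores))
  qs <- stats::quantile(profile_scores, c(0.25, 0.5, 0.75))
  # ties to the lower quartile: intervals closed on the right
  grp <- 4L - findInterval(-profile_scores, sort(-qs))
  grp <- factor(grp, levels = 1:4, labels = paste0("Q", 1:4))

  rows <- list()
  for (v in variables) {
    x <- scored[[v]]
    if (is.numeric(x)) {
      cells <- vapply(levels(grp), function(g) {
        xi <- x[grp == g]
        sprintf("%.2f (%.2f)", mean(xi), stats::sd(xi))
      }, character(1))
      p <- if (stats::sd(x) == 0) NA_real_ else {
        stats::anova(stats::aov(x ~ grp))[["Pr(>F)"]][1]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, t(cells),
        test = if (is.na(p)) "none (constant)" else "anova",
        p_value = p, zero_cell = FALSE
      )
    } else {
      x <- factor(x)
      tab <- table(x, grp)
      zero_cell <- any(tab == 0)
      p <- if (nlevels(x) < 2L) NA_real_ else {
        suppressWarnings(stats::chisq.test(tab)$p.value)
      }
      if (zero_cell && !is.na(p)) {
        warning(sprintf("zero cell in chi-square table for '%s'", v))
      }
      coltot <- colSums(tab)
      for (lev in rownames(tab)) {
        cells <- sprintf("%d (%.1f%%)", tab[lev, ],
                         100 * tab[lev, ] / pmax(coltot, 1))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev, t(stats::setNames(cells, levels(grp))),
          test = if (is.na(p)) "none (degenerate)" else "chi-square",
          p_value = p, zero_cell = zero_cell
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(table = out, quartile = grp)
}
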