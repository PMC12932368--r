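#' Fit the testcross (ridge-regression BLUP) model
#'
#' Fits `y = 1 mu + Z alpha + e` with i.i.d. normal marker effects
#' `alpha ~ N(0, sigma2_alpha I)` and residuals `e ~ N(0, sigma2_e I)`.
#' The variance ratio `lambda = sigma2_e / sigma2_alpha` is estimated by
#' exact single-component REML via a spectral decomposition of the marker
#' covariance `Z Z'` (one-dimensional likelihood optimisation), unless a
#' fixed `lambda` is supplied. Marker effects are the ridge BLUPs
#' `alpha_hat = Z' (Z Z' + lambda I)^{-1} (y - 1 mu_hat)`, identical to the
#' marker-space solution `(Z'Z + lambda I)^{-1} Z' (y - 1 mu_hat)`.
#'
#' @param y phenotype vector (length n >= 2).
#' @param Z `n x m` marker matrix coded 0/2 (homozygous lines).
#' @param lambda optional fixed ridge parameter; if `NULL`, REML-estimated.
#' @return a `testcross_fit`: list with `mu`, `alpha` (length m),
#'   `var_components` (`c(var_alpha, var_e)`), `lambda`. A constant `y`
#'   yields `alpha = 0` with a `sparsecross_degenerate` warning.
#' @export
fit_testcross_model <- function(y, Z, lambda = NULL) {
  n <- length(y)
  stopifnot(n >= 2, is.matrix(Z), nrow(Z) == n, ncol(Z) >= 1)
  m <- ncol(Z)
  if (var(y) == 0) {
    warning(structure(class = c("sparsecross_degenerate", "warning",
                                "condition"),
                      list(message = "constant phenotypes; returning zero marker effects",
                           call = sys.call(-1))))
    return(structure(list(mu = y[1], alpha = rep(0, m),
                          var_components = c(var_alpha = 0, var_e = 0),
                          lambda = Inf, n = n, m = m),
                     class = "testcross_fit"))
  }
  K <- tcrossprod(Z)
  if (is.null(lambda)) {
    yc <- y - mean(y)
    SKS <- K - rep(colMeans(K), each = n)
    SKS <- SKS - rowMeans(SKS)
    eig <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
    xi <- pmax(eig$values[seq_len(n - 1)], 0)
    eta2 <- as.vector(crossprod(eig$vectors[, seq_len(n - 1), drop = FALSE],
                                yc))^2
    negll <- function(logd) {
      d <- exp(logd)
      ss <- sum(eta2 / (xi + d))
      0.5 * ((n - 1) * log(ss) + sum(log(xi + d)))
    }
    opt <- optimize(negll, c(-14, 14))
    lambda <- exp(opt$minimum)
    var_alpha <- sum(eta2 / (xi + lambda)) / (n - 1)
    var_e <- lambda * var_alpha
  } else {
    var_alpha <- NA_real_
    var_e <- NA_real_
  }
  Vi <- chol2inv(chol(K + lambda * diag(n)))
  one <- rep(1, n)
  mu <- sum(Vi %*% y) / sum(Vi)
  alpha <- as.vector(crossprod(Z, Vi %*% (y - mu)))
  structure(list(mu = mu, alpha = alpha,
                 var_components = c(var_alpha = var_alpha, var_e = var_e),
                 lambda = lambda, n = n, m = m),
            class = "testcross_fit")
}

#' Fit the hybrid pool-specific additive effects + dominance model
#'
#' Fits `y = 1 mu + Z1 a1 + Z2 a2 + W1 mu_d + W d* + e`, where `Z1`/`Z2`
#' hold the line and tester marker alleles (coded 0/1), `W` is the hybrid
#' heterozygosity incidence matrix (1 where line and tester alleles differ),
#' `W1 = rowSums(W)` carries the fixed mean dominance effect `mu_d`, and
#' `a1`, `a2`, `d*` are independent i.i.d. normal marker-effect vectors with
#' their own variances. Variance components are estimated by
#' average-information REML with an expectation-maximisation fallback step
#' whenever an AI update would leave the parameter space (capped at
#' `max_iter` iterations, relative tolerance `tol`); supplying
#' `var_components` skips estimation and solves the mixed model directly at
#' those values.
#'
#' Unidentifiable terms degrade gracefully: with a single tester `Z2` is
#' constant across rows, its variance cannot move (the projected covariance
#' is null) and its BLUP is exactly zero (absorbed into the intercept);
#' a constant `W1` column is dropped with a warning and `mu_d = 0`.
#'
#' @param y phenotype vector (length n).
#' @param Z1 `n x m` line marker alleles in \{0, 1\}.
#' @param Z2 `n x m` tester marker alleles in \{0, 1\}.
#' @param W optional `n x m` dominance incidence; derived from
#'   `Z1 != Z2` when `NULL`, asserted equal when supplied.
#' @param var_components optional fixed variances
#'   `c(var_a1, var_a2, var_d, var_e)`.
#' @param max_iter REML iteration cap.
#' @param tol relative convergence tolerance.
#' @return a `pool_fit`: `mu`, `mu_d`, `a1`, `a2`, `d_star`,
#'   `d_total = d_star + mu_d`, `var_components`, `converged`, `iterations`.
#' @export
fit_pool_specific_model <- function(y, Z1, Z2, W = NULL,
                                    var_components = NULL,
                                    max_iter = 200L, tol = 1e-6) {
  n <- length(y)
  stopifnot(is.matrix(Z1), is.matrix(Z2), nrow(Z1) == n, nrow(Z2) == n,
            ncol(Z1) == ncol(Z2))
  m <- ncol(Z1)
  W_derived <- 1L * (Z1 != Z2)
  if (is.null(W)) {
    W <- W_derived
  } else {
    if (!all(W %in% c(0, 1))) stop("W entries must be 0 or 1")
    if (!all(W == W_derived)) {
      stop("W is inconsistent with Z1/Z2 (heterozygous iff alleles differ)")
    }
  }
  zero_fit <- function(mu) {
    structure(list(mu = mu, mu_d = 0, a1 = rep(0, m), a2 = rep(0, m),
                   d_star = rep(0, m), d_total = rep(0, m),
                   var_components = c(var_a1 = 0, var_a2 = 0, var_d = 0,
                                      var_e = 0),
                   converged = TRUE, iterations = 0L),
              class = "pool_fit")
  }
  if (var(y) == 0 && is.null(var_components)) {
    warning(structure(class = c("sparsecross_degenerate", "warning",
                                "condition"),
                      list(message = "constant phenotypes; returning zero effects",
                           call = sys.call(-1))))
    return(zero_fit(y[1]))
  }
  w1 <- rowSums(W)
  X <- cbind(intercept = 1, het_count = w1)
  has_mud <- TRUE
  if (sd(w1) < 1e-12) {
    warning(structure(class = c("sparsecross_degenerate", "warning",
                                "condition"),
                      list(message = "heterozygosity count is constant; dropping mu_d",
                           call = sys.call(-1))))
    X <- X[, 1, drop = FALSE]
    has_mud <- FALSE
  }
  K <- list(tcrossprod(Z1), tcrossprod(Z2), tcrossprod(W))
  vy <- var(y)
  if (vy == 0) vy <- 1
  floor_v <- 1e-8 * vy
  kd <- vapply(K, function(k) mean(diag(k)), numeric(1))
  if (is.null(var_components)) {
    theta <- c(ifelse(kd > 0, (vy / 4) / pmax(kd, 1e-12), 0), vy / 4)
  } else {
    stopifnot(length(var_components) == 4, all(var_components >= 0),
              var_components[4] > 0)
    theta <- as.numeric(var_components)
  }
  p_fix <- ncol(X)
  mk <- c(m, m, m)
  estimate <- is.null(var_components)
  converged <- !estimate
  iter <- 0L
  # restricted log-likelihood and the projection quantities at theta
  reml_state <- function(th) {
    V <- th[4] * diag(n)
    for (k in 1:3) if (th[k] > 0) V <- V + th[k] * K[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) ch <- chol(V + 1e-8 * vy * diag(n))
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    XtViX_i <- solve(XtViX)
    P <- Vi - ViX %*% XtViX_i %*% t(ViX)
    Py <- as.vector(P %*% y)
    logl <- -0.5 * (2 * sum(log(diag(ch))) +
                      as.numeric(determinant(XtViX)$modulus) + sum(y * Py))
    list(logl = logl, Vi = Vi, P = P, Py = Py, XtViX_i = XtViX_i)
  }
  st <- reml_state(theta)
  while (estimate && !converged && iter < max_iter) {
    iter <- iter + 1L
    Tk <- c(vapply(K, function(k) sum(st$P * k), numeric(1)),
            sum(diag(st$P)))
    qk <- c(vapply(K, function(k) sum(st$Py * (k %*% st$Py)), numeric(1)),
            sum(st$Py^2))
    active <- c(Tk[1:3] > 1e-10 * n, TRUE)
    score <- -0.5 * (Tk - qk)
    vlist <- c(lapply(K, function(k) as.vector(k %*% st$Py)), list(st$Py))
    ai <- matrix(0, 4, 4)
    for (a in 1:4) for (b in a:4) {
      ai[a, b] <- ai[b, a] <- 0.5 * sum(vlist[[a]] * (st$P %*% vlist[[b]]))
    }
    # components pinned at the floor with downhill scores are held fixed
    # this iteration (constrained AI-REML), otherwise they poison the step
    pinned <- theta <= 1.01 * floor_v & score < 0
    idx <- which(active & !pinned)
    if (!length(idx)) { converged <- TRUE; break }
    step <- rep(0, 4)
    sub <- tryCatch(solve(ai[idx, idx, drop = FALSE], score[idx]),
                    error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(sub) && all(is.finite(sub))) {
      step[idx] <- sub
      # step-halving against the restricted likelihood
      for (h in 0:4) {
        cand <- pmax(theta + step / 2^h, ifelse(active, floor_v, theta))
        st2 <- reml_state(cand)
        if (st2$logl >= st$logl - 1e-10) { accepted <- TRUE; break }
      }
    }
    if (!accepted) {
      # EM step: never decreases the restricted likelihood
      denom <- c(mk, n - p_fix)
      step <- ifelse(active, theta^2 * (qk - Tk) / denom, 0)
      cand <- pmax(theta + step, ifelse(active, floor_v, theta))
      st2 <- reml_state(cand)
    }
    rel <- max(abs(cand - theta) / (abs(theta) + floor_v))
    theta <- cand
    st <- st2
    if (rel < tol) converged <- TRUE
  }
  Vi <- st$Vi
  XtViX_i <- st$XtViX_i
  Py <- st$Py
  beta <- as.vector(XtViX_i %*% crossprod(X, Vi %*% y))
  mu <- beta[1]
  mu_d <- if (has_mud) beta[2] else 0
  a1 <- theta[1] * as.vector(crossprod(Z1, Py))
  a2 <- theta[2] * as.vector(crossprod(Z2, Py))
  d_star <- theta[3] * as.vector(crossprod(W, Py))
  structure(list(mu = mu, mu_d = mu_d, a1 = a1, a2 = a2, d_star = d_star,
                 d_total = d_star + mu_d,
                 var_components = c(var_a1 = theta[1], var_a2 = theta[2],
                                    var_d = theta[3], var_e = theta[4]),
                 converged = converged, iterations = iter),
            class = "pool_fit")
}

#' GCA marker effects from pool-specific estimates
#'
#' Combines pool-specific additive effects and dominance effects with the
#' opposite pool's allele frequencies into GCA allele effects:
#' `alpha1 = (a1 + d (q2 - p2)) / 2` and `alpha2 = (a2 + d (q1 - p1)) / 2`,
#' with `d` the total dominance effect (`d_star + mu_d`).
#'
#' @param fit a `pool_fit`.
#' @param freqs_pool1 marker allele frequencies in pool 1 (the lines' pool).
#' @param freqs_pool2 marker allele frequencies in pool 2 (the testers').
#' @return a `gca_effects`: `alpha_pool1`, `alpha_pool2`, `freq_basis`.
#' @export
gca_marker_effects <- function(fit, freqs_pool1, freqs_pool2) {
  stopifnot(inherits(fit, "pool_fit"))
  m <- length(fit$a1)
  if (length(freqs_pool1) != m || length(freqs_pool2) != m) {
    stop("frequency vectors must match the number of markers")
  }
  if (any(freqs_pool1 < 0 | freqs_pool1 > 1) ||
      any(freqs_pool2 < 0 | freqs_pool2 > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  d <- fit$d_total
  structure(list(
    alpha_pool1 = 0.5 * (fit$a1 + d * (1 - 2 * freqs_pool2)),
    alpha_pool2 = 0.5 * (fit$a2 + d * (1 - 2 * freqs_pool1)),
    freq_basis = list(p1 = freqs_pool1, p2 = freqs_pool2)),
    class = "gca_effects")
}

#' Predict line GCA from marker effects
#'
#' Sums the products of marker effects and line marker genotypes.
#'
#' @param genotypes `n x m` marker dosages (0/2 for homozygous lines).
#' @param alpha marker-effect vector of length m.
#' @return numeric vector of GCA scores.
#' @export
predict_gca <- function(genotypes, alpha) {
  stopifnot(ncol(genotypes) == length(alpha))
  as.vector(genotypes %*% alpha)
}

#' Select the top lines on predicted GCA
#'
#' Ties are broken by ascending line index, making selection deterministic.
#'
#' @param lines a `line_pop`.
#' @param scores predicted GCA, one per line.
#' @param n_select number of lines to keep.
#' @return the selected `line_pop` (in ascending index order).
#' @export
select_parents <- function(lines, scores, n_select) {
  n <- n_ind(lines)
  stopifnot(length(scores) == n)
  if (n_select > n) stop("cannot select more lines than available")
  idx <- order(-scores, seq_len(n))[seq_len(n_select)]
  subset_lines(lines, sort(idx))
}
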