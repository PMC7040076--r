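# Feasible generalised least squares with a compound-symmetry (CS)
# within-group correlation and optional heteroscedastic residual SDs per
# stratum (e.g. per DOY or per stand), plus AIC-based structure selection.
#
# Estimation is moment-based feasible GLS rather than (RE)ML: iterate
# (i) GLS for beta given (rho, sigma_k), (ii) moment updates of sigma_k
# from stratum residual mean squares and of rho from mean within-group
# cross-products of standardised residuals. A proposed variance update
# that would lower the Gaussian log-likelihood is rejected, so the
# log-likelihood is non-decreasing across iterations by construction.

# log-likelihood, GLS beta and quadratic form under the CS model, all via
# the closed-form inverse of R = (1-rho)I + rho J per group
.cs_gls_pass <- function(y, X, group, sigma_i, rho) {
  p <- ncol(X)
  XtX <- matrix(0, p, p)
  Xty <- numeric(p)
  for (g in split(seq_along(y), group)) {
    m <- length(g)
    ys <- y[g] / sigma_i[g]
    Xs <- X[g, , drop = FALSE] / sigma_i[g]
    # R^-1 = a I + b J with a = 1/(1-rho), b = -rho/((1-rho)(1+(m-1)rho))
    a <- 1 / (1 - rho)
    b <- -rho / ((1 - rho) * (1 + (m - 1) * rho))
    cs_x <- colSums(Xs)
    XtX <- XtX + a * crossprod(Xs) + b * tcrossprod(cs_x)
    Xty <- Xty + a * crossprod(Xs, ys) + b * cs_x * sum(ys)
  }
  beta <- as.vector(solve(XtX, Xty))
  names(beta) <- colnames(X)
  beta
}

.cs_loglik <- function(y, X, beta, group, sigma_i, rho) {
  e <- y - as.vector(X %*% beta)
  ll <- -0.5 * length(y) * log(2 * pi)
  for (g in split(seq_along(y), group)) {
    m <- length(g)
    es <- e[g] / sigma_i[g]
    a <- 1 / (1 - rho)
    b <- -rho / ((1 - rho) * (1 + (m - 1) * rho))
    quad <- a * sum(es^2) + b * sum(es)^2
    logdetR <- (m - 1) * log(1 - rho) + log(1 + (m - 1) * rho)
    ll <- ll - 0.5 * (2 * sum(log(sigma_i[g])) + logdetR + quad)
  }
  ll
}

#' Feasible GLS with compound-symmetry correlation
#'
#' Fits y = X beta + e where observations within a group (e.g. a
#' measurement point) share a common correlation rho (compound symmetry)
#' and the residual SD may differ between strata (e.g. DOYs or stands,
#' the varIdent-style variance structure). With `cs = FALSE` the
#' correlation is fixed at 0; with `stratum = NULL` a single residual SD
#' is used; with both, the fit reduces exactly to OLS.
#'
#' @param y response vector.
#' @param X design matrix (full column rank; include the intercept
#'   column).
#' @param group factor/vector of group ids (within-group CS correlation).
#' @param stratum optional factor/vector of variance strata; `NULL` for a
#'   single stratum.
#' @param cs estimate the CS correlation (default TRUE); FALSE fixes
#'   rho = 0.
#' @param tol convergence tolerance on the maximum parameter change,
#'   default 1e-8.
#' @param max_iter maximum feasible-GLS iterations, default 100.
#' @return an object of class `gls_fit`: `beta`, `rho`, `sigma`
#'   (named per stratum), `fitted`, `residuals`, `logLik`, `AIC`,
#'   `pseudo_r2` (squared correlation of fitted and observed), `n_par`,
#'   `iterations`, `converged`, `logLik_path`.
#' @export
fit_gls_cs <- function(y, X, group, stratum = NULL, cs = TRUE,
                       tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(group) == n)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  group <- as.factor(group)
  single_stratum <- is.null(stratum)
  stratum <- if (single_stratum) factor(rep("all", n)) else as.factor(stratum)
  m_max <- max(table(group))
  eps <- 1e-6
  rho_lo <- if (m_max > 1) -1 / (m_max - 1) + eps else -1 + eps
  rho_hi <- 1 - eps

  # init at OLS
  beta <- qr.solve(X, y)
  rho <- 0
  e <- y - as.vector(X %*% beta)
  sigma_k <- c(tapply(e, stratum, function(r) sqrt(mean(r^2))))
  sigma_k[sigma_k <= 0 | !is.finite(sigma_k)] <- stats::sd(y) + 1e-12
  sigma_i <- as.numeric(sigma_k[as.character(stratum)])
  ll <- .cs_loglik(y, X, beta, group, sigma_i, rho)
  ll_path <- ll
  converged <- FALSE
  iter <- 0
  clipped <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1
    e <- y - as.vector(X %*% beta)
    # moment updates of the variance parameters
    new_sigma_k <- c(tapply(e, stratum, function(r) sqrt(mean(r^2))))
    new_sigma_k[new_sigma_k <= 0 | !is.finite(new_sigma_k)] <- 1e-12
    sig_i_new <- as.numeric(new_sigma_k[as.character(stratum)])
    new_rho <- 0
    if (cs) {
      z <- e / sig_i_new
      num <- 0; den <- 0
      for (g in split(seq_len(n), group)) {
        m <- length(g)
        if (m < 2) next
        s <- sum(z[g])
        num <- num + (s^2 - sum(z[g]^2)) / 2   # sum over pairs z_i z_j
        den <- den + m * (m - 1) / 2
      }
      if (den > 0) new_rho <- num / (den * mean(z^2))
      if (new_rho < rho_lo || new_rho > rho_hi) {
        new_rho <- min(max(new_rho, rho_lo), rho_hi)
        clipped <- TRUE
      }
    }
    new_beta <- .cs_gls_pass(y, X, group, sig_i_new, new_rho)
    new_ll <- .cs_loglik(y, X, new_beta, group, sig_i_new, new_rho)
    if (new_ll < ll - 1e-12) {
      converged <- TRUE  # reject a likelihood-decreasing update and stop
      break
    }
    delta <- max(abs(c(new_beta - beta, new_rho - rho,
                       sig_i_new - sigma_i)))
    beta <- new_beta; rho <- new_rho
    sigma_k <- new_sigma_k; sigma_i <- sig_i_new
    ll <- new_ll
    ll_path <- c(ll_path, ll)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (clipped)
    message("estimated rho clipped into the feasible interval (",
            signif(rho_lo, 3), ", ", signif(rho_hi, 3), ")")
  fitted <- as.vector(X %*% beta)
  n_par <- ncol(X) + nlevels(droplevels(stratum)) + as.integer(cs)
  pseudo_r2 <- if (stats::sd(fitted) > 0)
    stats::cor(fitted, y)^2 else 0
  structure(list(beta = beta, rho = rho, sigma = sigma_k,
                 fitted = fitted, residuals = y - fitted,
                 logLik = ll, AIC = -2 * ll + 2 * n_par,
                 pseudo_r2 = pseudo_r2, n_par = n_par,
                 iterations = iter, converged = converged,
                 logLik_path = ll_path, cs = cs,
                 single_stratum = single_stratum),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf(
    "<gls_fit> %s, rho=%.3f, %d strata, logLik=%.2f AIC=%.2f pseudo-R2=%.3f\n",
    if (x$cs) "compound symmetry" else "independence",
    x$rho, length(x$sigma), x$logLik, x$AIC, x$pseudo_r2))
  print(x$beta)
  invisible(x)
}

#' Select a variance/correlation structure by AIC
#'
#' Fits each candidate structure on the same data and returns the fit
#' with the lowest AIC; ties are broken toward the candidate with fewer
#' parameters. Candidates that fail to converge (or error) are excluded
#' with a message.
#'
#' @param y,X,group as in [fit_gls_cs()].
#' @param candidates named list of candidate structures, each a list with
#'   elements `cs` (logical) and `stratum` (vector or NULL). Default
#'   menu: independence/homoscedastic and CS/homoscedastic.
#' @return the winning [fit_gls_cs()] object, with the candidate name in
#'   `$selected` and the AIC menu in `$aic_table`.
#' @export
select_model <- function(y, X, group,
                         candidates = list(
                           iid = list(cs = FALSE, stratum = NULL),
                           cs = list(cs = TRUE, stratum = NULL))) {
  fits <- list()
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    fit <- tryCatch(
      fit_gls_cs(y, X, group, stratum = cand$stratum, cs = cand$cs),
      error = function(e) {
        message("candidate ", nm, " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit) && !fit$converged) {
      message("candidate ", nm, " did not converge; excluded")
      fit <- NULL
    }
    fits[[nm]] <- fit
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate converged")
  fits <- fits[ok]
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  npar <- vapply(fits, `[[`, numeric(1), "n_par")
  # lowest AIC; ties toward fewer parameters
  best <- order(aic, npar)[1]
  out <- fits[[best]]
  out$selected <- names(fits)[best]
  out$aic_table <- data.frame(candidate = names(fits), AIC = aic,
                              n_par = npar, row.names = NULL)
  out
}
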