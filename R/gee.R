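#' Linear GEE with exchangeable working correlation for twin pairs
#'
#' Fits a marginal linear model by generalized estimating equations with an
#' exchangeable working correlation within clusters and cluster-robust
#' (sandwich) standard errors. Clusters are twin pairs; cluster sizes of 1
#' (singletons) and 2 are supported. The working correlation is estimated by
#' the usual moment estimator unless `rho` is fixed, in which case the fit is
#' exactly generalized least squares with the supplied correlation (and
#' reduces to OLS at `rho = 0`).
#'
#' @param y Numeric response vector.
#' @param X Design matrix (including intercept column).
#' @param id Cluster identifier, one per row of `X`; at most two rows may
#'   share an id.
#' @param rho Fixed working correlation in `(-1, 1)`, or `NULL` (default) to
#'   estimate it.
#' @param max_iter,tol Iteration control for the alternating beta/rho updates.
#' @return A list of class `gee_fit`: `coefficients`, `se` (robust),
#'   `vcov` (robust), `vcov_naive`, `p` (two-sided, normal reference on
#'   beta/se), `rho`, `sigma2`, `n`, `n_clusters`, `converged`, `residuals`.
#' @export
gee_exchangeable <- function(y, X, id, rho = NULL, max_iter = 25L, tol = 1e-8) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(id) == nrow(X))
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; id <- id[keep]
  idx <- split(seq_along(id), as.character(id))
  sizes <- lengths(idx)
  if (any(sizes > 2L))
    stop("gee_exchangeable supports cluster sizes 1 and 2 (twin pairs) only")
  pairs <- idx[sizes == 2L]
  ia <- vapply(pairs, `[`, integer(1), 1L)
  ib <- vapply(pairs, `[`, integer(1), 2L)
  is_ <- unlist(idx[sizes == 1L], use.names = FALSE)
  fit <- .gee_core(y, X, ia, ib, is_, rho_fixed = rho,
                   max_iter = max_iter, tol = tol, want_vcov = TRUE)
  fit$n <- length(y)
  fit$n_clusters <- length(idx)
  class(fit) <- "gee_fit"
  fit
}

# Core solver. ia/ib index the two members of each complete pair, is_ the
# singleton rows. All scale factors in sigma^2 cancel from beta and from the
# sandwich, so the bread is kept in working-weight units.
.gee_core <- function(y, X, ia, ib, is_, rho_fixed = NULL,
                      max_iter = 25L, tol = 1e-8, want_vcov = TRUE) {
  p <- ncol(X); n <- length(y); P <- length(ia)
  Xa <- X[ia, , drop = FALSE]; Xb <- X[ib, , drop = FALSE]
  ya <- y[ia]; yb <- y[ib]
  has_s <- length(is_) > 0L
  Xs <- if (has_s) X[is_, , drop = FALSE] else NULL
  ys <- if (has_s) y[is_] else NULL

  B0p <- crossprod(Xa) + crossprod(Xb)
  C12 <- crossprod(Xa, Xb)
  Csym <- C12 + t(C12)
  v0p <- crossprod(Xa, ya) + crossprod(Xb, yb)
  vx <- crossprod(Xa, yb) + crossprod(Xb, ya)
  Bs <- if (has_s) crossprod(Xs) else matrix(0, p, p)
  vs <- if (has_s) crossprod(Xs, ys) else matrix(0, p, 1)

  solve_beta <- function(rho) {
    w <- 1 / (1 - rho^2)
    B <- w * (B0p - rho * Csym) + Bs
    v <- w * (v0p - rho * vx) + vs
    list(beta = solve(B, v), bread = B)
  }

  rho <- if (is.null(rho_fixed)) 0 else rho_fixed
  sb <- solve_beta(rho)
  beta <- sb$beta
  converged <- TRUE
  sigma2 <- NA_real_
  if (is.null(rho_fixed)) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ea <- ya - Xa %*% beta; eb <- yb - Xb %*% beta
      es <- if (has_s) ys - Xs %*% beta else numeric(0)
      sigma2 <- (sum(ea^2) + sum(eb^2) + sum(es^2)) / (n - p)
      rho_new <- sum(ea * eb) / sigma2 / max(P - p, 1)
      rho_new <- max(min(rho_new, 0.95), -0.95)
      sb <- solve_beta(rho_new)
      if (max(abs(sb$beta - beta)) < tol && abs(rho_new - rho) < tol) {
        beta <- sb$beta; rho <- rho_new; converged <- TRUE
        break
      }
      beta <- sb$beta; rho <- rho_new
    }
  }
  ea <- ya - Xa %*% beta; eb <- yb - Xb %*% beta
  es <- if (has_s) ys - Xs %*% beta else numeric(0)
  sigma2 <- (sum(ea^2) + sum(eb^2) + sum(es^2)) / (n - p)

  out <- list(coefficients = drop(beta), rho = rho, sigma2 = sigma2,
              converged = converged)
  if (want_vcov) {
    w <- 1 / (1 - rho^2)
    sa <- w * (ea - rho * eb); sb_ <- w * (eb - rho * ea)
    U <- Xa * drop(sa) + Xb * drop(sb_)           # one row per pair
    if (has_s) U <- rbind(U, Xs * drop(es))
    bread_inv <- solve(sb$bread)
    vcov_rob <- bread_inv %*% crossprod(U) %*% bread_inv
    out$vcov <- vcov_rob
    out$vcov_naive <- sigma2 * bread_inv
    out$se <- sqrt(diag(vcov_rob))
    out$p <- 2 * stats::pnorm(-abs(out$coefficients / out$se))
  }
  out
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(
    "Linear GEE (exchangeable, rho = %.4f), %d obs in %d clusters\n",
    x$rho, x$n, x$n_clusters))
  tab <- cbind(Estimate = x$coefficients, `Robust SE` = x$se, `P` = x$p)
  print(tab)
  invisible(x)
}

# Lean coefficient-only fit on the co-twin design, used by the pair bootstrap.
# y1/y2 are the two members' outcomes, x1/x2 their predictor values; `model`
# selects the marginal self (1), marginal co-twin (2) or joint (3) regression.
.falcon_coefs <- function(y1, y2, x1, x2, model, rho_fixed = NULL,
                          max_iter = 25L, tol = 1e-8) {
  P <- length(y1)
  one <- rep(1, P)
  if (model == 1L) { Xa <- cbind(one, x1); Xb <- cbind(one, x2) }
  else if (model == 2L) { Xa <- cbind(one, x2); Xb <- cbind(one, x1) }
  else { Xa <- cbind(one, x1, x2); Xb <- cbind(one, x2, x1) }
  p <- ncol(Xa); n <- 2L * P
  B0p <- crossprod(Xa) + crossprod(Xb)
  C12 <- crossprod(Xa, Xb)
  Csym <- C12 + t(C12)
  v0p <- crossprod(Xa, y1) + crossprod(Xb, y2)
  vx <- crossprod(Xa, y2) + crossprod(Xb, y1)
  rho <- if (is.null(rho_fixed)) 0 else rho_fixed
  beta <- solve(B0p - rho * Csym, v0p - rho * vx)
  if (is.null(rho_fixed)) {
    for (it in seq_len(max_iter)) {
      ea <- y1 - Xa %*% beta; eb <- y2 - Xb %*% beta
      sigma2 <- (sum(ea^2) + sum(eb^2)) / (n - p)
      rho_new <- sum(ea * eb) / sigma2 / max(P - p, 1)
      rho_new <- max(min(rho_new, 0.95), -0.95)
      beta_new <- solve(B0p - rho_new * Csym, v0p - rho_new * vx)
      done <- max(abs(beta_new - beta)) < tol && abs(rho_new - rho) < tol
      beta <- beta_new; rho <- rho_new
      if (done) break
    }
  }
  drop(beta)
}
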