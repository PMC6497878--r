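#' Knight-Ruiz matrix balancing
#'
#' Balances a symmetric nonnegative contact matrix so that every unmapped
#' row and column sums to one, by the Knight-Ruiz inner-outer Newton
#' iteration (conjugate-gradient inner solves). Masked bins are removed
#' before balancing and re-inserted as zero rows afterwards, so the scaling
#' is computed on the mappable submatrix only.
#'
#' @param map a [contact_map()]; rows that sum to zero are masked first.
#' @param tol convergence tolerance on the row sums (default `1e-6`).
#' @param max_outer bound on outer Newton iterations; exceeding it signals
#'   a structurally unbalanceable matrix and raises an error.
#' @return a [contact_map()] with `balanced = TRUE`; unmasked rows and
#'   columns sum to 1 within `tol`, masked rows are zero. The scaling
#'   vector is attached as attribute `"kr_scale"` (NA for masked bins).
#' @examples
#' m <- matrix(runif(64, 0.5, 2), 8, 8)
#' bal <- kr_balance(contact_map((m + t(m)) / 2))
#' rowSums(bal$matrix)  # all 1 within 1e-6
#' @export
kr_balance <- function(map, tol = 1e-6, max_outer = 200) {
  stopifnot(inherits(map, "contact_map"))
  map <- mask_zero_bins(map)
  keep <- unmasked_bins(map)
  if (!length(keep)) stop("all bins are masked; nothing to balance")
  A <- map$matrix[keep, keep, drop = FALSE]
  x <- kr_scaling(A, tol = tol, max_outer = max_outer)
  B <- A * tcrossprod(x)
  out <- matrix(0, n_bins(map), n_bins(map))
  out[keep, keep] <- B
  res <- contact_map(out, bin_size = map$bin_size, mask = map$mask,
                     balanced = TRUE)
  scale_full <- rep(NA_real_, n_bins(map))
  scale_full[keep] <- x
  attr(res, "kr_scale") <- scale_full
  res
}

# Knight-Ruiz scaling vector x with diag(x) %*% A %*% diag(x) doubly
# stochastic (row sums 1). Inner-outer Newton scheme with CG inner solves
# and the standard step-length safeguards (delta/Delta box on the iterate).
kr_scaling <- function(A, tol = 1e-6, max_outer = 200,
                       delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  outer_it <- 0

  while (rout > rt) {
    outer_it <- outer_it + 1
    if (outer_it > max_outer)
      stop("KR balancing did not converge: matrix appears unbalanceable")
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- numeric(n)
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gam <- min((delta - y[ind]) / ap[ind])
        y <- y + gam * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gam <- min((Delta - y[ind]) / ap[ind])
        y <- y + gam * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 10 * n) break
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}
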