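# Independent oracles used by the unit and acceptance tests. These are
# deliberately written against the model definitions (dense matrices,
# exhaustive search) rather than the package's profiled/cumulative
# implementations.

# Dense REML log-likelihood at fixed (sigma_alpha, sigma_eps): builds
# V = se^2 I + sa^2 Z Z' explicitly and evaluates the restricted
# likelihood by generalized least squares.
dense_reml_loglik <- function(y, X, Z, sa, se) {
  n <- length(y)
  p <- ncol(X)
  V <- se^2 * diag(n) + sa^2 * tcrossprod(Z)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  logdetV <- 2 * sum(log(diag(L)))
  Vi_y <- backsolve(L, forwardsolve(t(L), y))
  Vi_X <- backsolve(L, forwardsolve(t(L), X))
  A <- crossprod(X, Vi_X)
  Ra <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Ra)) return(-Inf)
  beta <- backsolve(Ra, forwardsolve(t(Ra), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(L, forwardsolve(t(L), r))
  quad <- drop(crossprod(r, Vi_r))
  -0.5 * (logdetV + 2 * sum(log(diag(Ra))) + quad + (n - p) * log(2 * pi))
}

# Design and grouping matrices built independently via model.matrix.
dense_model_matrices <- function(data) {
  t_ <- as.numeric(data$role == "test")
  g_ <- as.numeric(data$genotype == "knockout")
  h_ <- as.numeric(data$hormone == "testosterone")
  X <- if (any(h_ > 0)) stats::model.matrix(~ t_ * g_ * h_) else
    stats::model.matrix(~ t_ * g_)
  Z <- stats::model.matrix(~ 0 + factor(animal), data = data)
  list(X = X, Z = Z, y = data$ct)
}

# Exhaustive grid search of the REML criterion over (sigma_alpha,
# sigma_eps) in [0, 2]^2; returns the best criterion value found.
# V = se^2 I + sa^2 Z Z' is diagonalized once through the symmetric
# eigendecomposition Z Z' = Q D Q', after which every grid point is a
# weighted (diagonal) GLS problem in the rotated coordinates.
grid_search_reml <- function(data, n_grid = 200) {
  mm <- dense_model_matrices(data)
  n <- length(mm$y)
  p <- ncol(mm$X)
  eig <- eigen(tcrossprod(mm$Z), symmetric = TRUE)
  d <- pmax(eig$values, 0)
  Xr <- crossprod(eig$vectors, mm$X)
  yr <- drop(crossprod(eig$vectors, mm$y))
  sas <- seq(0, 2, length.out = n_grid)
  ses <- seq(0, 2, length.out = n_grid)
  best <- -Inf
  for (se in ses) {
    if (se == 0) next  # singular residual covariance
    for (sa in sas) {
      w <- 1 / (se^2 + sa^2 * d)
      A <- crossprod(Xr, Xr * w)
      Ra <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(Ra)) next
      beta <- backsolve(Ra, forwardsolve(t(Ra), crossprod(Xr, yr * w)))
      r <- yr - drop(Xr %*% beta)
      ll <- -0.5 * (-sum(log(w)) + 2 * sum(log(diag(Ra))) +
                      sum(r^2 * w) + (n - p) * log(2 * pi))
      if (ll > best) best <- ll
    }
  }
  best
}

# Brute-force Otsu: for every cut t in 0..254 compute the two class means
# directly and the between-class variance; ties resolved by the mean of
# the maximizing cut points (same tie rule as the implementation, reached
# by a different arithmetic route).
brute_force_otsu <- function(gray) {
  v <- floor(pmin(pmax(as.numeric(gray), 0), 255))
  bcv <- rep(-Inf, 255)
  n <- length(v)
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / n
    bcv[t + 1] <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }
  best <- max(bcv)
  mean(which(bcv >= best - abs(best) * 1e-12) - 1)
}

# Draw a filled disk into a matrix (used by image fixtures).
draw_disk <- function(m, cy, cx, r, value) {
  idx <- (row(m) - cy)^2 + (col(m) - cx)^2 <= r^2
  m[idx] <- value
  m
}

# Cell-mean of ct for one (role, genotype, hormone) combination.
cell_mean <- function(d, role, genotype, hormone = NULL) {
  keep <- d$role == role & d$genotype == genotype
  if (!is.null(hormone)) keep <- keep & d$hormone == hormone
  mean(d$ct[keep])
}
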