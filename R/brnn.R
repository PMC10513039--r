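# Bayesian-regularized single-hidden-layer network (tanh units, linear
# output).  "Bayesian" in the classical evidence-approximation sense: the
# weight-decay strength is not tuned by cross-validation but re-estimated
# from the data via MacKay's updates, using the Gauss-Newton Hessian
# beta J'J + alpha I of the penalized sum-of-squares objective
#   F = beta * Ed + alpha * Ew,  Ed = 0.5 sum (yhat - y)^2,
#                                Ew = 0.5 sum w^2.
# Inputs and target are standardized internally.

unpack_w <- function(w, d, h) {
  W1 <- matrix(w[seq_len(d * h)], h, d)
  b1 <- w[d * h + seq_len(h)]
  w2 <- w[d * h + h + seq_len(h)]
  b2 <- w[d * h + 2 * h + 1]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_forward <- function(w, X, d, h) {
  p <- unpack_w(w, d, h)
  Z <- tanh(sweep(X %*% t(p$W1), 2, p$b1, `+`))
  list(Z = Z, yhat = drop(Z %*% p$w2) + p$b2, p = p)
}

mlp_obj <- function(w, X, y, d, h, alpha, beta) {
  fw <- mlp_forward(w, X, d, h)
  r <- fw$yhat - y
  beta * 0.5 * sum(r^2) + alpha * 0.5 * sum(w^2)
}

mlp_grad <- function(w, X, y, d, h, alpha, beta) {
  fw <- mlp_forward(w, X, d, h)
  r <- fw$yhat - y
  Z <- fw$Z
  delta <- (r %o% fw$p$w2) * (1 - Z^2)      # N x h
  gW1 <- t(delta) %*% X                      # h x d
  gb1 <- colSums(delta)
  gw2 <- drop(t(Z) %*% r)
  gb2 <- sum(r)
  beta * c(as.vector(gW1), gb1, gw2, gb2) + alpha * w
}

mlp_jacobian <- function(w, X, d, h) {
  fw <- mlp_forward(w, X, d, h)
  Z <- fw$Z
  D <- (1 - Z^2) * matrix(fw$p$w2, nrow(X), h, byrow = TRUE)  # N x h
  JW1 <- do.call(cbind, lapply(seq_len(d), function(k) D * X[, k]))
  # column order must match unpack_w: W1 is filled column-major (h x d),
  # i.e. blocks of h weights per input k -> JW1 block order is correct
  cbind(JW1, D, Z, rep(1, nrow(X)))
}

# train with evidence-approximation re-estimation of alpha/beta
brnn_train <- function(X, y, hidden = 15, n_reestimates = 3, maxit = 150) {
  X <- as.matrix(X)
  d <- ncol(X)
  h <- hidden
  xc <- colMeans(X)
  xs <- apply(X, 2, sd)
  xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xc), 2, xs, `/`)
  yc <- mean(y)
  ys <- sd(y)
  if (ys == 0) ys <- 1
  yn <- (y - yc) / ys
  N <- nrow(Xs)
  P <- d * h + 2 * h + 1
  w <- runif(P, -0.5, 0.5) / sqrt(d + 1)
  alpha <- 0.01
  beta <- 1
  for (it in seq_len(n_reestimates)) {
    opt <- optim(w, mlp_obj, mlp_grad, X = Xs, y = yn, d = d, h = h,
                 alpha = alpha, beta = beta, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-10))
    w <- opt$par
    if (it == n_reestimates) break
    fw <- mlp_forward(w, Xs, d, h)
    Ed <- 0.5 * sum((fw$yhat - yn)^2)
    Ew <- 0.5 * sum(w^2)
    J <- mlp_jacobian(w, Xs, d, h)
    H <- beta * crossprod(J) + diag(alpha, P)
    trHinv <- tryCatch(sum(diag(solve(H))), error = function(e) P / alpha)
    gamma <- P - alpha * trHinv
    gamma <- min(max(gamma, 1), min(P, N - 1))
    alpha <- gamma / max(2 * Ew, 1e-8)
    beta <- (N - gamma) / max(2 * Ed, 1e-8)
  }
  list(w = w, d = d, h = h, xc = xc, xs = xs, yc = yc, ys = ys,
       alpha = alpha, beta = beta)
}

brnn_predict <- function(net, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, net$xc), 2, net$xs, `/`)
  fw <- mlp_forward(net$w, Xs, net$d, net$h)
  fw$yhat * net$ys + net$yc
}
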