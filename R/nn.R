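# Internal neural-network primitives for the generator and critic.
#
# Batches of sequence activations are stored as (n * width) x channels
# matrices, rows grouped by sample, so that 1-D convolution becomes an
# im2col gather followed by one BLAS matmul. All gradients are exact
# reverse-mode; randomness only enters through R's RNG.

# -- parameter-tree utilities -------------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_zero <- function(a) tree_map(function(x) x * 0, a)

# flatten/unflatten for finite-difference checks
tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_flatten), use.names = FALSE)
  else as.numeric(a)
}

tree_unflatten <- function(template, v) {
  pos <- 0L
  rec <- function(a) {
    if (is.list(a)) return(lapply(a, rec))
    k <- length(a)
    out <- a
    out[] <- v[(pos + 1L):(pos + k)]
    pos <<- pos + k
    out
  }
  rec(template)
}

# -- layers -------------------------------------------------------------------

conv_fwd <- function(X, K, b, geom) {
  Xcol <- im2col_cpp(X, geom$width, geom$kernel)
  Y <- Xcol %*% K
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, Xcol = Xcol)
}

conv_bwd <- function(dY, K, Xcol, geom, cin, want_dX = TRUE) {
  dK <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dX <- NULL
  if (want_dX) {
    dX <- col2im_cpp(tcrossprod(dY, K), geom$width, geom$kernel, cin)
  }
  list(dX = dX, dK = dK, db = db)
}

relu_fwd <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  Y
}

relu_bwd <- function(dY, X) {
  dY * (X > 0)
}

softmax_rows <- function(L) {
  m <- L[, 1L]
  for (j in 2:ncol(L)) m <- pmax(m, L[, j])
  P <- exp(L - m)
  P / rowSums(P)
}

softmax_rows_bwd <- function(dY, P) {
  P * (dY - rowSums(P * dY))
}

# reshape between flat (n x width*channels) and batch ((n*width) x channels);
# the two are adjoint permutations of each other
flat_to_batch <- function(D, channels) {
  matrix(t(D), ncol = channels, byrow = TRUE)
}

batch_to_flat <- function(M, n) {
  matrix(t(M), nrow = n, byrow = TRUE)
}

# -- residual block (pre-activation: x + conv(relu(conv(relu(x))))) -----------

resblock_init <- function(channels, kernel, init_sd) {
  kc <- kernel * channels
  list(K1 = matrix(stats::rnorm(kc * channels, 0, init_sd), kc, channels),
       b1 = numeric(channels),
       K2 = matrix(stats::rnorm(kc * channels, 0, init_sd), kc, channels),
       b2 = numeric(channels))
}

resblock_fwd <- function(X, p, geom) {
  A1 <- relu_fwd(X)
  c1 <- conv_fwd(A1, p$K1, p$b1, geom)
  A2 <- relu_fwd(c1$Y)
  c2 <- conv_fwd(A2, p$K2, p$b2, geom)
  list(Y = X + c2$Y, X = X, C1 = c1$Y, Xcol1 = c1$Xcol, Xcol2 = c2$Xcol)
}

resblock_bwd <- function(dY, p, cache, geom) {
  channels <- ncol(p$K1)
  b2 <- conv_bwd(dY, p$K2, cache$Xcol2, geom, channels)
  dC1 <- relu_bwd(b2$dX, cache$C1)
  b1 <- conv_bwd(dC1, p$K1, cache$Xcol1, geom, channels)
  dX <- dY + relu_bwd(b1$dX, cache$X)
  list(dX = dX,
       grads = list(K1 = b1$dK, b1 = b1$db, K2 = b2$dK, b2 = b2$db))
}

# -- Adam ---------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.5,
                      beta2 = 0.9, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map2(function(p, mv) p - mv, params,
                      tree_map2(function(m, v) {
                        lr * (m / bc1) / (sqrt(v / bc2) + eps)
                      }, state$m, state$v))
  list(params = params, state = state)
}
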