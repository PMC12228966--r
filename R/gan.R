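# Wasserstein GAN with gradient penalty for variable-length 5' UTR sequences.
#
# The generator maps a 40-dimensional standard-normal latent vector to a
# 128 x 5 row-stochastic matrix (channels A,C,G,T,PAD); the critic returns an
# unbounded real score. Training alternates 5 critic updates per generator
# update and penalizes the critic's input-gradient norm away from 1 on
# uniform interpolates between real and generated batches.

#' Sample a batch of latent vectors
#'
#' Latent inputs to the generator are i.i.d. standard normal (mean 0, sd 1).
#'
#' @param n number of vectors.
#' @param dim latent dimensionality (default 40).
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and recorded as an attribute.
#' @return an `n` x `dim` numeric matrix with attribute `seed`.
#' @examples
#' z <- sample_latent(4, seed = 7)
#' @export
sample_latent <- function(n, dim = 40L, seed = NULL) {
  stopifnot(n >= 1, dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * dim), n, dim)
  attr(z, "seed") <- seed
  z
}

#' Construct an untrained generator
#'
#' Dense up-projection of the latent vector, five pre-activation residual
#' convolution blocks with a shared channel count, and a final 5-channel
#' convolution followed by a per-position softmax, so every output position
#' is a probability vector over (A, C, G, T, PAD).
#'
#' @param latent_dim latent input dimension (default 40).
#' @param channels channel count shared by all residual blocks (default 128).
#' @param kernel convolution kernel size, odd (default 5).
#' @param blocks number of residual blocks (default 5).
#' @param width sequence width in nucleotides (default 128).
#' @param init_sd sd of the normal weight initialization (default 0.1).
#' @param seed optional seed for the initialization draw.
#' @return an object of class `utr_generator`.
#' @export
utr_generator <- function(latent_dim = 40L, channels = 128L, kernel = 5L,
                          blocks = 5L, width = 128L, init_sd = 0.1,
                          seed = NULL) {
  stopifnot(kernel %% 2L == 1L, blocks >= 1L)
  if (!is.null(seed)) set.seed(seed)
  flat <- width * channels
  params <- list(
    dense = list(W = matrix(stats::rnorm(latent_dim * flat, 0, init_sd),
                            latent_dim, flat),
                 b = numeric(flat)),
    blocks = lapply(seq_len(blocks), function(i) {
      resblock_init(channels, kernel, init_sd)
    }),
    out = list(K = matrix(stats::rnorm(kernel * channels * 5L, 0, init_sd),
                          kernel * channels, 5L),
               b = numeric(5L))
  )
  structure(list(params = params,
                 cfg = list(latent_dim = latent_dim, channels = channels,
                            kernel = kernel, blocks = blocks, width = width,
                            init_sd = init_sd)),
            class = "utr_generator")
}

#' Construct an untrained critic
#'
#' An input convolution from the 5 sequence channels, five pre-activation
#' residual convolution blocks, and a final dense layer with a single
#' unbounded output (no saturating activation: the critic scores, it does
#' not classify).
#'
#' @inheritParams utr_generator
#' @return an object of class `utr_critic`.
#' @export
utr_critic <- function(channels = 128L, kernel = 5L, blocks = 5L,
                       width = 128L, init_sd = 0.1, seed = NULL) {
  stopifnot(kernel %% 2L == 1L, blocks >= 1L)
  if (!is.null(seed)) set.seed(seed)
  params <- list(
    inp = list(K = matrix(stats::rnorm(kernel * 5L * channels, 0, init_sd),
                          kernel * 5L, channels),
               b = numeric(channels)),
    blocks = lapply(seq_len(blocks), function(i) {
      resblock_init(channels, kernel, init_sd)
    }),
    dense = list(W = matrix(stats::rnorm(width * channels, 0, init_sd),
                            width * channels, 1L),
                 b = numeric(1L))
  )
  structure(list(params = params,
                 cfg = list(channels = channels, kernel = kernel,
                            blocks = blocks, width = width,
                            init_sd = init_sd)),
            class = "utr_critic")
}

generator_forward <- function(g, Z) {
  p <- g$params
  cfg <- g$cfg
  stopifnot(ncol(Z) == cfg$latent_dim)
  n <- nrow(Z)
  geom <- list(width = cfg$width, kernel = cfg$kernel)
  D <- sweep(Z %*% p$dense$W, 2L, p$dense$b, "+")
  X <- flat_to_batch(D, cfg$channels)
  bcaches <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    bc <- resblock_fwd(X, p$blocks[[i]], geom)
    bcaches[[i]] <- bc
    X <- bc$Y
  }
  oc <- conv_fwd(X, p$out$K, p$out$b, geom)
  P <- softmax_rows(oc$Y)
  list(P = onehot_batch(P, n, cfg$width),
       cache = list(Z = Z, geom = geom, blocks = bcaches,
                    Xcol_out = oc$Xcol, P = P))
}

generator_backward <- function(g, cache, dP) {
  p <- g$params
  cfg <- g$cfg
  n <- nrow(cache$Z)
  dL <- softmax_rows_bwd(dP, cache$P)
  ob <- conv_bwd(dL, p$out$K, cache$Xcol_out, cache$geom, cfg$channels)
  grads <- list(dense = NULL, blocks = vector("list", length(p$blocks)),
                out = list(K = ob$dK, b = ob$db))
  dX <- ob$dX
  for (i in rev(seq_along(p$blocks))) {
    rb <- resblock_bwd(dX, p$blocks[[i]], cache$blocks[[i]], cache$geom)
    grads$blocks[[i]] <- rb$grads
    dX <- rb$dX
  }
  dD <- batch_to_flat(dX, n)
  grads$dense <- list(W = crossprod(cache$Z, dD), b = colSums(dD))
  dZ <- tcrossprod(dD, p$dense$W)
  list(dZ = dZ, grads = grads)
}

critic_forward <- function(d, X) {
  p <- d$params
  cfg <- d$cfg
  nW <- nrow(X)
  stopifnot(nW %% cfg$width == 0L, ncol(X) == 5L)
  n <- nW %/% cfg$width
  geom <- list(width = cfg$width, kernel = cfg$kernel)
  ic <- conv_fwd(X, p$inp$K, p$inp$b, geom)
  M <- ic$Y
  bcaches <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    bc <- resblock_fwd(M, p$blocks[[i]], geom)
    bcaches[[i]] <- bc
    M <- bc$Y
  }
  A <- batch_to_flat(M, n)
  s <- drop(A %*% p$dense$W) + p$dense$b
  list(scores = s,
       cache = list(n = n, geom = geom, Xcol_in = ic$Xcol, blocks = bcaches,
                    A = A))
}

critic_backward <- function(d, cache, dS, want_input = FALSE,
                            want_params = TRUE) {
  p <- d$params
  cfg <- d$cfg
  n <- cache$n
  dSm <- matrix(dS, ncol = 1L)
  dA <- tcrossprod(dSm, p$dense$W)
  grads <- NULL
  dM <- flat_to_batch(dA, cfg$channels)
  bgrads <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    rb <- resblock_bwd(dM, p$blocks[[i]], cache$blocks[[i]], cache$geom)
    bgrads[[i]] <- rb$grads
    dM <- rb$dX
  }
  ib <- conv_bwd(dM, p$inp$K, cache$Xcol_in, cache$geom, 5L,
                 want_dX = want_input)
  if (want_params) {
    grads <- list(inp = list(K = ib$dK, b = ib$db),
                  blocks = bgrads,
                  dense = list(W = crossprod(cache$A, dSm), b = sum(dS)))
  }
  list(dX = ib$dX, grads = grads)
}

#' Run the generator on a latent batch
#'
#' Deterministic forward pass: the same generator and latent batch always
#' give bitwise-identical output. Every output position is a probability
#' vector over the 5 channels (softmax), so decoding never fails.
#'
#' @param generator a `utr_generator` (or a fitted `utr_gan`).
#' @param z an `n` x `latent_dim` matrix from [sample_latent()].
#' @return a soft `onehot_batch` (see [encode_utrs()] for the layout).
#' @export
utr_generate <- function(generator, z) {
  g <- as_generator(generator)
  if (ncol(z) != g$cfg$latent_dim) {
    stop("latent dimension mismatch: generator expects ", g$cfg$latent_dim,
         ", got ", ncol(z), call. = FALSE)
  }
  generator_forward(g, z)$P
}

as_generator <- function(x) {
  if (inherits(x, "utr_gan")) x$generator
  else if (inherits(x, "utr_generator")) x
  else stop("expected a utr_generator or utr_gan", call. = FALSE)
}

as_critic <- function(x) {
  if (inherits(x, "utr_gan")) x$critic
  else if (inherits(x, "utr_critic")) x
  else stop("expected a utr_critic or utr_gan", call. = FALSE)
}

#' Generate and decode sequences
#'
#' Convenience wrapper: sample latents, run the generator, decode by argmax
#' with the first-PAD stopping rule.
#'
#' @param object a fitted `utr_gan` or a `utr_generator`.
#' @param n number of sequences.
#' @param seed optional seed for the latent draw.
#' @return a UTR-set tibble (`id`, `seq`).
#' @export
generate_utrs <- function(object, n, seed = NULL) {
  g <- as_generator(object)
  z <- sample_latent(n, g$cfg$latent_dim, seed = seed)
  decode_batch(utr_generate(g, z), id = paste0("gen_", seq_len(n)))
}

#' Score a batch of sequences with the critic
#'
#' @param critic a `utr_critic` (or fitted `utr_gan`).
#' @param x an `onehot_batch` (hard or soft).
#' @return a numeric vector of unbounded per-sequence scores.
#' @export
critic_score <- function(critic, x) {
  critic_forward(as_critic(critic), x)$scores
}

# per-sample input-gradient norms of the critic at X; returns list(norms, dX)
critic_input_grad_norms <- function(d, X) {
  fw <- critic_forward(d, X)
  bw <- critic_backward(d, fw$cache, rep(1, fw$cache$n),
                        want_input = TRUE, want_params = FALSE)
  grp <- rep(seq_len(fw$cache$n), each = d$cfg$width)
  norms <- sqrt(rowsum(rowSums(bw$dX^2), grp))[, 1L]
  list(norms = norms, dX = bw$dX, n = fw$cache$n)
}

#' Gradient penalty of the critic
#'
#' Computes `lambda * E[(||grad_xhat D(xhat)||_2 - 1)^2]` over interpolates
#' `xhat = eps * x_real + (1 - eps) * x_fake` with per-pair
#' `eps ~ Uniform(0, 1)`, the soft Lipschitz constraint of WGAN-GP training.
#' The input gradient is exact (reverse mode).
#'
#' @param critic a `utr_critic`.
#' @param x_real,x_fake `onehot_batch`es of the same shape.
#' @param gp_lambda penalty coefficient (default 10).
#' @param mix optional numeric vector of per-pair interpolation weights in
#'   `[0, 1]`; drawn uniformly when `NULL`.
#' @return the penalty value, with attribute `grad_norms` carrying the
#'   per-interpolate gradient norms.
#' @export
gradient_penalty <- function(critic, x_real, x_fake, gp_lambda = 10,
                             mix = NULL) {
  d <- as_critic(critic)
  stopifnot(all(dim(x_real) == dim(x_fake)), gp_lambda >= 0)
  n <- nrow(x_real) %/% d$cfg$width
  if (is.null(mix)) mix <- stats::runif(n)
  Xhat <- make_interpolates(x_real, x_fake, mix, d$cfg$width)
  gn <- critic_input_grad_norms(d, Xhat)
  val <- gp_lambda * mean((gn$norms - 1)^2)
  attr(val, "grad_norms") <- gn$norms
  val
}

make_interpolates <- function(x_real, x_fake, mix, width) {
  m <- rep(mix, each = width)
  m * x_real + (1 - m) * x_fake
}

# Parameter gradient of the penalty via a central finite-difference
# Hessian-vector product: d penalty / d theta =
#   (2 lambda / n) * sum_i (g_i - 1) * d/d theta [ directional derivative of
#   D at xhat_i along the unit input-gradient v_i ],
# and the directional derivative is differentiated w.r.t. theta by evaluating
# ordinary backprop at xhat +- eps_fd * V with per-sample output seeds.
gp_param_grads <- function(d, Xhat, gn, gp_lambda, eps_fd = 1e-3) {
  n <- gn$n
  width <- d$cfg$width
  g <- gn$norms
  ok <- g > 1e-12
  coef <- ifelse(ok, gp_lambda * (g - 1) / (n * eps_fd), 0)
  scale <- rep(ifelse(ok, 1 / g, 0), each = width)
  V <- gn$dX * scale
  # both displaced batches in one pass; seeds carry the +/- of the central
  # difference
  fpm <- critic_forward(d, rbind(Xhat + eps_fd * V, Xhat - eps_fd * V))
  critic_backward(d, fpm$cache, c(coef, -coef), want_input = FALSE)$grads
}

#' Critic and generator losses
#'
#' `critic_loss` is `mean D(x_fake) - mean D(x_real) + penalty`;
#' `generator_loss` is `-mean D(x_fake)`. The critic minimizes its loss to
#' widen the score gap between natural and generated batches subject to the
#' gradient penalty; the generator minimizes its loss to close that gap.
#'
#' @inheritParams gradient_penalty
#' @return a single numeric loss value.
#' @export
critic_loss <- function(critic, x_real, x_fake, gp_lambda = 10, mix = NULL) {
  d <- as_critic(critic)
  sr <- critic_forward(d, x_real)$scores
  sf <- critic_forward(d, x_fake)$scores
  gp <- if (gp_lambda > 0) {
    as.numeric(gradient_penalty(d, x_real, x_fake, gp_lambda, mix = mix))
  } else 0
  mean(sf) - mean(sr) + gp
}

#' @rdname critic_loss
#' @export
generator_loss <- function(critic, x_fake) {
  -mean(critic_forward(as_critic(critic), x_fake)$scores)
}

# one full critic update; returns new critic/state plus logged terms
critic_update <- function(d, dstate, Xr, Xf, gp_lambda, opt) {
  n <- nrow(Xr) %/% d$cfg$width
  # real and fake batches share one forward/backward pass
  frf <- critic_forward(d, rbind(Xr, Xf))
  sr <- frf$scores[seq_len(n)]
  sf <- frf$scores[n + seq_len(n)]
  grads <- critic_backward(d, frf$cache,
                           c(rep(-1 / n, n), rep(1 / n, n)))$grads
  gp_val <- 0
  if (gp_lambda > 0) {
    mix <- stats::runif(n)
    Xhat <- make_interpolates(Xr, Xf, mix, d$cfg$width)
    gn <- critic_input_grad_norms(d, Xhat)
    gp_val <- gp_lambda * mean((gn$norms - 1)^2)
    grads <- tree_add(grads, gp_param_grads(d, Xhat, gn, gp_lambda))
  }
  loss <- mean(sf) - mean(sr) + gp_val
  st <- adam_step(d$params, grads, dstate, lr = opt$lr, beta1 = opt$beta1,
                  beta2 = opt$beta2)
  d$params <- st$params
  list(critic = d, state = st$state, loss = loss, gp = gp_val)
}

generator_update <- function(g, gstate, d, Z, opt) {
  n <- nrow(Z)
  fw <- generator_forward(g, Z)
  cf <- critic_forward(d, fw$P)
  cb <- critic_backward(d, cf$cache, rep(-1 / n, n), want_input = TRUE,
                        want_params = FALSE)
  gb <- generator_backward(g, fw$cache, cb$dX)
  st <- adam_step(g$params, gb$grads, gstate, lr = opt$lr, beta1 = opt$beta1,
                  beta2 = opt$beta2)
  g$params <- st$params
  list(generator = g, state = st$state, loss = -mean(cf$scores))
}

#' Train the UTR GAN
#'
#' Alternating WGAN-GP training: `critic_steps` critic updates (Wasserstein
#' loss plus gradient penalty) per generator update, Adam for both networks,
#' weights initialized from Normal(0, `init_sd`). Fully reproducible given
#' `seed` (single-threaded numerics).
#'
#' @param data a UTR-set tibble (columns `id`, `seq`); at least `batch_size`
#'   rows.
#' @param steps number of generator updates (default 3000).
#' @param critic_steps critic updates per generator update (default 5).
#' @param batch_size minibatch size (default 64).
#' @param gp_lambda gradient-penalty coefficient (default 10).
#' @param latent_dim,channels,kernel,blocks,width,init_sd architecture
#'   settings, see [utr_generator()].
#' @param lr,beta1,beta2 Adam hyperparameters (defaults 1e-4, 0.5, 0.9).
#' @param seed integer seed controlling initialization, minibatch draws and
#'   latent draws.
#' @param checkpoint_every write a checkpoint every this many generator
#'   steps (`NULL` to disable).
#' @param checkpoint_dir directory for checkpoints.
#' @param verbose print progress every 50 steps.
#' @return an object of class `utr_gan`: fields `generator`, `critic`,
#'   `history` (tibble: step, phase, substep, critic_loss, gp_term,
#'   generator_loss), `config`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
train_utr_gan <- function(data, steps = 3000L, critic_steps = 5L,
                          batch_size = 64L, gp_lambda = 10,
                          latent_dim = 40L, channels = 128L, kernel = 5L,
                          blocks = 5L, width = 128L, init_sd = 0.1,
                          lr = 1e-4, beta1 = 0.5, beta2 = 0.9,
                          seed = NULL, checkpoint_every = NULL,
                          checkpoint_dir = tempdir(), verbose = FALSE) {
  stopifnot(is.data.frame(data), nrow(data) >= batch_size,
            critic_steps >= 1L, gp_lambda >= 0)
  if (nrow(data) == 0) stop("empty training set", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- utr_generator(latent_dim, channels, kernel, blocks, width, init_sd)
  d <- utr_critic(channels, kernel, blocks, width, init_sd)
  gstate <- adam_init(g$params)
  dstate <- adam_init(d$params)
  opt <- list(lr = lr, beta1 = beta1, beta2 = beta2)

  enc <- encode_utrs(data, width = width)
  nd <- nrow(data)
  draw_real <- function() {
    ii <- sample.int(nd, batch_size, replace = nd < batch_size * 2L)
    rows <- as.vector(outer(seq_len(width), (ii - 1L) * width, `+`))
    onehot_batch(enc[rows, , drop = FALSE], batch_size, width)
  }

  hist <- vector("list", steps * (critic_steps + 1L))
  hi <- 0L
  for (s in seq_len(steps)) {
    for (k in seq_len(critic_steps)) {
      Xr <- draw_real()
      Zf <- matrix(stats::rnorm(batch_size * latent_dim), batch_size)
      Xf <- generator_forward(g, Zf)$P
      cu <- critic_update(d, dstate, Xr, Xf, gp_lambda, opt)
      if (!is.finite(cu$loss)) {
        stop("non-finite critic loss at generator step ", s, ", critic step ",
             k, call. = FALSE)
      }
      d <- cu$critic
      dstate <- cu$state
      hi <- hi + 1L
      hist[[hi]] <- list(step = s, phase = "critic", substep = k,
                         critic_loss = cu$loss, gp_term = cu$gp,
                         generator_loss = NA_real_)
    }
    Zg <- matrix(stats::rnorm(batch_size * latent_dim), batch_size)
    gu <- generator_update(g, gstate, d, Zg, opt)
    if (!is.finite(gu$loss)) {
      stop("non-finite generator loss at step ", s, call. = FALSE)
    }
    g <- gu$generator
    gstate <- gu$state
    hi <- hi + 1L
    hist[[hi]] <- list(step = s, phase = "generator", substep = NA_integer_,
                       critic_loss = NA_real_, gp_term = NA_real_,
                       generator_loss = gu$loss)
    if (verbose && s %% 50L == 0L) {
      message("step ", s, "/", steps,
              "  critic ", signif(hist[[hi - 1L]]$critic_loss, 4),
              "  generator ", signif(gu$loss, 4))
    }
    if (!is.null(checkpoint_every) && s %% checkpoint_every == 0L) {
      fit <- new_utr_gan(g, d, dplyr::bind_rows(hist[seq_len(hi)]),
                         match.call(), seed)
      save_utr_gan(fit, file.path(checkpoint_dir,
                                  sprintf("utr_gan_step%06d.rds", s)))
    }
  }
  new_utr_gan(g, d, dplyr::bind_rows(hist[seq_len(hi)]), match.call(), seed)
}

new_utr_gan <- function(g, d, history, call, seed) {
  structure(list(generator = g, critic = d, history = history,
                 config = c(g$cfg, list(seed = seed)), call = call),
            class = "utr_gan")
}

#' Save / load a fitted GAN checkpoint
#'
#' Checkpoints are self-describing: both networks, the resolved
#' configuration and the training history travel together.
#'
#' @param object a `utr_gan`.
#' @param path file path (`.rds`).
#' @return `path` (save) or the restored `utr_gan` (load).
#' @export
save_utr_gan <- function(object, path) {
  stopifnot(inherits(object, "utr_gan"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_utr_gan
#' @export
load_utr_gan <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "utr_gan"))
  obj
}

#' @export
print.utr_gan <- function(x, ...) {
  cfg <- x$config
  cat("<utr_gan>  width", cfg$width, " latent", cfg$latent_dim,
      " channels", cfg$channels, " blocks", cfg$blocks, "\n")
  n_steps <- max(x$history$step)
  cat("  trained for", n_steps, "generator steps;",
      sum(x$history$phase == "critic"), "critic updates\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted GAN
#'
#' @param x a `utr_gan`.
#' @param ... unused.
#' @return the history tibble (step, phase, substep, critic_loss, gp_term,
#'   generator_loss).
#' @export
tidy.utr_gan <- function(x, ...) x$history

#' One-row summary of a fitted GAN
#'
#' @param x a `utr_gan`.
#' @param ... unused.
#' @return a tibble with the step count, update counts and final running
#'   losses (mean over the last 10% of updates).
#' @export
glance.utr_gan <- function(x, ...) {
  h <- x$history
  cl <- h$critic_loss[h$phase == "critic"]
  gl <- h$generator_loss[h$phase == "generator"]
  tail_frac <- function(v) mean(utils::tail(v, max(1L, length(v) %/% 10L)))
  tibble::tibble(
    steps = max(h$step),
    critic_updates = sum(h$phase == "critic"),
    generator_updates = sum(h$phase == "generator"),
    final_critic_loss = tail_frac(cl),
    final_generator_loss = tail_frac(gl),
    final_gp_term = tail_frac(h$gp_term[h$phase == "critic"])
  )
}
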