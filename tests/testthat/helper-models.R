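# Small model builders shared across tests. Tests run at desk scale:
# few channels, short widths, so every check stays fast.

ns <- asNamespace("utrforge")

tiny_generator <- function(width = 16L, channels = 6L, latent_dim = 8L,
                           blocks = 2L, seed = 1L) {
  utr_generator(latent_dim = latent_dim, channels = channels, kernel = 5L,
                blocks = blocks, width = width, seed = seed)
}

tiny_critic <- function(width = 16L, channels = 6L, blocks = 2L, seed = 2L) {
  utr_critic(channels = channels, kernel = 5L, blocks = blocks,
             width = width, seed = seed)
}

# A critic that computes exactly D(x) = scale * <w, x> for a width x 5
# weight matrix w: kernel-1 input convolution passes the 5 channels through
# untouched, zeroed residual blocks are identities, and the dense layer
# holds the weights. Used for the gradient-penalty closed forms.
linear_critic <- function(w_mat, scale = 1) {
  width <- nrow(w_mat)
  channels <- 5L
  d <- utr_critic(channels = channels, kernel = 1L, blocks = 1L,
                  width = width, init_sd = 0)
  d$params$inp$K <- diag(5)
  dense <- numeric(width * channels)
  for (p in seq_len(width)) {
    dense[(p - 1L) * channels + 1:5] <- w_mat[p, ]
  }
  d$params$dense$W <- matrix(scale * dense, ncol = 1L)
  d
}

constant_critic <- function(width = 8L, value = 0) {
  d <- utr_critic(channels = 5L, kernel = 1L, blocks = 1L, width = width,
                  init_sd = 0)
  d$params$dense$b <- value
  d
}

# unit-norm width x 5 weight matrix
unit_w <- function(width = 8L, seed = 4L) {
  set.seed(seed)
  w <- matrix(rnorm(width * 5L), width, 5L)
  w / sqrt(sum(w^2))
}
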