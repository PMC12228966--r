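test_that("latent sampling is seed-deterministic with standard-normal law", {
  a <- sample_latent(4, 40, seed = 7)
  b <- sample_latent(4, 40, seed = 7)
  expect_identical(a, b)
  expect_equal(dim(sample_latent(1, 40)), c(1L, 40L))

  z <- sample_latent(10000, 40, seed = 1)
  mu <- colMeans(z)
  sdv <- apply(z, 2, sd)
  expect_true(all(abs(mu) < 0.05))
  expect_true(all(abs(sdv - 1) < 0.05))
})

test_that("generator output is row-stochastic, shaped, and deterministic", {
  g <- tiny_generator(width = 128L)
  z <- sample_latent(3, 8, seed = 5)
  p1 <- utr_generate(g, z)
  p2 <- utr_generate(g, z)
  expect_identical(unclass(p1), unclass(p2))
  expect_equal(nrow(p1), 3L * 128L)
  expect_equal(ncol(p1), 5L)
  expect_equal(rowSums(p1), rep(1, nrow(p1)), tolerance = 1e-6)
  # decoding generator output never fails
  expect_s3_class(decode_batch(p1), "tbl_df")
  expect_error(utr_generate(g, matrix(0, 2, 13)), "dimension mismatch")
})

test_that("gradient penalty matches closed forms for analytic critics", {
  set.seed(8)
  xr <- encode_utrs(utr_set(c("ACGTACGT", "GGCCAATT")), width = 8)
  xf <- random_soft_batch(2, 8, seed = 6)

  # linear critic with unit-norm weights: gradient norm 1 everywhere
  d1 <- linear_critic(unit_w(8))
  expect_equal(as.numeric(gradient_penalty(d1, xr, xf, gp_lambda = 10)), 0,
               tolerance = 1e-12)

  # constant critic: zero gradient, penalty = lambda
  d0 <- constant_critic(width = 8, value = 3)
  for (lam in c(1, 10, 25)) {
    expect_equal(as.numeric(gradient_penalty(d0, xr, xf, gp_lambda = lam)),
                 lam)
  }

  # scaled linear critic D = 3 * w.x: penalty = lambda * (3 - 1)^2
  d3 <- linear_critic(unit_w(8), scale = 3)
  expect_equal(as.numeric(gradient_penalty(d3, xr, xf, gp_lambda = 10)),
               40, tolerance = 1e-10)
  expect_equal(as.numeric(gradient_penalty(d3, xr, xf, gp_lambda = 2)),
               8, tolerance = 1e-10)
})

test_that("losses reduce to their definitions for a constant critic", {
  xr <- encode_utrs(utr_set(c("ACGT", "GGCC")), width = 8)
  xf <- random_soft_batch(2, 8, seed = 3)
  d0 <- constant_critic(width = 8, value = 2.5)
  expect_equal(critic_loss(d0, xr, xf, gp_lambda = 0), 0)
  expect_equal(generator_loss(d0, xf), -2.5)
})

test_that("critic parameter gradients agree with finite differences", {
  d <- tiny_critic()
  xr <- encode_utrs(utr_set(c("ACGTACGTACGT", "GGCCAATTGGCC")), width = 16)
  xf <- random_soft_batch(2, 16, seed = 5)
  fr <- ns$critic_forward(d, xr)
  ff <- ns$critic_forward(d, xf)
  grads <- ns$tree_add(
    ns$critic_backward(d, fr$cache, rep(-0.5, 2))$grads,
    ns$critic_backward(d, ff$cache, rep(0.5, 2))$grads)
  fl <- ns$tree_flatten(d$params)
  gfl <- ns$tree_flatten(grads)
  lossf <- function(v) {
    d2 <- d
    d2$params <- ns$tree_unflatten(d$params, v)
    critic_loss(d2, xr, xf, gp_lambda = 0)
  }
  set.seed(6)
  for (k in sample(length(fl), 8)) {
    vp <- fl; vp[k] <- vp[k] + 1e-5
    vm <- fl; vm[k] <- vm[k] - 1e-5
    fd <- (lossf(vp) - lossf(vm)) / 2e-5
    expect_equal(gfl[k], fd, tolerance = 1e-4)
  }
})

test_that("gradient-penalty parameter gradients agree with finite
           differences of the exact penalty", {
  d <- tiny_critic(seed = 9)
  xr <- random_soft_batch(2, 16, seed = 1)
  xf <- random_soft_batch(2, 16, seed = 2)
  mix <- c(0.25, 0.75)
  Xhat <- ns$make_interpolates(xr, xf, mix, 16L)
  gn <- ns$critic_input_grad_norms(d, Xhat)
  gpg <- ns$gp_param_grads(d, Xhat, gn, gp_lambda = 10)
  fl <- ns$tree_flatten(d$params)
  gfl <- ns$tree_flatten(gpg)
  penf <- function(v) {
    d2 <- d
    d2$params <- ns$tree_unflatten(d$params, v)
    as.numeric(gradient_penalty(d2, xr, xf, 10, mix = mix))
  }
  set.seed(10)
  for (k in sample(length(fl), 8)) {
    vp <- fl; vp[k] <- vp[k] + 1e-5
    vm <- fl; vm[k] <- vm[k] - 1e-5
    fd <- (penf(vp) - penf(vm)) / 2e-5
    expect_equal(gfl[k], fd, tolerance = 1e-3)
  }
})

test_that("training logs 5 critic updates per generator update and is
           seed-reproducible", {
  utrs <- simulate_utrs(40, min_len = 8, max_len = 24, seed = 31)
  fit1 <- train_utr_gan(utrs, steps = 6, critic_steps = 5, batch_size = 8,
                        channels = 4, width = 32, seed = 99)
  h <- tidy(fit1)
  counts <- table(h$step[h$phase == "critic"])
  expect_true(all(counts == 5))
  expect_equal(sum(h$phase == "generator"), 6L)

  fit2 <- train_utr_gan(utrs, steps = 6, critic_steps = 5, batch_size = 8,
                        channels = 4, width = 32, seed = 99)
  expect_identical(tidy(fit1), tidy(fit2))
  expect_identical(fit1$generator$params, fit2$generator$params)

  # checkpoint save/load round-trip
  path <- withr::local_tempfile(fileext = ".rds")
  save_utr_gan(fit1, path)
  back <- load_utr_gan(path)
  z <- sample_latent(2, 40, seed = 1)
  expect_identical(utr_generate(fit1, z), utr_generate(back, z))
})

test_that("critic loss trends downward over the first 50 critic updates", {
  utrs <- simulate_utrs(60, min_len = 8, max_len = 24, gc_mean = 0.7,
                        seed = 41)
  fit <- train_utr_gan(utrs, steps = 10, critic_steps = 5, batch_size = 8,
                       channels = 4, width = 32, seed = 13)
  cl <- tidy(fit)$critic_loss[tidy(fit)$phase == "critic"]
  expect_length(cl, 50L)
  # running-mean trend, not per-step monotonicity
  expect_lt(mean(tail(cl, 15)), mean(head(cl, 15)))
})

test_that("training rejects unusable inputs", {
  utrs <- simulate_utrs(10, seed = 1)
  expect_error(train_utr_gan(utrs, steps = 2, batch_size = 16), "nrow")
})
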