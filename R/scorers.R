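# Differentiable scorers.
#
# A scorer maps a batch of soft one-hot sequences to one real score per
# sequence and exposes the exact gradient of the score with respect to the
# input matrix. Latent optimization only ever needs these two callables, so
# external predictors (expression / ribosome-load / translation-efficiency
# models) plug in through the same contract; the built-in scorers are
# analytically tractable and serve as verifiable stand-ins.

#' Construct a differentiable scorer
#'
#' @param name short scorer name (used in traces and reports).
#' @param score function(batch) -> numeric vector, one score per sequence;
#'   `batch` is an `onehot_batch` (rows grouped by sequence, 5 channels).
#' @param grad function(batch) -> matrix of the same shape as `batch`:
#'   the gradient of each sequence's score with respect to its own rows.
#' @param requires_gene_context `TRUE` when the scorer expects a full gene
#'   window (UTR embedded at the TSS) rather than the bare UTR.
#' @param width expected input width in positions.
#' @return an object of class `utr_scorer`.
#' @export
utr_scorer <- function(name, score, grad, requires_gene_context = FALSE,
                       width = UTR_WIDTH) {
  stopifnot(is.function(score), is.function(grad))
  structure(list(name = name, score = score, grad = grad,
                 requires_gene_context = isTRUE(requires_gene_context),
                 width = as.integer(width)),
            class = "utr_scorer")
}

#' @export
print.utr_scorer <- function(x, ...) {
  cat("<utr_scorer>", x$name, " width", x$width,
      if (x$requires_gene_context) " (gene context)" else "", "\n")
  invisible(x)
}

#' Score a batch of sequences
#'
#' @param scorer a `utr_scorer`.
#' @param batch an `onehot_batch` of the scorer's expected width.
#' @return numeric vector of per-sequence scores.
#' @export
score_utrs <- function(scorer, batch) {
  stopifnot(inherits(scorer, "utr_scorer"))
  d <- batch_dims(batch)
  if (!is.null(d$width) && d$width != scorer$width) {
    stop("scorer '", scorer$name, "' expects width ", scorer$width,
         ", got ", d$width, call. = FALSE)
  }
  scorer$score(batch)
}

#' @rdname score_utrs
#' @return for `scorer_gradient`, a matrix of the same shape as `batch`.
#' @export
scorer_gradient <- function(scorer, batch) {
  stopifnot(inherits(scorer, "utr_scorer"))
  scorer$grad(batch)
}

# soft GC content per sequence: (C+G mass) / (non-PAD mass)
soft_gc <- function(batch) {
  d <- batch_dims(batch)
  grp <- rep(seq_len(d$n), each = d$width)
  s_gc <- rowsum(batch[, 2L] + batch[, 3L], grp)[, 1L]
  s_np <- rowsum(rowSums(batch[, 1:4, drop = FALSE]), grp)[, 1L]
  unname(ifelse(s_np > 0, s_gc / s_np, 0))
}

#' Toy GC-content scorer
#'
#' `score = -sharpness * (soft_gc - target_gc)^2` where `soft_gc` is the
#' C+G channel mass divided by the non-PAD mass. Maximum 0, attained exactly
#' when the soft GC fraction equals the target; the unique-optimum property
#' makes this the reference objective for optimizer tests and for
#' GC-controlled (constrained) optimization. An all-PAD sequence has zero
#' non-PAD mass; its score is defined as `-sharpness * target_gc^2` with a
#' zero gradient.
#'
#' @param target_gc target GC fraction in `[0, 1]`.
#' @param sharpness positive curvature of the penalty (default 1).
#' @return a `utr_scorer` (UTR-only, width 128).
#' @export
toy_gc_scorer <- function(target_gc, sharpness = 1) {
  stopifnot(target_gc >= 0, target_gc <= 1, sharpness > 0)
  score <- function(batch) {
    -sharpness * (soft_gc(batch) - target_gc)^2
  }
  grad <- function(batch) {
    d <- batch_dims(batch)
    grp <- rep(seq_len(d$n), each = d$width)
    s_gc <- rowsum(batch[, 2L] + batch[, 3L], grp)[, 1L]
    s_np <- rowsum(rowSums(batch[, 1:4, drop = FALSE]), grp)[, 1L]
    ok <- s_np > 0
    r <- ifelse(ok, s_gc / s_np, 0)
    # d score / d s_gc and d score / d s_np by the quotient rule
    da <- ifelse(ok, -2 * sharpness * (r - target_gc) / s_np, 0)
    db <- ifelse(ok, 2 * sharpness * (r - target_gc) * s_gc / s_np^2, 0)
    G <- matrix(0, nrow(batch), 5L)
    G[, 1L] <- rep(db, each = d$width)
    G[, 4L] <- G[, 1L]
    G[, 2L] <- rep(da + db, each = d$width)
    G[, 3L] <- G[, 2L]
    G
  }
  utr_scorer(sprintf("toy_gc(%.2f)", target_gc), score, grad)
}

#' Position-weight-matrix scorer
#'
#' Score of a sequence is the maximum over window positions of the inner
#' product between the PWM and the soft sequence window (A,C,G,T channels
#' only); windows are restricted to the decoded (pre-PAD) span, so on hard
#' sequences the score equals the classical best PWM match. The gradient is
#' the subgradient at the best window (earliest window on ties).
#'
#' @param pwm numeric matrix, one row per motif position, 4 columns
#'   (A, C, G, T).
#' @return a `utr_scorer` (UTR-only, width 128).
#' @export
pwm_scorer <- function(pwm) {
  pwm <- as.matrix(pwm)
  stopifnot(ncol(pwm) == 4L, nrow(pwm) >= 1L)
  w <- nrow(pwm)

  best_windows <- function(batch) {
    d <- batch_dims(batch)
    lens <- decoded_lengths(batch)
    if (any(lens < w)) {
      stop("PWM of width ", w, " is wider than sequence ",
           which(lens < w)[1], " (length ", min(lens), ")", call. = FALSE)
    }
    vapply(seq_len(d$n), function(i) {
      rows <- nth_seq_rows(batch, i)
      X <- batch[rows, 1:4, drop = FALSE]
      npos <- lens[i] - w + 1L
      sc <- vapply(seq_len(npos), function(p) {
        sum(pwm * X[p:(p + w - 1L), , drop = FALSE])
      }, numeric(1))
      p_best <- which.max(sc)
      c(sc[p_best], p_best)
    }, numeric(2))
  }

  score <- function(batch) best_windows(batch)[1L, ]
  grad <- function(batch) {
    d <- batch_dims(batch)
    bw <- best_windows(batch)
    G <- matrix(0, nrow(batch), 5L)
    for (i in seq_len(d$n)) {
      p <- bw[2L, i]
      rows <- (i - 1L) * d$width + p:(p + w - 1L)
      G[rows, 1:4] <- G[rows, 1:4] + pwm
    }
    G
  }
  utr_scorer(sprintf("pwm(%dnt)", w), score, grad)
}

# decoded (first-PAD) length of every sequence in a batch
decoded_lengths <- function(batch) {
  d <- batch_dims(batch)
  am <- max.col(batch, ties.method = "first")
  vapply(seq_len(d$n), function(i) {
    a <- am[nth_seq_rows(batch, i)]
    stop_at <- match(5L, a)
    if (is.na(stop_at)) d$width else stop_at - 1L
  }, integer(1))
}

#' Toy expression scorer over a gene window
#'
#' A differentiable stand-in for a fixed-width expression predictor: it
#' takes the full 10 500 nt gene window (UTR embedded at the TSS, index
#' 7000) and rewards C+G mass in the 128 positions downstream of the TSS,
#' plus a small A-mass term over the upstream promoter region. The upstream
#' term gives the scorer a nonzero gradient outside the UTR, which the
#' optimizer's gradient slicing must discard — making the slicing
#' observable in tests. The known optimum (an all-G/C UTR) lets
#' optimization runs be checked against ground truth.
#'
#' @param upstream_weight weight of the upstream A-mass term (default 0.01).
#' @return a `utr_scorer` with `requires_gene_context = TRUE`, width 10500.
#' @export
toy_expression_scorer <- function(upstream_weight = 0.01) {
  win <- GENE_WINDOW_LENGTH
  tss <- GENE_WINDOW_TSS
  utr_zone <- (tss + 1L):(tss + UTR_WIDTH)   # 1-based rows of the UTR slot
  up_zone <- 1L:tss
  score <- function(batch) {
    d <- batch_dims(batch)
    vapply(seq_len(d$n), function(i) {
      rows <- (i - 1L) * d$width
      X <- batch[rows + utr_zone, , drop = FALSE]
      U <- batch[rows + up_zone, 1L, drop = FALSE]
      mean(X[, 2L] + X[, 3L]) + upstream_weight * mean(U)
    }, numeric(1))
  }
  grad <- function(batch) {
    d <- batch_dims(batch)
    G <- matrix(0, nrow(batch), 5L)
    for (i in seq_len(d$n)) {
      rows <- (i - 1L) * d$width
      G[rows + utr_zone, 2L] <- 1 / length(utr_zone)
      G[rows + utr_zone, 3L] <- 1 / length(utr_zone)
      G[rows + up_zone, 1L] <- upstream_weight / length(up_zone)
    }
    G
  }
  utr_scorer("toy_expression", score, grad, requires_gene_context = TRUE,
             width = win)
}

#' Adapt an external differentiable predictor to the scorer contract
#'
#' Wraps a user-supplied forward/gradient pair (e.g. bindings to a
#' pretrained expression, mean-ribosome-load or translation-efficiency
#' model; no weights are bundled with this package). For models trained on
#' 4-letter inputs, the PAD channel is stripped and the remaining four
#' channels renormalized per position, with the gradient chained through
#' that renormalization. Expression-kind adapters are marked as requiring
#' gene context.
#'
#' @param score function(matrix) -> numeric vector; receives the (possibly
#'   4-channel) input described by `channels`.
#' @param grad function(matrix) -> matrix of the same shape as its input.
#' @param kind one of `"expression"`, `"mrl"`, `"te"`.
#' @param width input width the external model expects (defaults to 10500
#'   for expression, 128 otherwise).
#' @param channels 4 or 5: number of input channels the external model
#'   consumes (default 4: strip PAD and renormalize).
#' @param name scorer name (default derived from `kind`).
#' @return a `utr_scorer`.
#' @export
adapt_external <- function(score, grad, kind = c("expression", "mrl", "te"),
                           width = NULL, channels = 4L, name = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.function(score), is.function(grad), channels %in% c(4L, 5L))
  if (is.null(width)) {
    width <- if (kind == "expression") GENE_WINDOW_LENGTH else UTR_WIDTH
  }
  if (is.null(name)) name <- paste0("external_", kind)
  if (channels == 5L) {
    return(utr_scorer(name, score, grad,
                      requires_gene_context = kind == "expression",
                      width = width))
  }
  to4 <- function(batch) {
    X4 <- batch[, 1:4, drop = FALSE]
    rs <- rowSums(X4)
    Y <- X4 / ifelse(rs > 0, rs, 1)
    Y[rs == 0, ] <- 0.25
    list(Y = Y, rs = rs)
  }
  wrapped_score <- function(batch) score(to4(batch)$Y)
  wrapped_grad <- function(batch) {
    tr <- to4(batch)
    gy <- grad(tr$Y)
    if (!all(dim(gy) == dim(tr$Y))) {
      stop("external gradient has shape ", paste(dim(gy), collapse = "x"),
           ", expected ", paste(dim(tr$Y), collapse = "x"), call. = FALSE)
    }
    # chain through y = x / sum(x): dx_a = (g_a - sum_b g_b y_b) / sum(x)
    inner <- rowSums(gy * tr$Y)
    G <- matrix(0, nrow(batch), 5L)
    ok <- tr$rs > 0
    G[ok, 1:4] <- (gy[ok, , drop = FALSE] - inner[ok]) / tr$rs[ok]
    G
  }
  utr_scorer(name, wrapped_score, wrapped_grad,
             requires_gene_context = kind == "expression", width = width)
}

#' Random row-stochastic batch (for contract checks)
#'
#' @param n number of sequences.
#' @param width positions per sequence.
#' @param seed optional seed.
#' @param concentration softmax temperature of the random logits; larger
#'   values give harder (more peaked) rows.
#' @param pad_free when `TRUE` the PAD channel gets zero mass, so the
#'   decoded length is exactly `width` (useful for scorers that need a
#'   minimum pre-PAD span).
#' @return a soft `onehot_batch`.
#' @export
random_soft_batch <- function(n, width = UTR_WIDTH, seed = NULL,
                              concentration = 1, pad_free = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  L <- matrix(stats::rnorm(n * width * 5L, sd = concentration),
              n * width, 5L)
  P <- softmax_rows(L)
  if (pad_free) {
    P[, 5L] <- 0
    P <- P / rowSums(P)
  }
  onehot_batch(P, n, width)
}

#' Verify the differentiable-scorer contract
#'
#' Checks, at random row-stochastic inputs: determinism of the score,
#' finiteness of the gradient, and central finite-difference agreement of
#' the analytic gradient (the contract every scorer used for latent
#' optimization must satisfy).
#'
#' @param scorer a `utr_scorer`.
#' @param n_checks number of random inputs (default 10).
#' @param n_seq sequences per input batch (default 2).
#' @param fd_step finite-difference step (default 1e-4).
#' @param tol maximum admissible relative error (default 1e-3).
#' @param seed seed for the random inputs.
#' @return invisibly `TRUE`; errors with a diagnostic on contract violation.
#' @export
check_scorer <- function(scorer, n_checks = 10L, n_seq = 2L, fd_step = 1e-4,
                         tol = 1e-3, seed = 1L) {
  stopifnot(inherits(scorer, "utr_scorer"))
  set.seed(seed)
  for (chk in seq_len(n_checks)) {
    batch <- random_soft_batch(n_seq, scorer$width)
    s1 <- scorer$score(batch)
    s2 <- scorer$score(batch)
    if (!identical(s1, s2)) {
      stop("scorer '", scorer$name, "' is not deterministic", call. = FALSE)
    }
    G <- scorer$grad(batch)
    if (!all(is.finite(G))) {
      stop("scorer '", scorer$name, "' produced non-finite gradients",
           call. = FALSE)
    }
    # probe a handful of random coordinates by central differences
    for (probe in seq_len(5L)) {
      r <- sample.int(nrow(batch), 1L)
      c <- sample.int(5L, 1L)
      i <- (r - 1L) %/% scorer$width + 1L
      bp <- batch; bp[r, c] <- bp[r, c] + fd_step
      bm <- batch; bm[r, c] <- bm[r, c] - fd_step
      fd <- (scorer$score(bp)[i] - scorer$score(bm)[i]) / (2 * fd_step)
      denom <- max(abs(fd), abs(G[r, c]), 1e-8)
      if (abs(fd - G[r, c]) / denom > tol && abs(fd - G[r, c]) > 1e-8) {
        stop("scorer '", scorer$name, "' gradient mismatch at row ", r,
             " channel ", c, ": analytic ", signif(G[r, c], 6),
             " vs finite-difference ", signif(fd, 6), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
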