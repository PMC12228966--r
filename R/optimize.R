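# Latent-space gradient ascent.
#
# Optimization never touches the generator's weights: the latent batch z is
# updated by z <- z + step_size * d objective / d z, the per-iteration scores
# are stored, and for every batch element the iteration with the best score
# is selected independently (earliest iteration on ties). The default unit
# step mirrors the plain z_new = z0 + gradient update; gradient
# normalization is available as an escape hatch for sharp scorers.

#' Combine scorers into a weighted objective
#'
#' The objective value is `sum(weight_i * scorer_i(x))`, optionally plus a
#' GC-constraint term `-gc_penalty * (soft_gc(x) - gc_target)^2` that keeps
#' optimized sequences near a target composition (GC-controlled
#' optimization). All scorers must be UTR-only (no gene context) and share
#' one input width.
#'
#' @param ... `utr_scorer` objects.
#' @param weights numeric weights, recycled to the number of scorers
#'   (default all 1: equal weighting).
#' @param gc_target optional GC-constraint target in `[0, 1]`.
#' @param gc_penalty weight of the GC constraint (default 1).
#' @return an object of class `utr_objective`.
#' @export
utr_objective <- function(..., weights = NULL, gc_target = NULL,
                          gc_penalty = 1) {
  scorers <- list(...)
  stopifnot(length(scorers) >= 1L,
            all(vapply(scorers, inherits, logical(1), "utr_scorer")))
  if (any(vapply(scorers, function(s) s$requires_gene_context, logical(1)))) {
    stop("gene-context scorers cannot enter a UTR-only objective; ",
         "use optimize_expression()", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(scorers))
  weights <- rep_len(as.numeric(weights), length(scorers))
  stopifnot(all(is.finite(weights)))
  if (!is.null(gc_target)) {
    scorers <- c(scorers, list(toy_gc_scorer(gc_target, gc_penalty)))
    weights <- c(weights, 1)
  }
  width <- unique(vapply(scorers, function(s) s$width, integer(1)))
  if (length(width) != 1L) {
    stop("scorers disagree on input width: ", paste(width, collapse = ", "),
         call. = FALSE)
  }
  structure(list(scorers = scorers, weights = weights, width = width,
                 name = paste(vapply(scorers, function(s) s$name,
                                     character(1)), collapse = "+")),
            class = "utr_objective")
}

as_objective <- function(x) {
  if (inherits(x, "utr_objective")) x
  else if (inherits(x, "utr_scorer")) utr_objective(x)
  else stop("expected a utr_scorer or utr_objective", call. = FALSE)
}

objective_score <- function(obj, batch) {
  vals <- lapply(obj$scorers, function(s) s$score(batch))
  Reduce(`+`, Map(`*`, obj$weights, vals))
}

objective_grad <- function(obj, batch) {
  gs <- Map(function(w, s) w * s$grad(batch), obj$weights, obj$scorers)
  Reduce(`+`, gs)
}

#' Optimize latent vectors against a UTR-only objective
#'
#' Plain gradient ascent on the generator's input: each iteration evaluates
#' the objective on the decoded soft sequences, backpropagates through the
#' generator, and applies `z <- z + step_size * grad`. The full score
#' history is recorded; per element the best iteration (ties: earliest) and
#' its latent vector are tracked so the best sequence can be reproduced
#' exactly. Batch elements are fully independent: running an element alone
#' with the same start gives the identical trajectory.
#'
#' For harness use, `generator = NULL` treats the latent matrix itself as
#' the scored object; `objective` must then be a `list(score =, grad =)`
#' pair operating on the latent matrix.
#'
#' @param generator a `utr_generator` or fitted `utr_gan` (or `NULL`, see
#'   above).
#' @param objective a `utr_scorer` or [utr_objective()].
#' @param z0 initial latent batch from [sample_latent()]; required.
#' @param iterations number of ascent updates (default 10000, the regimen
#'   used for ribosome-load / translation-efficiency style scorers; scores
#'   are evaluated at iterations `0..iterations`).
#' @param step_size ascent step (default 1: the unit update
#'   `z_new = z0 + gradient`).
#' @param normalize_grad scale each element's gradient to unit norm before
#'   stepping (default `FALSE`).
#' @param snapshot_every record decoded sequences every this many
#'   iterations in the trace (`NULL`: only iterations 0 and the last).
#' @return an object of class `utr_opt_trace`; see [select_best()],
#'   [tidy.utr_opt_trace()], [autoplot.utr_opt_trace()].
#' @export
optimize_latent <- function(generator, objective, z0, iterations = 10000L,
                            step_size = 1, normalize_grad = FALSE,
                            snapshot_every = NULL) {
  stopifnot(is.matrix(z0), iterations >= 0L, step_size > 0)
  identity_map <- is.null(generator)
  if (!identity_map) {
    g <- as_generator(generator)
    obj <- as_objective(objective)
    if (obj$width != g$cfg$width) {
      stop("objective width ", obj$width, " does not match generator width ",
           g$cfg$width, call. = FALSE)
    }
    eval_fn <- function(z) {
      fw <- generator_forward(g, z)
      s <- objective_score(obj, fw$P)
      dP <- objective_grad(obj, fw$P)
      list(scores = s, dz = generator_backward(g, fw$cache, dP)$dZ,
           batch = fw$P)
    }
    obj_name <- obj$name
  } else {
    g <- NULL
    stopifnot(is.list(objective), is.function(objective$score),
              is.function(objective$grad))
    eval_fn <- function(z) {
      list(scores = objective$score(z), dz = objective$grad(z), batch = NULL)
    }
    obj_name <- "latent_harness"
  }
  run_ascent(g, eval_fn, z0, iterations, step_size, normalize_grad,
             snapshot_every, obj_name)
}

run_ascent <- function(g, eval_fn, z0, iterations, step_size,
                       normalize_grad, snapshot_every, obj_name) {
  n <- nrow(z0)
  z <- z0
  scores <- matrix(NA_real_, iterations + 1L, n)
  best_score <- rep(-Inf, n)
  best_iter <- rep(NA_integer_, n)
  best_z <- z0
  snaps <- list()
  take_snap <- function(it, batch) {
    if (is.null(batch)) return(NULL)
    want <- it == 0L || it == iterations ||
      (!is.null(snapshot_every) && it %% snapshot_every == 0L)
    if (!want) return(NULL)
    dplyr::mutate(decode_batch(batch), iteration = it,
                  element = dplyr::row_number())
  }
  for (it in 0:iterations) {
    ev <- eval_fn(z)
    s <- ev$scores
    scores[it + 1L, ] <- s
    improved <- !is.na(s) & s > best_score
    best_score[improved] <- s[improved]
    best_iter[improved] <- it
    best_z[improved, ] <- z[improved, , drop = FALSE]
    sn <- take_snap(it, ev$batch)
    if (!is.null(sn)) snaps[[length(snaps) + 1L]] <- sn
    if (it == iterations) break
    dz <- ev$dz
    dz[is.na(dz)] <- 0
    if (!all(is.finite(dz))) {
      stop("non-finite latent gradient at iteration ", it, call. = FALSE)
    }
    if (normalize_grad) {
      nm <- sqrt(rowSums(dz^2))
      dz <- dz / ifelse(nm > 0, nm, 1)
    }
    z <- z + step_size * dz
  }
  structure(list(scores = scores, best_iteration = best_iter,
                 best_score = best_score, best_z = best_z, z0 = z0,
                 final_z = z, generator = g,
                 snapshots = if (length(snaps)) dplyr::bind_rows(snaps)
                             else NULL,
                 config = list(objective = obj_name, iterations = iterations,
                               step_size = step_size,
                               normalize_grad = normalize_grad,
                               seed = attr(z0, "seed"))),
            class = "utr_opt_trace")
}

#' Optimize latent vectors for expression over gene windows
#'
#' Expression-style optimization: each iteration decodes the per-element
#' UTR length `L` (first-PAD rule), embeds the soft UTR into every gene
#' window at the TSS using the [replace_utr()] geometry, averages the
#' predictor score over the window set, slices the window gradient to the
#' UTR span `[7000, 7000 + L)`, chains it through the generator, and steps
#' the latent batch. Elements whose current decode is empty receive an `NA`
#' score and a zero update for that iteration.
#'
#' @param generator a `utr_generator` or fitted `utr_gan`.
#' @param windows a list of `gene_window` objects (the genes whose average
#'   expression is maximized).
#' @param predictor a `utr_scorer` with `requires_gene_context = TRUE` and
#'   width 10500.
#' @param z0 initial latent batch.
#' @param iterations ascent updates (default 3000, the expression regimen).
#' @param utr_objective optional UTR-only [utr_objective()] added to the
#'   window score (joint expression + translation-style optimization, or a
#'   GC constraint).
#' @inheritParams optimize_latent
#' @return a `utr_opt_trace`.
#' @export
optimize_expression <- function(generator, windows, predictor, z0,
                                iterations = 3000L, step_size = 1,
                                normalize_grad = FALSE,
                                utr_objective = NULL,
                                snapshot_every = NULL) {
  g <- as_generator(generator)
  stopifnot(length(windows) >= 1L,
            all(vapply(windows, inherits, logical(1), "gene_window")))
  if (!inherits(predictor, "utr_scorer") || !predictor$requires_gene_context) {
    stop("predictor must be a utr_scorer with requires_gene_context = TRUE",
         call. = FALSE)
  }
  if (predictor$width != GENE_WINDOW_LENGTH) {
    stop("gene-context predictor must accept width ", GENE_WINDOW_LENGTH,
         call. = FALSE)
  }
  if (!is.null(utr_objective)) {
    utr_objective <- as_objective(utr_objective)
  }
  width <- g$cfg$width
  tss <- GENE_WINDOW_TSS
  m <- length(windows)
  # cache hard-context encodings per (window, L); contexts only depend on L
  ctx_cache <- lapply(seq_len(m), function(w) vector("list", width))
  get_ctx <- function(w, L) {
    if (is.null(ctx_cache[[w]][[L]])) {
      ctx <- replace_utr(windows[[w]], strrep("A", L))
      ctx_cache[[w]][[L]] <<- encode_window_seq(ctx$sequence)
    }
    ctx_cache[[w]][[L]]
  }

  eval_fn <- function(z) {
    fw <- generator_forward(g, z)
    X <- fw$P
    n <- nrow(z)
    lens <- decoded_lengths(X)
    s <- rep(NA_real_, n)
    dX <- matrix(0, nrow(X), 5L)
    for (i in seq_len(n)) {
      L <- lens[i]
      if (L < 1L) next
      rows_utr <- (i - 1L) * width + seq_len(L)
      soft <- X[rows_utr, , drop = FALSE]
      Ms <- lapply(seq_len(m), function(w) {
        M <- get_ctx(w, L)
        M[(tss + 1L):(tss + L), ] <- soft
        M
      })
      wb <- onehot_batch(do.call(rbind, Ms), m, GENE_WINDOW_LENGTH)
      s[i] <- mean(predictor$score(wb))
      Gw <- predictor$grad(wb)
      acc <- matrix(0, L, 5L)
      for (w in seq_len(m)) {
        gw <- Gw[(w - 1L) * GENE_WINDOW_LENGTH + (tss + 1L):(tss + L), ,
                 drop = FALSE]
        acc <- acc + gw
      }
      dX[rows_utr, ] <- acc / m
    }
    if (!is.null(utr_objective)) {
      s_u <- objective_score(utr_objective, X)
      s <- ifelse(is.na(s), NA_real_, s + s_u)
      dX <- dX + objective_grad(utr_objective, X)
    }
    list(scores = s, dz = generator_backward(g, fw$cache, dX)$dZ, batch = X)
  }
  run_ascent(g, eval_fn, z0, iterations, step_size, normalize_grad,
             snapshot_every,
             paste0(predictor$name, "@", m, "windows",
                    if (!is.null(utr_objective))
                      paste0("+", utr_objective$name)))
}

#' Select the best sequence per element from an optimization trace
#'
#' For each batch element independently, regenerates the decoded sequence
#' at that element's best-scoring iteration (earliest iteration on ties) —
#' the selected score is therefore never below the initial score, so a run
#' that only degrades automatically falls back to the initial sequence.
#'
#' @param trace a `utr_opt_trace`.
#' @return a tibble with columns `id`, `seq`, `best_iteration` (0-based),
#'   `best_score`, `initial_score`, `gain`.
#' @export
select_best <- function(trace) {
  stopifnot(inherits(trace, "utr_opt_trace"))
  n <- ncol(trace$scores)
  seqs <- if (!is.null(trace$generator)) {
    decode_batch(generator_forward(trace$generator, trace$best_z)$P)$seq
  } else {
    rep(NA_character_, n)
  }
  tibble::tibble(
    id = paste0("opt_", seq_len(n)),
    seq = seqs,
    best_iteration = trace$best_iteration,
    best_score = ifelse(is.finite(trace$best_score), trace$best_score,
                        NA_real_),
    initial_score = trace$scores[1L, ],
    gain = .data$best_score - .data$initial_score
  )
}

#' @export
print.utr_opt_trace <- function(x, ...) {
  cat("<utr_opt_trace>", x$config$objective, "\n")
  cat("  ", ncol(x$scores), "elements,", x$config$iterations,
      "iterations, step", x$config$step_size, "\n")
  cat("  mean initial", signif(mean(x$scores[1L, ], na.rm = TRUE), 4),
      " mean best", signif(mean(x$best_score[is.finite(x$best_score)]), 4),
      "\n")
  invisible(x)
}

#' Tidy an optimization trace
#'
#' @param x a `utr_opt_trace`.
#' @param ... unused.
#' @return a long tibble: `iteration` (0-based), `element`, `score`,
#'   `best_so_far`.
#' @export
tidy.utr_opt_trace <- function(x, ...) {
  n <- ncol(x$scores)
  iters <- nrow(x$scores)
  out <- tibble::tibble(
    iteration = rep(0:(iters - 1L), n),
    element = rep(seq_len(n), each = iters),
    score = as.vector(x$scores)
  )
  dplyr::mutate(dplyr::group_by(out, .data$element),
                best_so_far = cummax(ifelse(is.na(.data$score), -Inf,
                                            .data$score))) |>
    dplyr::ungroup()
}

#' One-row summary of an optimization trace
#'
#' @param x a `utr_opt_trace`.
#' @param ... unused.
#' @return a tibble: element count, iterations, mean initial and best
#'   scores, mean gain, and the fraction of elements whose best beats their
#'   initial score.
#' @export
glance.utr_opt_trace <- function(x, ...) {
  init <- x$scores[1L, ]
  best <- x$best_score
  ok <- is.finite(best) & !is.na(init)
  tibble::tibble(
    elements = ncol(x$scores),
    iterations = x$config$iterations,
    mean_initial = mean(init[ok]),
    mean_best = mean(best[ok]),
    mean_gain = mean(best[ok] - init[ok]),
    frac_improved = mean(best[ok] > init[ok])
  )
}
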