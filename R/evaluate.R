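# Sequence-set evaluation: how close are generated UTRs to natural ones?
#
# The headline comparison is per-sequence nearest-neighbour distance to a
# natural reference set (Levenshtein and 4-mer frequency), plus GC content,
# predicted minimum free energy (delegated to a folding backend, never
# re-implemented), and motif scans (uORF, G-quadruplex, Kozak similarity).

#' Levenshtein (edit) distance
#'
#' Minimum number of single-character insertions, deletions or
#' substitutions between two strings.
#'
#' @param a,b character vectors.
#' @return an integer `length(a)` x `length(b)` matrix of distances
#'   (a scalar when both inputs are single strings).
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b)
  storage.mode(d) <- "integer"
  if (length(a) == 1L && length(b) == 1L) d[1L, 1L] else d
}

#' k-mer frequency vector
#'
#' Counts of overlapping k-mers normalized to sum 1; sequences shorter than
#' `k` yield the zero vector (with a warning, so exclusions are visible).
#'
#' @param seq a single nucleotide string.
#' @param k k-mer size (default 4).
#' @return a named numeric vector of length `4^k`.
#' @export
kmer_frequency <- function(seq, k = 4L) {
  M <- kmer_freq_matrix(seq, k)
  stats::setNames(M[1L, ], colnames(M))
}

kmer_freq_matrix <- function(seqs, k = 4L) {
  seqs <- normalize_seq(seqs)
  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than k = ", k,
            " have zero k-mer vectors", call. = FALSE)
    seqs[short] <- strrep("A", k)   # placeholder, zeroed below
  }
  M <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                            width = k)
  rs <- rowSums(M)
  M <- M / ifelse(rs > 0, rs, 1)
  M[short, ] <- 0
  M
}

#' k-mer frequency distance between two sequences
#'
#' Distance between length-normalized k-mer frequency vectors. Euclidean by
#' default; `"cosine"` (1 - cosine similarity) and `"l1"` are also
#' available.
#'
#' @param a,b single nucleotide strings.
#' @param k k-mer size (default 4).
#' @param method distance on the frequency vectors.
#' @return a nonnegative real.
#' @export
kmer_distance <- function(a, b, k = 4L,
                          method = c("euclidean", "cosine", "l1")) {
  method <- match.arg(method)
  fa <- kmer_frequency(a, k)
  fb <- kmer_frequency(b, k)
  switch(method,
         euclidean = sqrt(sum((fa - fb)^2)),
         l1 = sum(abs(fa - fb)),
         cosine = {
           na <- sqrt(sum(fa^2)); nb <- sqrt(sum(fb^2))
           if (na == 0 || nb == 0) 1 else 1 - sum(fa * fb) / (na * nb)
         })
}

#' GC content of sequences
#'
#' @param seq character vector of nonempty nucleotide strings.
#' @return numeric vector of (G+C)/length in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- normalize_seq(seq)
  if (any(nchar(seq) == 0)) {
    stop("GC content of an empty sequence is undefined", call. = FALSE)
  }
  vapply(seq, function(s) {
    n <- nchar(s)
    (n - nchar(gsub("[GC]", "", s))) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' Nearest-neighbour distance distribution
#'
#' For every query sequence, the minimum distance to the target set.
#' With `exclude_identical = TRUE` exact string matches are skipped — as
#' required when a set is compared against itself for a baseline — and
#' queries identical to every target are dropped from the output (the count
#' is attached as attribute `excluded` and reported via a message).
#'
#' @param query,target UTR-set tibbles or character vectors; `target` must
#'   be nonempty.
#' @param metric `"levenshtein"` or `"kmer"`.
#' @param exclude_identical skip exact string matches (default `FALSE`).
#' @param k k-mer size for the kmer metric.
#' @return numeric vector of per-query minimum distances, attribute
#'   `excluded` giving the number of dropped queries.
#' @export
nn_distance_distribution <- function(query, target,
                                     metric = c("levenshtein", "kmer"),
                                     exclude_identical = FALSE, k = 4L) {
  metric <- match.arg(metric)
  q <- if (is.data.frame(query)) query$seq else normalize_seq(query)
  t <- if (is.data.frame(target)) target$seq else normalize_seq(target)
  stopifnot(length(t) >= 1L)
  D <- if (metric == "levenshtein") {
    utils::adist(q, t)
  } else {
    A <- kmer_freq_matrix(q, k)
    B <- kmer_freq_matrix(t, k)
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  }
  if (exclude_identical) {
    D[outer(q, t, `==`)] <- Inf
  }
  mins <- apply(D, 1L, min)
  drop_i <- which(!is.finite(mins))
  if (length(drop_i) > 0) {
    message(length(drop_i),
            " query sequence(s) identical to every target excluded")
    mins <- mins[-drop_i]
  }
  attr(mins, "excluded") <- length(drop_i)
  mins
}

# -- minimum free energy (delegated) ------------------------------------------

#' Folding backends for minimum free energy
#'
#' `mfe_backend_rnafold()` wraps the ViennaRNA `RNAfold` command-line tool;
#' `mfe_backend_stub()` wraps an arbitrary R function (used in tests to
#' exercise the plumbing without thermodynamics). Backends carry their own
#' result cache, so a sequence is folded at most once per backend.
#'
#' @param cmd path to the RNAfold executable.
#' @return an object of class `mfe_backend`.
#' @export
mfe_backend_rnafold <- function(cmd = "RNAfold") {
  if (Sys.which(cmd) == "") {
    stop("RNAfold executable not found on PATH", call. = FALSE)
  }
  fold <- function(seqs) {
    rna <- chartr("T", "U", normalize_seq(seqs))
    out <- system2(cmd, args = c("--noPS"), input = rna, stdout = TRUE)
    # energy lines look like: "STRUCTURE ( -1.20)" or "... (  0.00)"
    en <- grep("\\(\\s*-?[0-9.]+\\)$", out, value = TRUE)
    if (length(en) != length(seqs)) {
      stop("RNAfold returned ", length(en), " energies for ", length(seqs),
           " sequences", call. = FALSE)
    }
    as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", en))
  }
  new_mfe_backend("rnafold", fold)
}

#' @param fold_fn function(character vector of DNA sequences) -> numeric
#'   vector of energies (kcal/mol).
#' @param name backend name recorded in reports.
#' @rdname mfe_backend_rnafold
#' @export
mfe_backend_stub <- function(fold_fn, name = "stub") {
  new_mfe_backend(name, fold_fn)
}

new_mfe_backend <- function(name, fold_fn) {
  structure(list(name = name, fold = fold_fn, cache = new.env(parent = emptyenv())),
            class = "mfe_backend")
}

#' Minimum free energy of sequences
#'
#' Delegates folding to the registered backend on the RNA transliteration
#' of each sequence; results are cached per backend so repeated queries do
#' not re-fold. MFE is never computed in this package itself.
#'
#' @param seq character vector of nucleotide strings.
#' @param backend an `mfe_backend`; `NULL` tries [mfe_backend_rnafold()].
#' @return numeric vector of energies (kcal/mol), attribute `backend`
#'   naming the backend used.
#' @export
mfe <- function(seq, backend = NULL) {
  if (is.null(backend)) backend <- mfe_backend_rnafold()
  stopifnot(inherits(backend, "mfe_backend"))
  seq <- normalize_seq(seq)
  out <- numeric(length(seq))
  todo <- !vapply(seq, exists, logical(1), envir = backend$cache)
  if (any(todo)) {
    fresh <- backend$fold(unique(seq[todo]))
    for (i in seq_along(fresh)) {
      assign(unique(seq[todo])[i], fresh[i], envir = backend$cache)
    }
  }
  out <- vapply(seq, get, numeric(1), envir = backend$cache)
  names(out) <- NULL
  attr(out, "backend") <- backend$name
  out
}

# -- motif scans --------------------------------------------------------------

KOZAK_CONSENSUS <- "GCCGCCACCATGG"   # DNA transliteration of the consensus

#' Scan for upstream open reading frames
#'
#' A uORF is an `ATG` followed by an in-frame stop codon (`TAA`, `TAG` or
#' `TGA`) within the sequence. Each qualifying start codon counts once;
#' spans are 0-based half-open `[start, stop_end)`.
#'
#' @param seq a single nucleotide string.
#' @return a list: `count`, and `spans` (tibble with `start`, `end`).
#' @export
scan_uorfs <- function(seq) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  starts <- integer(0)
  ends <- integer(0)
  if (n >= 6L) {
    atg <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
    if (atg[1] != -1L) {
      for (a in as.integer(atg)) {            # 1-based ATG position
        p <- a + 3L
        while (p + 2L <= n) {
          codon <- substr(seq, p, p + 2L)
          if (codon %in% c("TAA", "TAG", "TGA")) {
            starts <- c(starts, a - 1L)       # 0-based
            ends <- c(ends, p + 2L)           # half-open end
            break
          }
          p <- p + 3L
        }
      }
    }
  }
  list(count = length(starts),
       spans = tibble::tibble(start = starts, end = ends))
}

#' Scan for G-quadruplex motifs
#'
#' Matches the canonical pattern `G{3,}(N{1,7}G{3,}){3}` (four runs of at
#' least three guanines separated by 1-7 nt loops); non-overlapping matches
#' are counted left to right. The pattern is configurable since definitions
#' in the literature vary.
#'
#' @param seq a single nucleotide string.
#' @param pattern regular expression defining the motif.
#' @return a list: `count`, and `spans` (tibble with 0-based half-open
#'   `start`, `end`).
#' @export
scan_g_quadruplex <- function(seq,
                              pattern = "G{3,}([ACGT]{1,7}G{3,}){3}") {
  seq <- normalize_seq(seq)
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(list(count = 0L, spans = tibble::tibble(start = integer(0),
                                                   end = integer(0))))
  }
  st <- as.integer(m) - 1L
  en <- st + attr(m, "match.length")
  list(count = length(st), spans = tibble::tibble(start = st, end = en))
}

#' Similarity to the consensus Kozak sequence
#'
#' Best sliding-window position-wise identity fraction against the
#' consensus `GCCGCCACCATGG` (DNA transliteration of GCCGCCACCAUGG).
#' Sequences shorter than the 13 nt consensus are undefined and return
#' `NA` with a warning.
#'
#' @param seq a single nucleotide string.
#' @return a list: `score` (identity fraction in `[0, 1]`) and `position`
#'   (0-based offset of the best window; ties to the earliest).
#' @export
kozak_similarity <- function(seq) {
  seq <- normalize_seq(seq)
  w <- nchar(KOZAK_CONSENSUS)
  if (nchar(seq) < w) {
    warning("sequence shorter than the ", w, " nt Kozak consensus; NA",
            call. = FALSE)
    return(list(score = NA_real_, position = NA_integer_))
  }
  cons <- strsplit(KOZAK_CONSENSUS, "")[[1]]
  chars <- strsplit(seq, "")[[1]]
  npos <- nchar(seq) - w + 1L
  sc <- vapply(seq_len(npos), function(p) {
    mean(chars[p:(p + w - 1L)] == cons)
  }, numeric(1))
  best <- which.max(sc)
  list(score = sc[best], position = best - 1L)
}

#' Compare two metric distributions
#'
#' Two-sample distributional test between the same metric measured on two
#' sequence sets; Kolmogorov-Smirnov by default. Degenerate (constant,
#' identical) inputs are reported as such rather than tested.
#'
#' @param a,b numeric vectors, or `utr_eval` reports (then `metric` selects
#'   the distribution).
#' @param metric metric name when `a`/`b` are evaluation reports.
#' @param test `"ks"` or `"wilcox"`.
#' @return a tibble: `statistic`, `p_value`, `test`, `n_a`, `n_b`,
#'   `degenerate`.
#' @export
compare_sets <- function(a, b, metric = NULL, test = c("ks", "wilcox")) {
  test <- match.arg(test)
  if (inherits(a, "utr_eval")) a <- a$per_seq[[metric]]
  if (inherits(b, "utr_eval")) b <- b$per_seq[[metric]]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  degenerate <- length(unique(c(a, b))) == 1L
  if (degenerate) {
    return(tibble::tibble(statistic = 0, p_value = 1, test = test,
                          n_a = length(a), n_b = length(b),
                          degenerate = TRUE))
  }
  ht <- if (test == "ks") {
    suppressWarnings(stats::ks.test(a, b))
  } else {
    suppressWarnings(stats::wilcox.test(a, b))
  }
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = ht$p.value, test = test,
                 n_a = length(a), n_b = length(b), degenerate = FALSE)
}

#' Evaluate a sequence set
#'
#' Computes the per-sequence metric suite for a UTR set: length, GC
#' content, nearest-neighbour Levenshtein and k-mer distances to a natural
#' reference set (when supplied), MFE (when a folding backend is supplied
#' or RNAfold is available), and motif statistics (uORF count,
#' G-quadruplex count, best Kozak similarity). Empty sequences are excluded
#' with a logged count.
#'
#' @param x a UTR-set tibble or character vector (the set under
#'   evaluation).
#' @param natural optional reference UTR set for nearest-neighbour
#'   distances.
#' @param metrics subset of `c("gc", "levenshtein", "kmer", "mfe",
#'   "motifs")`.
#' @param exclude_identical skip exact matches in nearest-neighbour search
#'   (set `TRUE` when `x` and `natural` are the same set).
#' @param mfe_backend an `mfe_backend`; when `NULL` and `"mfe"` is
#'   requested, RNAfold is used if available, otherwise the metric is
#'   skipped with a warning (never fabricated).
#' @param k k-mer size (default 4).
#' @return an object of class `utr_eval`: `per_seq` tibble, `set_size`,
#'   `n_excluded_empty`, `mfe_backend` name, `config`.
#' @export
evaluate_utrs <- function(x, natural = NULL,
                          metrics = c("gc", "levenshtein", "kmer", "mfe",
                                      "motifs"),
                          exclude_identical = FALSE, mfe_backend = NULL,
                          k = 4L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  utrs <- if (is.data.frame(x)) x else utr_set(x)
  n_in <- nrow(utrs)
  empty <- nchar(utrs$seq) == 0
  if (any(empty)) {
    message(sum(empty), " empty sequence(s) excluded from evaluation")
    utrs <- utrs[!empty, ]
  }
  per <- tibble::tibble(id = utrs$id, seq = utrs$seq,
                        length = nchar(utrs$seq))
  if ("gc" %in% metrics) per$gc <- gc_content(utrs$seq)
  if (!is.null(natural)) {
    nat <- if (is.data.frame(natural)) natural else utr_set(natural)
    if ("levenshtein" %in% metrics) {
      per$levenshtein_nn <- nn_metric_column(utrs$seq, nat$seq,
                                             "levenshtein",
                                             exclude_identical, k)
    }
    if ("kmer" %in% metrics) {
      per$kmer_nn <- nn_metric_column(utrs$seq, nat$seq, "kmer",
                                      exclude_identical, k)
    }
  }
  backend_name <- NA_character_
  if ("mfe" %in% metrics) {
    if (is.null(mfe_backend) && Sys.which("RNAfold") != "") {
      mfe_backend <- mfe_backend_rnafold()
    }
    if (is.null(mfe_backend)) {
      warning("no folding backend available; MFE skipped", call. = FALSE)
    } else {
      vals <- mfe(utrs$seq, mfe_backend)
      per$mfe <- as.numeric(vals)
      backend_name <- attr(vals, "backend")
    }
  }
  if ("motifs" %in% metrics) {
    per$uorf_count <- vapply(utrs$seq, function(s) scan_uorfs(s)$count,
                             integer(1), USE.NAMES = FALSE)
    per$g4_count <- vapply(utrs$seq,
                           function(s) scan_g_quadruplex(s)$count,
                           integer(1), USE.NAMES = FALSE)
    per$kozak_best <- vapply(utrs$seq, function(s) {
      suppressWarnings(kozak_similarity(s)$score)
    }, numeric(1), USE.NAMES = FALSE)
  }
  structure(list(per_seq = per, set_size = nrow(per),
                 n_excluded_empty = n_in - nrow(per),
                 mfe_backend = backend_name,
                 config = list(metrics = metrics, k = k,
                               exclude_identical = exclude_identical)),
            class = "utr_eval")
}

# per-sequence NN distance aligned back to the full set (NA for excluded)
nn_metric_column <- function(q, t, metric, exclude_identical, k) {
  v <- suppressMessages(
    nn_distance_distribution(q, t, metric, exclude_identical, k))
  if (attr(v, "excluded") > 0) {
    # queries identical to every target were dropped; realign with NAs
    dropped <- vapply(q, function(s) all(t == s), logical(1))
    out <- rep(NA_real_, length(q))
    out[!dropped] <- v
    out
  } else {
    as.numeric(v)
  }
}

#' @export
print.utr_eval <- function(x, ...) {
  cat("<utr_eval>", x$set_size, "sequences\n")
  num <- dplyr::select(x$per_seq, dplyr::where(is.numeric))
  means <- vapply(num, mean, numeric(1), na.rm = TRUE)
  for (nm in names(means)) {
    cat(sprintf("  %-16s mean %.4g\n", nm, means[[nm]]))
  }
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x a `utr_eval`.
#' @param ... unused.
#' @return the per-sequence metric tibble.
#' @export
tidy.utr_eval <- function(x, ...) x$per_seq

#' One-row summary of an evaluation report
#'
#' @param x a `utr_eval`.
#' @param ... unused.
#' @return a tibble of set size and per-metric means.
#' @export
glance.utr_eval <- function(x, ...) {
  num <- dplyr::select(x$per_seq, dplyr::where(is.numeric))
  means <- lapply(num, mean, na.rm = TRUE)
  names(means) <- paste0("mean_", names(means))
  tibble::as_tibble(c(list(n = x$set_size), means))
}
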