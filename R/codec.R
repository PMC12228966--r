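# Sequence codec: nucleotide strings <-> 5-channel one-hot matrices.
#
# Channel order is fixed as (A, C, G, T, PAD). Pads live only at the 3' end of
# a hard sequence; decode() truncates at the first PAD argmax, which defines
# the canonical reading of arbitrary (soft) generator output.

UTR_CHANNELS <- c("A", "C", "G", "T", "PAD")
UTR_WIDTH <- 128L

#' Build a UTR set
#'
#' A UTR set is a tibble with columns `id` and `seq`, the container used by
#' every function in the package that consumes or produces sequence sets.
#' Sequences are normalized to uppercase DNA (`U` becomes `T`) and validated
#' against the `{A,C,G,T}` alphabet and the maximum width of `r UTR_WIDTH` nt.
#'
#' @param seq character vector of nucleotide sequences (DNA or RNA case
#'   insensitive).
#' @param id optional character vector of identifiers; defaults to
#'   `utr_1 ... utr_n`.
#' @param max_width maximum sequence length accepted (default 128).
#' @return a tibble with columns `id` (character) and `seq` (character).
#' @examples
#' utr_set(c("ACGU", "ggcc"))
#' @export
utr_set <- function(seq, id = NULL, max_width = UTR_WIDTH) {
  seq <- normalize_seq(seq)
  if (is.null(id)) id <- paste0("utr_", seq_along(seq))
  stopifnot(length(id) == length(seq))
  bad <- grep("[^ACGT]", seq)
  if (length(bad) > 0) {
    ch <- regmatches(seq[bad[1]], regexpr("[^ACGT]", seq[bad[1]]))
    stop("invalid character '", ch, "' in sequence ", bad[1],
         " (id ", id[bad[1]], ")", call. = FALSE)
  }
  too_long <- which(nchar(seq) > max_width)
  if (length(too_long) > 0) {
    stop("sequence ", too_long[1], " exceeds maximum width ", max_width,
         " (length ", nchar(seq[too_long[1]]), ")", call. = FALSE)
  }
  tibble::tibble(id = as.character(id), seq = seq)
}

normalize_seq <- function(seq) {
  seq <- toupper(as.character(seq))
  gsub("U", "T", seq, fixed = TRUE)
}

#' One-hot encode a nucleotide sequence
#'
#' Produces a `width` x 5 matrix over the channels (A, C, G, T, PAD): each
#' occupied position carries the unit vector of its base, and positions past
#' the end of the sequence carry the PAD unit vector.
#'
#' @param seq a single nucleotide string over `{A,C,G,T,U}` (case
#'   insensitive), length at most `width`.
#' @param width matrix width in positions (default 128).
#' @return a numeric `width` x 5 matrix with rows summing to 1.
#' @examples
#' x <- encode_utr("ACGT", width = 6)
#' decode_onehot(x)
#' @export
encode_utr <- function(seq, width = UTR_WIDTH) {
  stopifnot(length(seq) == 1)
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n > width) {
    stop("sequence length ", n, " exceeds width ", width, call. = FALSE)
  }
  mat <- matrix(0, nrow = width, ncol = 5L,
                dimnames = list(NULL, UTR_CHANNELS))
  if (n > 0) {
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    idx <- match(bases, UTR_CHANNELS[1:4])
    if (anyNA(idx)) {
      stop("invalid character '", bases[which(is.na(idx))[1]],
           "' at position ", which(is.na(idx))[1], call. = FALSE)
    }
    mat[cbind(seq_len(n), idx)] <- 1
  }
  if (n < width) mat[(n + 1L):width, 5L] <- 1
  mat
}

#' One-hot encode a set of sequences into a batch
#'
#' @param x a UTR set tibble (columns `id`, `seq`) or a character vector.
#' @param width matrix width in positions (default 128).
#' @return an `onehot_batch`: a `(n * width)` x 5 matrix whose rows are
#'   grouped by sequence (sequence i occupies rows `(i-1)*width + 1 ...
#'   i*width`), with attributes `n` and `width`.
#' @export
encode_utrs <- function(x, width = UTR_WIDTH) {
  seqs <- if (is.data.frame(x)) x$seq else x
  mats <- lapply(seqs, encode_utr, width = width)
  onehot_batch(do.call(rbind, mats), n = length(seqs), width = width)
}

onehot_batch <- function(mat, n, width) {
  stopifnot(nrow(mat) == n * width, ncol(mat) == 5L)
  structure(mat, n = as.integer(n), width = as.integer(width),
            class = c("onehot_batch", "matrix", "array"))
}

batch_dims <- function(x) {
  list(n = attr(x, "n"), width = attr(x, "width"))
}

#' Decode a one-hot (or soft) matrix back to a nucleotide string
#'
#' Takes the per-position argmax channel and truncates at the first position
#' whose argmax is PAD; any content after an interior PAD is discarded. Soft
#' matrices (e.g. raw generator output) are decoded the same way, which makes
#' this the canonical hard reading of a generated sequence.
#'
#' @param mat a `width` x 5 numeric matrix.
#' @return a nucleotide string (possibly empty).
#' @export
decode_onehot <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 5L)
  am <- max.col(mat, ties.method = "first")
  stop_at <- match(5L, am)
  keep <- if (is.na(stop_at)) am else am[seq_len(stop_at - 1L)]
  if (length(keep) == 0) return("")
  paste(UTR_CHANNELS[keep], collapse = "")
}

#' Decode a batch of one-hot matrices
#'
#' @param batch an `onehot_batch` (see [encode_utrs()]).
#' @param id optional identifiers for the decoded set.
#' @return a UTR-set tibble (`id`, `seq`); empty decodes are kept as `""`.
#' @export
decode_batch <- function(batch, id = NULL) {
  d <- batch_dims(batch)
  seqs <- vapply(seq_len(d$n), function(i) {
    rows <- ((i - 1L) * d$width + 1L):(i * d$width)
    decode_onehot(batch[rows, , drop = FALSE])
  }, character(1))
  if (is.null(id)) id <- paste0("utr_", seq_len(d$n))
  tibble::tibble(id = as.character(id), seq = seqs)
}

nth_seq_rows <- function(batch, i) {
  d <- batch_dims(batch)
  ((i - 1L) * d$width + 1L):(i * d$width)
}

#' Read a UTR set from a FASTA file
#'
#' @param path path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @param drop_invalid if `TRUE`, records containing non-ACGT characters
#'   (after `U -> T`) or exceeding `max_width` are dropped with a warning
#'   naming their indices; if `FALSE` (default) such records are an error.
#' @param max_width maximum sequence length accepted (default 128).
#' @return a UTR-set tibble (`id`, `seq`).
#' @export
read_utr_fasta <- function(path, drop_invalid = FALSE, max_width = UTR_WIDTH) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- normalize_seq(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  bad <- which(grepl("[^ACGT]", seqs) | nchar(seqs) > max_width)
  if (length(bad) > 0) {
    if (!drop_invalid) {
      stop("record ", bad[1], " ('", ids[bad[1]],
           "') contains non-ACGT characters or exceeds width ", max_width,
           call. = FALSE)
    }
    warning("dropped ", length(bad), " invalid record(s): index ",
            paste(bad, collapse = ", "), call. = FALSE)
    seqs <- seqs[-bad]
    ids <- ids[-bad]
  }
  utr_set(seqs, id = ids, max_width = max_width)
}

#' Write a UTR set to a FASTA file
#'
#' @param x a UTR-set tibble (columns `id`, `seq`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(x$seq)
  names(ss) <- x$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
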