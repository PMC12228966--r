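# Fixed-geometry gene windows for expression-style scoring.
#
# A window is exactly 10 500 nt: 7000 nt upstream of the transcription start
# site (TSS) and 3500 nt at/after it, so the TSS always sits at 0-based index
# 7000 and the native 5' UTR occupies [7000, 7000 + utr_len). Replacing the
# UTR keeps the window length and the TSS position fixed: the native UTR is
# removed, the designed UTR inserted, and the downstream side re-windowed
# (drawing on extra source-gene context when available, neutral 'N' fill
# otherwise). Coordinates are 0-based half-open throughout.

GENE_WINDOW_LENGTH <- 10500L
GENE_WINDOW_TSS <- 7000L

#' Construct a gene window
#'
#' @param sequence DNA string of length exactly 10 500 (characters
#'   `A,C,G,T,N`; `N` marks neutral fill).
#' @param utr_len length of the native 5' UTR starting at the TSS (0-based
#'   index 7000).
#' @param gene_id identifier.
#' @param downstream extra source-gene context immediately past the window
#'   end, used to re-fill the tail when a shorter UTR is swapped in
#'   (default none).
#' @return an object of class `gene_window` with fields `sequence`,
#'   `tss_index` (always 7000), `utr_len`, `gene_id`, `downstream`.
#' @export
gene_window <- function(sequence, utr_len, gene_id = "gene",
                        downstream = "") {
  sequence <- toupper(sequence)
  if (nchar(sequence) != GENE_WINDOW_LENGTH) {
    stop("gene window must be exactly ", GENE_WINDOW_LENGTH,
         " nt, got ", nchar(sequence), call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("gene window contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  utr_len <- as.integer(utr_len)
  if (utr_len < 1L || GENE_WINDOW_TSS + utr_len > GENE_WINDOW_LENGTH) {
    stop("utr_len must be in [1, ", GENE_WINDOW_LENGTH - GENE_WINDOW_TSS,
         "], got ", utr_len, call. = FALSE)
  }
  structure(list(sequence = sequence, tss_index = GENE_WINDOW_TSS,
                 utr_len = utr_len, gene_id = gene_id,
                 downstream = toupper(downstream)),
            class = "gene_window")
}

#' @export
print.gene_window <- function(x, ...) {
  cat("<gene_window>", x$gene_id, " TSS@", x$tss_index,
      " native UTR [", x$tss_index, ",", x$tss_index + x$utr_len, ")\n",
      sep = "")
  invisible(x)
}

#' Extract a gene window around a TSS
#'
#' Slices `[tss_in_gene - 7000, tss_in_gene + 3500)` out of a gene sequence
#' so the TSS lands at window index 7000; positions falling outside the gene
#' are filled with `N` (a warning reports how many). Up to 128 nt of extra
#' downstream context is retained for later UTR replacement.
#'
#' @param gene_seq the full gene/locus DNA string.
#' @param tss_in_gene 0-based TSS index within `gene_seq`.
#' @param utr_len native 5' UTR length (>= 1).
#' @param gene_id identifier.
#' @return a `gene_window`.
#' @export
build_window <- function(gene_seq, tss_in_gene, utr_len, gene_id = "gene") {
  gene_seq <- toupper(gene_seq)
  n <- nchar(gene_seq)
  tss_in_gene <- as.integer(tss_in_gene)
  start0 <- tss_in_gene - GENE_WINDOW_TSS          # 0-based, may be < 0
  end0 <- tss_in_gene + (GENE_WINDOW_LENGTH - GENE_WINDOW_TSS)
  left_pad <- max(0L, -start0)
  right_pad <- max(0L, end0 - n)
  core <- substr(gene_seq, max(1L, start0 + 1L), min(n, end0))
  seq <- paste0(strrep("N", left_pad), core, strrep("N", right_pad))
  if (left_pad + right_pad > 0L) {
    warning("gene '", gene_id, "': ", left_pad + right_pad,
            " window position(s) outside the gene filled with N",
            call. = FALSE)
  }
  extra <- substr(gene_seq, min(n, end0) + 1L, min(n, end0 + UTR_WIDTH))
  gene_window(seq, utr_len, gene_id, downstream = extra)
}

#' Replace the 5' UTR of a gene window
#'
#' Removes the native UTR at `[7000, 7000 + utr_len)`, inserts `ug`, and
#' re-windows to exactly 10 500 nt with the TSS fixed at index 7000. The
#' upstream 7000 nt are never touched. When `ug` is shorter than the native
#' UTR the tail is extended from the stored downstream context (neutral `N`
#' fill once that runs out); when longer, the tail is truncated.
#'
#' With `literal = TRUE` the raw published slicing arithmetic
#' `S[0:7000] + Ug + S[7000+len(Ug) : 10500-(len(Ug)-len(Ur))]` is applied
#' verbatim and the (generally not length-preserving) string is returned for
#' audit; the default path implements the length- and TSS-preserving
#' contract that a fixed-input-width predictor requires.
#'
#' @param w a `gene_window`.
#' @param ug replacement UTR, a DNA string of length 1..128.
#' @param literal return the literal slicing-formula string instead.
#' @return a `gene_window` (or a character string when `literal = TRUE`).
#' @export
replace_utr <- function(w, ug, literal = FALSE) {
  stopifnot(inherits(w, "gene_window"))
  ug <- normalize_seq(ug)
  lg <- nchar(ug)
  if (lg < 1L || lg > UTR_WIDTH) {
    stop("replacement UTR length must be in [1, ", UTR_WIDTH, "], got ", lg,
         call. = FALSE)
  }
  if (grepl("[^ACGT]", ug)) stop("replacement UTR must be ACGT", call. = FALSE)
  tss <- GENE_WINDOW_TSS
  if (literal) {
    upper <- GENE_WINDOW_LENGTH - (lg - w$utr_len)
    return(paste0(substr(w$sequence, 1L, tss), ug,
                  substr(w$sequence, tss + lg + 1L, upper)))
  }
  prefix <- substr(w$sequence, 1L, tss)
  after_native <- paste0(
    substr(w$sequence, tss + w$utr_len + 1L, GENE_WINDOW_LENGTH),
    w$downstream)
  tail_needed <- GENE_WINDOW_LENGTH - tss - lg
  tail <- substr(after_native, 1L, tail_needed)
  if (nchar(tail) < tail_needed) {
    tail <- paste0(tail, strrep("N", tail_needed - nchar(tail)))
  }
  leftover <- substr(after_native, tail_needed + 1L,
                     tail_needed + UTR_WIDTH)
  gene_window(paste0(prefix, ug, tail), utr_len = lg, gene_id = w$gene_id,
              downstream = leftover)
}

#' Slice the UTR part out of a window gradient
#'
#' Keeps positions `[7000, 7000 + L)` of a per-position gradient over the
#' 10 500 nt window — the only part of the predictor's input gradient that
#' the latent optimizer may act on — and discards the rest.
#'
#' @param grad numeric matrix with 10 500 rows (any number of channel
#'   columns) or a length-10 500 vector.
#' @param utr_len UTR length `L` in `[1, 128]`.
#' @return the gradient rows for the UTR span, same column structure.
#' @export
slice_utr_gradient <- function(grad, utr_len) {
  utr_len <- as.integer(utr_len)
  if (utr_len < 1L || utr_len > UTR_WIDTH) {
    stop("utr_len must be in [1, ", UTR_WIDTH, "], got ", utr_len,
         call. = FALSE)
  }
  if (is.matrix(grad)) {
    stopifnot(nrow(grad) == GENE_WINDOW_LENGTH)
    grad[(GENE_WINDOW_TSS + 1L):(GENE_WINDOW_TSS + utr_len), , drop = FALSE]
  } else {
    stopifnot(length(grad) == GENE_WINDOW_LENGTH)
    grad[(GENE_WINDOW_TSS + 1L):(GENE_WINDOW_TSS + utr_len)]
  }
}

# encode a window string to 10500 x 5; N becomes the uniform 4-channel vector
encode_window_seq <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, c(UTR_CHANNELS[1:4], "N"))
  stopifnot(!anyNA(idx))
  mat <- matrix(0, length(chars), 5L, dimnames = list(NULL, UTR_CHANNELS))
  hard <- idx <= 4L
  mat[cbind(which(hard), idx[hard])] <- 1
  mat[!hard, 1:4] <- 0.25
  mat
}

# Soft embedding used by the optimizer: apply the replace_utr geometry with a
# placeholder of length L, encode the resulting context, then overlay the
# soft UTR rows at [7000, 7000 + L). With a hard UTR this reduces exactly to
# encode(replace_utr(w, ug)).
embed_soft_utr <- function(w, soft_utr_rows) {
  L <- nrow(soft_utr_rows)
  ctx <- replace_utr(w, strrep("A", L))
  M <- encode_window_seq(ctx$sequence)
  M[(GENE_WINDOW_TSS + 1L):(GENE_WINDOW_TSS + L), ] <- soft_utr_rows
  M
}

#' Read gene windows from FASTA plus annotation
#'
#' The side-car annotation is tab-separated with columns `gene_id`,
#' `tss_index` (0-based index of the TSS within the FASTA record) and
#' `utr_length`; every annotation row must match a FASTA record by id.
#'
#' @param fasta_path FASTA of gene/locus sequences.
#' @param annot_path TSV annotation path.
#' @return a list of `gene_window` objects.
#' @export
read_gene_windows <- function(fasta_path, annot_path) {
  ss <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  ann <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
  need <- c("gene_id", "tss_index", "utr_length")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(ann$gene_id, ids)
  if (length(missing) > 0) {
    stop("annotation rows without FASTA record: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(ann)), function(i) {
    rec <- as.character(ss[[match(ann$gene_id[i], ids)]])
    build_window(rec, ann$tss_index[i], ann$utr_length[i], ann$gene_id[i])
  })
}
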