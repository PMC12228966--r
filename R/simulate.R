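# Synthetic data generation.
#
# Emulates, at desk scale, the natural 5' UTR training sets and annotated
# gene windows the pipeline consumes: i.i.d. bases with a per-sequence GC
# fraction drawn from a truncated normal, uniform lengths, and optionally
# planted canonical motifs with ground-truth spans. The i.i.d. base model
# carries no positional dependence and is deliberately not a model of real
# human UTR statistics; it exists so every consumer is testable offline.

#' Simulate a natural-like 5' UTR set
#'
#' @param n number of sequences.
#' @param min_len,max_len length range; lengths are uniform in
#'   `[min_len, max_len]` (defaults 32 and 128).
#' @param gc_mean,gc_sd per-sequence GC fraction is drawn from
#'   Normal(`gc_mean`, `gc_sd`) truncated to `[0, 1]` (defaults 0.6, 0.1,
#'   a human-5'-UTR-like composition).
#' @param kozak_rate,uorf_rate,g4_rate per-sequence probabilities of
#'   planting, at a random valid position: the Kozak consensus
#'   `GCCGCCACCATGG`, a minimal uORF (`ATG` + 0-3 random codons + stop),
#'   or a minimal G-quadruplex (`GGGAGGGAGGGAGGG`). Planted spans are
#'   recorded in the `motifs` attribute (tibble: id, motif, start, end;
#'   0-based half-open) as ground truth for scanner checks.
#' @param seed optional integer seed; same seed, same set.
#' @return a UTR-set tibble (`id`, `seq`) with attribute `motifs`.
#' @export
simulate_utrs <- function(n, min_len = 32L, max_len = 128L, gc_mean = 0.6,
                          gc_sd = 0.1, kozak_rate = 0, uorf_rate = 0,
                          g4_rate = 0, seed = NULL) {
  stopifnot(n >= 1, min_len >= 1L, min_len <= max_len,
            max_len <= UTR_WIDTH,
            kozak_rate >= 0, kozak_rate <= 1, uorf_rate >= 0,
            uorf_rate <= 1, g4_rate >= 0, g4_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(min_len:max_len, n, replace = TRUE)
  gcs <- rtrunc_norm(n, gc_mean, gc_sd)
  seqs <- vapply(seq_len(n), function(i) {
    p <- c((1 - gcs[i]) / 2, gcs[i] / 2, gcs[i] / 2, (1 - gcs[i]) / 2)
    paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  ids <- paste0("nat_", seq_len(n))
  motifs <- list()
  plant <- function(i, motif_seq, label) {
    L <- nchar(seqs[i])
    w <- nchar(motif_seq)
    if (w > L) return(invisible(NULL))
    at <- sample.int(L - w + 1L, 1L)           # 1-based insertion point
    seqs[i] <<- paste0(substr(seqs[i], 1L, at - 1L), motif_seq,
                       substr(seqs[i], at + w, L))
    motifs[[length(motifs) + 1L]] <<- tibble::tibble(
      id = ids[i], motif = label, start = at - 1L, end = at - 1L + w)
  }
  for (i in seq_len(n)) {
    if (kozak_rate > 0 && stats::runif(1) < kozak_rate) {
      plant(i, KOZAK_CONSENSUS, "kozak")
    }
    if (uorf_rate > 0 && stats::runif(1) < uorf_rate) {
      k_codons <- sample(0:3, 1L)
      body <- paste(sample(c("A", "C", "G", "T"), 3L * k_codons,
                           replace = TRUE), collapse = "")
      # codons must not themselves be stops, or the span shifts
      u <- paste0("ATG", gsub("TAA|TAG|TGA", "CCC", body), "TAA")
      plant(i, u, "uorf")
    }
    if (g4_rate > 0 && stats::runif(1) < g4_rate) {
      plant(i, "GGGAGGGAGGGAGGG", "g4")
    }
  }
  out <- tibble::tibble(id = ids, seq = seqs)
  attr(out, "motifs") <- if (length(motifs)) dplyr::bind_rows(motifs)
                         else tibble::tibble(id = character(0),
                                             motif = character(0),
                                             start = integer(0),
                                             end = integer(0))
  out
}

rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Simulate annotated gene windows
#'
#' Builds synthetic genes long enough that the extracted window needs no
#' fill: each gene is 10 628 nt of uniform-random bases with its TSS at
#' index 7000, a native UTR of the drawn length starting there, and 128 nt
#' of spare downstream context retained for UTR replacement.
#'
#' @param n number of windows.
#' @param utr_len_range native UTR length range (default `c(32, 128)`).
#' @param seed optional integer seed.
#' @return a list of `gene_window` objects.
#' @export
simulate_gene_windows <- function(n, utr_len_range = c(32L, 128L),
                                  seed = NULL) {
  stopifnot(n >= 1, utr_len_range[1] >= 1L,
            utr_len_range[2] >= utr_len_range[1])
  if (!is.null(seed)) set.seed(seed)
  gene_len <- GENE_WINDOW_LENGTH + UTR_WIDTH
  lapply(seq_len(n), function(i) {
    gene <- paste(sample(c("A", "C", "G", "T"), gene_len, replace = TRUE),
                  collapse = "")
    ulen <- sample(utr_len_range[1]:utr_len_range[2], 1L)
    build_window(gene, GENE_WINDOW_TSS, ulen,
                 gene_id = paste0("gene_", i))
  })
}

#' Write gene windows as FASTA plus annotation
#'
#' The inverse of [read_gene_windows()]: window sequences go to FASTA, and
#' a TSV records `gene_id`, `tss_index` (always 7000 within the written
#' record) and `utr_length`.
#'
#' @param windows a list of `gene_window` objects.
#' @param fasta_path,annot_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_gene_windows <- function(windows, fasta_path, annot_path) {
  stopifnot(all(vapply(windows, inherits, logical(1), "gene_window")))
  ss <- Biostrings::BStringSet(vapply(windows, function(w) w$sequence,
                                      character(1)))
  names(ss) <- vapply(windows, function(w) w$gene_id, character(1))
  Biostrings::writeXStringSet(ss, fasta_path)
  ann <- data.frame(
    gene_id = names(ss),
    tss_index = GENE_WINDOW_TSS,
    utr_length = vapply(windows, function(w) w$utr_len, integer(1)))
  utils::write.table(ann, annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, annot = annot_path))
}
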