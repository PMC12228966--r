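# Independent brute-force oracles used to validate the package's operations.
# These deliberately share no code with the implementation.

# textbook dynamic-programming edit distance
lev_dp <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[nb + 1]
}

# dictionary-counting k-mer frequency
kmer_freq_brute <- function(seq, k = 4) {
  n <- nchar(seq)
  if (n < k) return(stats::setNames(numeric(0), character(0)))
  kmers <- vapply(seq_len(n - k + 1), function(i) substr(seq, i, i + k - 1),
                  character(1))
  table(kmers) / length(kmers)
}

kmer_dist_brute <- function(a, b, k = 4) {
  fa <- kmer_freq_brute(a, k); fb <- kmer_freq_brute(b, k)
  keys <- union(names(fa), names(fb))
  va <- ifelse(keys %in% names(fa), as.numeric(fa[keys]), 0)
  vb <- ifelse(keys %in% names(fb), as.numeric(fb[keys]), 0)
  sqrt(sum((va - vb)^2))
}

# sliding-window best PWM match on a plain string
pwm_best_brute <- function(seq, pwm) {
  w <- nrow(pwm)
  chars <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  n <- length(chars)
  best <- -Inf
  for (p in seq_len(n - w + 1)) {
    s <- sum(pwm[cbind(seq_len(w), chars[p:(p + w - 1)])])
    if (s > best) best <- s
  }
  best
}

# frame-wise codon-walk uORF counter: for each reading frame, mark codons,
# and count ATG codons that have a stop codon later in the same frame
uorf_count_brute <- function(seq) {
  n <- nchar(seq)
  total <- 0L
  for (f in 0:2) {
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    if (f + 1L > n - 2L) next
    codons <- substring(seq, starts, starts + 2L)
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    atgs <- which(codons == "ATG")
    for (a in atgs) total <- total + any(stops > a)
  }
  total
}

# G-quadruplex count through R's TRE (non-perl) regex engine
g4_count_brute <- function(seq) {
  m <- gregexpr("G{3,}([ACGT]{1,7}G{3,}){3}", seq, perl = FALSE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

random_dna <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}
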