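# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; no data files.

rand_genome <- function(n) pssmap::simulate_genome(n)

rand_quals <- function(L, lo = 2L, hi = 40L) sample(lo:hi, L, replace = TRUE)

# substitute k random positions of a base string with a different base
with_mismatches <- function(s, k) {
  if (k == 0) return(s)
  v <- strsplit(s, "")[[1]]
  for (j in sample(length(v), k))
    v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
  paste(v, collapse = "")
}

# a read planted at 0-based position p of the genome, possibly on '-'
planted_read <- function(genome, p, L, strand = "+", quals = NULL,
                         mismatches = 0L, name = "r") {
  s <- substr(genome, p + 1, p + L)
  if (strand == "-") s <- pssmap::revcomp(s)
  s <- with_mismatches(s, mismatches)
  if (is.null(quals)) quals <- rand_quals(L)
  pssmap::read_record(name, s, quals)
}

# independent brute-force suffix array of a text (integer codes, sentinel 0
# appended), via string ordering of the decoded suffixes
naive_suffix_array <- function(text_int) {
  n <- length(text_int) + 1
  full <- c(text_int, 0L)
  suff <- vapply(seq_len(n), function(i)
    paste(full[i:n], collapse = ","), character(1))
  # pad each code to fixed width so lexicographic string order matches
  suff <- vapply(seq_len(n), function(i)
    paste(sprintf("%02d", full[i:n]), collapse = ""), character(1))
  order(suff) - 1L
}

# all 0-based occurrences of pattern in genome (both strands), naive scan
naive_occurrences <- function(genome, pattern) {
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pattern else pssmap::revcomp(pattern)
    G <- nchar(genome); L <- nchar(pat)
    if (L <= G) {
      for (p in 0:(G - L)) {
        if (substr(genome, p + 1, p + L) == pat)
          hits[[length(hits) + 1]] <- list(pos = p, strand = strand)
      }
    }
  }
  hits
}

hit_key <- function(df) paste(df$pos, df$strand)

# best linear-gap alignment score of a PSSM against a genome (both strands):
# global in the read, free genome start/end.  Independent DP oracle for the
# gapped search.  Returns the best score over all windows.
dp_best_score <- function(genome, pssm, rho_i, rho_d) {
  best <- -Inf
  for (gv in list(pssmap:::encode_bases(genome),
                  pssmap:::encode_bases(pssmap::revcomp(genome)))) {
    G <- length(gv)
    L <- nrow(pssm$scores)
    # M[i+1, j+1]: best score of read columns 1..i aligned ending at genome
    # position j (read consumed left to right on this strand's forward text)
    M <- matrix(-Inf, L + 1, G + 1)
    M[1, ] <- 0  # free start
    for (i in seq_len(L)) {
      for (j in 0:G) {
        v <- -Inf
        if (j >= 1) v <- max(v, M[i, j] + pssm$scores[i, gv[j]])   # (mis)match
        v <- max(v, M[i, j + 1] - rho_i)                           # insertion
        if (j >= 1) v <- max(v, M[i + 1, j] - rho_d)               # deletion
        M[i + 1, j + 1] <- v
      }
    }
    best <- max(best, max(M[L + 1, ]))
  }
  best
}
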