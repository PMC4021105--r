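# Shared alphabet constants and encoding helpers.
BASES <- c("A", "C", "G", "T")

# integer encoding A=1 C=2 G=3 T=4, N=0 (see src/); complement is 5-b
encode_bases <- function(x) {
  code <- integer(128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("a")] <- 1L
  code[utf8ToInt("C")] <- 2L; code[utf8ToInt("c")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("g")] <- 3L
  code[utf8ToInt("T")] <- 4L; code[utf8ToInt("t")] <- 4L
  code[utf8ToInt("N")] <- 5L; code[utf8ToInt("n")] <- 5L
  v <- code[utf8ToInt(x)]
  if (any(v == 0L)) stop("sequence contains characters outside A,C,G,T,N")
  v[v == 5L] <- 0L  # N
  v
}

decode_bases <- function(v) {
  intToUtf8(c(utf8ToInt("N"), utf8ToInt("A"), utf8ToInt("C"),
              utf8ToInt("G"), utf8ToInt("T"))[v + 1L])
}

revcomp_int <- function(v) {
  out <- rev(5L - v)
  out[out == 5L] <- 0L  # N stays N
  out
}

#' Reverse-complement a nucleotide string
#'
#' @param x character scalar over A, C, G, T, N (case-insensitive).
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(x) decode_bases(revcomp_int(encode_bases(x)))
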