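# FM-index over the concatenation of the genome and its reverse complement.
# A single sentinel (lexicographically smallest) terminates the text; hits
# from the second half are reflected onto '-'-strand forward coordinates.

#' Build an FM-index of a genome
#'
#' Indexes `genome ++ reverse_complement(genome) ++ sentinel`, so a single
#' backward search of the read finds both strands.  `N` bases are replaced
#' by a deterministic pseudo-random base and their positions recorded; hits
#' overlapping them are rejected at locate time.  Multi-sequence input is
#' concatenated and per-sequence offsets recorded; hits spanning a junction
#' are rejected.
#'
#' @param genome a character string, a named character vector (one element
#'   per chromosome), or a `Biostrings::DNAStringSet`.
#' @param occ_rate spacing of occurrence checkpoints (default 128).
#' @param sa_rate suffix-array sampling rate (default 32).
#' @return Object of class `fm_index`.
#' @export
fm_index <- function(genome, occ_rate = 128L, sa_rate = 32L) {
  if (inherits(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  if (!is.character(genome) || length(genome) < 1)
    stop("genome must be a character vector or DNAStringSet")
  if (any(nchar(genome) == 0)) stop("empty genome sequence")
  nms <- names(genome)
  if (is.null(nms)) nms <- if (length(genome) == 1) "seq1"
                           else paste0("seq", seq_along(genome))
  lens <- nchar(genome)
  offsets <- cumsum(c(0, lens[-length(lens)]))
  v <- encode_bases(paste(toupper(genome), collapse = ""))
  if (any(!v %in% 0:4)) stop("genome contains characters outside A,C,G,T,N")
  fwd_len <- length(v)

  mask <- which(v == 0L) - 1L  # 0-based former-N positions
  if (length(mask)) {
    # deterministic pseudo-random replacement keyed by position
    v[mask + 1L] <- ((mask * 2654435761) %% 4) + 1L
  }
  text <- c(v, rev(5L - v))
  core <- cpp_fm_build(text, as.integer(occ_rate), as.integer(sa_rate))

  structure(list(core = core,
                 forward_length = fwd_len,
                 text_length = 2L * fwd_len,
                 mask = as.integer(mask),
                 junctions = as.integer(offsets[-1]),
                 meta = reference_meta(nms, lens),
                 base_freqs = .base_freqs(v)),
            class = "fm_index")
}

#' Per-sequence reference metadata
#'
#' @param names,lengths sequence names and lengths.
#' @return Object of class `reference_meta` with names, lengths and strictly
#'   increasing cumulative offsets into the concatenated genome.
#' @export
reference_meta <- function(names, lengths) {
  stopifnot(length(names) == length(lengths), all(lengths > 0))
  structure(list(names = as.character(names), lengths = as.integer(lengths),
                 offsets = as.integer(cumsum(c(0, lengths[-length(lengths)])))),
            class = "reference_meta")
}

#' @export
print.fm_index <- function(x, ...) {
  cat("<fm_index> ", length(x$meta$names), " sequence(s), ",
      x$forward_length, " bp forward, text length ", x$text_length + 1L,
      " (incl. sentinel)\n", sep = "")
  invisible(x)
}

#' Suffix-array interval
#'
#' Intervals are 0-based inclusive ranks; the interval is empty iff `k > l`.
#'
#' @param k,l lower and upper rank.
#' @return Object of class `sa_interval`.
#' @export
sa_interval <- function(k, l) {
  structure(list(k = as.integer(k), l = as.integer(l)), class = "sa_interval")
}

#' Full-text interval of an index
#' @param idx an [fm_index()].
#' @return The [sa_interval()] covering every suffix rank.
#' @export
full_interval <- function(idx) sa_interval(0L, idx$core$n - 1L)

#' Is an interval empty?
#' @param iv an [sa_interval()].
#' @export
is_empty_interval <- function(iv) iv$k > iv$l

#' Interval width (number of occurrences of the spelled pattern)
#' @param iv an [sa_interval()].
#' @export
interval_width <- function(iv) max(0L, iv$l - iv$k + 1L)

#' One backward-search step
#'
#' Prepends base `b` to the current pattern, updating the suffix-array
#' interval via the C array and occurrence counts.
#'
#' @param idx an [fm_index()].
#' @param iv an [sa_interval()].
#' @param b a base `"A","C","G","T"` (or its integer code 1..4).
#' @return The updated [sa_interval()]; empty in, empty out.
#' @export
backward_step <- function(idx, iv, b) {
  stopifnot(inherits(idx, "fm_index"), inherits(iv, "sa_interval"))
  if (is.character(b)) b <- match(b, BASES)
  if (is.na(b) || b < 1 || b > 4) stop("base must be one of A, C, G, T")
  r <- cpp_backward_step(idx$core, iv$k, iv$l, as.integer(b))
  sa_interval(r[1], r[2])
}

#' Locate a suffix rank on the forward genome
#'
#' Recovers the text position via the sampled suffix array and LF walking,
#' then maps it onto forward coordinates: positions in the second
#' (reverse-complement) half are reflected and reported on strand `-`.
#' Matches spanning the strand junction, a chromosome junction, or masked
#' (former `N`) positions are rejected (`NULL`).
#'
#' @param idx an [fm_index()].
#' @param k a suffix rank.
#' @param match_length reference span of the match (default 1).
#' @return `list(position=, strand=)` with a 0-based forward offset, or
#'   `NULL` for a rejected junction/mask overlap.
#' @export
locate <- function(idx, k, match_length = 1L) {
  stopifnot(inherits(idx, "fm_index"))
  if (k < 0 || k >= idx$core$n) stop("rank out of range")
  p <- cpp_locate_rank(idx$core, as.integer(k))
  F <- idx$forward_length
  m <- as.integer(match_length)
  if (p + m <= F) {
    pos <- p; strand <- "+"
  } else if (p >= F && p + m <= 2L * F) {
    pos <- 2L * F - p - m; strand <- "-"
  } else {
    return(NULL)
  }
  if (length(idx$mask) &&
      any(idx$mask >= pos & idx$mask < pos + m)) return(NULL)
  if (length(idx$junctions) &&
      any(idx$junctions > pos & idx$junctions < pos + m)) return(NULL)
  list(position = pos, strand = strand)
}

# map a concatenated forward offset to (sequence name, 0-based local offset)
chromosome_of <- function(meta, pos) {
  i <- findInterval(pos, meta$offsets)
  list(name = meta$names[i], offset = pos - meta$offsets[i])
}
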