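# Seeded synthetic data: genomes, reads with position-dependent quality
# profiles and optional damage / PAR-CLIP / mutation processes, and the
# sensitivity/PPV evaluation harness.

#' Simulate an i.i.d. genome
#'
#' @param length genome length (>= 1).
#' @param composition named base probabilities (A, C, G, T); defaults to
#'   uniform.  An `at_fraction` shortcut is available via
#'   [at_composition()].
#' @param seed optional RNG seed; the output is fully determined by it.
#' @return A character string.
#' @export
simulate_genome <- function(length, composition = NULL, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(composition)) composition <- rep(0.25, 4)
  composition <- as.numeric(composition[seq_len(4)])
  if (anyNA(composition) || any(composition < 0) || sum(composition) <= 0)
    stop("invalid composition")
  composition <- composition / sum(composition)
  decode_bases(sample.int(4, length, replace = TRUE, prob = composition))
}

#' Base composition with a given AT fraction
#'
#' @param at_fraction total probability of A plus T (split evenly), e.g.
#'   0.8 for an AT-rich genome.
#' @return Named probability vector.
#' @export
at_composition <- function(at_fraction) {
  stopifnot(at_fraction >= 0, at_fraction <= 1)
  setNames(c(at_fraction / 2, (1 - at_fraction) / 2,
             (1 - at_fraction) / 2, at_fraction / 2), BASES)
}

#' Read-simulation profile
#'
#' Qualities are drawn per position from normal distributions whose mean
#' and standard deviation interpolate linearly between the 5' and 3' values
#' (the usual position-dependent Illumina profile shape), rounded and
#' clamped to `[2, 40]`.  Base changes are applied in generative order:
#' sample-level mutation `P(a|g)`, then bias `p_i(b|a)`, then a sequencing
#' error at rate `10^(-Q_i/10)`.
#'
#' @param read_length read length, or a length-2 range to draw uniformly.
#' @param q_mean,q_sd length-2 vectors: mean/sd of the quality at the 5'
#'   and 3' end.
#' @param q_range drawn qualities are clamped to this range
#'   (default `c(2, 40)`, the usual Illumina span).
#' @param mut a [mutation_model()] for sample-level mutations.
#' @param bias a [bias_model()] applied to the sampled bases.
#' @return Object of class `sim_profile`.
#' @export
sim_profile <- function(read_length = 36L, q_mean = c(35, 22),
                        q_sd = c(2, 6), q_range = c(2L, 40L),
                        mut = mutation_model(p0 = 0),
                        bias = bias_model("none")) {
  structure(list(read_length = as.integer(read_length),
                 q_mean = q_mean, q_sd = q_sd,
                 q_range = as.integer(q_range), mut = mut, bias = bias),
            class = "sim_profile")
}

# one quality vector under the profile
.draw_quals <- function(profile, L) {
  w <- if (L > 1) (seq_len(L) - 1) / (L - 1) else 0
  m <- profile$q_mean[1] * (1 - w) + profile$q_mean[2] * w
  s <- profile$q_sd[1] * (1 - w) + profile$q_sd[2] * w
  pmin(profile$q_range[2], pmax(profile$q_range[1],
                                as.integer(round(rnorm(L, m, s)))))
}

# apply a 4x4 row-stochastic change matrix to encoded bases, by sampling
.apply_change <- function(v, M) {
  out <- v
  for (b in 1:4) {
    sel <- which(v == b)
    if (length(sel))
      out[sel] <- sample.int(4, length(sel), replace = TRUE, prob = M[b, ])
  }
  out
}

#' Simulate reads from a genome
#'
#' Start positions are uniform, strands random.  The truth table records
#' the 0-based origin and strand of every read.
#'
#' @param genome character string (single sequence).
#' @param profile a [sim_profile()].
#' @param n_reads number of reads.
#' @param seed optional RNG seed.
#' @return `list(reads = <list of read_record>, truth = <data.frame>)` with
#'   truth columns `name`, `pos` (0-based forward), `strand`, `length`.
#' @export
simulate_reads <- function(genome, profile, n_reads, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- encode_bases(genome)
  G <- length(g)
  lens <- if (length(profile$read_length) == 2)
    sample(profile$read_length[1]:profile$read_length[2], n_reads,
           replace = TRUE)
  else rep(profile$read_length, n_reads)
  if (max(lens) > G) stop("genome shorter than the read length")
  Mmut <- mutation_matrix(profile$mut)
  reads <- vector("list", n_reads)
  pos <- integer(n_reads)
  strand <- character(n_reads)
  for (i in seq_len(n_reads)) {
    L <- lens[i]
    p <- sample.int(G - L + 1L, 1L) - 1L
    minus <- runif(1) < 0.5
    frag <- g[(p + 1):(p + L)]
    if (minus) frag <- 5L - rev(frag)
    # sample-level mutation, then data-specific bias (both in read
    # orientation: damage acts on the sequenced fragment ends)
    a <- .apply_change(frag, Mmut)
    b <- a
    if (profile$bias$kind == "parclip") {
      B <- bias_matrix(profile$bias, 0L, L)
      b <- .apply_change(a, B)
    } else if (profile$bias$kind == "ancient") {
      for (j in seq_len(L)) {
        B <- bias_matrix(profile$bias, j - 1L, L)
        b[j] <- sample.int(4, 1L, prob = B[a[j], ])
      }
    }
    q <- .draw_quals(profile, L)
    pe <- phred_to_error_prob(q)
    err <- runif(L) < pe
    x <- b
    if (any(err)) {
      # a sequencing error substitutes one of the three other bases
      shift <- sample.int(3L, sum(err), replace = TRUE)
      x[err] <- ((x[err] - 1L + shift) %% 4L) + 1L
    }
    reads[[i]] <- read_record(sprintf("read%06d", i), decode_bases(x), q)
    pos[i] <- p
    strand[i] <- if (minus) "-" else "+"
  }
  truth <- data.frame(name = vapply(reads, `[[`, "", "name"),
                      pos = pos, strand = strand, length = lens,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Evaluate a mapping against the simulation truth
#'
#' A read counts as correctly mapped iff the primary record's chromosome,
#' strand and start position equal the truth — exactly for ungapped hits,
#' within the total indel count for gapped ones (the coordinate ambiguity
#' a gap introduces).  Sensitivity is correct/total reads, PPV is
#' correct/reported.  Filtered metrics drop records below the MapQ
#' threshold first.
#'
#' @param mapping a [map_reads()] result, or a path to a SAM file written
#'   by [write_sam()].
#' @param truth truth table from [simulate_reads()] (must cover every
#'   evaluated read; single-sequence references use its `pos` as the
#'   0-based offset in the first indexed sequence).
#' @param mapq_threshold MapQ cutoff for the filtered metrics (default 25).
#' @return Object of class `eval_report`: total/reported/correct counts and
#'   sensitivity/PPV, unfiltered and filtered.
#' @export
evaluate_mapping <- function(mapping, truth, mapq_threshold = 25L) {
  if (is.character(mapping)) {
    sam <- read_sam(mapping)
    hits <- sam[sam$mapped, c("name", "chrom", "pos", "strand", "mapq",
                              "cigar")]
    hits$offset <- hits$pos - 1L
    hits$indels <- vapply(hits$cigar, .cigar_indels, integer(1))
  } else {
    ph <- primary_hits(mapping)
    hits <- ph
    hits$indels <- ph$a_i + ph$a_d
  }
  if (!all(hits$name %in% truth$name))
    stop("mapped read(s) absent from the truth table")
  m <- match(hits$name, truth$name)
  tol <- hits$indels
  correct <- hits$strand == truth$strand[m] &
    abs(hits$offset - truth$pos[m]) <= tol
  report <- function(keep) {
    n_rep <- sum(keep)
    n_cor <- sum(correct & keep)
    list(reported = n_rep, correct = n_cor,
         sensitivity = n_cor / nrow(truth),
         ppv = if (n_rep > 0) n_cor / n_rep else NA_real_)
  }
  unf <- report(rep(TRUE, nrow(hits)))
  fil <- report(hits$mapq >= mapq_threshold)
  structure(list(total = nrow(truth), unfiltered = unf, filtered = fil,
                 mapq_threshold = mapq_threshold),
            class = "eval_report")
}

.cigar_indels <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  parts <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1]]
  sum(as.integer(sub("[MID]", "", parts[grepl("[ID]", parts)])), 0L)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$total, " reads\n", sep = "")
  cat(sprintf("  unfiltered: %d reported, %d correct, sens %.4f, ppv %.4f\n",
              x$unfiltered$reported, x$unfiltered$correct,
              x$unfiltered$sensitivity, x$unfiltered$ppv))
  cat(sprintf("  MapQ>=%d:  %d reported, %d correct, sens %.4f, ppv %.4f\n",
              x$mapq_threshold, x$filtered$reported, x$filtered$correct,
              x$filtered$sensitivity, x$filtered$ppv))
  invisible(x)
}
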