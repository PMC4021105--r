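# Readers and writers: FASTA/FASTQ (via Biostrings), PSSM text files,
# score lookup tables, SAM output.

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @param offset quality encoding offset, 33 (default) or 64.
#' @return List of [read_record()]s.
#' @export
read_fastq <- function(path, offset = 33L) {
  if (!offset %in% c(33L, 64L)) stop("offset must be 33 or 64")
  # light structural pre-validation: the established parser pads malformed
  # quality lines silently instead of erroring, so length mismatches are
  # caught here, by record name
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("FASTQ file is not made of 4-line records: ", path)
  if (length(lines) == 0) return(list())
  nm_line <- lines[seq(1, length(lines), by = 4)]
  sq <- lines[seq(2, length(lines), by = 4)]
  ql <- lines[seq(4, length(lines), by = 4)]
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop("FASTQ record '", sub("^@", "", nm_line[bad[1]]),
         "': sequence and quality lengths differ")
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- unname(as.character(x))
  nms <- names(x)
  lapply(seq_along(x), function(i) {
    q <- utf8ToInt(quals[i]) - as.integer(offset)
    read_record(nms[i], seqs[i], q)
  })
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads as FASTQ (offset 33)
#'
#' @param reads list of [read_record()]s.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    writeLines(c(paste0("@", r$name), r$bases, "+",
                 intToUtf8(r$quals + 33L)), con)
  }
  invisible(path)
}

#' Read a PSSM text file
#'
#' Format: a header line `>name length` followed by one line per read
#' position holding four tab-separated log2 scores in A, C, G, T order.
#' Several PSSMs may be concatenated in one file.
#'
#' @param path input file.
#' @return List of `pssm` objects (with an `N`-filled placeholder read).
#' @export
read_pssm_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">"))
      stop("expected a '>' header at line ", i)
    hdr <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    name <- hdr[1]
    L <- as.integer(hdr[2])
    if (is.na(L) || i + L > length(lines))
      stop("PSSM '", name, "': bad or truncated length")
    rows <- lines[(i + 1):(i + L)]
    scores <- do.call(rbind, lapply(rows, function(s)
      as.numeric(strsplit(s, "\t", fixed = TRUE)[[1]])))
    if (ncol(scores) != 4 || anyNA(scores))
      stop("PSSM '", name, "': each row needs 4 numeric scores")
    colnames(scores) <- BASES
    out[[length(out) + 1]] <- structure(
      list(scores = scores,
           col_max = apply(scores, 1, max),
           col_min = apply(scores, 1, min),
           read = read_record(name, strrep("N", L), rep(0L, L))),
      class = "pssm")
    i <- i + L + 1
  }
  out
}

#' Write PSSMs to a text file
#'
#' @param pssms a `pssm` or list of them.
#' @param path output file.
#' @export
write_pssm_file <- function(pssms, path) {
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pssms) {
    writeLines(paste0(">", p$read$name, " ", nrow(p$scores)), con)
    apply(p$scores, 1, function(row)
      writeLines(paste(format(row, digits = 10, trim = TRUE),
                       collapse = "\t"), con))
  }
  invisible(path)
}

#' Write a (base, quality) -> scores lookup table
#'
#' Tab-separated rows `base  quality  s(A) s(C) s(G) s(T)` giving the direct
#' translation of called base and quality to PSSM scores under a model
#' (position-independent models only).
#'
#' @param mut,bias,bg the model (see [build_pssm()]).
#' @param path output file.
#' @param quals qualities to tabulate (default 0:93).
#' @export
write_lookup_table <- function(mut, bias, bg, path, quals = 0:93) {
  if (bias$kind == "ancient")
    stop("the ancient model is position-dependent; no flat table exists")
  tab <- .pssm_table(mut, bias, bg, quals, 0L, 1L)
  rows <- do.call(rbind, lapply(1:4, function(b) {
    data.frame(base = BASES[b], quality = quals,
               A = tab[b, , 1, 1], C = tab[b, , 1, 2],
               G = tab[b, , 1, 3], T = tab[b, , 1, 4])
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# reverse-complement of a base string, reversed quality string
.orient <- function(bases, quals, minus) {
  if (!minus) return(list(seq = bases, qual = intToUtf8(quals + 33L)))
  list(seq = revcomp(bases), qual = intToUtf8(rev(quals) + 33L))
}

#' Write mapping results as SAM
#'
#' Emits a valid SAM file: `@HD`/`@SQ`/`@PG` header, 1-based positions,
#' FLAG 4 for unmapped reads, FLAG 16 (and reverse-complemented SEQ,
#' reversed QUAL) for `-`-strand hits, CIGAR from the indel path, MAPQ from
#' the posterior, and the posterior itself in the `ZP:f` tag.
#'
#' @param result a [map_reads()] result.
#' @param path output file.
#' @param secondary also emit non-primary hits as FLAG-256 records
#'   (default FALSE).
#' @return The path, invisibly.
#' @export
write_sam <- function(result, path, secondary = FALSE) {
  stopifnot(inherits(result, "pssmap_result"))
  meta <- result$meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(paste0("@SQ\tSN:", meta$names, "\tLN:", meta$lengths), con)
  writeLines(paste0("@PG\tID:pssmap\tPN:pssmap\tVN:",
                    as.character(utils::packageVersion("pssmap"))), con)
  for (rr in result$per_read) {
    read <- rr$read
    hits <- rr$hits
    if (is.null(hits) || nrow(hits) == 0) {
      writeLines(paste(read$name, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                       read$bases, intToUtf8(read$quals + 33L),
                       sep = "\t"), con)
      next
    }
    n_emit <- if (secondary) nrow(hits) else 1L
    for (j in seq_len(n_emit)) {
      h <- hits[j, ]
      chrom <- chromosome_of(meta, h$pos)
      if (chrom$offset + .ref_span(h, nchar(read$bases)) >
          meta$lengths[match(chrom$name, meta$names)])
        stop("internal error: hit extends past reference sequence end")
      flag <- 0L
      if (h$strand == "-") flag <- flag + 16L
      if (j > 1L) flag <- flag + 256L
      o <- .orient(read$bases, read$quals, h$strand == "-")
      writeLines(paste(read$name, flag, chrom$name, chrom$offset + 1L,
                       h$mapq, h$cigar, "*", 0L, 0L, o$seq, o$qual,
                       paste0("ZP:f:", signif(h$posterior, 6)),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

.ref_span <- function(hit, read_length) {
  read_length - hit$a_i + hit$a_d
}

#' Parse a SAM file's primary records (for evaluation)
#'
#' @param path SAM file.
#' @return data.frame with `name`, `flag`, `chrom`, `pos` (1-based),
#'   `mapq`, `cigar`, `strand`, `mapped`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 256L) == 0L  # primary records only
  f <- f[keep]; flag <- flag[keep]
  data.frame(name = vapply(f, `[`, "", 1),
             flag = flag,
             chrom = vapply(f, `[`, "", 3),
             pos = vapply(f, function(x) as.integer(x[4]), integer(1)),
             mapq = vapply(f, function(x) as.integer(x[5]), integer(1)),
             cigar = vapply(f, `[`, "", 6),
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mapped = bitwAnd(flag, 4L) == 0L,
             stringsAsFactors = FALSE)
}
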