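# High-level mapping driver.

#' Map reads against an FM-index
#'
#' For each read: build the PSSM under the supplied models, derive the
#' global threshold (from the mismatch limit unless an explicit `t` is
#' set), compute lookahead thresholds, run the best-first search, and turn
#' the raw hits into posterior probabilities and MapQ.  The highest-
#' posterior hit is the primary record.
#'
#' @param idx an [fm_index()].
#' @param reads list of [read_record()]s (e.g. from [read_fastq()]), or a
#'   list of `pssm` objects (e.g. from [read_pssm_file()]) to map
#'   pre-built matrices.
#' @param mut a [mutation_model()].
#' @param bias a [bias_model()].
#' @param bg a [background()]; the default `"genome"` uses the base
#'   frequencies recorded in the index, `"uniform"` uses 1/4 each.
#' @param opts a [search_options()].
#' @param prior_match prior match probability `P(M)` (default 0.8).
#' @param quiet suppress the per-run summary on standard error.
#' @return Object of class `pssmap_result`: per-read hit tables with
#'   posteriors/MapQ plus a run `summary`.
#' @export
map_reads <- function(idx, reads, mut = mutation_model(),
                      bias = bias_model("none"), bg = "genome",
                      opts = search_options(), prior_match = 0.8,
                      quiet = FALSE) {
  stopifnot(inherits(idx, "fm_index"))
  if (inherits(reads, "read_record") || inherits(reads, "pssm"))
    reads <- list(reads)
  bg <- if (identical(bg, "genome")) background(idx$base_freqs)
        else if (identical(bg, "uniform")) background()
        else if (inherits(bg, "background")) bg
        else background(bg)
  cfg <- posterior_config(prior_match, 2 * idx$forward_length)

  # lookup tables are model x read-length bound: cache across reads
  tab_cache <- new.env(parent = emptyenv())
  get_pssm <- function(read) {
    v <- encode_bases(read$bases)
    L <- length(v)
    key <- as.character(L)
    if (is.null(tab_cache[[key]]))
      tab_cache[[key]] <- .pos_keys(bias, L)
    pk <- tab_cache[[key]]
    qkey <- paste0(key, ":tab")
    if (is.null(tab_cache[[qkey]]))
      tab_cache[[qkey]] <- .pssm_table(mut, bias, bg, 0:93, pk$keys, L)
    tab <- tab_cache[[qkey]]
    scores <- matrix(0, L, 4, dimnames = list(NULL, BASES))
    known <- v >= 1L
    qidx <- read$quals + 1L
    if (any(known)) {
      for (g in 1:4)
        scores[known, g] <- tab[cbind(v[known], qidx[known], pk$idx[known],
                                      rep(g, sum(known)))]
    }
    structure(list(scores = scores,
                   col_max = apply(scores, 1, max),
                   col_min = apply(scores, 1, min),
                   read = read),
              class = "pssm")
  }

  per_read <- vector("list", length(reads))
  n_mapped <- 0L
  n_conf <- 0L
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    if (inherits(r, "pssm")) {
      p <- r
      read <- r$read
    } else {
      read <- r
      p <- get_pssm(read)
    }
    t <- resolve_threshold(p, opts)
    thr <- calculate_thresholds(p, read, idx, t, opts)
    raw <- pssm_search(idx, p, thr, opts)
    hits <- match_posterior(raw, cfg, opts$rho_i, opts$rho_d)
    if (nrow(hits) > 0) {
      n_mapped <- n_mapped + 1L
      if (hits$mapq[1] >= 25L) n_conf <- n_conf + 1L
    }
    per_read[[i]] <- list(read = read, hits = hits)
  }
  summary <- list(n_reads = length(reads), n_mapped = n_mapped,
                  n_mapq25 = n_conf)
  if (!quiet)
    message(sprintf("pssmap: %d reads processed, %d mapped, %d at MapQ>=25",
                    summary$n_reads, summary$n_mapped, summary$n_mapq25))
  structure(list(per_read = per_read, meta = idx$meta, summary = summary,
                 prior_match = prior_match),
            class = "pssmap_result")
}

#' @export
print.pssmap_result <- function(x, ...) {
  s <- x$summary
  cat("<pssmap_result> ", s$n_reads, " reads: ", s$n_mapped, " mapped, ",
      s$n_mapq25, " at MapQ>=25\n", sep = "")
  invisible(x)
}

#' Primary hits of a mapping result as one table
#'
#' @param result a [map_reads()] result.
#' @return data.frame with one row per mapped read: `name`, `chrom`,
#'   `offset` (0-based within chromosome), `pos` (0-based concatenated),
#'   `strand`, `score`, `a_i`, `a_d`, `posterior`, `mapq`.
#' @export
primary_hits <- function(result) {
  stopifnot(inherits(result, "pssmap_result"))
  rows <- lapply(result$per_read, function(rr) {
    if (nrow(rr$hits) == 0) return(NULL)
    h <- rr$hits[1, ]
    chrom <- chromosome_of(result$meta, h$pos)
    data.frame(name = rr$read$name, chrom = chrom$name,
               offset = chrom$offset, pos = h$pos, strand = h$strand,
               score = h$score, a_i = h$a_i, a_d = h$a_d,
               posterior = h$posterior, mapq = h$mapq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(name = character(), chrom = character(),
                      offset = integer(), pos = integer(),
                      strand = character(), score = numeric(),
                      a_i = integer(), a_d = integer(),
                      posterior = numeric(), mapq = integer(),
                      stringsAsFactors = FALSE)
  out
}
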