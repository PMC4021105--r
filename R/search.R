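# Best-first PSSM search over the FM-index: lookahead thresholds with an
# occurrence-based tightening, interval-heap pruning, linear-penalty indels.

#' Sum of column maxima over a half-open column range
#'
#' @param pssm a [build_pssm()] result.
#' @param from,to 0-based half-open range `[from, to)`.
#' @return Best possible score of those columns, in bits.
#' @export
summax <- function(pssm, from, to) {
  L <- nrow(pssm$scores)
  if (from < 0 || to > L || from > to) stop("invalid column range")
  if (from == to) return(0)
  sum(pssm$col_max[(from + 1):to])
}

#' Minimum per-column drop over a closed column range
#'
#' The drop of a column is its maximum minus its minimum score; `mindrop`
#' is the smallest drop over columns `i..j` (0-based, inclusive) — the least
#' score that one mismatch placed anywhere in the range must cost when each
#' column's best score sits at the read base.
#'
#' @param pssm a [build_pssm()] result.
#' @param i,j 0-based inclusive range.
#' @return Minimum drop in bits.
#' @export
mindrop <- function(pssm, i, j) {
  L <- nrow(pssm$scores)
  if (i < 0 || j >= L || i > j) stop("invalid column range")
  min((pssm$col_max - pssm$col_min)[(i + 1):(j + 1)])
}

#' Search options
#'
#' @param n mismatch limit used to derive the global threshold when `t` is
#'   not given (default: 2 for reads under 64 nt, 3 otherwise).
#' @param t explicit global score threshold in bits (overrides `n`).
#' @param rho_i,rho_d insertion and deletion penalties in bits (default 17;
#'   the gap probability is `2^-rho`).
#' @param heap_capacity bound on live partial hits; the worst-offset element
#'   is discarded on overflow.  `0` means unbounded.  Default 500.
#' @param max_hits maximum number of distinct loci reported per read
#'   (default 100).
#' @param max_indels maximum total indels per alignment (default 2).
#' @param indels enable gapped alignment (default TRUE).
#' @param gap_margin indels are disallowed within this many columns of
#'   either read end (default 3).
#' @return Object of class `search_options`.
#' @export
search_options <- function(n = NULL, t = NULL, rho_i = 17, rho_d = 17,
                           heap_capacity = 500L, max_hits = 100L,
                           max_indels = 2L, indels = TRUE, gap_margin = 3L) {
  if (rho_i <= 0 || rho_d <= 0) stop("gap penalties must be positive")
  structure(list(n = n, t = t, rho_i = rho_i, rho_d = rho_d,
                 heap_capacity = as.integer(heap_capacity),
                 max_hits = as.integer(max_hits),
                 max_indels = as.integer(max_indels),
                 indels = isTRUE(indels),
                 gap_margin = as.integer(gap_margin)),
            class = "search_options")
}

# resolve the global threshold for a pssm under options
resolve_threshold <- function(pssm, opts) {
  if (!is.null(opts$t)) return(opts$t)
  n <- if (!is.null(opts$n)) opts$n
       else default_mismatch_limit(nrow(pssm$scores))
  threshold_from_mismatches(pssm, min(n, nrow(pssm$scores)))
}

#' Per-position lookahead thresholds
#'
#' Column `i`'s threshold bounds the partial score accumulated after the
#' backward search has consumed read columns `i..L-1`:
#' `T[i] = t - summax(0, i) + D[i]`, where the lookahead term
#' `summax(0, i)` is the best possible score of the unconsumed columns and
#' `D[i]` is a tightening accumulated by scanning the read from its start:
#' each time the scanned subsequence stops occurring anywhere in the
#' two-strand text, one forced mismatch is charged at the smallest cost any
#' single mismatch can have in that stretch, and the scan interval resets.
#' The charge of a column is its maximum score minus the best score among
#' bases other than the read base, which for the plain quality-only model
#' equals the column drop used by [mindrop()]; this form stays admissible
#' when a bias model moves a column's maximum away from the read base.
#' With indels enabled the tightening is capped at `min(rho_i, rho_d)`,
#' since a gapped alignment can sidestep a forced mismatch at one gap's
#' cost.
#'
#' @param pssm a [build_pssm()] result.
#' @param read the [read_record()] the PSSM was built from.
#' @param idx an [fm_index()].
#' @param t global score threshold in bits.
#' @param opts a [search_options()] (for the indel cap).
#' @return Object of class `threshold_vector`: list with per-position
#'   thresholds `T` (length L), the global threshold `t`, and the
#'   tightening `D`.
#' @export
calculate_thresholds <- function(pssm, read, idx, t,
                                 opts = search_options()) {
  stopifnot(inherits(pssm, "pssm"), inherits(idx, "fm_index"))
  v <- encode_bases(read$bases)
  L <- length(v)
  charges <- vapply(seq_len(L), function(i) {
    if (v[i] == 0L) return(0)  # N constrains nothing
    pssm$col_max[i] - max(pssm$scores[i, -v[i]])
  }, numeric(1))
  cap <- if (opts$indels && opts$max_indels > 0) min(opts$rho_i, opts$rho_d)
         else Inf
  D <- cpp_tightening(idx$core, v, charges, cap)
  cum_max <- c(0, cumsum(pssm$col_max))        # summax(0, i)
  Tvec <- t - cum_max[seq_len(L)] + D[seq_len(L)]
  structure(list(T = Tvec, t = t, D = D[seq_len(L)]),
            class = "threshold_vector")
}

#' Best-first PSSM search
#'
#' Consumes the read from its last position towards its first (backward
#' search), expanding at each node the four match/mismatch branches (step
#' the interval by genome base `g`, add `scores[i, g]`), an insertion branch
#' (consume the read base, `-rho_i`) and deletion branches (step the
#' interval without consuming, `-rho_d`).  Nodes are kept in a bounded
#' double-ended heap keyed by the offset from the best possible score, so
#' the most promising partial hits expand first and the worst are discarded
#' on overflow.  Nodes falling below the per-position threshold are pruned.
#' Fully consumed nodes with score at least `t` are located, filtered for
#' junction/mask overlap, and deduplicated by (position, strand) keeping
#' the best score.
#'
#' @param idx an [fm_index()].
#' @param pssm a [build_pssm()] result.
#' @param thresholds a [calculate_thresholds()] result (or a bare global
#'   threshold, in which case pure lookahead thresholds are used).
#' @param opts a [search_options()].
#' @return `data.frame` with columns `pos` (0-based forward offset),
#'   `strand` (`"+"`/`"-"`), `score` (bits, gap penalties included),
#'   `pssm_score` (bits, ungapped part), `a_i`, `a_d`, `cigar`, ordered by
#'   emission (best-first: the first row has the maximal score when the
#'   heap is unbounded).
#' @export
pssm_search <- function(idx, pssm, thresholds, opts = search_options()) {
  stopifnot(inherits(idx, "fm_index"), inherits(pssm, "pssm"))
  L <- nrow(pssm$scores)
  if (inherits(thresholds, "threshold_vector")) {
    Tvec <- thresholds$T
    t <- thresholds$t
  } else {
    t <- as.numeric(thresholds)
    cum_max <- c(0, cumsum(pssm$col_max))
    Tvec <- t - cum_max[seq_len(L)]
  }
  hits <- cpp_search(idx$core, pssm$scores, Tvec, t,
                     opts$rho_i, opts$rho_d, opts$heap_capacity,
                     opts$max_hits, opts$max_indels, opts$indels,
                     opts$gap_margin, idx$forward_length,
                     idx$mask, idx$junctions)
  hits$strand <- c("+", "-")[hits$strand + 1L]
  hits
}

#' Exhaustive window scan (reference implementation)
#'
#' Scores every window of both strands of a genome against a PSSM:
#' `S = sum_i scores[i, g[l+i]]` on `+`, and against the reverse complement
#' on `-`.  Ungapped only.  Serves as the independent oracle for
#' [pssm_search()] and for posterior denominators on toy genomes.
#'
#' @param genome character string (or integer-encoded vector).
#' @param pssm a [build_pssm()] result.
#' @param t report windows with score `>= t` (with the same 1e-9 slack the
#'   search applies, so boundary windows agree between the two routes).
#' @return `data.frame` with `pos` (0-based), `strand`, `score`.
#' @export
brute_force_scan <- function(genome, pssm, t) {
  if (is.character(genome)) genome <- encode_bases(genome)
  if (any(genome == 0L))
    stop("brute_force_scan expects an N-free genome")
  if (length(genome) < nrow(pssm$scores))
    return(data.frame(pos = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  res <- cpp_scan_windows(genome, pssm$scores, t)
  res$strand <- c("+", "-")[res$strand + 1L]
  res
}
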