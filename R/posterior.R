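# Posterior mapping probabilities and MapQ.

#' Posterior configuration
#'
#' @param prior_match prior probability `P(M)` that a read originates from
#'   the genome at all (default 0.8); contamination-heavy samples warrant
#'   lower values.
#' @param genome_length length `L` of the searchable text — both strands,
#'   i.e. twice the forward genome length, since hits on either strand
#'   enter the sum.
#' @return Object of class `posterior_config`.
#' @export
posterior_config <- function(prior_match = 0.8, genome_length) {
  if (prior_match <= 0 || prior_match > 1)
    stop("prior_match must lie in (0, 1]")
  if (genome_length < 1) stop("genome_length must be at least 1")
  structure(list(prior_match = prior_match,
                 genome_length = as.numeric(genome_length)),
            class = "posterior_config")
}

#' Posterior probability of each mapping position
#'
#' For hits with PSSM scores `S_j` (bits) and indel counts, each hit gets
#' weight `2^(S_j - a_i*rho_i - a_d*rho_d)` and posterior
#' \deqn{p_j = \frac{w_j}{\sum_k w_k + L\,(1 - P(M))/P(M)},}
#' where the sum runs over the hits found above threshold (the high-scoring
#' windows dominate the full-genome sum) and the second term is the
#' background (random-match) mass, proportional to the genome size.
#'
#' @param hits data.frame of raw hits from [pssm_search()] (columns
#'   `pssm_score`, `a_i`, `a_d`; or just `score` when penalties are already
#'   included and indel counts absent).
#' @param cfg a [posterior_config()].
#' @param rho_i,rho_d gap penalties in bits (default 17).
#' @return The hits with columns `posterior` and `mapq` appended, ordered by
#'   decreasing posterior; the background mass is attached as attribute
#'   `unmapped_mass`.  Empty input gives an empty result (read unmapped).
#' @export
match_posterior <- function(hits, cfg, rho_i = 17, rho_d = 17) {
  stopifnot(inherits(cfg, "posterior_config"))
  if (is.null(hits) || nrow(hits) == 0) {
    out <- data.frame(pos = integer(), strand = character(),
                      score = numeric(), pssm_score = numeric(),
                      a_i = integer(), a_d = integer(),
                      posterior = numeric(), mapq = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "unmapped_mass") <- 1
    return(out)
  }
  S <- if (!is.null(hits$pssm_score)) {
    hits$pssm_score -
      (if (is.null(hits$a_i)) 0 else hits$a_i) * rho_i -
      (if (is.null(hits$a_d)) 0 else hits$a_d) * rho_d
  } else {
    hits$score
  }
  # factor out the maximum for numerical stability of 2^S
  m <- max(S)
  w <- 2^(S - m)
  bg_mass <- cfg$genome_length * (1 - cfg$prior_match) / cfg$prior_match
  denom <- sum(w) + bg_mass * 2^(-m)
  hits$posterior <- w / denom
  hits$mapq <- mapq_from_posterior(hits$posterior)
  hits <- hits[order(-hits$posterior), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "unmapped_mass") <- (bg_mass * 2^(-m)) / denom
  hits
}

#' Phred-scaled mapping quality from a posterior probability
#'
#' `MQ = floor(-10 * log10(1 - p) + 0.5)`, capped at 254; `p = 1` maps to
#' the cap.  `1 - p` is the probability that the reported location is
#' wrong, so high-confidence hits get high MapQ (the MAQ convention).
#'
#' @param p posterior probabilities in `[0, 1]`.
#' @return Integer MapQ values in `[0, 254]`.
#' @export
mapq_from_posterior <- function(p) {
  if (any(p < 0 | p > 1)) stop("posterior must lie in [0, 1]")
  err <- 1 - p
  mq <- ifelse(err <= 0, 254L,
               as.integer(pmin(254, floor(-10 * log10(err) + 0.5))))
  as.integer(mq)
}
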