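# Probabilistic read models: sequencing error, evolutionary substitution,
# data-specific bias, background composition, and their combination into a
# per-read position-specific scoring matrix (PSSM).

#' Convert a Phred quality score to an error probability
#'
#' The Phred convention relates the probability of a base-calling error
#' \eqn{p_e} to the quality score \eqn{Q} by \eqn{p_e = 10^{-Q/10}}.
#'
#' @param Q integer (or vector of) Phred quality scores, `Q >= 0`.
#' @return Error probabilities in `(0, 1]`.
#' @examples
#' phred_to_error_prob(c(0, 10, 20))
#' @export
phred_to_error_prob <- function(Q) {
  if (any(Q < 0)) stop("Phred scores must be non-negative")
  10^(-Q / 10)
}

#' Sequencing error model P(a | x)
#'
#' Probability that the sample base is `a` given that the machine called `x`
#' with quality `Q`: the called base with probability \eqn{1 - p_e} and each
#' of the three other bases with probability \eqn{p_e / 3}.
#'
#' @param x called base, one of `"A","C","G","T"`.
#' @param Q Phred quality of the call.
#' @return Named numeric vector of length 4 (A, C, G, T) summing to 1.
#' @examples
#' sequencing_error_model("A", 10)
#' @export
sequencing_error_model <- function(x, Q) {
  b <- match(x, BASES)
  if (is.na(b)) stop("base must be one of A, C, G, T")
  pe <- phred_to_error_prob(Q)
  p <- rep(pe / 3, 4)
  p[b] <- 1 - pe
  setNames(p, BASES)
}

#' Evolutionary substitution model
#'
#' Describes the probability `P(g|a)` that the reference genome carries base
#' `g` where the sampled molecule carries `a`.  Three parameterisations:
#'
#' * `"uniform"`: a single mutation probability `p0`, spread evenly over the
#'   three alternatives.
#' * `"two-rate"`: transition probability `m1` (A<->G, C<->T) and transversion
#'   probability `m2` per transversion (used with the ancient-DNA model).
#' * `"xeno"`: total substitution probability `ps` and conditional transition
#'   fraction `pt`, for mapping reads against a related species' genome.
#'
#' @param mode one of `"uniform"`, `"two-rate"`, `"xeno"`.
#' @param p0,m1,m2,ps,pt model parameters in `[0, 1]` (see above).
#' @return An object of class `mutation_model`.
#' @examples
#' mutation_matrix(mutation_model("xeno", ps = 0.15, pt = 0.45))
#' @export
mutation_model <- function(mode = c("uniform", "two-rate", "xeno"),
                           p0 = 0.001, m1 = 0.002, m2 = 0.001,
                           ps = 0.15, pt = 0.45) {
  mode <- match.arg(mode)
  pars <- switch(mode,
    "uniform" = c(p0 = p0),
    "two-rate" = c(m1 = m1, m2 = m2),
    "xeno" = c(ps = ps, pt = pt))
  if (any(pars < 0 | pars > 1)) stop("mutation parameters must lie in [0, 1]")
  if (mode == "two-rate" && m1 + 2 * m2 > 1)
    stop("two-rate model needs m1 + 2*m2 <= 1")
  structure(list(mode = mode, pars = as.list(pars)), class = "mutation_model")
}

# transitions: A<->G, C<->T
.TRANSITION <- matrix(FALSE, 4, 4, dimnames = list(BASES, BASES))
.TRANSITION["A", "G"] <- .TRANSITION["G", "A"] <- TRUE
.TRANSITION["C", "T"] <- .TRANSITION["T", "C"] <- TRUE

#' Substitution matrix P(g | a) of a mutation model
#'
#' @param model a [mutation_model()].
#' @return 4x4 matrix, rows `a` (sample base), columns `g` (genome base);
#'   every row sums to 1.
#' @export
mutation_matrix <- function(model) {
  stopifnot(inherits(model, "mutation_model"))
  p <- model$pars
  M <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  if (model$mode == "uniform") {
    M[] <- p$p0 / 3
    diag(M) <- 1 - p$p0
  } else if (model$mode == "two-rate") {
    M[] <- p$m2
    M[.TRANSITION] <- p$m1
    diag(M) <- 1 - p$m1 - 2 * p$m2
  } else {
    M[] <- 0.5 * p$ps * (1 - p$pt)
    M[.TRANSITION] <- p$ps * p$pt
    diag(M) <- 1 - p$ps
  }
  M
}

#' Data-specific bias model
#'
#' Describes the probability `p_i(b|a)` that the sampled base `a` is read as
#' the modified base `b` at read position `i` (0-based).
#'
#' * `"none"`: identity.
#' * `"ancient"`: deamination damage; C->T at rate `gamma[i+1]` and G->A at
#'   rate `delta[i+1]`, position-dependent (rates highest at the read ends,
#'   see [damage_profile()]).
#' * `"parclip"`: position-independent T->C conversion at rate `tc_rate`.
#'
#' @param kind one of `"none"`, `"ancient"`, `"parclip"`.
#' @param gamma per-position C->T damage rates; `gamma[k]` is the rate at
#'   distance `k - 1` from the 5' end.  Positions beyond the vector use its
#'   last value.
#' @param delta per-position G->A damage rates; `delta[k]` is the rate at
#'   distance `k - 1` from the 3' end.
#' @param tc_rate global T->C conversion rate.
#' @return An object of class `bias_model`.
#' @export
bias_model <- function(kind = c("none", "ancient", "parclip"),
                       gamma = NULL, delta = NULL, tc_rate = 0.11) {
  kind <- match.arg(kind)
  if (kind == "ancient") {
    if (is.null(gamma) || is.null(delta))
      stop("ancient model needs gamma and delta rate vectors")
    if (any(c(gamma, delta) < 0 | c(gamma, delta) > 1))
      stop("damage rates must lie in [0, 1]")
  }
  if (kind == "parclip" && (tc_rate < 0 || tc_rate > 1))
    stop("tc_rate must lie in [0, 1]")
  structure(list(kind = kind, gamma = gamma, delta = delta,
                 tc_rate = tc_rate, window = 10L),
            class = "bias_model")
}

#' Exponential-decay damage profile for ancient DNA
#'
#' Deamination rates in degraded DNA peak at the fragment termini and decay
#' rapidly towards the center.  This helper builds per-position rate vectors
#' `gamma` (C->T, anchored at the 5' end) and `delta` (G->A, anchored at the
#' 3' end) of the form `peak * exp(-i / decay)`.  The profile is a user
#' input in real analyses; this parametric form is a convenient default.
#'
#' @param peak terminal damage rate (default 0.3).
#' @param decay decay length in nucleotides (default 3).
#' @param window number of positions from each end carrying the profile
#'   (default 10); beyond it the residual rate of the last position applies.
#' @return A [bias_model()] of kind `"ancient"`.
#' @export
damage_profile <- function(peak = 0.3, decay = 3, window = 10) {
  i <- seq_len(window) - 1
  bias_model("ancient",
             gamma = peak * exp(-i / decay),
             delta = peak * exp(-i / decay))
}

# per-position damage rates for read position i (0-based) and length L;
# gamma is indexed by distance from the 5' end, delta from the 3' end
.bias_rates <- function(model, i, read_length) {
  c(gamma = model$gamma[min(i, length(model$gamma) - 1) + 1],
    delta = model$delta[min(read_length - 1 - i, length(model$delta) - 1) + 1])
}

#' Bias matrix p_i(b | a) at a read position
#'
#' @param model a [bias_model()].
#' @param i 0-based read position.
#' @param read_length length of the read.
#' @return 4x4 matrix, rows `a` (sample base), columns `b` (modified base);
#'   rows sum to 1.
#' @export
bias_matrix <- function(model, i, read_length) {
  stopifnot(inherits(model, "bias_model"))
  if (i < 0 || i >= read_length) stop("position out of range")
  B <- diag(4)
  dimnames(B) <- list(BASES, BASES)
  if (model$kind == "ancient") {
    r <- .bias_rates(model, i, read_length)
    B["C", "T"] <- r[["gamma"]]; B["C", "C"] <- 1 - r[["gamma"]]
    B["G", "A"] <- r[["delta"]]; B["G", "G"] <- 1 - r[["delta"]]
  } else if (model$kind == "parclip") {
    B["T", "C"] <- model$tc_rate
    B["T", "T"] <- 1 - model$tc_rate
  }
  B
}

#' Background base distribution
#'
#' @param q named probabilities for A, C, G, T (normalised if needed), or a
#'   genome string / integer-encoded genome to take empirical frequencies
#'   from.  Defaults to uniform.
#' @return An object of class `background`: a named probability vector.
#' @export
background <- function(q = NULL) {
  if (is.null(q)) q <- rep(0.25, 4)
  if (is.character(q) && length(q) == 1 && nchar(q) > 4)
    q <- .base_freqs(encode_bases(q))
  if (is.integer(q)) q <- .base_freqs(q)
  q <- as.numeric(q[seq_len(4)])
  if (any(q <= 0)) stop("background probabilities must be positive")
  structure(setNames(q / sum(q), BASES), class = "background")
}

.base_freqs <- function(v) {
  v <- v[v >= 1L & v <= 4L]
  tab <- tabulate(v, nbins = 4)
  # keep all probabilities strictly positive
  (tab + 1) / (sum(tab) + 4)
}

#' Posterior genomic base distribution P(g | x)
#'
#' Combines the sequencing error model, the evolutionary model and (if
#' present) the bias model into the probability of genome base `g` given the
#' called base `x` at read position `i`.  Without bias this is
#' \deqn{P(g|x) = \sum_a P(g|a) P(a|x).}
#' With a bias model the sampled base `a` is first modified into `b`, and
#' \deqn{P(g|x) = \sum_b P(g|b) P(b|x),\quad
#'       P(g|b) = \frac{P(b|g) P(g)}{\sum_{g'} P(b|g') P(g')},\quad
#'       P(b|g) = \sum_a P(b|a) P(a|g),}
#' where `P(a|g)` is obtained from `P(g|a)` by Bayesian inversion under a
#' uniform prior over `a`, and the prior `P(g)` is the background.
#'
#' @param x called base.
#' @param Q Phred quality.
#' @param i 0-based read position (only relevant for position-dependent
#'   bias models).
#' @param mut a [mutation_model()].
#' @param bias a [bias_model()].
#' @param bg a [background()].
#' @param read_length read length (for position-dependent bias).
#' @param via_bias force the bias-model pathway even for `kind = "none"`
#'   (the two pathways agree exactly for the identity bias under a uniform
#'   background).
#' @return Named probability vector over A, C, G, T.
#' @export
genomic_posterior <- function(x, Q, i = 0, mut = mutation_model(),
                              bias = bias_model("none"), bg = background(),
                              read_length = i + 1, via_bias = FALSE) {
  M <- mutation_matrix(mut)           # rows a, cols g
  if (bias$kind == "none" && !via_bias) {
    pax <- sequencing_error_model(x, Q)
    out <- as.numeric(pax %*% M)
    return(setNames(out / sum(out), BASES))
  }
  B <- bias_matrix(bias, i, read_length)   # rows a, cols b
  # P(a|g): invert P(g|a) with a uniform prior over a
  Aag <- sweep(M, 2, colSums(M), "/")      # rows a, cols g -> P(a|g) per col
  PbG <- t(Aag) %*% B                      # rows g, cols b: P(b|g)
  W <- PbG * as.numeric(bg)                # P(b|g) P(g)
  PgB <- sweep(W, 2, colSums(W), "/")      # rows g, cols b: P(g|b)
  pbx <- sequencing_error_model(x, Q)      # P(b|x)
  out <- as.numeric(PgB %*% pbx)
  setNames(out / sum(out), BASES)
}

#' Read record
#'
#' @param name read name.
#' @param bases base string over A, C, G, T, N.
#' @param quals integer Phred qualities, one per base, in `[0, 93]`.
#' @return Object of class `read_record`.
#' @export
read_record <- function(name, bases, quals) {
  bases <- toupper(bases)
  if (nchar(bases) != length(quals))
    stop("read '", name, "': bases and qualities differ in length")
  if (any(quals < 0 | quals > 93))
    stop("read '", name, "': Phred scores must lie in [0, 93]")
  structure(list(name = name, bases = bases, quals = as.integer(quals)),
            class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat("<read_record>", x$name, " (", nchar(x$bases), " nt)\n", sep = "")
  invisible(x)
}

# Score lookup table: array [called base, quality, position key, genome base]
# of log2-odds scores.  Position-independent except under position-dependent
# bias, where pos_keys are representative read positions.  For fixed position
# the map P(g|.) is quality-independent, so all qualities are filled with one
# matrix product per called base.
.pssm_table <- function(mut, bias, bg, quals, pos_keys, read_length,
                        floor = 1e-9) {
  M <- mutation_matrix(mut)                 # rows a, cols g
  bgv <- as.numeric(bg)
  pe <- phred_to_error_prob(quals)
  nq <- length(quals)
  tab <- array(NA_real_, dim = c(4, nq, length(pos_keys), 4))
  for (ki in seq_along(pos_keys)) {
    if (bias$kind == "none") {
      K <- t(M)                             # P(g|x) = K %*% P(a|x)
    } else {
      B <- bias_matrix(bias, pos_keys[ki], read_length)
      Aag <- sweep(M, 2, colSums(M), "/")   # P(a|g), uniform prior over a
      PbG <- t(Aag) %*% B                   # rows g, cols b
      W <- PbG * bgv
      K <- sweep(W, 2, colSums(W), "/")     # P(g|b); P(g|x) = K %*% P(b|x)
    }
    for (x in 1:4) {
      P <- matrix(pe / 3, 4, nq, byrow = TRUE)
      P[x, ] <- 1 - pe                      # P(.|x) over all qualities
      PG <- K %*% P                         # rows g, cols quality
      PG <- sweep(PG, 2, colSums(PG), "/")
      tab[x, , ki, ] <- t(log2(pmax(PG, floor) / bgv))
    }
  }
  tab
}

# representative position keys for a read of length L: each of the first and
# last `w` positions is its own key, interior positions share one center key
.pos_keys <- function(bias, L) {
  if (bias$kind != "ancient") {
    return(list(keys = 0L, idx = rep(1L, L)))
  }
  w <- min(bias$window, ceiling(L / 2))
  i <- seq_len(L) - 1L
  center <- L %/% 2L
  rep_pos <- ifelse(i < w, i, ifelse(i >= L - w, i, center))
  keys <- sort(unique(rep_pos))
  list(keys = keys, idx = match(rep_pos, keys))
}

#' Build the position-specific scoring matrix of a read
#'
#' Scores are log2-odds in bits: `s(g|x_i) = log2(P(g|x_i) / q(g))` with
#' `P(g|x_i)` from [genomic_posterior()].  `N` read bases get an all-zero
#' (neutral) column.  Construction goes through a precomputed lookup table
#' keyed by (base, quality) — and by distance to the nearer read end, up to
#' the damage window, for the ancient model.  Probabilities are floored at
#' `1e-9` before the log so structural zeros of a bias model stay finite.
#'
#' @param read a [read_record()].
#' @param mut a [mutation_model()].
#' @param bias a [bias_model()].
#' @param bg a [background()].
#' @return Object of class `pssm` with elements `scores` (L x 4 matrix, bits),
#'   `col_max`, `col_min`, and `read`.
#' @export
build_pssm <- function(read, mut = mutation_model(),
                       bias = bias_model("none"), bg = background()) {
  stopifnot(inherits(read, "read_record"))
  v <- encode_bases(read$bases)
  L <- length(v)
  if (L == 0) stop("empty read")
  quals <- sort(unique(read$quals))
  qidx <- match(read$quals, quals)
  pk <- .pos_keys(bias, L)
  tab <- .pssm_table(mut, bias, bg, quals, pk$keys, L)
  kidx <- pk$idx

  scores <- matrix(0, L, 4, dimnames = list(NULL, BASES))
  known <- v >= 1L
  if (any(known)) {
    for (g in 1:4)
      scores[known, g] <- tab[cbind(v[known], qidx[known], kidx[known],
                                    rep(g, sum(known)))]
  }
  structure(list(scores = scores,
                 col_max = apply(scores, 1, max),
                 col_min = apply(scores, 1, min),
                 read = read),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  L <- nrow(x$scores)
  cat("<pssm> ", x$read$name, ": ", L, " columns, perfect score ",
      format(sum(x$col_max), digits = 6), " bits\n", sep = "")
  invisible(x)
}

#' Global score threshold from a mismatch limit
#'
#' Converts a cap of `n` mismatches into the minimum possible PSSM score a
#' window with `n` mismatches can have: the perfect score minus the `n`
#' largest per-column drops (column max minus column min).  High-quality
#' columns have large drops, so this allows `n` mismatches of high-quality
#' bases and more mismatches of low-quality ones.
#'
#' @param pssm a [build_pssm()] result.
#' @param n mismatch limit, `0 <= n <= L`.
#' @return Threshold in bits.
#' @export
threshold_from_mismatches <- function(pssm, n) {
  stopifnot(inherits(pssm, "pssm"))
  L <- nrow(pssm$scores)
  if (n < 0 || n > L) stop("mismatch limit out of range")
  drops <- pssm$col_max - pssm$col_min
  sum(pssm$col_max) - sum(sort(drops, decreasing = TRUE)[seq_len(n)])
}

# default mismatch cap (overridable): 2 for reads under 64 nt, 3 otherwise
default_mismatch_limit <- function(read_length) {
  if (read_length < 64) 2L else 3L
}
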