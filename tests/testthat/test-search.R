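# Best-first PSSM search: lookahead thresholds, completeness against the
# window-scan oracle, indels, heap behavior.

test_that("summax and mindrop summarize PSSM columns", {
  scores <- rbind(c(2, -3, -3, -3), c(2, -1, -1, -1), c(2, -2, -2, -2))
  p <- structure(list(scores = scores,
                      col_max = apply(scores, 1, max),
                      col_min = apply(scores, 1, min),
                      read = read_record("r", "AAA", rep(30L, 3))),
                 class = "pssm")
  expect_equal(summax(p, 0, 0), 0)
  expect_equal(summax(p, 0, 3), 6)
  expect_equal(summax(p, 0, 1) + summax(p, 1, 3), summax(p, 0, 3))
  expect_equal(mindrop(p, 0, 0), 5)
  expect_equal(mindrop(p, 0, 2), 3)
  expect_lte(mindrop(p, 0, 2), mindrop(p, 1, 1))  # min over superset
  expect_error(summax(p, 2, 1), "invalid")
  expect_error(mindrop(p, 0, 3), "invalid")
})

test_that("thresholds reduce to pure lookahead when the read occurs", {
  set.seed(20)
  g <- rand_genome(800)
  rd <- planted_read(g, 200, 20, quals = rep(35L, 20))
  idx <- fm_index(g)
  p <- build_pssm(rd)
  t <- sum(p$col_max)
  thr <- calculate_thresholds(p, rd, idx, t, search_options(indels = FALSE))
  cum <- c(0, cumsum(p$col_max))
  expect_equal(thr$D, rep(0, 20))
  expect_equal(thr$T, t - cum[1:20])
})

test_that("absent reads force tightening and empty results", {
  set.seed(21)
  g <- rand_genome(1500)
  repeat {  # a random 16-mer almost surely absent from 3 kb of text
    rd_s <- simulate_genome(16)
    if (length(naive_occurrences(g, rd_s)) == 0) break
  }
  rd <- read_record("r", rd_s, rep(40L, 16))
  idx <- fm_index(g)
  p <- build_pssm(rd, mut = mutation_model(p0 = 0))
  t <- sum(p$col_max)
  thr <- calculate_thresholds(p, rd, idx, t, search_options(indels = FALSE))
  expect_gt(max(thr$D), 10)
  hits <- pssm_search(idx, p, thr,
                      search_options(indels = FALSE, heap_capacity = 0))
  expect_equal(nrow(hits), 0)
  expect_equal(nrow(brute_force_scan(g, p, t)), 0)
})

test_that("threshold vectors are admissible for every above-threshold window", {
  set.seed(22)
  for (rep in 1:25) {
    G <- sample(300:1200, 1)
    g <- rand_genome(G)
    L <- sample(8:25, 1)
    rd <- planted_read(g, sample(0:(G - L), 1), L,
                       strand = sample(c("+", "-"), 1),
                       mismatches = sample(0:2, 1))
    idx <- fm_index(g)
    p <- build_pssm(rd)
    t <- threshold_from_mismatches(p, sample(0:3, 1))
    thr <- calculate_thresholds(p, rd, idx, t, search_options(indels = FALSE))
    wins <- brute_force_scan(g, p, t)
    gv <- pssmap:::encode_bases(g)
    for (w in seq_len(nrow(wins))) {
      cols <- if (wins$strand[w] == "+") gv[wins$pos[w] + 1:L]
              else 5L - rev(gv[wins$pos[w] + 1:L])
      colscore <- p$scores[cbind(1:L, cols)]
      # partial sums in backward consumption order: after consuming i..L-1
      partial <- rev(cumsum(rev(colscore)))
      expect_true(all(partial >= thr$T - 1e-9))
    }
  }
})

test_that("search with unbounded heap equals the exhaustive window scan", {
  set.seed(23)
  for (rep in 1:40) {
    G <- sample(300:2000, 1)
    g <- rand_genome(G)
    L <- sample(8:30, 1)
    rd <- planted_read(g, sample(0:(G - L), 1), L,
                       strand = sample(c("+", "-"), 1),
                       mismatches = sample(0:2, 1))
    idx <- fm_index(g)
    p <- build_pssm(rd)
    t <- threshold_from_mismatches(p, sample(0:3, 1))
    thr <- calculate_thresholds(p, rd, idx, t, search_options(indels = FALSE))
    hits <- pssm_search(idx, p, thr,
                        search_options(indels = FALSE, heap_capacity = 0,
                                       max_hits = 100000))
    bf <- brute_force_scan(g, p, t)
    expect_setequal(hit_key(hits), hit_key(bf))
    if (nrow(hits) > 0) {
      m <- merge(hits, bf, by = c("pos", "strand"))
      expect_equal(m$score.x, m$score.y, tolerance = 1e-9)
      # best-first: the first emitted hit carries the maximal score
      expect_equal(hits$score[1], max(bf$score), tolerance = 1e-9)
    }
  }
})

test_that("reads matching only the reverse complement land on strand -", {
  set.seed(24)
  g <- rand_genome(600)
  rd <- planted_read(g, 150, 18, strand = "-", quals = rep(35L, 18))
  idx <- fm_index(g)
  p <- build_pssm(rd)
  hits <- pssm_search(idx, p, calculate_thresholds(p, rd, idx,
                        threshold_from_mismatches(p, 0)),
                      search_options())
  expect_true(any(hits$pos == 150 & hits$strand == "-"))
})

test_that("a threshold above the best achievable score yields nothing", {
  set.seed(25)
  g <- rand_genome(400)
  rd <- planted_read(g, 100, 15, quals = rep(35L, 15))
  idx <- fm_index(g)
  p <- build_pssm(rd)
  hits <- pssm_search(idx, p, sum(p$col_max) + 1, search_options())
  expect_equal(nrow(hits), 0)
})

test_that("planted indel copies are recovered at the linear gap penalty", {
  set.seed(26)
  found_i <- 0L; found_d <- 0L
  for (rep in 1:15) {
    g <- rand_genome(900)
    L <- 25
    rd_s <- simulate_genome(L)
    j <- sample(6:(L - 6), 1)
    del_copy <- paste0(substr(rd_s, 1, j - 1), substr(rd_s, j + 1, L))
    ins_copy <- paste0(substr(rd_s, 1, j),
                       sample(c("A", "C", "G", "T"), 1),
                       substr(rd_s, j + 1, L))
    g2 <- paste0(substr(g, 1, 300), del_copy, substr(g, 301, 600),
                 ins_copy, substr(g, 601, 900))
    idx <- fm_index(g2)
    rd <- read_record("r", rd_s, rep(35L, L))
    p <- build_pssm(rd)
    t <- sum(p$col_max) - max(p$col_max) - 17 - 0.01
    thr <- calculate_thresholds(p, rd, idx, t, search_options())
    h <- pssm_search(idx, p, thr,
                     search_options(heap_capacity = 0, max_hits = 10000))
    ins_hit <- h[h$a_i == 1 & h$pos == 300, ]
    del_hit <- h[h$a_d == 1 & h$pos == 300 + (L - 1) + 300, ]
    found_i <- found_i + (nrow(ins_hit) >= 1)
    found_d <- found_d + (nrow(del_hit) >= 1)
    # indel scoring identity: score = ungapped part - a_i*rho_i - a_d*rho_d
    expect_equal(h$score, h$pssm_score - 17 * (h$a_i + h$a_d),
                 tolerance = 1e-9)
    # gapped CIGARs stay consistent with the read length
    for (cg in h$cigar) {
      ops <- regmatches(cg, gregexpr("[0-9]+[MID]", cg))[[1]]
      n_read <- sum(as.integer(sub("[MID]", "", ops[grepl("[MI]", ops)])))
      expect_equal(n_read, L)
    }
    # best gapped hit matches the independent DP oracle
    if (nrow(h) > 0)
      expect_equal(max(h$score), dp_best_score(g2, p, 17, 17),
                   tolerance = 1e-6)
  }
  expect_equal(found_i, 15L)
  expect_equal(found_d, 15L)
})

test_that("a capacity-1 heap degrades to a greedy path but still maps
           error-free reads", {
  set.seed(27)
  for (rep in 1:10) {
    g <- rand_genome(500)
    rd <- planted_read(g, sample(0:(470), 1), 20, quals = rep(35L, 20))
    idx <- fm_index(g)
    p <- build_pssm(rd)
    t <- sum(p$col_max) - 1e-6
    h <- pssm_search(idx, p, calculate_thresholds(p, rd, idx, t),
                     search_options(heap_capacity = 1))
    expect_gte(nrow(h), 1)
  }
})

test_that("the window-scan oracle itself behaves as specified", {
  # all-zero PSSM at t = 0 reports every window of both strands
  g <- "ACGTAC"
  p <- structure(list(scores = matrix(0, 3, 4),
                      col_max = rep(0, 3), col_min = rep(0, 3),
                      read = read_record("r", "NNN", rep(0L, 3))),
                 class = "pssm")
  bf <- brute_force_scan(g, p, 0)
  expect_equal(nrow(bf), 2 * (6 - 3 + 1))
  # shorter genome than read: empty
  expect_equal(nrow(brute_force_scan("AC", p, 0)), 0)
  # certainty PSSM at perfect threshold = exact string matching
  set.seed(28)
  g <- rand_genome(400)
  rd <- planted_read(g, 37, 10, quals = rep(40L, 10))
  ps <- build_pssm(rd, mut = mutation_model(p0 = 0))
  bf <- brute_force_scan(g, ps, sum(ps$col_max))
  want <- naive_occurrences(g, rd$bases)
  expect_setequal(hit_key(bf),
                  vapply(want, function(h) paste(h[[1]], h[[2]]), ""))
})
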