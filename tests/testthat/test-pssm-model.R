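# Error / mutation / bias models and PSSM construction.

test_that("Phred conversion follows 10^(-Q/10)", {
  expect_equal(phred_to_error_prob(0), 1.0)
  expect_equal(phred_to_error_prob(10), 0.1)
  expect_equal(phred_to_error_prob(20), 0.01)
  expect_error(phred_to_error_prob(-1), "non-negative")
})

test_that("sequencing error model splits p_e over the three other bases", {
  p <- sequencing_error_model("A", 10)
  expect_equal(unname(p), c(0.9, 1/30, 1/30, 1/30))
  # zero-error limit concentrates on the called base
  p <- sequencing_error_model("C", 930)
  expect_equal(unname(p["C"]), 1, tolerance = 1e-12)
  expect_error(sequencing_error_model("N", 10), "A, C, G, T")
  set.seed(1)
  for (rep in 1:20) {
    p <- sequencing_error_model(sample(c("A","C","G","T"), 1), sample(0:93, 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("mutation matrices have the stated cells and unit row sums", {
  ident <- mutation_matrix(mutation_model("uniform", p0 = 0))
  expect_equal(ident, diag(4), ignore_attr = TRUE)
  M <- mutation_matrix(mutation_model("uniform", p0 = 0.003))
  expect_equal(unname(diag(M)), rep(0.997, 4))
  expect_equal(M["A", "C"], 0.001)
  # xeno model at the Drosophila-derived rates
  X <- mutation_matrix(mutation_model("xeno", ps = 0.15, pt = 0.45))
  expect_equal(unname(diag(X)), rep(0.85, 4))
  expect_equal(X["A", "G"], 0.0675)    # transition
  expect_equal(X["A", "C"], 0.04125)   # transversion
  expect_equal(unname(rowSums(X)), rep(1, 4))
  # two-rate model
  TR <- mutation_matrix(mutation_model("two-rate", m1 = 0.02, m2 = 0.005))
  expect_equal(TR["C", "T"], 0.02)
  expect_equal(TR["C", "A"], 0.005)
  expect_equal(unname(rowSums(TR)), rep(1, 4))
  expect_error(mutation_model("uniform", p0 = 1.5), "\\[0, 1\\]")
})

test_that("bias matrices implement damage and T-to-C conversion", {
  none <- bias_matrix(bias_model("none"), 0, 36)
  expect_equal(none, diag(4), ignore_attr = TRUE)
  zero <- bias_model("ancient", gamma = rep(0, 10), delta = rep(0, 10))
  expect_equal(bias_matrix(zero, 3, 36), diag(4), ignore_attr = TRUE)
  anc <- bias_model("ancient", gamma = c(0.3, 0.1), delta = c(0.25, 0.05))
  B0 <- bias_matrix(anc, 0, 36)
  expect_equal(B0["C", "T"], 0.3)
  expect_equal(B0["C", "C"], 0.7)
  expect_equal(B0["A", "A"], 1)
  # delta anchors at the 3' end
  B_end <- bias_matrix(anc, 35, 36)
  expect_equal(B_end["G", "A"], 0.25)
  expect_equal(B_end["C", "T"], 0.1)   # gamma tail value
  pc <- bias_matrix(bias_model("parclip", tc_rate = 0.11), 17, 36)
  expect_equal(pc["T", "C"], 0.11)
  expect_equal(pc["T", "T"], 0.89)
  expect_equal(unname(rowSums(pc)), rep(1, 4))
  expect_error(bias_model("parclip", tc_rate = 2), "\\[0, 1\\]")
})

test_that("genomic posterior composes error and mutation models", {
  # identity mutation reduces to the pure error model
  p <- genomic_posterior("G", 17, mut = mutation_model("uniform", p0 = 0))
  expect_equal(p, sequencing_error_model("G", 17), tolerance = 1e-12)
  # hand evaluation of the diagonal term:
  # P(g=A|x=A) = (1-p0)(1-pe) + 3 * (p0/3)(pe/3) = 0.997*0.9 + 0.001*0.1
  p <- genomic_posterior("A", 10, mut = mutation_model("uniform", p0 = 0.003))
  expect_equal(unname(p["A"]), 0.8974, tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:20) {
    p <- genomic_posterior(sample(c("A","C","G","T"), 1), sample(0:60, 1),
                           i = 2, mut = mutation_model(p0 = runif(1, 0, 0.2)),
                           bias = bias_model("parclip", tc_rate = runif(1)),
                           bg = background(c(runif(4, 0.1, 1))),
                           read_length = 10)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("the bias pathway reproduces the plain pathway for identity bias", {
  for (Q in c(5, 20, 40)) {
    for (x in c("A", "C", "G", "T")) {
      plain <- genomic_posterior(x, Q, mut = mutation_model(p0 = 0.01))
      via <- genomic_posterior(x, Q, mut = mutation_model(p0 = 0.01),
                               via_bias = TRUE)
      expect_equal(via, plain, tolerance = 1e-12)
    }
  }
})

test_that("PSSM scores are log2-odds against the background", {
  rd <- read_record("r", "A", 40L)
  p <- build_pssm(rd, mut = mutation_model(p0 = 0))
  expect_equal(unname(p$scores[1, "A"]), log2(0.9999 / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(p$scores[1, "C"]), log2((0.0001 / 3) / 0.25),
               tolerance = 1e-12)
  expect_equal(p$col_max[1], max(p$scores[1, ]))
  expect_equal(p$col_min[1], min(p$scores[1, ]))
  # sum_g q(g) 2^s = 1: the scores are normalised log-odds
  set.seed(3)
  bg <- background(c(0.4, 0.1, 0.2, 0.3))
  rd <- read_record("r", "ACGTTGCA", rand_quals(8))
  p <- build_pssm(rd, mut = mutation_model(p0 = 0.01), bg = bg)
  for (i in 1:8)
    expect_equal(sum(as.numeric(bg) * 2^p$scores[i, ]), 1, tolerance = 1e-9)
  # N columns are neutral
  rdN <- read_record("r", "ANT", c(30L, 30L, 30L))
  pN <- build_pssm(rdN)
  expect_equal(unname(pN$scores[2, ]), rep(0, 4))
  expect_error(build_pssm(read_record("r", "", integer(0))))
})

test_that("ancient-model PSSM columns follow the end-anchored profile", {
  anc <- damage_profile(peak = 0.3, decay = 3)
  L <- 30L
  rd <- read_record("r", strrep("T", L), rep(30L, L))
  p <- build_pssm(rd, mut = mutation_model("two-rate"), bias = anc)
  # a called T near the 5' end may plausibly be a damaged genomic C, so the
  # C score is raised there relative to the read center
  expect_gt(p$scores[1, "C"], p$scores[15, "C"])
  # the 3' end is G>A damage territory; called T carries no extra C signal
  expect_lt(abs(p$scores[L, "C"] - p$scores[15, "C"]), 0.2)
  # symmetric check on called A and genomic G at the 3' end
  rdA <- read_record("r", strrep("A", L), rep(30L, L))
  pA <- build_pssm(rdA, mut = mutation_model("two-rate"), bias = anc)
  expect_gt(pA$scores[L, "G"], pA$scores[15, "G"])
})

test_that("mismatch-limit threshold equals the exhaustive minimum", {
  set.seed(4)
  for (rep in 1:10) {
    L <- sample(3:8, 1)
    rd <- read_record("r", simulate_genome(L), rand_quals(L))
    p <- build_pssm(rd, mut = mutation_model(p0 = 0.01))
    perfect <- sum(p$col_max)
    drops <- p$col_max - p$col_min
    prev <- Inf
    for (n in 0:L) {
      t <- threshold_from_mismatches(p, n)
      # exhaustive oracle: minimum over all ways to place n mismatches,
      # each forced to the worst base of its column
      combos <- utils::combn(L, n)
      oracle <- if (n == 0) perfect else
        min(apply(matrix(combos, nrow = n), 2,
                  function(ix) perfect - sum(drops[ix])))
      expect_equal(t, oracle, tolerance = 1e-12)
      expect_lte(t, prev)  # monotone non-increasing in n
      prev <- t
    }
  }
  p <- build_pssm(read_record("r", "ACG", c(30L, 30L, 30L)))
  expect_error(threshold_from_mismatches(p, 4), "out of range")
})

test_that("PSSM text files round-trip", {
  set.seed(5)
  rd <- read_record("myread", simulate_genome(12), rand_quals(12))
  p <- build_pssm(rd)
  f <- tempfile(fileext = ".pssm")
  write_pssm_file(p, f)
  q <- read_pssm_file(f)[[1]]
  expect_equal(q$scores, p$scores, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(q$read$name, "myread")
})

test_that("lookup tables tabulate base/quality score translation", {
  f <- tempfile(fileext = ".tsv")
  write_lookup_table(mutation_model(p0 = 0.01), bias_model("none"),
                     background(), f, quals = c(10L, 30L))
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 8)
  row <- tab[tab$base == "A" & tab$quality == 10, ]
  want <- genomic_posterior("A", 10, mut = mutation_model(p0 = 0.01))
  expect_equal(row$A, log2(want[["A"]] / 0.25), tolerance = 1e-9)
})
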