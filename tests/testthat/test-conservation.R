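test_that("Hamming neighborhoods have the exact combinatorial size", {
  expect_identical(instance_neighborhood("ACGTAC", 0), "ACGTAC")
  n1 <- instance_neighborhood("ACGTAC", 1)
  expect_length(n1, 19)            # 1 + 6*3
  expect_false(anyDuplicated(n1) > 0)
  n4 <- instance_neighborhood("ACGTAC", 4)
  expect_length(n4, 1909)          # sum_{k<=4} C(6,k) 3^k
  expect_false(anyDuplicated(n4) > 0)
  expect_length(instance_neighborhood("ACGTACGT", 2),
                1 + 8 * 3 + choose(8, 2) * 9)
  # every member is within distance d and includes the word itself
  expect_true(all(vapply(n1, hamming, numeric(1), b = "ACGTAC") <= 1))
  expect_true("ACGTAC" %in% n4)
})

test_that("zero-radius scoring reduces to exact-word counts and s1 = 1", {
  set.seed(61)
  refseq <- rand_dna(400)
  g <- self_group(refseq, n_related = 2)      # mu = 0, neutral = same seqs
  expect_true(all(g$related$mu == 0))
  words <- unique(vapply(seq(1, 300, by = 37), function(i)
    substr(refseq, i, i + 5), character(1)))
  sc <- conservation(words, g)
  # members are ref + 2 copies; the neutral set is 3 copies of the same
  members <- promoter_set(setNames(rep(refseq, 3), paste0("m", 1:3)))
  for (i in seq_along(words)) {
    expect_equal(sc$ao_sum[i], count_occurrences(words[i], members))
    expect_equal(sc$eo_sum[i], expected_occurrence(words[i], members))
  }
  scorable <- sc$ao_sum > 0
  expect_true(all(abs(sc$s1[scorable] - 1) < 1e-9))
})

test_that("instance-set AO/EO match brute-force loops over the neighborhood", {
  set.seed(67)
  refseq <- rand_dna(300)
  rel <- c(r1 = mutate_frac(refseq, 0.1), r2 = mutate_frac(refseq, 0.3))
  g <- manual_group(refseq, rel, mus = c(1 / 6, 2 / 6),
                    neutral_seqs = setNames(c(rand_dna(500), rand_dna(500)),
                                            c("n1", "n2")))
  word <- substr(refseq, 50, 55)
  r <- raw_ratio(word, g)
  # literal double loop: members (ref d=0, r1 d=1, r2 d=2) x instances
  seqs <- c(refseq, rel)
  ds <- c(0, 1, 2)
  ao <- 0; eo <- 0
  for (i in 1:3) {
    one <- promoter_set(setNames(seqs[i], "x"))
    for (inst in instance_neighborhood(word, ds[i])) {
      ao <- ao + count_occurrences(inst, one)
      eo <- eo + expected_occurrence(inst, one)
    }
  }
  expect_equal(unname(r["ao_sum"]), ao)
  expect_equal(unname(r["eo_sum"]), eo, tolerance = 1e-9)
})

test_that("uniform-composition EO over a radius-1 ball hits the closed form", {
  u <- strrep("ACGT", 250)                      # exactly uniform, 1000 bp
  g <- manual_group(u, c(r1 = u), mus = 1 / 6,  # d = 1 for the related copy
                    neutral_seqs = c(n1 = strrep("ACGT", 50)))
  r <- raw_ratio("GATTAC", g)
  # ref contributes at d = 0 (ball of 1), related at d = 1 (ball of 19)
  expect_equal(unname(r["eo_sum"]),
               2 * 995 * (1 / 4096) + 2 * 995 * (19 / 4096),
               tolerance = 1e-12)
})

test_that("k1 floors at eps when the word family is absent from neutral", {
  cg <- strrep("CG", 300)
  g <- manual_group(strrep("A", 200), c(r1 = strrep("A", 200)), mus = 0,
                    neutral_seqs = c(n1 = cg))
  expect_equal(correction_k1("AAAAAA", g), 1e-6)
})

test_that("k2 equals a literal loop over the observed same-length words", {
  set.seed(71)
  refseq <- rand_dna(60)
  rel <- c(r1 = mutate_frac(refseq, 0.2))
  g <- manual_group(refseq, rel, mus = 1 / 6,
                    neutral_seqs = c(n1 = rand_dna(80)))
  k2 <- correction_k2("ACGTAC", g)
  seqs <- c(refseq, rel); ds <- c(0, 1)
  obs <- unique(c(vapply(1:55, function(i) substr(refseq, i, i + 5),
                         character(1)),
                  vapply(1:55, function(i) substr(rel[1], i, i + 5),
                         character(1))))
  ratios <- vapply(obs, function(w) {
    ao <- 0; eo <- 0
    for (i in 1:2) {
      one <- promoter_set(setNames(seqs[i], "x"))
      for (inst in instance_neighborhood(w, ds[i])) {
        ao <- ao + count_occurrences(inst, one)
        eo <- eo + expected_occurrence(inst, one)
      }
    }
    ao / eo
  }, numeric(1))
  expect_equal(k2, mean(ratios), tolerance = 1e-9)
})

test_that("degenerate single-word group self-normalizes through k2", {
  # a promoter holding exactly one 6-mer: n = 1 observed word, so s2 = 1
  g <- manual_group("ACGTAC", c(r1 = "ACGTAC"), mus = 0,
                    neutral_seqs = c(n1 = "ACGTAC"))
  sc <- conservation("ACGTAC", g)
  expect_equal(sc$s2, 1, tolerance = 1e-9)
})

test_that("adding an instance occurrence raises s1; thresholds behave", {
  set.seed(73)
  refseq <- rand_dna(300)
  neutral <- setNames(c(rand_dna(600), rand_dna(600)), c("n1", "n2"))
  word <- "ACGTCA"
  rel0 <- c(r1 = mutate_frac(refseq, 0.05))
  g0 <- manual_group(refseq, rel0, mus = 0, neutral_seqs = neutral)
  s1_before <- conservation(word, g0)$s1
  boosted <- rel0
  substr(boosted["r1"], 100, 105) <- word
  g1 <- manual_group(refseq, boosted, mus = 0, neutral_seqs = neutral)
  s1_after <- conservation(word, g1)$s1
  expect_gte(s1_after, s1_before)

  # infinite threshold conserves nothing
  sc <- conservation(word, g1, threshold = Inf)
  expect_false(any(sc$conserved))

  # a word absent within radius scores zero and is not conserved
  absent <- "GGGGGG"
  if (count_occurrences(absent, promoter_set(c(a = refseq, boosted))) == 0) {
    sc0 <- conservation(absent, g1)
    expect_equal(sc0$ao_sum, 0)
    expect_equal(sc0$s1, 0)
    expect_false(sc0$conserved)
  }
})

test_that("under a complete null, few words clear the conservation bar", {
  set.seed(79)
  frac <- vapply(1:20, function(i) {
    refseq <- rand_dna(300)
    rel <- setNames(vapply(1:3, function(j)
      mutate_frac(refseq, runif(1, 0, 0.2)), character(1)),
      paste0("r", 1:3))
    neu <- setNames(vapply(1:3, function(j) rand_dna(900), character(1)),
                    paste0("n", 1:3))
    g <- build_phylo_group(c(ref = refseq), promoter_set(rel),
                           promoter_set(neu))
    # candidate words come from an unrelated promoter, as in the pipeline
    # null where the co-expressed set has nothing to do with this group
    other <- rand_dna(300)
    words <- unique(vapply(seq(1, 290, by = 13), function(k)
      substr(other, k, k + 5), character(1)))
    sc <- conservation(words, g)
    mean(sc$conserved)
  }, numeric(1))
  expect_lt(mean(frac), 0.5)
})
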