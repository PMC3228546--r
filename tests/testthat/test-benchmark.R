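test_that("generated groups obey the protocol's construction invariants", {
  spec <- benchmark_spec(seed = 131, mutation_level = 0.2)
  g <- generate_group(spec)
  expect_equal(n_promoters(g$coexpressed), 7)
  expect_equal(n_promoters(g$background), 210)
  expect_true(all(nchar(g$coexpressed$seq) == 1000))
  expect_true(all(nchar(g$background$seq) == 1000))
  expect_equal(nchar(g$consensus), 6)
  expect_length(g$orthologs, 7)
  expect_length(g$neutral, 7)
  for (id in names(g$orthologs)) {
    expect_equal(n_promoters(g$orthologs[[id]]), 5)
    expect_true(all(nchar(g$orthologs[[id]]$seq) == 1000))
    expect_equal(n_promoters(g$neutral[[id]]), 5)
    expect_true(all(nchar(g$neutral[[id]]$seq) == 5000))
  }
  # one planted instance per co-expressed promoter, within 1 mismatch
  expect_equal(nrow(g$truth), 7)
  expect_setequal(g$truth$promoter, names(g$coexpressed$seq))
  for (i in seq_len(nrow(g$truth))) {
    seq <- g$coexpressed$seq[[g$truth$promoter[i]]]
    planted <- substr(seq, g$truth$start[i] + 1, g$truth$end[i])
    expect_identical(planted, g$truth$instance[i])
    expect_lte(hamming(planted, g$consensus), 1)
  }
})

test_that("generation is deterministic given the seed", {
  a <- generate_group(benchmark_spec(seed = 137))
  b <- generate_group(benchmark_spec(seed = 137))
  expect_identical(a$consensus, b$consensus)
  expect_identical(a$coexpressed$seq, b$coexpressed$seq)
  expect_identical(a$background$seq, b$background$seq)
  expect_identical(lapply(a$orthologs, `[[`, "seq"),
                   lapply(b$orthologs, `[[`, "seq"))
  expect_identical(a$truth, b$truth)
  c <- generate_group(benchmark_spec(seed = 139))
  expect_false(identical(a$coexpressed$seq, c$coexpressed$seq))
})

test_that("ortholog divergence respects the mutation level", {
  spec <- benchmark_spec(seed = 149, mutation_level = 0.2,
                         promoter_len = 600, n_background = 5,
                         neutral_len = 600)
  g <- generate_group(spec)
  for (id in names(g$orthologs)) {
    src <- g$coexpressed$seq[[id]]
    for (o in g$orthologs[[id]]$seq)
      expect_gte(1 - hamming(src, o) / 600, 0.8)
  }
  # level 0: orthologs identical; alignment-estimated mu is exactly 0
  g0 <- generate_group(benchmark_spec(seed = 151, mutation_level = 0,
                                      promoter_len = 400,
                                      n_background = 5, neutral_len = 400))
  id <- names(g0$orthologs)[1]
  expect_true(all(g0$orthologs[[id]]$seq == g0$coexpressed$seq[[id]]))
  pg <- build_phylo_group(setNames(g0$coexpressed$seq[id], id),
                          g0$orthologs[[id]], g0$neutral[[id]])
  expect_true(all(pg$related$mu == 0))
})

test_that("neutral promoters mirror their ortholog's base composition", {
  g <- generate_group(benchmark_spec(seed = 157, promoter_len = 500,
                                     n_background = 5, neutral_len = 2500))
  id <- names(g$orthologs)[1]
  for (r in 1:5) {
    co <- base_composition(g$orthologs[[id]]$seq[[r]])
    cn <- base_composition(g$neutral[[id]]$seq[[r]])
    expect_true(all(abs(co - cn) < 0.05))
  }
})

test_that("noise injection appends unrelated promoters, truth untouched", {
  g <- generate_group(benchmark_spec(seed = 163, promoter_len = 300,
                                     n_background = 5, neutral_len = 300))
  g0 <- inject_noise(g, 0)
  expect_identical(g0$orthologs, g$orthologs)
  g8 <- inject_noise(g, 8, seed = 7)
  for (id in names(g8$orthologs)) {
    expect_equal(n_promoters(g8$orthologs[[id]]), 13)
    expect_true(all(nchar(g8$orthologs[[id]]$seq) == 300))
  }
  expect_identical(g8$truth, g$truth)
  expect_false(any(grepl("noise", g8$truth$promoter)))
})

test_that("nucleotide-level metrics match hand-enumerable cases", {
  toy <- promoter_set(c(p = strrep("A", 20)))
  truth <- data.frame(promoter = "p", start = 0L, end = 6L)
  pred <- data.frame(promoter = "p", start = 3L, end = 9L)
  ev <- evaluate_predictions(pred, truth, toy)
  expect_equal(ev$nTP, 3); expect_equal(ev$nFN, 3)
  expect_equal(ev$nFP, 3); expect_equal(ev$nTN, 11)
  expect_equal(ev$nSN, 0.5)
  expect_equal(ev$nPPV, 0.5)
  expect_equal(ev$nSP, 11 / 14)
  expect_equal(ev$nTP + ev$nFN + ev$nFP + ev$nTN, 20)

  # perfect prediction
  evp <- evaluate_predictions(truth, truth, toy)
  expect_equal(c(evp$nSN, evp$nSP, evp$nPPV), c(1, 1, 1))

  # empty prediction: sensitivity 0, specificity 1, precision undefined
  ev0 <- evaluate_predictions(NULL, truth, toy)
  expect_equal(ev0$nSN, 0)
  expect_equal(ev0$nSP, 1)
  expect_true(is.nan(ev0$nPPV))
  expect_false(ev0$defined[["nPPV"]])

  # overlapping predicted sites are not double-counted
  pred2 <- rbind(pred, data.frame(promoter = "p", start = 4L, end = 8L))
  expect_equal(evaluate_predictions(pred2, truth, toy)$nTP, 3)

  expect_error(
    evaluate_predictions(data.frame(promoter = "p", start = 15L, end = 25L),
                         truth, toy), "bounds")
  expect_error(
    evaluate_predictions(data.frame(promoter = "q", start = 0L, end = 5L),
                         truth, toy), "unknown promoter")
})

test_that("a reduced benchmark run completes and is reproducible", {
  spec <- benchmark_spec(promoter_len = 300, n_background = 60,
                         neutral_len = 900)
  b1 <- run_benchmark(spec, levels = 0.2, n_repeats = 1, seed = 5)
  expect_equal(nrow(b1$results), 1)
  expect_true(all(c("nSN", "nSP", "nPPV", "consensus_hit") %in%
                    names(b1$results)))
  ok <- is.finite(unlist(b1$results[, c("nSN", "nSP", "nPPV")]))
  vals <- unlist(b1$results[, c("nSN", "nSP", "nPPV")])[ok]
  expect_true(all(vals >= 0 & vals <= 1))
  b2 <- run_benchmark(spec, levels = 0.2, n_repeats = 1, seed = 5)
  expect_identical(b1$results, b2$results)
})
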