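# Shared fixtures and brute-force oracles, built in code.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(len, prob = rep(0.25, 4)) {
  paste(sample(BASES, len, replace = TRUE, prob = prob), collapse = "")
}

rand_set <- function(n, len, prefix = "p", prob = rep(0.25, 4)) {
  promoter_set(setNames(vapply(seq_len(n), function(i) rand_dna(len, prob),
                               character(1)),
                        paste0(prefix, seq_len(n))))
}

# Point-substitute a fraction `frac` of positions (each to a different base).
mutate_frac <- function(seq, frac) {
  chars <- strsplit(seq, "")[[1]]
  k <- round(frac * length(chars))
  if (k > 0) for (p in sample(length(chars), k))
    chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  paste(chars, collapse = "")
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# Brute-force both-strand occurrence count by position-wise scan.
brute_count <- function(word, seqs, both_strands = TRUE) {
  targets <- if (both_strands) unique(c(word, revcomp(word))) else word
  # a palindrome must still be counted twice under both strands
  mult <- if (both_strands && revcomp(word) == word) 2 else 1
  tot <- 0
  for (s in seqs) for (i in seq_len(nchar(s) - nchar(word) + 1)) {
    win <- substr(s, i, i + nchar(word) - 1)
    if (win %in% targets) tot <- tot + 1
  }
  tot * mult
}

# A phylo group in which every member is an exact copy of the reference
# (mu = 0 everywhere) and the neutral set is a copy of the same sequences:
# the self-normalizing configuration where s1 must be exactly 1.
self_group <- function(refseq, n_related = 2) {
  rel <- promoter_set(setNames(rep(refseq, n_related),
                               paste0("rel", seq_len(n_related))))
  neu <- promoter_set(setNames(rep(refseq, n_related + 1),
                               paste0("neu", seq_len(n_related + 1))))
  build_phylo_group(c(ref = refseq), rel, neu)
}

# A hand-assembled phylo group with prescribed mutation degrees, used to
# pin instance radii exactly in unit tests.
manual_group <- function(refseq, related_seqs, mus, neutral_seqs,
                         mu_cap = 0.5) {
  structure(list(
    reference_id = "ref", reference = refseq,
    related = data.frame(id = names(related_seqs), mu = mus,
                         min_identity = 1 - mus,
                         n_blocks = 1L, excluded = is.na(mus)),
    related_seq = related_seqs,
    neutral = promoter_set(neutral_seqs),
    mu_cap = mu_cap, usable = any(!is.na(mus))),
    class = "phylo_group")
}

# Build the per-gene phylo groups of a generated benchmark group through
# the full alignment-based estimation.
benchmark_phylo <- function(g, scoring = align_scoring(), mu_cap = 0.5) {
  lapply(names(g$orthologs), function(id)
    suppressWarnings(build_phylo_group(
      setNames(g$coexpressed$seq[id], id),
      g$orthologs[[id]], g$neutral[[id]], scoring = scoring,
      mu_cap = mu_cap)))
}

# Memoised full-protocol benchmark shared by the operating-point and
# divergence-robustness acceptance tests (4 levels x 5 repeats).
acceptance_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_benchmark(spec = benchmark_spec(), n_repeats = 5L,
                              levels = c(0.2, 0.4, 0.6, 0.8),
                              seed = 424243L)
    cache
  }
})
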