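# Word enumeration and actual/expected occurrence counting.
#
# The null model is per-sequence: a word's expected occurrence in promoter i
# is (L_p,i - L_m + 1) * (p_i(word) + p_i(revcomp(word))), where p_i is the
# product of promoter i's own base frequencies over the word's positions.
# Overlapping matches are counted and palindromes are counted on both
# strands (twice), keeping actual and expected counts on one convention.

#' Enumerate candidate words from a promoter set
#'
#' All distinct forward-strand substrings with lengths in
#' \code{[lmin, lmax]} present in at least one promoter.  This is the first
#' stage of the discovery flow: every word seen in the co-expressed
#' promoters is a candidate motif.
#'
#' @param promoters A \code{\link{promoter_set}}.
#' @param lmin,lmax Inclusive word-length range (the tool's convention is
#'   6-10 bp).
#' @return Character vector of distinct words (all lengths pooled).
#' @export
enumerate_words <- function(promoters, lmin = 6L, lmax = 10L) {
  stopifnot(inherits(promoters, "promoter_set"))
  lmin <- as.integer(lmin); lmax <- as.integer(lmax)
  if (lmin < 1L || lmin > lmax) stop("need 1 <= lmin <= lmax")
  if (lmax > max(nchar(promoters$seq)))
    stop("lmax (", lmax, ") exceeds the longest promoter (",
         max(nchar(promoters$seq)), " bp)")
  out <- lapply(lmin:lmax, function(L)
    unique(unlist(lapply(promoters$seq, .windows, lm = L),
                  use.names = FALSE)))
  unlist(out, use.names = FALSE)
}

#' Count occurrences of a word in a promoter set
#'
#' Exact matches at every position (overlaps counted).  With
#' \code{both_strands = TRUE} forward matches of the word and of its
#' reverse complement are summed, so a palindrome's count is exactly twice
#' its forward count.
#'
#' @param word A single DNA word over \code{A,C,G,T}.
#' @param promoters A \code{\link{promoter_set}}.
#' @param both_strands Count the reverse complement too? Default TRUE.
#' @return Integer total occurrence count.
#' @export
count_occurrences <- function(word, promoters, both_strands = TRUE) {
  stopifnot(inherits(promoters, "promoter_set"),
            is.character(word), length(word) == 1L)
  if (grepl("[^ACGT]", word) || !nzchar(word))
    stop("word must be a non-empty string over {A,C,G,T}")
  targets <- word
  if (both_strands) targets <- c(targets, revcomp(word))
  sum(vapply(promoters$seq, function(s) {
    w <- .windows(s, nchar(word))
    sum(w == targets[1]) +
      if (length(targets) > 1L) sum(w == targets[2]) else 0L
  }, numeric(1)))
}

# Product-of-base-frequencies probability of each word (columns of Widx)
# under composition `basep`.
.word_prob <- function(Widx, basep) {
  if (ncol(Widx) == 0L) return(numeric())
  exp(colSums(matrix(log(basep)[Widx], nrow = nrow(Widx))))
}

#' Expected occurrence of a word under the composition null
#'
#' For each promoter the word's match probability is the product of that
#' promoter's base frequencies over the word's letters; the expected count
#' over \code{L_p - L_m + 1} window positions and (optionally) both strands
#' is summed across the set.
#'
#' @inheritParams count_occurrences
#' @return Non-negative expected occurrence (real).
#' @examples
#' # one 1000-bp uniform promoter: 2 * 995 * 0.25^6
#' set.seed(1)
#' ps <- promoter_set(c(p = paste(sample(c("A","C","G","T"), 1000,
#'                                       replace = TRUE), collapse = "")))
#' expected_occurrence("ACGTAC", ps)
#' @export
expected_occurrence <- function(word, promoters, both_strands = TRUE) {
  stopifnot(inherits(promoters, "promoter_set"),
            is.character(word), length(word) == 1L)
  if (grepl("[^ACGT]", word) || !nzchar(word))
    stop("word must be a non-empty string over {A,C,G,T}")
  lm <- nchar(word)
  Widx <- .words_to_idx(if (both_strands) c(word, revcomp(word)) else word)
  sum(vapply(promoters$seq, function(s) {
    np <- nchar(s) - lm + 1L
    if (np < 1L) return(0)
    np * sum(.word_prob(Widx, base_composition(s)))
  }, numeric(1)))
}
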