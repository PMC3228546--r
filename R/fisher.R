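# Over-representation screening: one-sided Fisher's exact test of word
# presence in co-expressed promoters against a background promoter set.

#' Presence contingency table for a word
#'
#' Counts promoters containing at least one exact occurrence of the word on
#' either strand: \code{n1}/\code{n2} among the co-expressed promoters
#' (containing / not containing), \code{m1}/\code{m2} among the background
#' promoters.
#'
#' @param word A DNA word over \code{A,C,G,T}.
#' @param coexpressed,background \code{\link{promoter_set}} objects.
#' @return Named integer vector \code{c(n1=,n2=,m1=,m2=)}.
#' @export
presence_table <- function(word, coexpressed, background) {
  stopifnot(inherits(coexpressed, "promoter_set"),
            inherits(background, "promoter_set"))
  if (n_promoters(background) == 0L) stop("background set is empty")
  pres <- function(set) {
    hits <- grepl(word, set$seq, fixed = TRUE) |
      grepl(revcomp(word), set$seq, fixed = TRUE)
    sum(hits)
  }
  n1 <- pres(coexpressed); m1 <- pres(background)
  c(n1 = n1, n2 = n_promoters(coexpressed) - n1,
    m1 = m1, m2 = n_promoters(background) - m1)
}

#' One-sided Fisher's exact p-value for over-representation
#'
#' Probability, under the hypergeometric null with fixed margins, of
#' observing \code{n1} or more co-expressed promoters containing the word.
#' Equivalent to \code{fisher.test(..., alternative = "greater")} on the
#' 2x2 table.  Vectorized over table rows.
#'
#' @param n1,n2,m1,m2 Table cells, or pass a single named vector/table as
#'   \code{n1} (as produced by \code{\link{presence_table}}).
#' @return p-value(s) in (0, 1].
#' @export
fisher_p <- function(n1, n2 = NULL, m1 = NULL, m2 = NULL) {
  if (is.null(n2)) {
    tab <- n1
    n1 <- tab[["n1"]]; n2 <- tab[["n2"]]
    m1 <- tab[["m1"]]; m2 <- tab[["m2"]]
  }
  if (any(c(n1, n2, m1, m2) < 0)) stop("table cells must be non-negative")
  # P(X >= n1), X ~ Hypergeometric(drawn = n1+n2 co-expressed promoters,
  # successes = n1+m1 word-containing promoters in the population)
  phyper(n1 - 1, n1 + m1, n2 + m2, n1 + n2, lower.tail = FALSE)
}

#' Screen words for over-representation
#'
#' Applies the presence-based Fisher test to every candidate word and keeps
#' those with (optionally multiplicity-adjusted) p-value below \code{alpha},
#' sorted by p-value with lexicographic tie-breaks.
#'
#' @param words Character vector of candidate words (lengths may be mixed).
#' @param coexpressed,background \code{\link{promoter_set}} objects.
#' @param alpha Significance cutoff (strict \code{p < alpha}); the tool's
#'   convention is 0.01.
#' @param correction Multiple-testing adjustment: \code{"none"} (default,
#'   the original setting), \code{"bonferroni"} or \code{"BH"}.
#' @return Data frame \code{word, n1, n2, m1, m2, p_value, p_adj}, one row
#'   per retained word, ordered by \code{p_adj} then word.
#' @export
filter_overrepresented <- function(words, coexpressed, background,
                                   alpha = 0.01, correction = "none") {
  stopifnot(inherits(coexpressed, "promoter_set"),
            inherits(background, "promoter_set"))
  correction <- match.arg(correction, c("none", "bonferroni", "BH"))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (length(words) == 0L)
    return(data.frame(word = character(), n1 = integer(), n2 = integer(),
                      m1 = integer(), m2 = integer(), p_value = numeric(),
                      p_adj = numeric()))
  res <- lapply(split(words, nchar(words)), function(w) {
    rcw <- revcomp(w)
    count_presence <- function(set) {
      pres <- integer(length(w))
      L <- nchar(w[1])
      for (s in set$seq) {
        u <- unique(.windows(s, L))
        pres <- pres + ((w %in% u) | (rcw %in% u))
      }
      pres
    }
    n1 <- count_presence(coexpressed)
    m1 <- count_presence(background)
    data.frame(word = w, n1 = n1, n2 = n_promoters(coexpressed) - n1,
               m1 = m1, m2 = n_promoters(background) - m1)
  })
  res <- do.call(rbind, res)
  res$p_value <- fisher_p(res$n1, res$n2, res$m1, res$m2)
  res$p_adj <- p.adjust(res$p_value, method =
                          if (correction == "none") "none" else correction)
  if (alpha < 1) res <- res[res$p_adj < alpha, , drop = FALSE]
  res <- res[order(res$p_adj, res$word), , drop = FALSE]
  rownames(res) <- NULL
  res
}
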