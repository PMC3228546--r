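# Mutation-degree estimation from pairwise local alignment.
#
# For each phylogenetically related promoter the reference promoter is
# locally aligned (Smith-Waterman, affine gaps, BLASTN-like scoring);
# further blocks are recovered by masking the previously aligned regions
# with N and re-aligning.  The mutation degree of the pair is
# mu = 1 - min(identity over retained blocks); pairs with no block above
# the score threshold are excluded as false homologs.

#' Alignment scoring parameters
#'
#' BLASTN-style defaults: match +1, mismatch -2, gap open 5, gap extend 2
#' (penalties are positive numbers, subtracted from the score).
#' \code{min_score} is the retention threshold for a local block (16, i.e.
#' the score of a perfect 16-bp match), a practical stand-in for an
#' alignment-significance cutoff that keeps unrelated random promoters out.
#' Up to \code{max_blocks} non-overlapping blocks are recovered per pair.
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param min_score Minimum block score for retention.
#' @param max_blocks Maximum number of blocks recovered by iterative
#'   masking.
#' @return A list of class \code{align_scoring}.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = 5,
                          gap_extend = 2, min_score = 16, max_blocks = 4L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            min_score > 0, max_blocks >= 1L)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score = min_score,
                 max_blocks = as.integer(max_blocks)),
            class = "align_scoring")
}

# Substitution matrix over A,C,G,T,N; N is scored prohibitively so masked
# (or genuinely ambiguous) positions never enter an alignment block.
.submat <- function(sc) {
  ab <- c(.BASES, "N")
  m <- matrix(sc$mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- sc$match
  m["N", ] <- -1e6; m[, "N"] <- -1e6
  m
}

#' Local alignment blocks between two promoters
#'
#' Smith-Waterman local alignment with affine gaps; after each block the
#' aligned intervals are masked in both sequences and the alignment is
#' repeated, so up to \code{max_blocks} non-overlapping conserved blocks
#' are reported, sorted by score (descending).  Identity is identical
#' columns over all alignment columns, gap columns counting as mismatches.
#'
#' @param ref,other DNA strings (single sequences).
#' @param scoring An \code{\link{align_scoring}} object.
#' @return Data frame with one row per retained block:
#'   \code{ref_start, ref_end, other_start, other_end} (0-based half-open),
#'   \code{length} (alignment columns), \code{identity}, \code{score}.
#' @export
local_align <- function(ref, other, scoring = align_scoring()) {
  stopifnot(is.character(ref), is.character(other),
            nzchar(ref), nzchar(other))
  sm <- .submat(scoring)
  p <- toupper(ref); s <- toupper(other)
  out <- vector("list", scoring$max_blocks)
  for (i in seq_len(scoring$max_blocks)) {
    aln <- Biostrings::pairwiseAlignment(
      p, s, type = "local", substitutionMatrix = sm,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    if (score(aln) < scoring$min_score) break
    rs <- start(pattern(aln)); re <- end(pattern(aln))
    os <- start(subject(aln)); oe <- end(subject(aln))
    out[[i]] <- data.frame(
      ref_start = rs - 1L, ref_end = re,
      other_start = os - 1L, other_end = oe,
      length = nchar(aln),
      identity = Biostrings::nmatch(aln) / nchar(aln),
      score = score(aln))
    substr(p, rs, re) <- strrep("N", re - rs + 1L)
    substr(s, os, oe) <- strrep("N", oe - os + 1L)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(ref_start = integer(), ref_end = integer(),
                      other_start = integer(), other_end = integer(),
                      length = integer(), identity = numeric(),
                      score = numeric())
  out[order(-out$score), , drop = FALSE]
}

#' Mutation degree from alignment blocks
#'
#' \code{mu = 1 - min(identity)} over the retained blocks — the conserved
#' block with maximal mutation sets the divergence allowed for motif
#' instances.  An empty block list means the related promoter shows no
#' credible homology and is excluded (\code{NA}).  \code{mu} is clamped to
#' \code{[0, mu_cap]} so the mismatch radius used downstream stays within
#' half the word length.
#'
#' @param blocks Data frame from \code{\link{local_align}}.
#' @param mu_cap Upper clamp for \code{mu} (default 0.5).
#' @return Mutation degree in \code{[0, mu_cap]}, or \code{NA_real_} when
#'   no block was retained.
#' @export
mutation_degree <- function(blocks, mu_cap = 0.5) {
  if (is.null(blocks) || nrow(blocks) == 0L) return(NA_real_)
  mu <- 1 - min(blocks$identity)
  min(max(mu, 0), mu_cap)
}

#' Assemble a phylogenetic promoter group
#'
#' Aligns the reference promoter to each related (orthologous) promoter,
#' annotates each with its mutation degree or an excluded flag, and
#' attaches the matched neutral set.  In conservation scoring the
#' reference itself participates as a member with \code{mu = 0}.
#'
#' @param reference Named character vector of length 1 (the reference
#'   promoter), or a single-sequence \code{\link{promoter_set}}.
#' @param related \code{\link{promoter_set}} of candidate orthologous
#'   promoters.
#' @param neutral \code{\link{promoter_set}} of phylogenetically unrelated
#'   promoters (the conservation null).
#' @param scoring An \code{\link{align_scoring}} object.
#' @param mu_cap Upper clamp for \code{mu}.
#' @return An object of class \code{phylo_group}: reference id/sequence,
#'   per-related-promoter table (\code{id, mu, min_identity, n_blocks,
#'   excluded}), sequences, the neutral set, and a \code{usable} flag
#'   (FALSE, with a warning, when every related promoter was excluded).
#' @export
build_phylo_group <- function(reference, related, neutral,
                              scoring = align_scoring(), mu_cap = 0.5) {
  if (inherits(reference, "promoter_set")) {
    stopifnot(n_promoters(reference) == 1L)
    reference <- reference$seq
  }
  stopifnot(is.character(reference), length(reference) == 1L,
            !is.null(names(reference)),
            inherits(related, "promoter_set"),
            inherits(neutral, "promoter_set"))
  if (n_promoters(related) == 0L) stop("related promoter set is empty")
  ann <- lapply(related$seq, function(s) {
    blocks <- local_align(reference[[1]], s, scoring)
    list(mu = mutation_degree(blocks, mu_cap),
         min_identity = if (nrow(blocks)) min(blocks$identity) else NA_real_,
         n_blocks = nrow(blocks))
  })
  tab <- data.frame(
    id = names(related$seq),
    mu = vapply(ann, `[[`, numeric(1), "mu"),
    min_identity = vapply(ann, `[[`, numeric(1), "min_identity"),
    n_blocks = vapply(ann, `[[`, integer(1), "n_blocks"))
  tab$excluded <- is.na(tab$mu)
  rownames(tab) <- NULL
  usable <- any(!tab$excluded)
  if (!usable)
    warning("all related promoters excluded for reference '",
            names(reference), "'; group flagged unusable")
  structure(list(reference_id = names(reference),
                 reference = unname(reference[[1]]),
                 related = tab,
                 related_seq = related$seq,
                 neutral = neutral,
                 mu_cap = mu_cap,
                 usable = usable),
            class = "phylo_group")
}

#' @export
print.phylo_group <- function(x, ...) {
  kept <- sum(!x$related$excluded)
  cat(sprintf(
    "phylo_group '%s': %d related promoter(s) (%d retained), %d neutral\n",
    x$reference_id, nrow(x$related), kept, n_promoters(x$neutral)))
  if (kept)
    cat(sprintf("  mu range of retained: %.3f-%.3f\n",
                min(x$related$mu, na.rm = TRUE),
                max(x$related$mu, na.rm = TRUE)))
  invisible(x)
}
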