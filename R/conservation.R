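# Mutation-degree conservation scoring.
#
# A word's conservation in a phylogenetic promoter group is the ratio of
# the actual to the expected occurrence of its mutational instances —
# all words within Hamming distance d_i = floor(mu_i * L_m) of it, where
# mu_i is promoter i's estimated mutation degree — summed over the group's
# retained promoters (the reference participates with mu = 0), and
# normalized twice:
#   s1 = (AO/EO) / k1, k1 = AO'/EO' of the same word in the neutral set;
#   s2 = (AO/EO) / k2, k2 = mean AO''/EO'' over every same-length word
#        observed in the group.
# A word is called conserved when both corrected scores exceed the
# threshold (default 1.1).

#' Hamming neighborhood of a word
#'
#' All words of the same length within Hamming distance \code{d} of
#' \code{word} (the word's mutational instances), including the word
#' itself.  The neighborhood size is \code{sum_k C(L,k) 3^k} for
#' \code{k = 0..d}.
#'
#' @param word A DNA word over \code{A,C,G,T}.
#' @param d Maximum Hamming distance, \code{0 <= d <= nchar(word)}.
#' @return Character vector of distinct instances.
#' @examples
#' length(instance_neighborhood("ACGTAC", 1))  # 1 + 6*3 = 19
#' @export
instance_neighborhood <- function(word, d) {
  stopifnot(is.character(word), length(word) == 1L, nzchar(word))
  if (grepl("[^ACGT]", word)) stop("word must be over {A,C,G,T}")
  L <- nchar(word)
  d <- as.integer(d)
  if (d < 0L || d > L) stop("need 0 <= d <= word length")
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  out <- list(word)
  for (k in seq_len(d)) {
    pos_sets <- combn(L, k)
    for (ci in seq_len(ncol(pos_sets))) {
      pos <- pos_sets[, ci]
      subs <- lapply(pos, function(p) setdiff(.BASES, chars[p]))
      grid <- as.matrix(do.call(expand.grid,
                                c(subs, stringsAsFactors = FALSE)))
      out[[length(out) + 1L]] <- apply(grid, 1L, function(repl) {
        v <- chars; v[pos] <- repl; paste(v, collapse = "")
      })
    }
  }
  unlist(out, use.names = FALSE)
}

# Occurrence profile of one promoter at word length lm: distinct observed
# forward words with counts, the base composition, and the number of
# window positions.
.member_profile <- function(seq, lm) {
  w <- .windows(seq, lm)
  tab <- table(w)
  list(obs = names(tab),
       obs_idx = .words_to_idx(names(tab)),
       counts = as.numeric(tab),
       basep = base_composition(seq),
       npos = max(0L, nchar(seq) - lm + 1L))
}

# Probability mass of the Hamming ball of radius d around each query word
# (columns of Widx) under independent-base composition basep, via the
# coefficient recursion of prod_j (a_j + z b_j) truncated at z^d.
.ball_prob <- function(Widx, basep, d) {
  m <- ncol(Widx)
  if (m == 0L) return(numeric())
  L <- nrow(Widx)
  d <- min(d, L)
  a <- matrix(basep[Widx], nrow = L)
  C <- matrix(0, d + 1L, m)
  C[1L, ] <- 1
  for (j in seq_len(L)) {
    aj <- matrix(a[j, ], d + 1L, m, byrow = TRUE)
    Cn <- C * aj
    if (d > 0L)
      Cn[-1L, ] <- Cn[-1L, , drop = FALSE] +
        C[-(d + 1L), , drop = FALSE] *
        matrix(1 - a[j, ], d, m, byrow = TRUE)
    C <- Cn
  }
  colSums(C)
}

# Both-strand instance-set AO and EO of each query word, summed over a
# list of members; members = list(list(profile=, d=)).  Queries are folded
# with their reverse complements (rc of a Hamming ball is the ball of the
# rc), matching the both-strand convention of the exact-word counts.
.group_ao_eo <- function(words, members) {
  m <- length(words)
  q2 <- c(words, revcomp(words))
  Q <- .words_to_idx(q2)
  ao2 <- numeric(2L * m)
  eo2 <- numeric(2L * m)
  for (mem in members) {
    p <- mem$profile
    if (p$npos == 0L || length(p$obs) == 0L) next
    ao2 <- ao2 + .hamming_ball_sums(Q, p$obs_idx, p$counts, mem$d)
    eo2 <- eo2 + p$npos * .ball_prob(Q, p$basep, mem$d)
  }
  list(ao = ao2[seq_len(m)] + ao2[m + seq_len(m)],
       eo = eo2[seq_len(m)] + eo2[m + seq_len(m)])
}

# Retained members of a phylo group at word length lm: the reference
# (mu = 0) plus every non-excluded related promoter, each with its
# mismatch radius d_i = floor(mu_i * lm).
.group_members <- function(group, lm) {
  stopifnot(inherits(group, "phylo_group"))
  keep <- !group$related$excluded
  mus <- c(0, group$related$mu[keep])
  seqs <- c(group$reference, unname(group$related_seq[keep]))
  lapply(seq_along(seqs), function(i)
    list(profile = .member_profile(seqs[i], lm),
         d = as.integer(floor(pmin(mus[i], group$mu_cap) * lm)),
         mu = mus[i]))
}

# Uniform radius used on the neutral set: the neutral promoters carry no
# mutation degree of their own, so the mean mu of the retained phylo
# members is applied to all of them.
.neutral_members <- function(group, lm, members) {
  mus <- vapply(members, `[[`, numeric(1), "mu")
  d_neu <- as.integer(floor(min(mean(mus), group$mu_cap) * lm))
  lapply(group$neutral$seq, function(s)
    list(profile = .member_profile(s, lm), d = d_neu))
}

#' Raw instance-occurrence ratio of a word in a phylo group
#'
#' Numerator of the conservation score: actual and expected occurrences of
#' all mutational instances of \code{word}, summed over the group's
#' retained promoters (reference included at \code{mu = 0}), both strands.
#'
#' @param word A DNA word.
#' @param group A \code{\link{phylo_group}}.
#' @return Named numeric \code{c(ao_sum=, eo_sum=)}.
#' @export
raw_ratio <- function(word, group) {
  r <- .group_ao_eo(word, .group_members(group, nchar(word)))
  c(ao_sum = r$ao, eo_sum = r$eo)
}

#' Neutral-set correction factor k1
#'
#' The same instance-occurrence ratio evaluated on the group's neutral
#' (phylogenetically unrelated) promoter set, with the retained members'
#' mean mismatch radius applied uniformly; floored at \code{eps}.
#'
#' @inheritParams raw_ratio
#' @param eps Positive floor guarding against division by zero.
#' @return Scalar \code{k1 >= eps}.
#' @export
correction_k1 <- function(word, group, eps = 1e-6) {
  lm <- nchar(word)
  members <- .group_members(group, lm)
  r <- .group_ao_eo(word, .neutral_members(group, lm, members))
  if (r$eo <= 0) return(eps)
  max(r$ao / r$eo, eps)
}

#' Word-level correction factor k2
#'
#' Mean instance-occurrence ratio over all distinct same-length words
#' observed in the group's retained promoters, under the same per-promoter
#' radii as the word under study; floored at \code{eps}.  \code{k2} is a
#' property of the group and the word length, not of the individual word.
#'
#' @inheritParams correction_k1
#' @param observed_words Optional character vector overriding the set of
#'   observed words averaged over (mainly for testing); by default every
#'   distinct forward-strand word of the group's retained promoters.
#' @param scope \code{"group"} (default) pools occurrences across the
#'   group's promoters before averaging over words; \code{"promoter"}
#'   averages each promoter's own observed-word ratios, then the
#'   promoters.
#' @return Scalar \code{k2 >= eps}.
#' @export
correction_k2 <- function(word, group, observed_words = NULL, eps = 1e-6,
                          scope = c("group", "promoter")) {
  scope <- match.arg(scope)
  lm <- nchar(word)
  members <- .group_members(group, lm)
  ratio_over <- function(mem_list, obs) {
    r <- .group_ao_eo(obs, mem_list)
    ok <- r$eo > 0
    if (!any(ok)) return(NA_real_)
    mean(r$ao[ok] / r$eo[ok])
  }
  if (scope == "group") {
    obs <- observed_words %||%
      unique(unlist(lapply(members, function(m) m$profile$obs),
                    use.names = FALSE))
    k2 <- ratio_over(members, obs)
  } else {
    per <- vapply(members, function(m)
      ratio_over(list(m), observed_words %||% m$profile$obs), numeric(1))
    k2 <- mean(per, na.rm = TRUE)
  }
  if (!is.finite(k2)) return(eps)
  max(k2, eps)
}

#' Conservation scores of candidate words in a phylo group
#'
#' Computes, for every word (all of one length), the instance-occurrence
#' ratio and both corrected scores, and calls the word conserved when
#' \code{min(s1, s2) > threshold}.  Words with zero expected occurrence
#' are unscorable and reported with \code{conserved = FALSE} and a reason
#' flag; words whose correction factors hit the \code{eps} floor are
#' flagged as well.
#'
#' @param words Character vector of DNA words of a single common length
#'   (typically the Fisher-passing candidates).
#' @param group A \code{\link{phylo_group}} with at least one retained
#'   member.
#' @param threshold Conservation threshold on both corrected scores
#'   (default 1.1).
#' @param eps Floor for the correction factors.
#' @param k2_scope Passed to \code{\link{correction_k2}} as \code{scope}.
#' @return Data frame \code{word, ao_sum, eo_sum, k1, k2, s1, s2,
#'   conserved, flag} with one row per word.
#' @export
conservation <- function(words, group, threshold = 1.1, eps = 1e-6,
                         k2_scope = "group") {
  stopifnot(inherits(group, "phylo_group"), length(words) >= 1L)
  lm <- unique(nchar(words))
  if (length(lm) != 1L)
    stop("all words must share one length; got lengths ",
         paste(lm, collapse = ", "))
  if (!group$usable)
    stop("phylo group '", group$reference_id, "' has no retained members")
  members <- .group_members(group, lm)
  num <- .group_ao_eo(words, members)

  neutral <- .neutral_members(group, lm, members)
  neu <- .group_ao_eo(words, neutral)
  k1 <- ifelse(neu$eo > 0, pmax(neu$ao / neu$eo, eps), eps)
  k1_floored <- k1 <= eps

  k2 <- correction_k2(words[1], group, eps = eps, scope = k2_scope)

  ratio <- ifelse(num$eo > 0, num$ao / num$eo, NA_real_)
  s1 <- ratio / k1
  s2 <- ratio / k2
  conserved <- !is.na(ratio) & s1 > threshold & s2 > threshold
  flag <- rep("ok", length(words))
  flag[k1_floored] <- "k1_floored"
  flag[is.na(ratio)] <- "unscorable_eo0"
  data.frame(word = words, ao_sum = num$ao, eo_sum = num$eo,
             k1 = k1, k2 = k2, s1 = s1, s2 = s2,
             conserved = conserved, flag = flag)
}
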