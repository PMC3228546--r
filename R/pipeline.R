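# The four-stage discovery flow: enumerate words in the co-expressed
# promoters, screen by Fisher over-representation against background,
# score conservation in each phylogenetic group, and report words
# conserved in enough groups together with their nucleotide-level sites.

#' Configuration for a discovery run
#'
#' @param lmin,lmax Word-length range enumerated (default 6-10 bp).  Pin
#'   \code{lmin = lmax} when the target motif length is known.
#' @param fisher_alpha Strict p-value cutoff of the over-representation
#'   screen (default 0.01).
#' @param s_threshold Conservation threshold applied to both corrected
#'   scores (default 1.1).
#' @param mu_cap Upper clamp on the mutation degree (default 0.5), keeping
#'   the instance radius within half the word length.
#' @param min_groups_conserved Number of usable phylogenetic groups in
#'   which a word must be conserved to be reported (default 1), or the
#'   string \code{"majority"} for a majority of the usable groups.  On the
#'   synthetic benchmark the ortholog sets are mutated copies of the
#'   co-expressed promoters, so words present by chance in a co-expressed
#'   promoter reappear in its orthologs and single-group conservation is
#'   easy to clear; raising this knob trades sensitivity for specificity.
#' @param correction Multiple-testing adjustment of the Fisher screen
#'   (\code{"none"}, the original setting, \code{"bonferroni"} or
#'   \code{"BH"}).
#' @param eps Floor for the conservation correction factors.
#' @param k2_scope Scope of the word-level correction (see
#'   \code{\link{correction_k2}}).
#' @param scoring \code{\link{align_scoring}} parameters used when phylo
#'   groups are built through \code{\link{run_ocw}} helpers.
#' @return A list of class \code{ocw_config}.
#' @export
ocw_config <- function(lmin = 6L, lmax = 10L, fisher_alpha = 0.01,
                       s_threshold = 1.1, mu_cap = 0.5,
                       min_groups_conserved = 1L, correction = "none",
                       eps = 1e-6, k2_scope = "group",
                       scoring = align_scoring()) {
  stopifnot(lmin >= 1L, lmin <= lmax, fisher_alpha > 0, fisher_alpha <= 1,
            s_threshold >= 0, mu_cap >= 0, mu_cap <= 1, eps > 0)
  if (is.character(min_groups_conserved))
    min_groups_conserved <- match.arg(min_groups_conserved, "majority")
  else stopifnot(min_groups_conserved >= 1L)
  structure(list(lmin = as.integer(lmin), lmax = as.integer(lmax),
                 fisher_alpha = fisher_alpha, s_threshold = s_threshold,
                 mu_cap = mu_cap,
                 min_groups_conserved = min_groups_conserved,
                 correction = correction, eps = eps, k2_scope = k2_scope,
                 scoring = scoring),
            class = "ocw_config")
}

#' Exact-match sites of a word in a promoter set
#'
#' All positions where the word or its reverse complement matches exactly,
#' in 0-based half-open coordinates on the forward strand.  For a
#' palindromic word each position is reported once, with strand \code{+}.
#'
#' @param word A DNA word over \code{A,C,G,T}.
#' @param promoters A \code{\link{promoter_set}}.
#' @return Data frame \code{promoter, start, end, strand}.
#' @export
word_sites <- function(word, promoters) {
  stopifnot(inherits(promoters, "promoter_set"),
            is.character(word), length(word) == 1L, nzchar(word))
  lm <- nchar(word)
  rc <- revcomp(word)
  rows <- lapply(names(promoters$seq), function(id) {
    w <- substring(promoters$seq[[id]],
                   seq_len(max(0L, nchar(promoters$seq[[id]]) - lm + 1L)),
                   lm:nchar(promoters$seq[[id]]))
    fwd <- which(w == word)
    rev <- if (rc == word) integer() else which(w == rc)
    if (!length(fwd) && !length(rev)) return(NULL)
    data.frame(promoter = id,
               start = c(fwd, rev) - 1L,
               end = c(fwd, rev) - 1L + lm,
               strand = rep(c("+", "-"), c(length(fwd), length(rev))))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(promoter = character(), start = integer(),
                      end = integer(), strand = character())
  out[order(out$promoter, out$start, out$strand), , drop = FALSE]
}

#' Run the over-represented-and-conserved-word discovery flow
#'
#' Enumerates every word of the configured lengths present in the
#' co-expressed promoters, keeps words over-represented against the
#' background by the one-sided Fisher test, scores each survivor's
#' mutation-degree conservation in every usable phylogenetic group, and
#' reports the words conserved in at least
#' \code{min_groups_conserved} groups, with their exact-match sites in the
#' co-expressed promoters.
#'
#' @param coexpressed \code{\link{promoter_set}} of co-expressed gene
#'   promoters.
#' @param background \code{\link{promoter_set}} of background promoters.
#' @param phylo_groups List of \code{\link{phylo_group}} objects (one per
#'   co-expressed gene; see \code{\link{build_phylo_group}}).
#' @param config An \code{\link{ocw_config}}.
#' @return An object of class \code{ocw_result} with elements
#'   \code{predictions} (word, Fisher counts and p, groups conserved),
#'   \code{sites} (exact-match site list of the reported words),
#'   \code{conservation} (per-group scores of every Fisher-passing word),
#'   \code{counts} (per-stage word counts) and \code{n_groups_usable}.
#' @export
run_ocw <- function(coexpressed, background, phylo_groups,
                    config = ocw_config()) {
  stopifnot(inherits(coexpressed, "promoter_set"),
            inherits(background, "promoter_set"),
            inherits(config, "ocw_config"),
            is.list(phylo_groups), length(phylo_groups) >= 1L)
  ok <- vapply(phylo_groups, function(g)
    inherits(g, "phylo_group") && g$usable, logical(1))
  if (!any(ok))
    stop("no usable phylogenetic group: every related promoter was ",
         "excluded in all ", length(phylo_groups), " group(s)")
  groups <- phylo_groups[ok]
  gmin <- if (identical(config$min_groups_conserved, "majority"))
    ceiling(length(groups) / 2) else config$min_groups_conserved

  words <- enumerate_words(coexpressed, config$lmin, config$lmax)
  enr <- filter_overrepresented(words, coexpressed, background,
                                alpha = config$fisher_alpha,
                                correction = config$correction)
  counts <- list(n_enumerated = length(words),
                 n_pass_fisher = nrow(enr),
                 n_groups_usable = length(groups))

  cons <- NULL
  if (nrow(enr) > 0L) {
    per_len <- split(enr$word, nchar(enr$word))
    cons <- do.call(rbind, unlist(lapply(seq_along(groups), function(gi) {
      lapply(per_len, function(w) {
        sc <- conservation(w, groups[[gi]],
                           threshold = config$s_threshold,
                           eps = config$eps, k2_scope = config$k2_scope)
        sc$group <- groups[[gi]]$reference_id
        sc
      })
    }), recursive = FALSE))
    rownames(cons) <- NULL
  }

  if (is.null(cons) || nrow(cons) == 0L) {
    n_cons <- setNames(integer(nrow(enr)), enr$word)
  } else {
    agg <- tapply(cons$conserved, cons$word, sum)
    n_cons <- setNames(as.integer(agg[enr$word]), enr$word)
    n_cons[is.na(n_cons)] <- 0L
  }
  keep <- n_cons >= gmin
  predictions <- enr[keep, , drop = FALSE]
  predictions$n_groups_conserved <- n_cons[keep]
  predictions <- predictions[order(predictions$p_value, predictions$word), ,
                             drop = FALSE]
  rownames(predictions) <- NULL
  counts$n_reported <- nrow(predictions)

  sites <- do.call(rbind, lapply(predictions$word, function(w) {
    s <- word_sites(w, coexpressed)
    if (nrow(s) == 0L) return(NULL)
    s$word <- w
    best <- if (!is.null(cons)) {
      sc <- cons[cons$word == w & cons$conserved, , drop = FALSE]
      if (nrow(sc)) max(pmin(sc$s1, sc$s2)) else 0
    } else 0
    s$score <- best
    s
  }))
  if (is.null(sites))
    sites <- data.frame(promoter = character(), start = integer(),
                        end = integer(), strand = character(),
                        word = character(), score = numeric())
  structure(list(predictions = predictions, sites = sites,
                 conservation = cons, counts = counts,
                 n_groups_usable = length(groups),
                 min_groups_conserved = gmin, config = config),
            class = "ocw_result")
}

#' @export
print.ocw_result <- function(x, ...) {
  cat(sprintf(
    "ocw_result: %d words enumerated -> %d over-represented -> %d reported\n",
    x$counts$n_enumerated, x$counts$n_pass_fisher, x$counts$n_reported))
  cat(sprintf("  %d usable phylo group(s); conservation required in >= %d\n",
              x$n_groups_usable, x$min_groups_conserved))
  if (nrow(x$predictions))
    print(head(x$predictions[, c("word", "n1", "m1", "p_value",
                                 "n_groups_conserved")], 10))
  invisible(x)
}

#' Write the prediction table as TSV
#' @param result An \code{ocw_result}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_predictions_tsv <- function(result, path) {
  stopifnot(inherits(result, "ocw_result"))
  write.table(result$predictions, path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}
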