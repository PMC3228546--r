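# Planted-motif benchmark: synthetic co-expressed promoters with one
# planted degenerate motif instance each, uniform background promoters,
# simulated orthologs obtained by random point substitution at a chosen
# divergence level, composition-matched neutral promoters, optional
# injection of random "noisy" promoters, and nucleotide-level evaluation.

.rand_seq <- function(n, len, prob = rep(0.25, 4)) {
  m <- matrix(sample(.BASES, n * len, replace = TRUE, prob = prob),
              nrow = len)
  apply(m, 2L, paste, collapse = "")
}

#' Benchmark specification
#'
#' Defaults reproduce the synthetic protocol used to characterize the
#' method: 7 co-expressed promoters of 1000 bp with uniform base
#' composition, each carrying one planted instance of a 6-bp consensus
#' with at most 1 mismatch; 210 background promoters (thirty times the
#' co-expressed count); 5 simulated orthologs per gene, each a copy of the
#' source promoter with a random fraction (uniform on
#' \code{[0, mutation_level]}) of positions substituted; one 5000-bp
#' neutral promoter per ortholog (five times the promoter length), drawn
#' i.i.d. from that ortholog's realized base composition.
#'
#' @param n_coexpressed,n_background Set sizes.
#' @param promoter_len,neutral_len Sequence lengths (bp).
#' @param motif_len Planted consensus length.
#' @param motif_max_mismatch Maximum mismatches of a planted instance; the
#'   mismatch count is drawn uniformly from \code{0:motif_max_mismatch}.
#' @param n_orthologs Simulated orthologs per co-expressed gene.
#' @param mutation_level Divergence level, one of the protocol's
#'   0.2/0.4/0.6/0.8 (any value in \code{[0,1]} accepted).
#' @param fixed_mutation_fraction If TRUE the mutated fraction is exactly
#'   \code{mutation_level} instead of uniform on \code{[0, level]}.
#' @param instances_per_promoter Planted instances per co-expressed
#'   promoter (default 1); 0 gives a motif-free null group.
#' @param n_noise Random promoters appended to every ortholog set.
#' @param seed Integer seed making generation fully reproducible;
#'   \code{NULL} uses (and advances) the caller's RNG stream.
#' @return A list of class \code{benchmark_spec}.
#' @export
benchmark_spec <- function(n_coexpressed = 7L, n_background = 210L,
                           promoter_len = 1000L, motif_len = 6L,
                           motif_max_mismatch = 1L, n_orthologs = 5L,
                           mutation_level = 0.2, neutral_len = 5000L,
                           fixed_mutation_fraction = FALSE,
                           instances_per_promoter = 1L, n_noise = 0L,
                           seed = NULL) {
  stopifnot(n_coexpressed >= 1L, n_background >= 1L,
            promoter_len >= motif_len, motif_len >= 1L,
            motif_max_mismatch >= 0L, motif_max_mismatch <= motif_len,
            n_orthologs >= 1L, mutation_level >= 0, mutation_level <= 1,
            neutral_len >= motif_len, instances_per_promoter >= 0L,
            n_noise >= 0L)
  structure(as.list(environment()), class = "benchmark_spec")
}

# One planted instance: the consensus with `mm` positions substituted.
.mutate_word <- function(word, mm) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  if (mm > 0L) {
    pos <- sample(length(chars), mm)
    for (p in pos) chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Substitute `k` random positions of a sequence with different bases.
.mutate_seq <- function(seq, k) {
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Generate one synthetic benchmark group
#'
#' Draws a uniform consensus motif, plants one (or more) instances within
#' the allowed mismatch count into each co-expressed promoter at a uniform
#' position (overwriting the sequence), and builds the background,
#' ortholog and neutral sets per the protocol in
#' \code{\link{benchmark_spec}}.  Identical spec and seed give identical
#' output.
#'
#' @param spec A \code{\link{benchmark_spec}}.
#' @return A list of class \code{benchmark_group}: \code{consensus},
#'   \code{coexpressed}, \code{background} (promoter sets),
#'   \code{orthologs} and \code{neutral} (lists of promoter sets, one per
#'   co-expressed gene), and \code{truth} (data frame of planted sites:
#'   \code{promoter, start, end, strand, instance, mismatches}, 0-based
#'   half-open).
#' @export
generate_group <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  .with_seed(spec$seed, {
    consensus <- paste(sample(.BASES, spec$motif_len, replace = TRUE),
                       collapse = "")
    ids <- paste0("gene", seq_len(spec$n_coexpressed))
    coseq <- .rand_seq(spec$n_coexpressed, spec$promoter_len)
    truth <- list()
    for (i in seq_len(spec$n_coexpressed)) {
      for (r in seq_len(spec$instances_per_promoter)) {
        mm <- sample(0:spec$motif_max_mismatch, 1L)
        inst <- .mutate_word(consensus, mm)
        pos <- sample(spec$promoter_len - spec$motif_len + 1L, 1L)
        substr(coseq[i], pos, pos + spec$motif_len - 1L) <- inst
        truth[[length(truth) + 1L]] <- data.frame(
          promoter = ids[i], start = pos - 1L,
          end = pos - 1L + spec$motif_len, strand = "+",
          instance = inst, mismatches = mm)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(promoter = character(), start = integer(),
                 end = integer(), strand = character(),
                 instance = character(), mismatches = integer())
    # re-read the planted strings: later instances may overwrite earlier
    # ones, and the recorded instance must always match the sequence
    truth$instance <- substring(coseq[match(truth$promoter, ids)],
                                truth$start + 1L, truth$end)
    coexpressed <- promoter_set(setNames(coseq, ids), "coexpressed")
    background <- promoter_set(
      setNames(.rand_seq(spec$n_background, spec$promoter_len),
               paste0("bg", seq_len(spec$n_background))), "background")
    orthologs <- vector("list", spec$n_coexpressed)
    neutral <- vector("list", spec$n_coexpressed)
    for (i in seq_len(spec$n_coexpressed)) {
      oseq <- character(spec$n_orthologs)
      for (r in seq_len(spec$n_orthologs)) {
        u <- if (spec$fixed_mutation_fraction) spec$mutation_level
             else runif(1, 0, spec$mutation_level)
        oseq[r] <- .mutate_seq(coseq[i], round(u * spec$promoter_len))
      }
      names(oseq) <- paste0(ids[i], "_orth", seq_len(spec$n_orthologs))
      if (spec$n_noise > 0L) {
        noise <- .rand_seq(spec$n_noise, spec$promoter_len)
        names(noise) <- paste0(ids[i], "_noise", seq_len(spec$n_noise))
        oseq <- c(oseq, noise)
      }
      orthologs[[i]] <- promoter_set(oseq, paste0(ids[i], "_orthologs"))
      nseq <- vapply(seq_len(spec$n_orthologs), function(r) {
        .rand_seq(1L, spec$neutral_len,
                  prob = base_composition(oseq[r]))
      }, character(1))
      names(nseq) <- paste0(ids[i], "_neutral", seq_len(spec$n_orthologs))
      neutral[[i]] <- promoter_set(nseq, paste0(ids[i], "_neutral"))
    }
    names(orthologs) <- names(neutral) <- ids
    structure(list(spec = spec, consensus = consensus,
                   coexpressed = coexpressed, background = background,
                   orthologs = orthologs, neutral = neutral,
                   truth = truth),
              class = "benchmark_group")
  })
}

#' Inject noisy promoters into a benchmark group
#'
#' Appends \code{k} i.i.d. uniform-composition random promoters to every
#' ortholog set, leaving the planted-site truth untouched — the noisy
#' promoters emulate mistaken orthologs.
#'
#' @param group A \code{\link{benchmark_group}}.
#' @param k Number of noisy promoters per ortholog set.
#' @param seed Optional seed for the noise draw.
#' @return The modified \code{benchmark_group}.
#' @export
inject_noise <- function(group, k, seed = NULL) {
  stopifnot(inherits(group, "benchmark_group"), k >= 0L)
  if (k == 0L) return(group)
  .with_seed(seed, {
    for (id in names(group$orthologs)) {
      noise <- .rand_seq(k, group$spec$promoter_len)
      names(noise) <- paste0(id, "_noise",
                             seq_len(k) + sum(grepl("_noise",
                                                    names(group$orthologs[[id]]$seq))))
      group$orthologs[[id]] <- promoter_set(
        c(group$orthologs[[id]]$seq, noise),
        group$orthologs[[id]]$name)
    }
    group
  })
}

#' Nucleotide-level evaluation of predicted sites
#'
#' Compares predicted and known (planted) sites position by position over
#' all promoters of the evaluated set: a position is a true positive when
#' covered by both a known and a predicted site.  Sensitivity
#' \code{nSN = nTP/(nTP+nFN)}, specificity \code{nSP = nTN/(nTN+nFP)} and
#' positive predictive value \code{nPPV = nTP/(nTP+nFP)}; a metric with a
#' zero denominator is returned as \code{NaN} with its \code{defined} flag
#' set to FALSE.
#'
#' @param prediction_sites,truth_sites Data frames with columns
#'   \code{promoter, start, end} (0-based half-open) referring to
#'   \code{promoters}.
#' @param promoters The evaluated \code{\link{promoter_set}} (normally the
#'   co-expressed set).
#' @return List with confusion counts \code{nTP,nFP,nFN,nTN}, metrics
#'   \code{nSN,nSP,nPPV} and logical vector \code{defined}.
#' @export
evaluate_predictions <- function(prediction_sites, truth_sites, promoters) {
  stopifnot(inherits(promoters, "promoter_set"))
  mask <- function(sites) {
    ms <- lapply(promoters$seq, function(s) logical(nchar(s)))
    if (!is.null(sites) && nrow(sites)) {
      if (!all(sites$promoter %in% names(promoters$seq)))
        stop("site refers to unknown promoter id")
      for (i in seq_len(nrow(sites))) {
        id <- sites$promoter[i]
        if (sites$start[i] < 0L || sites$end[i] > nchar(promoters$seq[[id]]) ||
            sites$start[i] >= sites$end[i])
          stop("site outside promoter bounds: ", id, " [",
               sites$start[i], ",", sites$end[i], ")")
        ms[[id]][(sites$start[i] + 1L):sites$end[i]] <- TRUE
      }
    }
    unlist(ms, use.names = FALSE)
  }
  truth <- mask(truth_sites)
  pred <- mask(prediction_sites)
  nTP <- sum(truth & pred); nFP <- sum(!truth & pred)
  nFN <- sum(truth & !pred); nTN <- sum(!truth & !pred)
  metric <- function(num, den) if (den > 0) num / den else NaN
  list(nTP = nTP, nFP = nFP, nFN = nFN, nTN = nTN,
       nSN = metric(nTP, nTP + nFN),
       nSP = metric(nTN, nTN + nFP),
       nPPV = metric(nTP, nTP + nFP),
       defined = c(nSN = (nTP + nFN) > 0, nSP = (nTN + nFP) > 0,
                   nPPV = (nTP + nFP) > 0))
}

# Is the planted consensus (or a word within 1 mismatch of it, on either
# strand) among the reported words?
.consensus_hit <- function(words, consensus) {
  words <- words[nchar(words) == nchar(consensus)]
  if (!length(words)) return(FALSE)
  dist <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  any(vapply(words, function(w)
    min(dist(w, consensus), dist(revcomp(w), consensus)) <= 1L, logical(1)))
}

#' Run the full synthetic benchmark
#'
#' For each divergence level and repeat: generate a benchmark group, build
#' the phylogenetic groups by local alignment (the full mutation-degree
#' estimation, not the generator's truth), run the discovery flow with the
#' motif length pinned to the planted length, and evaluate the reported
#' sites at nucleotide level.
#'
#' @param spec Base \code{\link{benchmark_spec}}; its
#'   \code{mutation_level} and \code{seed} are overridden per run.
#' @param config \code{\link{ocw_config}} for the discovery flow;
#'   \code{NULL} (default) pins \code{lmin = lmax = spec$motif_len}.
#' @param levels Divergence levels (default the protocol's
#'   0.2/0.4/0.6/0.8).
#' @param n_repeats Repeats per level (the full protocol uses 15).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param n_noise Noisy promoters injected into every ortholog set.
#' @return List of class \code{ocw_benchmark}: \code{results} (one row per
#'   group: level, repeat, metrics, consensus recovery) and \code{summary}
#'   (per-level means and standard errors over the defined values).
#' @export
run_benchmark <- function(spec = benchmark_spec(), config = NULL,
                          levels = c(0.2, 0.4, 0.6, 0.8), n_repeats = 15L,
                          seed = 1L, n_noise = 0L) {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (is.null(config))
    config <- ocw_config(lmin = spec$motif_len, lmax = spec$motif_len)
  rows <- list()
  counter <- 0L
  for (lev in levels) {
    for (r in seq_len(n_repeats)) {
      counter <- counter + 1L
      s <- spec
      s$mutation_level <- lev
      s$n_noise <- n_noise
      s$seed <- as.integer((seed * 1009L + counter * 7919L) %% 2147483647L)
      grp <- generate_group(s)
      pg <- lapply(names(grp$orthologs), function(id) {
        suppressWarnings(build_phylo_group(
          setNames(grp$coexpressed$seq[id], id),
          grp$orthologs[[id]], grp$neutral[[id]],
          scoring = config$scoring, mu_cap = config$mu_cap))
      })
      res <- tryCatch(
        run_ocw(grp$coexpressed, grp$background, pg, config),
        error = function(e) NULL)
      ev <- evaluate_predictions(if (is.null(res)) NULL else res$sites,
                                 grp$truth, grp$coexpressed)
      rows[[counter]] <- data.frame(
        level = lev, rep = r, seed = s$seed,
        nSN = ev$nSN, nSP = ev$nSP, nPPV = ev$nPPV,
        n_reported = if (is.null(res)) 0L else nrow(res$predictions),
        n_pass_fisher = if (is.null(res)) NA_integer_ else
          res$counts$n_pass_fisher,
        consensus_hit = if (is.null(res)) FALSE else
          .consensus_hit(res$predictions$word, grp$consensus))
    }
  }
  results <- do.call(rbind, rows)
  sum_one <- function(v) {
    v <- v[is.finite(v)]
    c(mean = if (length(v)) mean(v) else NaN,
      se = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NaN,
      n = length(v))
  }
  summary <- do.call(rbind, lapply(split(results, results$level), function(d)
    data.frame(level = d$level[1],
               t(c(nSN = sum_one(d$nSN), nSP = sum_one(d$nSP),
                   nPPV = sum_one(d$nPPV))),
               consensus_rate = mean(d$consensus_hit))))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, spec = spec,
                 config = config),
            class = "ocw_benchmark")
}

#' @export
print.ocw_benchmark <- function(x, ...) {
  cat("ocw_benchmark:", nrow(x$results), "group(s)\n")
  print(x$summary, digits = 3)
  invisible(x)
}
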