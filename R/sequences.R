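# Sequence containers, FASTA IO, base composition and strand conventions.
#
# Promoters are stored as a named character vector of uppercase DNA over
# {A,C,G,T,N}.  N is tolerated on input but never matches any word: every
# counting routine drops windows that touch an N, while the full promoter
# length still enters the expected-occurrence terms.

#' Create a promoter set
#'
#' A promoter set is the basic container used throughout the package: a
#' named collection of uppercase DNA sequences over \code{A,C,G,T,N}.  It
#' plays four roles in the method: the co-expressed set, the background set,
#' a phylogenetically related (orthologous) set, and a neutral set.
#'
#' @param sequences Named character vector (or named list) of DNA sequences.
#'   Lowercase input is normalized to uppercase.  Names are the promoter ids
#'   and must be unique and non-empty.
#' @param name Label for the set (used in printing and reports).
#' @return An object of class \code{promoter_set} with elements \code{name}
#'   and \code{seq} (named character vector).
#' @examples
#' ps <- promoter_set(c(p1 = "ACGTACGT", p2 = "GGGCCC"))
#' n_promoters(ps)
#' @export
promoter_set <- function(sequences, name = "promoters") {
  if (is.list(sequences)) sequences <- unlist(sequences)
  if (length(sequences) == 0L)
    stop("promoter set must contain at least one sequence")
  if (!is.character(sequences))
    stop("sequences must be supplied as character strings")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence needs a non-empty id (vector names)")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(sequences)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence(s) ", paste(ids[bad], collapse = ", "),
         " contain characters outside {A,C,G,T,N}")
  if (any(!nzchar(seqs)))
    stop("empty sequence(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  structure(list(name = as.character(name)[1], seq = seqs),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set '%s': %d sequence(s), lengths %d-%d bp\n",
              x$name, length(x$seq), min(nchar(x$seq)), max(nchar(x$seq))))
  invisible(x)
}

#' Number of promoters in a set
#' @param x A \code{promoter_set}.
#' @return Integer count of sequences.
#' @export
n_promoters <- function(x) {
  stopifnot(inherits(x, "promoter_set"))
  length(x$seq)
}

#' Read promoters from a FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file into a
#' \code{\link{promoter_set}}.  Record ids are the header text up to the
#' first whitespace; record order is preserved.  Empty files, duplicate ids
#' and characters outside \code{A,C,G,T,N} raise parse errors.
#'
#' @param path Path to a FASTA file.
#' @param name Label for the resulting set; defaults to the file name.
#' @return A \code{promoter_set}.
#' @export
read_promoter_fasta <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("FASTA parse error in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  promoter_set(seqs, name = name)
}

#' Write a promoter set to FASTA
#' @param x A \code{promoter_set}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_promoter_fasta <- function(x, path) {
  stopifnot(inherits(x, "promoter_set"))
  writeLines(paste0(">", names(x$seq), "\n", x$seq), path)
  invisible(path)
}

#' Base composition of a sequence
#'
#' Frequencies of A, C, G and T among the non-N positions of a sequence.
#' These per-sequence compositions drive the expected-occurrence null of the
#' word-counting model and the construction of composition-matched neutral
#' promoters in the benchmark generator.
#'
#' @param seq A single DNA string (or an element of a promoter set).
#' @return Named numeric vector \code{c(A=,C=,G=,T=)} summing to 1.
#' @examples
#' base_composition("AACG")
#' @export
base_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  counts <- Biostrings::letterFrequency(Biostrings::BString(seq), .BASES)
  tot <- sum(counts)
  if (tot == 0L) stop("sequence has no non-N bases")
  setNames(as.numeric(counts) / tot, .BASES)
}

#' Reverse complement of DNA words
#'
#' Standard reverse complement over the strict alphabet \code{A,C,G,T}
#' (an involution).  Vectorized over words.
#'
#' @param word Character vector of DNA words.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTGT")
#' revcomp("CACGTG")  # palindrome
#' @export
revcomp <- function(word) {
  if (length(word) == 0L) return(character())
  if (!is.character(word) || any(is.na(word)) || any(!nzchar(word)))
    stop("words must be non-empty character strings")
  if (any(grepl("[^ACGT]", word)))
    stop("words must be over {A,C,G,T}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(word)))
}

# All length-lm windows of a sequence on the forward strand, with windows
# containing N removed (N never matches a word).
.windows <- function(seq, lm) {
  np <- nchar(seq) - lm + 1L
  if (np < 1L) return(character())
  w <- substring(seq, seq_len(np), lm:nchar(seq))
  if (grepl("N", seq, fixed = TRUE)) w <- w[!grepl("N", w, fixed = TRUE)]
  w
}

# Encode words (equal length) as an L x m integer matrix of base codes 1..4.
.words_to_idx <- function(words) {
  if (length(words) == 0L) return(matrix(integer(), nrow = 0L, ncol = 0L))
  L <- nchar(words[1])
  matrix(match(unlist(strsplit(words, "", fixed = TRUE), use.names = FALSE),
               .BASES),
         nrow = L)
}

#' Write motif sites as BED6
#'
#' Sites use 0-based half-open coordinates with the promoter id as the
#' chromosome field.  The BED score column is the word's best per-group
#' conservation score (\code{min(s1,s2)}) times 100, rounded and clipped to
#' the BED 0-1000 range; when no score is available 0 is written.
#'
#' @param sites Data frame with columns \code{promoter,start,end,word,strand}
#'   and optionally \code{score}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_sites_bed <- function(sites, path) {
  score <- if ("score" %in% names(sites)) {
    pmax(0, pmin(1000, round(sites$score * 100)))
  } else rep(0L, nrow(sites))
  bed <- data.frame(sites$promoter, sites$start, sites$end,
                    sites$word, score, sites$strand)
  write.table(bed, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
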