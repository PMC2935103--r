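#' Assemble a wild isolate panel
#'
#' A wild panel is a set of pre-aligned, gap-free genome sequences of
#' natural isolates, all the same length as the reference. Natural standing
#' variation is read off its variable columns.
#'
#' @param sequences Named character vector of nucleotide strings (one per
#'   isolate), all equal length.
#' @return Object of class `wild_panel`: list with `mat` (isolate x position
#'   character matrix), `isolates`, `length`.
#' @export
wild_panel <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("isolate", seq_along(sequences))
  }
  sequences <- toupper(sequences)
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    bad <- names(sequences)[nchar(sequences) != len[1]][1]
    stop("panel sequences differ in length (isolate ", bad, ")")
  }
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  rownames(mat) <- names(sequences)
  structure(list(mat = mat, isolates = names(sequences), length = len),
            class = "wild_panel")
}

#' @export
print.wild_panel <- function(x, ...) {
  cat("Wild panel:", length(x$isolates), "isolates x", x$length, "nt\n")
  invisible(x)
}

#' Read a wild panel from aligned FASTA
#'
#' @param path FASTA of equal-length, ungapped isolate genomes.
#' @return A [wild_panel()].
#' @export
read_wild_panel <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  wild_panel(stats::setNames(as.character(seqs), names(seqs)))
}

# majority state per column, ties broken by the reference base
panel_consensus <- function(panel, genome) {
  if (panel$length != genome$length) {
    stop("panel length ", panel$length, " differs from genome length ",
         genome$length)
  }
  vapply(seq_len(panel$length), function(j) {
    tab <- table(panel$mat[, j])
    top <- names(tab)[tab == max(tab)]
    if (genome$chars[j] %in% top) genome$chars[j] else top[1]
  }, character(1))
}

#' Variable nucleotides and residues in a wild panel
#'
#' A nucleotide column is variable when at least two distinct states occur
#' among the isolates. A residue `(gene, residue)` is variable when some
#' non-consensus state at a covering position changes that gene's amino acid
#' (changes are polarized against the panel consensus — majority state, ties
#' broken by the reference — and mapped on the consensus background).
#'
#' @param panel A [wild_panel()].
#' @param genome A [genome_annotation()].
#' @return List with `variable_nucleotides` (integer positions),
#'   `variable_residues` (data.frame `gene`, `residue`) and `consensus`
#'   (character vector of consensus bases).
#' @export
derive_wild_variation <- function(panel, genome) {
  cons <- panel_consensus(panel, genome)
  nstates <- apply(panel$mat, 2, function(col) length(unique(col)))
  var_nt <- which(nstates >= 2L)
  diffs <- panel_differences(panel, cons, var_nt)
  if (nrow(diffs)) {
    ch <- map_changes(genome, diffs$position, diffs$alt, background = cons)
    ch <- ch[!ch$silent, , drop = FALSE]
    res <- unique(ch[, c("gene", "residue")])
    res <- res[order(match(res$gene, genome$genes$name), res$residue), ,
               drop = FALSE]
    rownames(res) <- NULL
  } else {
    res <- data.frame(gene = character(), residue = integer(),
                      stringsAsFactors = FALSE)
  }
  list(variable_nucleotides = var_nt, variable_residues = res,
       consensus = cons)
}

# one row per (variable column, distinct non-consensus state)
panel_differences <- function(panel, cons, var_nt) {
  out <- lapply(var_nt, function(j) {
    states <- setdiff(unique(panel$mat[, j]), cons[j])
    if (!length(states)) return(NULL)
    data.frame(position = j, alt = states, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(position = integer(), alt = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Expected overlap of two site sets under independent placement
#'
#' With a sites of one kind and b of another drawn independently from a
#' universe of N sites, the expected intersection is `a * b / N` — the mean
#' of the hypergeometric distribution of the intersection size. For the
#' phiX174 comparison (N = 1986 residues, a = 216 experimentally evolved,
#' b = 206 wild-variable) this is ~22.4, i.e. ~1.1% of the universe.
#'
#' @param N Universe size (positive).
#' @param a,b Set sizes, each `<= N`.
#' @return Real-valued expected intersection.
#' @export
expected_overlap <- function(N, a, b) {
  if (N <= 0) stop("universe size N must be positive")
  if (a > N || b > N || a < 0 || b < 0) {
    stop("set sizes must lie in [0, N]")
  }
  a * b / N
}

#' Test the overlap of experimental and wild variable sites
#'
#' Compares the observed intersection of two site sets with its expectation
#' under independent placement and attaches an upper-tail hypergeometric
#' p-value, `P(X >= observed)`. The p-value is an extension beyond the
#' expected-vs-observed comparison and is labelled as such in printed
#' output.
#'
#' @inheritParams expected_overlap
#' @param observed Observed intersection size, `<= min(a, b)`.
#' @return Object of class `overlap_result`: list with `N`, `a`, `b`,
#'   `expected`, `observed`, `p_value`.
#' @export
overlap_test <- function(N, a, b, observed) {
  expected <- expected_overlap(N, a, b)
  if (observed > min(a, b) || observed < 0) {
    stop("observed intersection ", observed, " inconsistent with set sizes")
  }
  p <- stats::phyper(observed - 1, a, N - a, b, lower.tail = FALSE)
  structure(list(N = N, a = a, b = b, expected = expected,
                 observed = observed, p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Site-set overlap: universe ", x$N, ", |A| = ", x$a, " (",
      round(100 * x$a / x$N), "%), |B| = ", x$b, " (",
      round(100 * x$b / x$N), "%)\n", sep = "")
  cat("  expected in common: ", round(x$expected, 1), " (",
      round(100 * x$expected / x$N, 1), "% of universe); observed: ",
      x$observed, "\n", sep = "")
  cat("  hypergeometric P(X >= ", x$observed, ") = ",
      format(x$p_value, digits = 3),
      "  [extension: not part of the expectation-only comparison]\n",
      sep = "")
  invisible(x)
}

#' Silent-to-missense ratio of wild panel differences
#'
#' Counts the distinct nucleotide differences (per column, each distinct
#' non-consensus state) in a wild panel and classifies each as silent or
#' missense in its gene context. With `exclude_overlaps = TRUE` (the
#' default), positions inside out-of-frame gene overlaps are dropped first,
#' so every remaining coding position has an unambiguous single-frame
#' classification (same-frame overlaps such as A/A* agree by construction).
#' With `exclude_overlaps = FALSE` a difference counts as missense if it is
#' non-silent in any covering frame. Non-coding positions are not
#' classifiable and are skipped. A strongly silent-biased ratio (phiX174
#' wild isolates: 3.8) is the signature of purifying selection.
#'
#' @param panel A [wild_panel()] with at least 2 isolates.
#' @param genome A [genome_annotation()].
#' @param exclude_overlaps Drop positions in the out-of-frame overlap mask.
#' @return Object of class `silent_missense_ratio`: list with `silent`,
#'   `missense`, `ratio` (silent/missense), `exclusion`, `n_classifiable`.
#'   It is an error when no position is classifiable or when no missense
#'   difference exists (the ratio is then undefined).
#' @export
silent_missense_ratio <- function(panel, genome, exclude_overlaps = TRUE) {
  if (length(panel$isolates) < 2L) {
    stop("panel must contain at least 2 isolates")
  }
  wv <- derive_wild_variation(panel, genome)
  diffs <- panel_differences(panel, wv$consensus, wv$variable_nucleotides)
  if (exclude_overlaps) {
    mask <- build_overlap_mask(genome)
    diffs <- diffs[!diffs$position %in% mask, , drop = FALSE]
  }
  if (nrow(diffs)) {
    ch <- map_changes(genome, diffs$position, diffs$alt,
                      background = wv$consensus)
    # classify per difference: missense if non-silent in any covering frame
    if (nrow(ch)) {
      silent_by_event <- tapply(ch$silent, ch$event, all)
      silent <- sum(silent_by_event)
      missense <- sum(!silent_by_event)
    } else {
      silent <- 0L; missense <- 0L
    }
    n_class <- if (nrow(ch)) length(unique(ch$event)) else 0L
  } else {
    silent <- 0L; missense <- 0L; n_class <- 0L
  }
  if (n_class == 0L) stop("no classifiable sites")
  if (missense == 0L) {
    stop("no missense differences; silent:missense ratio undefined")
  }
  structure(list(silent = as.integer(silent),
                 missense = as.integer(missense),
                 ratio = silent / missense,
                 exclusion = exclude_overlaps,
                 n_classifiable = n_class),
            class = "silent_missense_ratio")
}

#' @export
print.silent_missense_ratio <- function(x, ...) {
  cat("Silent:missense among wild differences",
      if (x$exclusion) "(out-of-frame overlaps excluded):" else
        "(overlaps included):",
      x$silent, ":", x$missense, "=", round(x$ratio, 2), "\n")
  invisible(x)
}
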