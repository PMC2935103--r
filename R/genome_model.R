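#' Circular genome annotation with overlapping reading frames
#'
#' Constructs a validated annotation of a circular single-stranded genome
#' (the phiX174-like case: ~5.4 kb, forward-strand genes only, genes may
#' overlap each other in different reading frames and may wrap the origin).
#' Coordinates are 1-based inclusive; a gene with `end < start` wraps the
#' origin, i.e. it covers `start..G, 1..end`.
#'
#' Validation enforces that every gene span is a multiple of 3 and that no
#' gene contains an internal stop codon (a terminal stop codon is allowed
#' and is excluded from the residue count).
#'
#' @param sequence Single nucleotide string over A/C/G/T (case-insensitive).
#' @param genes `data.frame` with columns `name`, `start`, `end` and
#'   optionally `essential` (logical).
#' @return An object of class `genome_annotation`: a list with elements
#'   `sequence`, `chars`, `length`, `genes`, `circular`, plus precomputed
#'   per-gene position maps used by the mapping functions.
#' @examples
#' g <- genome_annotation("ATGGCATTAGCG",
#'                        data.frame(name = "X", start = 1, end = 9))
#' gene_protein(g, "X")  # "MAL"
#' @export
genome_annotation <- function(sequence, genes) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("sequence contains characters outside {A,C,G,T}")
  }
  G <- length(chars)
  if (!is.data.frame(genes) || !all(c("name", "start", "end") %in% names(genes))) {
    stop("genes must be a data.frame with columns name, start, end")
  }
  genes <- data.frame(
    name = as.character(genes$name),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    essential = if ("essential" %in% names(genes)) as.logical(genes$essential) else NA,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$name)) stop("duplicate gene names in annotation")
  if (any(genes$start < 1L | genes$start > G | genes$end < 1L | genes$end > G)) {
    stop("gene coordinates outside [1, ", G, "]")
  }

  gene_positions <- lapply(seq_len(nrow(genes)), function(i) {
    circular_span(genes$start[i], genes$end[i], G)
  })
  names(gene_positions) <- genes$name

  spans <- lengths(gene_positions)
  bad <- which(spans %% 3L != 0L)
  if (length(bad)) {
    stop("gene ", genes$name[bad[1]], ": span of ", spans[bad[1]],
         " nt is not a multiple of 3")
  }

  # per-gene lookup: offset within gene for every genomic position (NA if
  # not covered); overlapping genes each get their own map
  posmap <- lapply(gene_positions, function(p) {
    m <- rep(NA_integer_, G)
    m[p] <- seq_along(p)
    m
  })

  obj <- structure(
    list(sequence = sequence, chars = chars, length = G, genes = genes,
         circular = TRUE, gene_positions = gene_positions, posmap = posmap),
    class = "genome_annotation"
  )

  # no internal stop codons
  for (i in seq_len(nrow(genes))) {
    aa <- translate_codons(chars[gene_positions[[i]]])
    internal <- aa[-length(aa)]
    if (any(internal == "*")) {
      stop("gene ", genes$name[i], ": internal stop codon at codon index ",
           which(internal == "*")[1])
    }
  }
  obj
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("Circular genome annotation:", x$length, "nt,", nrow(x$genes), "genes\n")
  print(x$genes)
  invisible(x)
}

# positions covered by a (possibly origin-wrapping) interval on a circle of
# size G, in reading order
circular_span <- function(start, end, G) {
  if (end >= start) seq.int(start, end) else c(seq.int(start, G), seq.int(1L, end))
}

# standard genetic code (tables 1 and 11 agree at the codon level)
translate_codons <- function(chars) {
  stopifnot(length(chars) %% 3L == 0L)
  n <- length(chars) %/% 3L
  codons <- paste0(chars[seq.int(1L, by = 3L, length.out = n)],
                   chars[seq.int(2L, by = 3L, length.out = n)],
                   chars[seq.int(3L, by = 3L, length.out = n)])
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Protein sequence of an annotated gene
#'
#' Translates a gene off the (possibly origin-wrapping) reference, dropping a
#' terminal stop codon if present.
#'
#' @param genome A [genome_annotation()].
#' @param gene Gene name.
#' @return Single-letter amino acid string.
#' @export
gene_protein <- function(genome, gene) {
  pos <- genome$gene_positions[[gene]]
  if (is.null(pos)) stop("unknown gene: ", gene)
  aa <- translate_codons(genome$chars[pos])
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Number of amino-acid coding codons per gene
#'
#' Codon count per gene excluding a terminal stop codon. The sum over genes
#' is the residue universe used for overlap expectations (positions inside
#' gene-gene overlaps count once per gene).
#'
#' @param genome A [genome_annotation()].
#' @return Named integer vector of residue counts.
#' @export
gene_residue_counts <- function(genome) {
  vapply(genome$genes$name, function(nm) {
    pos <- genome$gene_positions[[nm]]
    n <- length(pos) %/% 3L
    last <- translate_codons(genome$chars[pos[(3L * n - 2L):(3L * n)]])
    as.integer(n - (last == "*"))
  }, integer(1))
}

#' Load a genome and its gene annotation from files
#'
#' Reads a single-record FASTA and an annotation given either as GFF3
#' (rows of type `CDS` are used, gene names from the `Name` attribute) or as
#' a tab-separated table with header `name start end [essential]`. An
#' annotation row whose `end` exceeds the genome length, or is smaller than
#' its `start`, encodes an origin-wrapping gene.
#'
#' @param fasta_source Path to a FASTA file with exactly one sequence.
#' @param annotation_source Path to a GFF3 (`.gff`/`.gff3`) or TSV file.
#' @return A validated [genome_annotation()].
#' @export
load_genome <- function(fasta_source, annotation_source) {
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  if (length(seqs) != 1L) {
    stop("expected exactly one sequence in FASTA, found ", length(seqs))
  }
  sequence <- as.character(seqs[[1]])
  genes <- read_gene_table(annotation_source, G = nchar(sequence))
  genome_annotation(sequence, genes)
}

read_gene_table <- function(path, G) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md)) {
      keep <- as.character(md$type) == "CDS"
      if (any(keep)) gr <- gr[keep]
    }
    md <- S4Vectors::mcols(gr)
    nm <- if ("Name" %in% names(md)) as.character(md$Name)
          else if ("ID" %in% names(md)) as.character(md$ID)
          else paste0("gene", seq_along(gr))
    genes <- data.frame(name = nm,
                        start = BiocGenerics::start(gr),
                        end = BiocGenerics::end(gr),
                        stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "start", "end")
    if (!all(need %in% names(genes))) {
      stop("annotation table must have columns: ", paste(need, collapse = ", "))
    }
  }
  # end > G is an alternative origin-wrap encoding; normalise to end < start
  wrap <- genes$end > G
  genes$end[wrap] <- genes$end[wrap] - G
  genes
}

#' Map a nucleotide substitution to its amino-acid consequences
#'
#' Returns one row per gene covering the position (overlapping reading
#' frames mean a single base change can alter more than one protein).
#' Silent changes are included and flagged; changes creating a stop codon
#' carry `alt_aa = "*"`.
#'
#' @param genome A [genome_annotation()].
#' @param position 1-based genomic position.
#' @param ref Reference base at `position` (checked against the genome).
#' @param alt Alternative base, different from `ref`.
#' @return `data.frame` with columns `gene`, `residue`, `ref_aa`, `alt_aa`,
#'   `silent`, `codon_start` (genomic position of the codon's first base);
#'   zero rows for a non-coding position.
#' @examples
#' g <- genome_annotation("ATGGCATTAGCG",
#'                        data.frame(name = c("X", "Y"),
#'                                   start = c(1, 3), end = c(9, 11)))
#' map_substitution(g, 4, "G", "A")  # affects X (A2T) and Y (G1D)
#' @export
map_substitution <- function(genome, position, ref, alt) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > genome$length) {
    stop("position ", position, " outside genome [1, ", genome$length, "]")
  }
  ref <- toupper(ref); alt <- toupper(alt)
  have <- genome$chars[position]
  if (ref != have) {
    stop("reference mismatch at position ", position,
         ": expected ", have, ", got ", ref)
  }
  if (ref == alt) stop("ref and alt are identical at position ", position)
  out <- map_changes(genome, position, alt)
  out$event <- NULL
  rownames(out) <- NULL
  out
}

# vectorised core: amino-acid consequences of alt bases at positions, on an
# arbitrary background (defaults to the reference chars). One output row per
# (event, covering gene); `event` indexes the input vectors.
map_changes <- function(genome, positions, alts, background = genome$chars) {
  out <- vector("list", nrow(genome$genes))
  for (gi in seq_len(nrow(genome$genes))) {
    off <- genome$posmap[[gi]][positions]
    sel <- which(!is.na(off))
    if (!length(sel)) next
    off <- off[sel]
    gpos <- genome$gene_positions[[gi]]
    residue <- (off - 1L) %/% 3L + 1L
    within <- (off - 1L) %% 3L + 1L
    cstart <- (residue - 1L) * 3L
    p1 <- gpos[cstart + 1L]; p2 <- gpos[cstart + 2L]; p3 <- gpos[cstart + 3L]
    b1 <- background[p1]; b2 <- background[p2]; b3 <- background[p3]
    a1 <- b1; a2 <- b2; a3 <- b3
    a1[within == 1L] <- alts[sel][within == 1L]
    a2[within == 2L] <- alts[sel][within == 2L]
    a3[within == 3L] <- alts[sel][within == 3L]
    ref_aa <- unname(Biostrings::GENETIC_CODE[paste0(b1, b2, b3)])
    alt_aa <- unname(Biostrings::GENETIC_CODE[paste0(a1, a2, a3)])
    out[[gi]] <- data.frame(
      event = sel,
      gene = genome$genes$name[gi],
      residue = residue,
      ref_aa = ref_aa,
      alt_aa = alt_aa,
      silent = ref_aa == alt_aa,
      codon_start = p1,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(event = integer(), gene = character(),
                      residue = integer(), ref_aa = character(),
                      alt_aa = character(), silent = logical(),
                      codon_start = integer(), stringsAsFactors = FALSE)
  }
  out[order(out$event, match(out$gene, genome$genes$name)), , drop = FALSE]
}

#' Positions covered by out-of-frame gene overlaps
#'
#' A position enters the mask when at least two genes cover it in different
#' codon phases. Same-frame overlaps (e.g. an in-frame internal start such
#' as A* within A) are excluded: both genes read the same codons there, so a
#' change has the same silent/missense status in both.
#'
#' @param genome A [genome_annotation()].
#' @return Sorted integer vector of genomic positions (possibly empty).
#' @export
build_overlap_mask <- function(genome) {
  G <- genome$length
  nphase <- matrix(FALSE, nrow = G, ncol = 3L)
  for (gi in seq_len(nrow(genome$genes))) {
    off <- genome$posmap[[gi]]
    cov <- which(!is.na(off))
    phase <- (off[cov] - 1L) %% 3L + 1L
    nphase[cbind(cov, phase)] <- TRUE
  }
  which(rowSums(nphase) >= 2L)
}
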