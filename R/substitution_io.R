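#' Read per-lineage substitution tables
#'
#' Reads the compiled molecular changes of a set of evolved lineages, either
#' from a tab-separated table with header
#' `lineage position ref alt kind` (`kind` one of `substitution`,
#' `insertion`, `deletion`; the column may be omitted, defaulting to
#' `substitution`) or from a VCF in which each sample column is one lineage
#' and any non-reference genotype call is one event.
#'
#' Within a lineage the same mutation is counted only once: duplicated
#' `(lineage, position, alt, kind)` rows are collapsed (and reported via a
#' message). Different alt bases at the same position in one lineage are
#' different mutations and are all retained.
#'
#' @param source Path to the TSV or VCF file.
#' @param format `"tsv"` or `"vcf"`.
#' @param genome Optional [genome_annotation()]; when given, positions are
#'   checked against the genome length and substitution `ref` bases against
#'   the reference sequence.
#' @return A `lineage_set`: list with `records` (data.frame `lineage`,
#'   `position`, `ref`, `alt`, `kind`), `lineages` (character vector) and
#'   `founder` (NULL until set; see [subtract_founder()]).
#' @export
read_substitutions <- function(source, format = c("tsv", "vcf"), genome = NULL) {
  format <- match.arg(format)
  records <- if (format == "tsv") read_subs_tsv(source) else read_subs_vcf(source)
  lineage_set(records, genome = genome)
}

#' Assemble a lineage set from a substitution record table
#'
#' @param records `data.frame` with columns `lineage`, `position`, `ref`,
#'   `alt` and optionally `kind`.
#' @param founder Optional `data.frame` (`lineage`, `position`, `alt`) of
#'   founder-carried substitutions, see [subtract_founder()].
#' @inheritParams read_substitutions
#' @return A `lineage_set` (see [read_substitutions()]).
#' @export
lineage_set <- function(records, founder = NULL, genome = NULL) {
  if (!"kind" %in% names(records)) records$kind <- "substitution"
  records <- data.frame(
    lineage = as.character(records$lineage),
    position = as.integer(records$position),
    ref = toupper(as.character(records$ref)),
    alt = toupper(as.character(records$alt)),
    kind = as.character(records$kind),
    stringsAsFactors = FALSE
  )
  bad_kind <- !records$kind %in% c("substitution", "insertion", "deletion")
  if (any(bad_kind)) {
    stop("unknown event kind in row ", which(bad_kind)[1], ": ",
         records$kind[which(bad_kind)[1]])
  }
  is_sub <- records$kind == "substitution"
  bases <- c("A", "C", "G", "T")
  bad <- is_sub & (!records$ref %in% bases | !records$alt %in% bases)
  if (any(bad)) {
    stop("unknown base symbol in substitution row ", which(bad)[1], ": ",
         records$ref[which(bad)[1]], ">", records$alt[which(bad)[1]])
  }
  same <- is_sub & records$ref == records$alt
  if (any(same)) {
    stop("substitution with identical ref and alt in row ", which(same)[1])
  }
  if (!is.null(genome)) {
    out <- records$position < 1L | records$position > genome$length
    if (any(out)) {
      stop("position ", records$position[which(out)[1]],
           " outside genome [1, ", genome$length, "]")
    }
    mis <- is_sub & genome$chars[records$position] != records$ref
    if (any(mis)) {
      i <- which(mis)[1]
      stop("reference mismatch at position ", records$position[i],
           ": expected ", genome$chars[records$position[i]],
           ", got ", records$ref[i])
    }
  }
  key <- paste(records$lineage, records$position, records$alt, records$kind,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate record(s) within lineages removed")
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 lineages = unique(records$lineage),
                 founder = founder),
            class = "lineage_set")
}

#' @export
print.lineage_set <- function(x, ...) {
  cat("Lineage set:", nrow(x$records), "events across",
      length(x$lineages), "lineages\n")
  invisible(x)
}

read_subs_tsv <- function(path) {
  empty <- data.frame(lineage = character(), position = integer(),
                      ref = character(), alt = character(),
                      kind = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(lineage = character(), position = integer(),
                      ref = character(), alt = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  need <- c("lineage", "position", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("substitution TSV must have columns: ", paste(need, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos)) {
    stop("malformed position in line ", which(is.na(pos))[1] + 1L,
         " of ", path)
  }
  df$position <- pos
  df
}

read_subs_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no sample genotype columns")
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_field <- fix[, "ALT"]
  out <- list()
  for (s in colnames(gt)) {
    calls <- gt[, s]
    allele <- sub("[/|].*$", "", calls)          # haploid or first allele
    hit <- which(!is.na(allele) & allele != "." & allele != "0")
    for (i in hit) {
      alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
      a <- alts[as.integer(allele[i])]
      kind <- if (nchar(ref[i]) == 1L && nchar(a) == 1L) "substitution"
              else if (nchar(a) > nchar(ref[i])) "insertion" else "deletion"
      out[[length(out) + 1L]] <- data.frame(
        lineage = s, position = pos[i],
        ref = substr(ref[i], 1L, 1L),
        alt = if (kind == "substitution") a else a,
        kind = kind, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(lineage = character(), position = integer(),
                      ref = character(), alt = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write a lineage set back to the canonical TSV
#'
#' @param lineages A `lineage_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_substitutions <- function(lineages, path) {
  utils::write.table(lineages$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove founder-carried substitutions from lineages
#'
#' Some lineages are extensions of earlier experiments and already carry
#' substitutions relative to the common ancestor; those events are not new
#' and can be subtracted before tallying.
#'
#' @param lineages A `lineage_set`.
#' @param founder `data.frame` with columns `lineage`, `position`, `alt`
#'   listing founder-carried substitutions; defaults to the `founder`
#'   element of `lineages`. `NULL` is the identity.
#' @return A new `lineage_set` without the founder events. A founder entry
#'   naming an unknown lineage is an error; a founder substitution absent
#'   from that lineage's records produces a warning.
#' @export
subtract_founder <- function(lineages, founder = lineages$founder) {
  stopifnot(inherits(lineages, "lineage_set"))
  if (is.null(founder) || nrow(founder) == 0L) return(lineages)
  unknown <- !founder$lineage %in% lineages$lineages
  if (any(unknown)) {
    stop("founder genotype references unknown lineage: ",
         founder$lineage[which(unknown)[1]])
  }
  rec <- lineages$records
  rkey <- paste(rec$lineage, rec$position, rec$alt, sep = "\r")
  fkey <- paste(founder$lineage, founder$position, founder$alt, sep = "\r")
  missing <- !fkey %in% rkey
  if (any(missing)) {
    warning(sum(missing), " founder substitution(s) absent from lineage ",
            "records; those lineages left unchanged")
  }
  keep <- !rkey %in% fkey
  message(sum(!keep), " founder-carried event(s) removed")
  out <- lineages
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out$founder <- founder
  out
}

#' Tally substitution events per nucleotide site and per residue
#'
#' Aggregates events across lineages. At the nucleotide level every retained
#' event (substitutions and indels) counts once at its position. At the
#' residue level only substitutions are mapped (via the genome's reading
#' frames); an event covered by k genes increments k residue keys.
#'
#' Two counting modes:
#' * `site_level`: any event at a site/residue increments it — reversions
#'   and alternate substitutions at the same residue pool together.
#' * `identical_change`: events pool only when they are the same change —
#'   nucleotide keys are `(position, alt)`, residue keys
#'   `(gene, residue, ref_aa, alt_aa)`.
#'
#' @param lineages A `lineage_set`.
#' @param genome A [genome_annotation()].
#' @param mode `"site_level"` or `"identical_change"`.
#' @param map_residues Set `FALSE` to skip residue mapping (nucleotide
#'   tallies only), e.g. in large simulation loops.
#' @return A `site_tally`: list with `nucleotide` (data.frame `position`,
#'   [`alt`,] `count`), `residue` (data.frame `gene`, `residue`,
#'   [`ref_aa`, `alt_aa`,] `count`, `codon_start`), `mode`, `n_events`,
#'   `n_aa_events`.
#' @export
tally_sites <- function(lineages, genome,
                        mode = c("site_level", "identical_change"),
                        map_residues = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(lineages, "lineage_set"))
  rec <- lineages$records
  if (any(rec$position < 1L | rec$position > genome$length)) {
    stop("substitution position outside genome")
  }

  if (mode == "site_level") {
    nt <- as.data.frame(table(position = rec$position),
                        responseName = "count", stringsAsFactors = FALSE)
    nt$position <- as.integer(nt$position)
  } else {
    nt <- stats::aggregate(list(count = rec$position),
                           by = list(position = rec$position, alt = rec$alt),
                           FUN = length)
    nt <- nt[order(nt$position, nt$alt), , drop = FALSE]
  }

  res <- NULL
  n_aa <- 0L
  if (map_residues) {
    sub <- rec[rec$kind == "substitution", , drop = FALSE]
    ch <- map_changes(genome, sub$position, sub$alt)
    n_aa <- nrow(ch)
    if (mode == "site_level") {
      if (nrow(ch)) {
        res <- stats::aggregate(list(count = ch$gene),
                                by = list(gene = ch$gene, residue = ch$residue,
                                          codon_start = ch$codon_start),
                                FUN = length)
      } else {
        res <- data.frame(gene = character(), residue = integer(),
                          codon_start = integer(), count = integer())
      }
    } else {
      if (nrow(ch)) {
        res <- stats::aggregate(list(count = ch$gene),
                                by = list(gene = ch$gene, residue = ch$residue,
                                          ref_aa = ch$ref_aa, alt_aa = ch$alt_aa,
                                          codon_start = ch$codon_start),
                                FUN = length)
      } else {
        res <- data.frame(gene = character(), residue = integer(),
                          ref_aa = character(), alt_aa = character(),
                          codon_start = integer(), count = integer())
      }
    }
    res <- res[order(match(res$gene, genome$genes$name), res$residue), ,
               drop = FALSE]
    rownames(res) <- NULL
  }

  structure(list(nucleotide = nt, residue = res, mode = mode,
                 n_events = nrow(rec), n_aa_events = n_aa),
            class = "site_tally")
}

#' @export
print.site_tally <- function(x, ...) {
  cat("Site tally (", x$mode, "): ", x$n_events, " events, ",
      x$n_aa_events, " amino-acid substitution events\n", sep = "")
  invisible(x)
}

#' Write a residue-level tally to the canonical TSV
#'
#' Columns: `position gene residue ref_aa alt_aa count mode` (`ref_aa` and
#' `alt_aa` are `NA` in `site_level` mode, where alternate changes pool).
#'
#' @param tally A `site_tally` with residue counts.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_site_tally <- function(tally, path) {
  res <- tally$residue
  if (is.null(res)) stop("tally has no residue counts")
  out <- data.frame(position = res$codon_start, gene = res$gene,
                    residue = res$residue,
                    ref_aa = if ("ref_aa" %in% names(res)) res$ref_aa else NA,
                    alt_aa = if ("alt_aa" %in% names(res)) res$alt_aa else NA,
                    count = res$count, mode = tally$mode)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tally events at known regulatory nucleotide positions
#'
#' Counts substitutions and indels falling at a user-supplied list of
#' positions with regulatory roles (promoter, terminator, ribosome-binding
#' sites, ...). The phiX174 literature identifies 133 such positions; the
#' list itself is an input.
#'
#' @param lineages A `lineage_set`.
#' @param regulatory_positions Integer vector of genomic positions (nonempty).
#' @return List with `events` (all events at listed positions),
#'   `positions_hit` (distinct listed positions with at least one event) and
#'   `fraction` (`positions_hit / length(regulatory_positions)`).
#' @export
tally_regulatory <- function(lineages, regulatory_positions) {
  stopifnot(inherits(lineages, "lineage_set"))
  regulatory_positions <- unique(as.integer(regulatory_positions))
  if (!length(regulatory_positions)) stop("regulatory position set is empty")
  rec <- lineages$records
  at <- rec$position %in% regulatory_positions
  list(events = sum(at),
       positions_hit = length(unique(rec$position[at])),
       fraction = length(unique(rec$position[at])) / length(regulatory_positions))
}
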