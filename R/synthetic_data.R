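#' Configuration for the synthetic data generator
#'
#' Defaults emulate the statistical structure of the compiled phiX174
#' experimental-evolution dataset: a 5386-nt circular genome carrying 11
#' forward-strand genes (with out-of-frame overlaps and one origin-wrapping
#' gene), 58 lineages contributing on average 667/58 substitution events
#' each, 25% of sites invariant, a minority of strongly repeated hotspot
#' sites (13 hotspots, hit-rate weight 150: each then collects ~17 events in
#' expectation, in the range of the most-hit residues), and a wild panel of
#' 40 isolates whose background differences are silent-biased 3.8:1 and
#' which shares 11/13 of the hotspots.
#'
#' @param genome_length Genome size G in nt.
#' @param n_genes Number of genes.
#' @param coding_density Approximate fraction of the genome covered by genes
#'   before overlaps.
#' @param n_overlap_pairs Number of adjacent gene pairs overlapping
#'   out-of-frame.
#' @param overlap_nt Nominal overlap length in nt (adjusted by 1 where
#'   needed to force a frame difference).
#' @param wrap_gene Place the last gene across the origin.
#' @param n_lineages Number of evolved lineages.
#' @param events_per_lineage Mean substitution events per lineage (Poisson).
#' @param total_events If non-NULL, fixes the total number of events
#'   (distributed uniformly over lineages) instead of Poisson sampling.
#' @param n_hotspots Number of planted hotspot sites.
#' @param hotspot_weight Relative hit rate of a hotspot site vs a background
#'   variable site.
#' @param hotspot_fixed_alt Give each hotspot one designated alt base (so
#'   repeated hits are the identical change, as in parallel evolution).
#' @param hotspot_coding_only Restrict hotspots to coding positions.
#' @param invariant_fraction Fraction f of sites excluded from placement.
#' @param n_regulatory Number of positions in the synthetic regulatory list.
#' @param n_isolates Wild panel size.
#' @param n_wild_differences Background differences in the wild panel.
#' @param silent_missense_intensity Silent:missense intensity ratio of wild
#'   background differences.
#' @param wild_shared_fraction Fraction of hotspot sites also made variable
#'   in the wild panel.
#' @param seed Base RNG seed; the genome, lineage, wild-panel and regulatory
#'   generators use `seed`, `seed + 1`, `seed + 2`, `seed + 3`.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(genome_length = 5386,
                             n_genes = 11,
                             coding_density = 0.88,
                             n_overlap_pairs = 2,
                             overlap_nt = 31,
                             wrap_gene = TRUE,
                             n_lineages = 58,
                             events_per_lineage = 667 / 58,
                             total_events = NULL,
                             n_hotspots = 13,
                             hotspot_weight = 150,
                             hotspot_fixed_alt = TRUE,
                             hotspot_coding_only = TRUE,
                             invariant_fraction = 0.25,
                             n_regulatory = 133,
                             n_isolates = 40,
                             n_wild_differences = 1000,
                             silent_missense_intensity = 3.8,
                             wild_shared_fraction = 11 / 13,
                             seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(genome_length > 0, n_genes >= 1, coding_density > 0,
              coding_density < 1, n_overlap_pairs >= 0, overlap_nt >= 4,
              n_lineages >= 0, events_per_lineage >= 0, n_hotspots >= 0,
              hotspot_weight >= 1, invariant_fraction >= 0,
              invariant_fraction < 1, n_regulatory >= 0, n_isolates >= 0,
              n_wild_differences >= 0, silent_missense_intensity > 0,
              wild_shared_fraction >= 0, wild_shared_fraction <= 1)
  })
  structure(cfg, class = "synthetic_config")
}

# scoped RNG: restore the caller's random stream afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random annotated circular genome
#'
#' Lays out `n_genes` forward-strand genes (equal codon counts filling about
#' `coding_density` of the circle), overlaps the first `n_overlap_pairs`
#' adjacent pairs out-of-frame, optionally wraps the last gene across the
#' origin, fills the sequence with random bases and then resamples bases
#' inside internal stop codons until every gene translates cleanly.
#'
#' @param config A [synthetic_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return A validated [genome_annotation()].
#' @export
generate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    G <- config$genome_length
    n <- config$n_genes
    codons <- max(2, floor(G * config$coding_density / (3 * n)))
    len <- as.integer(3 * codons)
    gap <- 8L
    ov <- min(as.integer(config$overlap_nt), len - 3L)
    tail_nt <- min(30L, max(3L, G %/% 12L))
    first_start <- if (config$wrap_gene) tail_nt + 10L else 1L

    start <- integer(n); end <- integer(n)
    cursor <- first_start
    ov_heads <- if (config$n_overlap_pairs > 0)
      seq_len(min(config$n_overlap_pairs, n - 1L)) * 2L - 1L else integer(0)
    ov_heads <- ov_heads[ov_heads < n - as.integer(config$wrap_gene)]
    for (i in seq_len(n)) {
      if (i > 1L && (i - 1L) %in% ov_heads) {
        s <- end[i - 1L] - ov + 1L
        if ((s - start[i - 1L]) %% 3L == 0L) s <- s + 1L  # force frame shift
      } else {
        s <- cursor
      }
      start[i] <- s
      end[i] <- s + len - 1L
      cursor <- end[i] + 1L + gap
    }
    if (config$wrap_gene && n >= 2L) {
      start[n] <- G - len + tail_nt + 1L
      end[n] <- tail_nt  # wraps: start..G, 1..tail_nt
      if (start[n] <= end[n - 1L] + gap || tail_nt >= first_start) {
        stop("infeasible gene layout for these config values")
      }
    } else if (end[n] > G) {
      stop("infeasible gene layout for these config values")
    }

    genes <- data.frame(name = paste0("g", seq_len(n)), start = start,
                        end = end, essential = TRUE,
                        stringsAsFactors = FALSE)
    bases <- c("A", "C", "G", "T")
    chars <- sample(bases, G, replace = TRUE)

    # resample bases inside internal stop codons until all genes are clean
    spans <- lapply(seq_len(n), function(i) circular_span(start[i], end[i], G))
    for (iter in seq_len(500L)) {
      dirty <- FALSE
      for (i in seq_len(n)) {
        pos <- spans[[i]]
        aa <- translate_codons(chars[pos])
        stops <- which(aa[-length(aa)] == "*")
        if (length(stops)) {
          dirty <- TRUE
          for (ci in stops) {
            p <- pos[(ci - 1L) * 3L + sample.int(3L, 1L)]
            chars[p] <- sample(setdiff(bases, chars[p]), 1L)
          }
        }
      }
      if (!dirty) break
      if (iter == 500L) stop("could not remove internal stop codons")
    }
    genome_annotation(paste(chars, collapse = ""), genes)
  })
}

#' Generate per-lineage substitution events with planted hotspots
#'
#' Chooses a fixed invariant site set (`f * G` positions), plants
#' `n_hotspots` hotspot sites among the remaining variable sites, and drops
#' each lineage's events onto the variable sites multinomially, hotspots
#' upweighted by `hotspot_weight`. Within a lineage the same change is kept
#' only once. Every event carries a truth label (`hotspot` or `background`).
#'
#' @param genome A [genome_annotation()].
#' @param config A [synthetic_config()].
#' @param seed RNG seed (default `config$seed + 1`).
#' @return List with `lineages` (a `lineage_set`) and `truth` (list:
#'   `hotspots` data.frame with `position`, `ref`, `alt`, `wild_shared`;
#'   `invariant_sites`; `events`, the generated event table with `source`
#'   labels — under `total_events` this is the counted (deduplicated) table,
#'   otherwise the raw draws before per-lineage deduplication).
#' @export
generate_lineages <- function(genome, config, seed = config$seed + 1) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    G <- genome$length
    bases <- c("A", "C", "G", "T")
    n_inv <- round(config$invariant_fraction * G)
    invariant <- sort(sample.int(G, n_inv))
    variable <- setdiff(seq_len(G), invariant)

    coding <- which(Reduce(`|`, lapply(genome$posmap, function(m) !is.na(m))))
    cand <- if (config$hotspot_coding_only) intersect(variable, coding)
            else variable
    n_hot <- min(config$n_hotspots, length(cand))
    hot <- sort(sample(cand, n_hot))
    hot_alt <- vapply(hot, function(p) {
      if (config$hotspot_fixed_alt)
        sample(setdiff(bases, genome$chars[p]), 1L) else NA_character_
    }, character(1))
    shared <- rep(FALSE, n_hot)
    n_shared <- round(config$wild_shared_fraction * n_hot)
    if (n_shared > 0) shared[sample.int(n_hot, n_shared)] <- TRUE

    weights <- rep(1, length(variable))
    weights[match(hot, variable)] <- config$hotspot_weight

    draw_events <- function(k, lineage_of = NULL) {
      if (is.null(lineage_of)) {
        lineage_of <- paste0("L", sample.int(config$n_lineages, k,
                                             replace = TRUE))
      }
      pos <- sample(variable, k, replace = TRUE, prob = weights)
      hot_idx <- match(pos, hot)
      alt <- character(k)
      for (i in seq_len(k)) {
        if (!is.na(hot_idx[i]) && !is.na(hot_alt[hot_idx[i]])) {
          alt[i] <- hot_alt[hot_idx[i]]
        } else {
          alt[i] <- sample(setdiff(bases, genome$chars[pos[i]]), 1L)
        }
      }
      data.frame(lineage = lineage_of, position = pos,
                 ref = genome$chars[pos], alt = alt, kind = "substitution",
                 source = ifelse(is.na(hot_idx), "background", "hotspot"),
                 stringsAsFactors = FALSE)
    }
    empty <- data.frame(lineage = character(), position = integer(),
                        ref = character(), alt = character(),
                        kind = character(), source = character(),
                        stringsAsFactors = FALSE)

    if (config$n_lineages == 0L) {
      events <- empty
    } else if (!is.null(config$total_events)) {
      # total_events is the number of *counted* changes: within a lineage a
      # repeated identical change is counted once, so top up until the
      # deduplicated total reaches the target
      S <- as.integer(config$total_events)
      events <- empty[, ]
      for (iter in seq_len(100L)) {
        need <- S - nrow(events)
        if (need <= 0L) break
        events <- rbind(events, draw_events(need))
        events <- events[!duplicated(paste(events$lineage, events$position,
                                           events$alt)), , drop = FALSE]
      }
      rownames(events) <- NULL
    } else {
      per <- stats::rpois(config$n_lineages, config$events_per_lineage)
      events <- if (sum(per) > 0L) {
        draw_events(sum(per),
                    lineage_of = paste0("L", rep(seq_len(config$n_lineages),
                                                 per)))
      } else empty
    }

    ls <- suppressMessages(
      lineage_set(events[, c("lineage", "position", "ref", "alt", "kind")])
    )
    truth <- list(
      hotspots = data.frame(position = hot, ref = genome$chars[hot],
                            alt = hot_alt, wild_shared = shared,
                            stringsAsFactors = FALSE),
      invariant_sites = invariant,
      events = events
    )
    list(lineages = ls, truth = truth)
  })
}

#' Generate a wild isolate panel with a purifying-selection signature
#'
#' Starts every isolate from the reference sequence and introduces
#' `n_wild_differences` background differences at single-frame coding
#' positions (outside out-of-frame overlaps, hotspots and the invariant
#' set), each difference silent with probability
#' `r / (1 + r)` where `r = silent_missense_intensity`. Hotspot sites
#' flagged `wild_shared` in the truth are additionally made variable. Each
#' difference is carried by a minority subset of isolates, so the panel
#' consensus stays the reference.
#'
#' @param genome A [genome_annotation()].
#' @param config A [synthetic_config()].
#' @param truth Truth list from [generate_lineages()] (use `truth = NULL`
#'   for a panel with background differences only).
#' @param seed RNG seed (default `config$seed + 2`).
#' @return A [wild_panel()].
#' @export
generate_wild_panel <- function(genome, config, truth = NULL,
                                seed = config$seed + 2) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    n_iso <- config$n_isolates
    G <- genome$length
    mat <- matrix(rep(genome$chars, each = n_iso), nrow = n_iso,
                  dimnames = list(paste0("isolate", seq_len(n_iso)), NULL))
    if (n_iso < 2L || (config$n_wild_differences == 0L && is.null(truth))) {
      return(wild_panel(apply(mat, 1, paste, collapse = "")))
    }

    mask <- build_overlap_mask(genome)
    coding <- which(Reduce(`|`, lapply(genome$posmap, function(m) !is.na(m))))
    cand <- setdiff(coding, mask)
    if (!is.null(truth)) {
      cand <- setdiff(cand, truth$hotspots$position)
      cand <- setdiff(cand, truth$invariant_sites)
    }

    # classify every candidate (position, alt) as silent or missense
    bases <- c("A", "C", "G", "T")
    pos3 <- rep(cand, each = 3L)
    alt3 <- unlist(lapply(cand, function(p) setdiff(bases, genome$chars[p])))
    ch <- map_changes(genome, pos3, alt3)
    silent_by_event <- tapply(ch$silent, ch$event, all)
    ev <- as.integer(names(silent_by_event))
    pools <- data.frame(position = pos3[ev], alt = alt3[ev],
                        silent = as.logical(silent_by_event),
                        stringsAsFactors = FALSE)

    r <- config$silent_missense_intensity
    n_diff <- min(config$n_wild_differences, nrow(pools))
    n_silent <- stats::rbinom(1L, n_diff, r / (1 + r))
    sil_pool <- which(pools$silent)
    mis_pool <- which(!pools$silent)
    n_silent <- min(n_silent, length(sil_pool))
    n_mis <- min(n_diff - n_silent, length(mis_pool))
    take <- c(sample(sil_pool, n_silent), sample(mis_pool, n_mis))
    diffs <- pools[take, c("position", "alt"), drop = FALSE]

    if (!is.null(truth) && any(truth$hotspots$wild_shared)) {
      hs <- truth$hotspots[truth$hotspots$wild_shared, , drop = FALSE]
      alt <- ifelse(is.na(hs$alt),
                    vapply(hs$position, function(p)
                      sample(setdiff(bases, genome$chars[p]), 1L),
                      character(1)),
                    hs$alt)
      diffs <- rbind(diffs, data.frame(position = hs$position, alt = alt,
                                       stringsAsFactors = FALSE))
    }

    # minority carriers per difference; per column, carriers are drawn from
    # a disjoint budget of at most floor((n_iso - 1) / 2) isolates so no
    # difference is overwritten and the consensus stays the reference
    kmax <- max(1L, (n_iso - 1L) %/% 2L)
    free <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(diffs))) {
      p <- diffs$position[i]
      key <- as.character(p)
      avail <- if (is.null(free[[key]])) sample.int(n_iso, kmax)
               else free[[key]]
      k <- min(sample.int(kmax, 1L), length(avail))
      if (k < 1L) next
      carriers <- if (length(avail) == 1L) avail else sample(avail, k)
      mat[carriers, p] <- diffs$alt[i]
      free[[key]] <- setdiff(avail, carriers)
    }
    wild_panel(apply(mat, 1, paste, collapse = ""))
  })
}

#' Generate a synthetic regulatory-position list
#'
#' @param genome A [genome_annotation()].
#' @param config A [synthetic_config()].
#' @param seed RNG seed (default `config$seed + 3`).
#' @return Sorted integer vector of `n_regulatory` distinct positions.
#' @export
generate_regulatory <- function(genome, config, seed = config$seed + 3) {
  with_seed(seed, sort(sample.int(genome$length,
                                  min(config$n_regulatory, genome$length))))
}

#' Write a deterministic synthetic test bundle
#'
#' Generates a genome, lineage substitutions, wild panel and regulatory list
#' from `config` and writes them in the same formats the pipeline consumes
#' (FASTA, gene TSV, substitution TSV, aligned FASTA, one-column TSV), plus
#' the hotspot truth table.
#'
#' @param dir Output directory (created if needed).
#' @param config A [synthetic_config()].
#' @return Named list of file paths, invisibly.
#' @export
write_synthetic_bundle <- function(dir, config = synthetic_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(config)
  sim <- generate_lineages(genome, config)
  panel <- generate_wild_panel(genome, config, sim$truth)
  reg <- generate_regulatory(genome, config)

  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    genes = file.path(dir, "genes.tsv"),
    substitutions = file.path(dir, "substitutions.tsv"),
    wild = file.path(dir, "wild_panel.fasta"),
    regulatory = file.path(dir, "regulatory.tsv"),
    truth = file.path(dir, "truth_hotspots.tsv")
  )
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  names(seqs) <- "synthetic_genome"
  Biostrings::writeXStringSet(seqs, paths$genome)
  utils::write.table(genome$genes, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_substitutions(sim$lineages, paths$substitutions)
  pseqs <- Biostrings::DNAStringSet(apply(panel$mat, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(pseqs, paths$wild)
  utils::write.table(data.frame(position = reg), paths$regulatory,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$hotspots, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
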