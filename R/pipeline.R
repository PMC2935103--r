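#' Run the full parallel-evolution analysis pipeline
#'
#' Orchestrates the stages end to end: load genome and annotation, read and
#' optionally founder-subtract the substitution table, tally sites in both
#' counting modes, evaluate the coincidence null model, classify adaptive
#' sites, compute per-gene enrichment, tally regulatory positions, and — when
#' a wild panel is supplied — derive natural variation, test the overlap of
#' experimental and wild variable residues, and estimate the silent:missense
#' ratio. Writes a bundle of machine-readable TSVs, a Fig.-style bar chart
#' of repeatedly hit residues, a human-readable summary (every number in it
#' comes from one of the TSVs) and a run log.
#'
#' @param config Either a path to a YAML file or a named list. Recognised
#'   entries: paths `genome_fasta`, `annotation`, `substitutions`
#'   (+ `substitutions_format`, default `"tsv"`), optional `founder`,
#'   `wild_fasta`, `regulatory`; parameters `invariant_fraction` (default
#'   0.25), `threshold` (default 3), `mode` (default `"site_level"`),
#'   `universe_N` (default: residue count of the annotation), `exclude_overlaps`
#'   (default TRUE), `max_n` (default 8), `seed` (default 1); and `out_dir`.
#' @return Invisibly, a list with all stage results and `files` (paths
#'   written). Any stage failure aborts with the stage name; files already
#'   written for the bundle are removed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(substitutions_format = "tsv", invariant_fraction = 0.25,
                   threshold = 3, mode = "site_level", universe_N = NULL,
                   exclude_overlaps = TRUE, max_n = 8, seed = 1)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("genome_fasta", "annotation", "substitutions", "out_dir")) {
    if (is.null(config[[nm]])) stop("pipeline config is missing '", nm, "'")
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  set.seed(config$seed)
  log_lines <- c(
    paste0("parallevol ", as.character(utils::packageVersion("parallevol"))),
    R.version.string,
    paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", config$seed),
    paste0("parameters: f=", config$invariant_fraction,
           " threshold=", config$threshold, " mode=", config$mode,
           " exclude_overlaps=", config$exclude_overlaps))

  genome <- stage("load_genome",
                  load_genome(config$genome_fasta, config$annotation))
  lineages <- stage("read_substitutions",
                    read_substitutions(config$substitutions,
                                       config$substitutions_format,
                                       genome = genome))
  if (!is.null(config$founder)) {
    founder <- stage("read_founder",
                     utils::read.delim(config$founder,
                                       stringsAsFactors = FALSE))
    lineages <- stage("subtract_founder",
                      suppressMessages(subtract_founder(lineages, founder)))
  }

  tally <- stage("tally_sites", tally_sites(lineages, genome, "site_level"))
  tally_id <- stage("tally_sites",
                    tally_sites(lineages, genome, "identical_change"))
  emit(tally$nucleotide, "tally_nucleotide_site_level.tsv")
  emit(tally_id$nucleotide, "tally_nucleotide_identical_change.tsv")
  write_site_tally(tally, file.path(out_dir, "tally_residue_site_level.tsv"))
  written <- c(written, file.path(out_dir, "tally_residue_site_level.tsv"))

  null_tab <- stage("nullmodel", {
    params <- null_model_params(S = tally$n_events, G = genome$length,
                                f = config$invariant_fraction)
    n <- seq_len(config$max_n)
    obs <- vapply(n, function(k) sum(tally$nucleotide$count == k), numeric(1))
    data.frame(n = n,
               expected = expected_coincident_sites(params, n),
               fraction_of_substitutions =
                 fraction_substitutions_in_coincidences(params, n),
               observed_sites_exactly_n = obs)
  })
  emit(null_tab, "null_model.tsv")

  wild <- NULL
  if (!is.null(config$wild_fasta)) {
    wild <- stage("wild_panel", {
      panel <- read_wild_panel(config$wild_fasta)
      wv <- derive_wild_variation(panel, genome)
      N <- if (!is.null(config$universe_N)) config$universe_N
           else sum(gene_residue_counts(genome))
      exp_res <- unique(tally$residue[, c("gene", "residue")])
      a <- nrow(exp_res)
      b <- nrow(wv$variable_residues)
      common <- sum(paste(exp_res$gene, exp_res$residue) %in%
                      paste(wv$variable_residues$gene,
                            wv$variable_residues$residue))
      ov <- overlap_test(N, a, b, common)
      ratio <- silent_missense_ratio(panel, genome,
                                     exclude_overlaps = config$exclude_overlaps)
      list(panel = panel, variation = wv, overlap = ov, ratio = ratio)
    })
  }

  adaptive <- stage("adaptive", {
    classify_adaptive_sites(tally, threshold = config$threshold,
                            wild = if (!is.null(wild))
                              wild$variation$variable_residues)
  })
  emit(adaptive$sites, "adaptive_sites.tsv")

  enrich <- stage("enrich", gene_enrichment(tally, genome))
  emit(enrich, "gene_enrichment.tsv")

  regulatory <- NULL
  if (!is.null(config$regulatory)) {
    regulatory <- stage("regulatory", {
      reg <- utils::read.delim(config$regulatory, stringsAsFactors = FALSE)
      tally_regulatory(lineages, reg[[1]])
    })
    emit(data.frame(events = regulatory$events,
                    positions_hit = regulatory$positions_hit,
                    fraction = regulatory$fraction), "regulatory.tsv")
  }

  if (!is.null(wild)) {
    emit(data.frame(N = wild$overlap$N, a = wild$overlap$a, b = wild$overlap$b,
                    expected = wild$overlap$expected,
                    observed = wild$overlap$observed,
                    p_value = wild$overlap$p_value), "wild_overlap.tsv")
    emit(data.frame(silent = wild$ratio$silent, missense = wild$ratio$missense,
                    ratio = wild$ratio$ratio,
                    overlaps_excluded = wild$ratio$exclusion),
         "silent_missense.tsv")
  }

  if (nrow(adaptive$sites)) {
    fig <- file.path(out_dir, "adaptive_sites.png")
    stage("figure", ggplot2::ggsave(fig, plot_adaptive_sites(adaptive),
                                    width = 8, height = 4, dpi = 150))
    written <- c(written, fig)
  }

  summary_lines <- c(
    "Parallel evolution analysis summary",
    "===================================",
    sprintf("Genome: %d nt, %d genes [genes: see gene_enrichment.tsv]",
            genome$length, nrow(genome$genes)),
    sprintf("Events: %d across %d lineages at %d nucleotide sites [tally_nucleotide_site_level.tsv]",
            tally$n_events, length(lineages$lineages),
            nrow(tally$nucleotide)),
    sprintf("Amino-acid substitution events: %d at %d residues [tally_residue_site_level.tsv]",
            tally$n_aa_events, nrow(tally$residue)),
    sprintf("Null model (f = %.2f, L = %.1f): expected %.1f two-fold and %.1f three-fold coincident sites [null_model.tsv]",
            config$invariant_fraction,
            effective_sites(genome$length, config$invariant_fraction),
            null_tab$expected[2], null_tab$expected[3]),
    sprintf("Adaptive sites (>= %d events): %d residues covering %d events (%.0f%%) [adaptive_sites.tsv]",
            adaptive$threshold, nrow(adaptive$sites),
            adaptive$substitutions_covered,
            100 * adaptive$fraction_covered),
    if (!is.null(regulatory))
      sprintf("Regulatory positions: %d events at %d positions (%.1f%%) [regulatory.tsv]",
              regulatory$events, regulatory$positions_hit,
              100 * regulatory$fraction)
    else "Regulatory positions: not computed (no list supplied)",
    if (!is.null(wild))
      c(sprintf("Wild overlap: observed %d vs expected %.1f of universe %d (hypergeometric p = %.3g, extension) [wild_overlap.tsv]",
                wild$overlap$observed, wild$overlap$expected, wild$overlap$N,
                wild$overlap$p_value),
        sprintf("Silent:missense among wild differences: %d:%d = %.2f [silent_missense.tsv]",
                wild$ratio$silent, wild$ratio$missense, wild$ratio$ratio))
    else "Wild panel comparison: not computed (no panel supplied)"
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  written <- c(written, file.path(out_dir, c("summary.txt", "run_log.txt")))

  invisible(list(genome = genome, lineages = lineages, tally = tally,
                 tally_identical = tally_id, null_model = null_tab,
                 adaptive = adaptive, enrichment = enrich,
                 regulatory = regulatory, wild = wild, files = written))
}

#' Bar chart of repeatedly hit residues
#'
#' One bar per qualifying residue (ordered along the genome), height equal
#' to the number of amino-acid substitution events; when wild-variability
#' flags are present, bars are shaded by whether the residue also varies
#' among wild isolates.
#'
#' @param report An `adaptive_site_report` from [classify_adaptive_sites()]
#'   at residue level.
#' @return A ggplot object.
#' @export
plot_adaptive_sites <- function(report) {
  stopifnot(inherits(report, "adaptive_site_report"),
            report$level == "residue")
  df <- report$sites
  df <- df[order(df$codon_start), , drop = FALSE]
  df$label <- factor(paste0(df$gene, df$residue),
                     levels = paste0(df$gene, df$residue))
  if (is.null(df$wild_variable)) df$wild_variable <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$count,
                                   fill = .data$wild_variable)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "grey60", `FALSE` = "black"),
      na.value = "grey30",
      name = "varies in wild panel") +
    ggplot2::labs(x = "residue (genome order)",
                  y = "amino-acid substitution events") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
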