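test_that("effective variable sites discount the invariant fraction", {
  expect_equal(effective_sites(5386, 0.25), 4039.5)
  expect_equal(effective_sites(5386, 0), 5386)
  expect_equal(effective_sites(100, 0.5), 50)
  expect_error(effective_sites(100, 1), "\\[0, 1\\)")
  expect_error(effective_sites(100, -0.1), "\\[0, 1\\)")
})

test_that("coincidence expectation matches closed form and small oracles", {
  p <- null_model_params(S = 667, G = 5386, f = 0.25)
  expect_equal(expected_coincident_sites(p, 1), 667)
  expect_equal(expected_coincident_sites(p, 2), choose(667, 2) / 4039.5)

  # n beyond S is impossible
  tiny <- null_model_params(S = 3, G = 10, f = 0)
  expect_equal(expected_coincident_sites(tiny, 5), 0)

  # Monte-Carlo oracle at S = 2, L = 4: drop 2 events into 4 boxes, count
  # pairs sharing a box; closed form says 0.25
  small <- null_model_params(S = 2, G = 4, f = 0)
  expect_equal(expected_coincident_sites(small, 2), 0.25)
  set.seed(7)
  reps <- 20000
  coinc <- replicate(reps, {
    b <- sample.int(4, 2, replace = TRUE)
    sum(choose(tabulate(b, 4), 2))
  })
  se <- stats::sd(coinc) / sqrt(reps)
  expect_lt(abs(mean(coinc) - 0.25), 3 * se)
})

test_that("occupancy method gives the Poisson at-least-n site count", {
  p <- null_model_params(S = 667, G = 5386, f = 0.25)
  lam <- p$lambda
  expect_equal(expected_coincident_sites(p, 2, method = "occupancy"),
               p$L * (1 - exp(-lam) * (1 + lam)))
  # sensitivity of the two functional forms at the compiled-data scale
  expect_equal(round(expected_coincident_sites(p, 2, method = "occupancy")), 49)
  expect_equal(round(expected_coincident_sites(p, 2)), 55)
})

test_that("occupancy tracks the coincidence expectation in the sparse regime", {
  # for lambda = S/L <= 0.2 the expected number of sites with >= n events
  # stays within 15% of the n-fold coincidence expectation E_n (n = 2, 3);
  # E_n itself is a coincidence count, not exact occupancy
  set.seed(33)
  S <- 50; L <- 250; reps <- 4000
  occ2 <- numeric(reps); occ3 <- numeric(reps)
  for (r in seq_len(reps)) {
    tb <- tabulate(sample.int(L, S, replace = TRUE), L)
    occ2[r] <- sum(tb >= 2)
    occ3[r] <- sum(tb >= 3)
  }
  p <- null_model_params(S = S, G = L, f = 0)
  expect_lte(p$lambda, 0.2)
  expect_lt(abs(mean(occ2) - expected_coincident_sites(p, 2)) /
              expected_coincident_sites(p, 2), 0.15)
  expect_lt(abs(mean(occ3) - expected_coincident_sites(p, 3)) /
              expected_coincident_sites(p, 3), 0.15)
})

test_that("E_n decreases in n (lambda < 1) and increases in S", {
  p <- null_model_params(S = 300, G = 2000, f = 0.2)
  en <- expected_coincident_sites(p, 1:8)
  expect_true(all(diff(en) < 0))
  es <- vapply(c(50, 100, 200, 400), function(S)
    expected_coincident_sites(null_model_params(S, 2000, 0.2), 3), numeric(1))
  expect_true(all(diff(es) > 0))
})

test_that("fraction of substitutions at n-fold coincidences", {
  p <- null_model_params(S = 667, G = 5386, f = 0.25)
  expect_equal(fraction_substitutions_in_coincidences(p, 1), 1)
  expect_equal(fraction_substitutions_in_coincidences(p, 2),
               2 * choose(667, 2) / 4039.5 / 667)
  small <- null_model_params(S = 2, G = 4, f = 0)
  expect_equal(fraction_substitutions_in_coincidences(small, 2), 0.25)
  expect_error(
    fraction_substitutions_in_coincidences(null_model_params(0, 10, 0), 2),
    "S is zero")
})

fake_residue_tally <- function(counts) {
  # counts: named vector like c(F101 = 5, ...); genome order = codon_start
  genes <- sub("[0-9]+$", "", names(counts))
  residues <- as.integer(sub("^[A-Za-z]+", "", names(counts)))
  structure(list(
    nucleotide = data.frame(position = seq_along(counts),
                            count = as.integer(counts)),
    residue = data.frame(gene = genes, residue = residues,
                         codon_start = seq_along(counts) * 10L,
                         count = as.integer(counts),
                         stringsAsFactors = FALSE),
    mode = "site_level", n_events = sum(counts), n_aa_events = sum(counts)),
    class = "site_tally")
}

test_that("adaptive-site classification thresholds, sorts and flags", {
  tal <- fake_residue_tally(c(F101 = 5, F102 = 3, G66 = 5, H7 = 2))
  rep3 <- classify_adaptive_sites(tal, threshold = 3)
  expect_identical(nrow(rep3$sites), 3L)
  expect_false("H7" %in% paste0(rep3$sites$gene, rep3$sites$residue))
  # count descending, ties by genome order: F101 before G66
  expect_identical(paste0(rep3$sites$gene, rep3$sites$residue),
                   c("F101", "G66", "F102"))
  expect_identical(rep3$substitutions_covered, 13L)
  expect_equal(rep3$fraction_covered, 13 / 15)

  rep1 <- classify_adaptive_sites(tal, threshold = 1)
  expect_identical(nrow(rep1$sites), 4L)
  expect_equal(rep1$fraction_covered, 1.0)

  wild <- data.frame(gene = c("F", "Q"), residue = c(101L, 5L))
  repw <- classify_adaptive_sites(tal, threshold = 3, wild = wild)
  expect_identical(repw$sites$wild_variable,
                   c(TRUE, FALSE, FALSE))

  repn <- classify_adaptive_sites(tal, threshold = 4, level = "nucleotide")
  expect_identical(repn$sites$position, c(1L, 3L))
})

test_that("gene enrichment: expectation is coding share times total", {
  tal <- fake_residue_tally(c(H10 = 100, F3 = 200))
  enr <- gene_enrichment(tal, genome = NULL, total_aa_subs = 508,
                         fractions = c(H = 0.16, F = 0.84))
  expect_equal(enr$expected[enr$gene == "H"], 81.28)
  expect_equal(sum(enr$expected), 508)
  expect_error(gene_enrichment(tal, NULL, 508, fractions = c(H = 0.2, F = 0.3)),
               "sum to")

  # degenerate single-gene universe: observed = expected = total, p = 1
  g1 <- toy_genome_x()
  one <- tally_sites(lineage_set(data.frame(
    lineage = c("a", "b"), position = c(4, 7), ref = c("G", "T"),
    alt = c("A", "C"))), g1)
  enr1 <- gene_enrichment(one, g1)
  expect_equal(enr1$coding_fraction, 1)
  expect_equal(enr1$observed, enr1$expected)
  expect_equal(enr1$p_value, 1)
})

test_that("uniform placement keeps per-gene counts inside binomial bounds", {
  cfg <- synthetic_config(n_hotspots = 0, total_events = 667, seed = 5)
  g <- generate_genome(cfg)
  sim <- generate_lineages(g, cfg)
  tal <- tally_sites(sim$lineages, g)
  enr <- gene_enrichment(tal, g)
  tot <- sum(enr$observed)
  lo <- stats::qbinom(0.0005, tot, enr$coding_fraction)
  hi <- stats::qbinom(0.9995, tot, enr$coding_fraction)
  expect_true(all(enr$observed >= lo & enr$observed <= hi))
})
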