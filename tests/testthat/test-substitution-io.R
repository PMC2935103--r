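test_that("reading a TSV deduplicates identical changes within a lineage", {
  path <- write_subs_fixture(data.frame(
    lineage = c("l1", "l1", "l1", "l2"),
    position = c(4, 4, 4, 4),
    ref = "G", alt = c("A", "A", "C", "A"),
    kind = "substitution"))
  ls <- suppressMessages(read_substitutions(path, "tsv"))
  # the duplicate (l1, 4, A) collapses; (l1, 4, C) is a different mutation
  expect_identical(nrow(ls$records), 3L)
  expect_identical(ls$lineages, c("l1", "l2"))
})

test_that("an empty substitution file yields an empty lineage set", {
  path <- tempfile(fileext = ".tsv")
  file.create(path)
  ls <- read_substitutions(path, "tsv")
  expect_identical(nrow(ls$records), 0L)
  expect_length(ls$lineages, 0)
})

test_that("malformed rows and unknown bases are rejected with context", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("lineage\tposition\tref\talt", "l1\tfoo\tG\tA"), path)
  expect_error(read_substitutions(path, "tsv"), "malformed position in line 2")

  path2 <- write_subs_fixture(data.frame(lineage = "l1", position = 4,
                                         ref = "G", alt = "Z"))
  expect_error(read_substitutions(path2, "tsv"), "unknown base symbol")

  # positions and ref bases are checked against a supplied genome
  g <- toy_genome_xy()
  path3 <- write_subs_fixture(data.frame(lineage = "l1", position = 4,
                                         ref = "C", alt = "A"))
  expect_error(read_substitutions(path3, "tsv", genome = g),
               "reference mismatch at position 4")
})

test_that("VCF samples become lineages with their non-reference calls", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "toy\t4\t.\tG\tA\t.\tPASS\t.\tGT\t1\t0",
    "toy\t5\t.\tC\tT,G\t.\tPASS\t.\tGT\t0\t2",
    "toy\t7\t.\tT\tTA\t.\tPASS\t.\tGT\t.\t1"), vcf)
  ls <- read_substitutions(vcf, "vcf")
  # hand-parsed expectation: s1 carries 4 G>A; s2 carries 5 C>G (allele 2)
  # and an insertion at 7
  expect_identical(sort(ls$lineages), c("s1", "s2"))
  s1 <- ls$records[ls$records$lineage == "s1", ]
  expect_identical(s1$position, 4L)
  expect_identical(s1$alt, "A")
  s2 <- ls$records[ls$records$lineage == "s2", ]
  expect_identical(sort(s2$position), c(5L, 7L))
  expect_identical(s2$alt[s2$position == 5], "G")
  expect_identical(s2$kind[s2$position == 7], "insertion")
})

test_that("founder-carried substitutions are subtracted per lineage", {
  ls <- lineage_set(data.frame(
    lineage = c("l1", "l1", "l2"),
    position = c(1001, 2002, 1001),
    ref = "A", alt = c("G", "T", "G")))
  founder <- data.frame(lineage = "l1", position = 1001, alt = "G")
  out <- suppressMessages(subtract_founder(ls, founder))
  expect_identical(out$records$position, c(2002L, 1001L))
  expect_identical(out$records$lineage, c("l1", "l2"))

  # empty founder map is the identity
  expect_identical(subtract_founder(ls, NULL)$records, ls$records)

  # founder substitution absent from records: warning, lineage unchanged
  absent <- data.frame(lineage = "l2", position = 3003, alt = "C")
  expect_warning(out2 <- suppressMessages(subtract_founder(ls, absent)),
                 "absent from lineage")
  expect_identical(out2$records, ls$records)

  unknown <- data.frame(lineage = "l9", position = 1001, alt = "G")
  expect_error(suppressMessages(subtract_founder(ls, unknown)),
               "unknown lineage")
})

test_that("tally modes pool events as defined", {
  g <- toy_genome_xy()
  # three lineages with the same change at position 4
  same <- lineage_set(data.frame(lineage = c("a", "b", "c"), position = 4,
                                 ref = "G", alt = "A"))
  t1 <- tally_sites(same, g, "site_level")
  t2 <- tally_sites(same, g, "identical_change")
  expect_identical(t1$nucleotide$count[t1$nucleotide$position == 4], 3L)
  expect_identical(t2$nucleotide$count[t2$nucleotide$position == 4], 3L)

  # two identical changes plus one alternate at the same site
  mix <- lineage_set(data.frame(lineage = c("a", "b", "c"), position = 5,
                                ref = "C", alt = c("T", "T", "A")))
  m1 <- tally_sites(mix, g, "site_level")
  expect_identical(m1$nucleotide$count[m1$nucleotide$position == 5], 3L)
  m2 <- tally_sites(mix, g, "identical_change")
  expect_identical(m2$nucleotide$count[m2$nucleotide$alt == "T"], 2L)
  expect_identical(m2$nucleotide$count[m2$nucleotide$alt == "A"], 1L)

  # one event inside a two-gene overlap increments two residue keys
  expect_identical(sum(tally_sites(lineage_set(data.frame(
    lineage = "a", position = 4, ref = "G", alt = "A")), g)$residue$count), 2L)
})

test_that("nucleotide tallies conserve events and identical <= site level", {
  g <- generate_genome(synthetic_config(genome_length = 600, n_genes = 4,
                                        seed = 3))
  for (seed in 1:5) {
    sim <- generate_lineages(g, synthetic_config(genome_length = 600,
                                                 n_genes = 4,
                                                 n_lineages = 10,
                                                 events_per_lineage = 6,
                                                 n_hotspots = 3,
                                                 hotspot_weight = 20,
                                                 seed = seed))
    ts <- tally_sites(sim$lineages, g, "site_level")
    ti <- tally_sites(sim$lineages, g, "identical_change")
    expect_identical(sum(ts$nucleotide$count), nrow(sim$lineages$records))
    expect_identical(sum(ti$nucleotide$count), nrow(sim$lineages$records))
    # mode dominance per (position, alt)
    site_at <- ts$nucleotide$count[match(ti$nucleotide$position,
                                         ts$nucleotide$position)]
    expect_true(all(ti$nucleotide$count <= site_at))
  }
})

test_that("a round-trip through the TSV writer preserves tallies", {
  g <- generate_genome(synthetic_config(genome_length = 600, n_genes = 4,
                                        seed = 3))
  sim <- generate_lineages(g, synthetic_config(genome_length = 600,
                                               n_genes = 4, n_lineages = 8,
                                               events_per_lineage = 5,
                                               seed = 11))
  path <- tempfile(fileext = ".tsv")
  write_substitutions(sim$lineages, path)
  back <- read_substitutions(path, "tsv", genome = g)
  t_orig <- tally_sites(sim$lineages, g)
  t_back <- tally_sites(back, g)
  expect_identical(t_back$nucleotide, t_orig$nucleotide)
  expect_identical(t_back$residue, t_orig$residue)
})

test_that("regulatory tallies count events and distinct positions hit", {
  reg <- 1:133
  # events at 17 distinct listed positions (one of them hit twice), plus an
  # indel at a listed position and one event off the list
  df <- data.frame(lineage = paste0("l", 1:20),
                   position = c(1:16, 16, 17, 500, 17),
                   ref = "A", alt = "G", kind = "substitution")
  df$kind[18] <- "deletion"
  ls <- lineage_set(df)
  out <- tally_regulatory(ls, reg)
  expect_identical(out$positions_hit, 17L)
  expect_identical(out$events, 19L)
  expect_equal(out$fraction, 17 / 133)

  none <- lineage_set(df[0, ])
  expect_identical(tally_regulatory(none, reg),
                   list(events = 0L, positions_hit = 0L, fraction = 0))

  five <- lineage_set(data.frame(lineage = paste0("l", 1:5), position = 42,
                                 ref = "A", alt = c("G", "C", "T", "G", "C"),
                                 kind = c("substitution", "substitution",
                                          "substitution", "insertion",
                                          "deletion")))
  out5 <- tally_regulatory(five, reg)
  expect_identical(out5$events, 5L)
  expect_identical(out5$positions_hit, 1L)
})
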