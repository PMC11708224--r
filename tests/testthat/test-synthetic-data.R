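test_that("generators are pure functions of the seed", {
  spec <- genome_spec(n_chromosomes = 2, chrom_length_range = c(60e3, 80e3),
                      gene_count_per_chrom = 15, repeat_count_per_chrom = 15,
                      seed = 123)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  d1 <- withr::local_tempdir()
  write_genome(g1, file.path(d1, "a.fa"), file.path(d1, "a.gff3"))
  write_genome(g2, file.path(d1, "b.fa"), file.path(d1, "b.gff3"))
  expect_identical(readLines(file.path(d1, "a.fa")),
                   readLines(file.path(d1, "b.fa")))
  expect_identical(readLines(file.path(d1, "a.gff3")),
                   readLines(file.path(d1, "b.gff3")))
  # annotation draws unaffected by skipping sequence generation
  g3 <- generate_genome(spec, with_sequence = FALSE)
  expect_identical(g3$genes, g1$genes)
})

test_that("zero center bias gives uniform gene midpoints (KS test)", {
  g <- generate_genome(genome_spec(n_chromosomes = 23,
                                   gene_count_per_chrom = 87,
                                   gene_center_bias = 0, seed = 31),
                       with_sequence = FALSE)
  rel <- (g$genes$start + g$genes$end) / 2 / g$lengths[g$genes$seqid]
  ks <- suppressWarnings(stats::ks.test(rel, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("center and terminal biases shape the expected density profile", {
  g <- generate_genome(genome_spec(seed = 17, gene_center_bias = 3,
                                   repeat_terminal_bias = 4),
                       with_sequence = FALSE)
  third <- function(f) {
    rel <- (f$start + f$end) / 2 / g$lengths[f$seqid]
    c(outer1 = sum(rel < 1 / 3), mid = sum(rel >= 1 / 3 & rel < 2 / 3),
      outer2 = sum(rel >= 2 / 3))
  }
  tg <- third(g$genes)
  expect_gt(tg[["mid"]], tg[["outer1"]])
  expect_gt(tg[["mid"]], tg[["outer2"]])
  tr <- third(g$repeats)
  expect_lt(tr[["mid"]], tr[["outer1"]])
  expect_lt(tr[["mid"]], tr[["outer2"]])
})

test_that("rearrangement plans conserve content and log truth", {
  g <- small_genome(seed = 3)
  empty <- apply_rearrangement_plan(g, rearrangement_plan())
  expect_identical(empty$genome$genes, g$genes)
  expect_identical(empty$genome$lengths, g$lengths)

  chroms <- names(g$lengths)
  plan <- rearrangement_plan(
    fusions = data.frame(chrom_a = chroms[1], chrom_b = chroms[2]))
  res <- apply_rearrangement_plan(g, plan, fusion_gap = 500)
  g2 <- res$genome
  expect_equal(g2$lengths[[chroms[1]]],
               g$lengths[[chroms[1]]] + g$lengths[[chroms[2]]] + 500)
  # non-gap length and gene count conserved
  expect_equal(sum(g2$lengths) - 500, sum(g$lengths))
  expect_equal(nrow(g2$genes), nrow(g$genes))
  expect_equal(res$truth$kind, "fusion")
  expect_equal(res$truth$new_name, chroms[1])
})

test_that("a planted inversion reverses the relative gene order", {
  g <- small_genome(seed = 21)
  chrom <- names(g$lengths)[1]
  iv <- inversion_interval(g, chrom, first_gene_idx = 5, n_genes = 12)
  plan <- rearrangement_plan(inversions = data.frame(
    chrom = chrom, start = iv[1], end = iv[2]))
  res <- apply_rearrangement_plan(g, plan)
  ids_before <- gff_attr(g$genes[g$genes$seqid == chrom &
                                   g$genes$start >= iv[1] &
                                   g$genes$end <= iv[2], ], "ID")
  after <- res$genome$genes
  after <- after[after$seqid == chrom & after$start >= iv[1] &
                   after$end <= iv[2], ]
  after <- after[order(after$start), ]
  expect_equal(gff_attr(after, "ID"), rev(ids_before))
  expect_equal(res$truth$n_genes, 12)
})

test_that("overlapping planned edits are rejected", {
  g <- small_genome(seed = 3)
  chrom <- names(g$lengths)[1]
  plan <- rearrangement_plan(inversions = data.frame(
    chrom = chrom, start = c(1000, 1500), end = c(2000, 2500)))
  expect_error(apply_rearrangement_plan(g, plan), "overlapping edits")
})

test_that("repeat copies honour the divergence profile degenerately and reproducibly", {
  prof0 <- repeat_age_profile(family_classes = "DNA", copies_per_family = 20,
                              divergence_weights = 1)
  cp <- generate_repeat_copies(100, prof0, seed = 4)
  # weight wholly at the zero-divergence bin: exact consensus copies
  expect_true(all(cp$aligned_copy == cp$aligned_consensus))

  prof <- repeat_age_profile(copies_per_family = 30)
  c1 <- generate_repeat_copies(200, prof, seed = 8)
  c2 <- generate_repeat_copies(200, prof, seed = 8)
  expect_identical(c1, c2)
})

test_that("read simulation plants chimeras at the requested rate", {
  g <- generate_genome(genome_spec(n_chromosomes = 2,
                                   chrom_length_range = c(4e5, 5e5),
                                   gene_count_per_chrom = 10,
                                   repeat_count_per_chrom = 10, seed = 6))
  sim0 <- simulate_long_reads(g, read_sim_spec(n_reads = 50,
                                               chimera_rate = 0, seed = 2))
  expect_true(all(sim0$truth$label == "clean"))

  spec <- read_sim_spec(n_reads = 2000, chimera_rate = 0.05, seed = 3)
  sim <- simulate_long_reads(g, spec)
  phat <- mean(sim$truth$label == "chimeric")
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(phat - 0.05), ci + 1e-9)

  sim2 <- simulate_long_reads(g, spec)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)
})

test_that("idealized overlaps leave chimeric junctions uncovered", {
  g <- generate_genome(genome_spec(n_chromosomes = 2,
                                   chrom_length_range = c(4e5, 5e5),
                                   gene_count_per_chrom = 10,
                                   repeat_count_per_chrom = 10, seed = 6))
  sim <- simulate_long_reads(g, read_sim_spec(n_reads = 600,
                                              chimera_rate = 0.1, seed = 9))
  ov <- make_overlaps(sim, seed = 10)
  chim <- sim$truth[sim$truth$label == "chimeric", ]
  for (i in seq_len(min(10, nrow(chim)))) {
    r <- chim$read[i]
    j <- chim$junction[i]
    rows <- ov[ov$qname == r | ov$tname == r, , drop = FALSE]
    cov <- coverage_profile(chim$length[i], rows, read = r)
    expect_equal(cov[j], 0)
  }
})

test_that("assembly-map export round-trips through the reader", {
  f <- withr::local_tempfile()
  lens <- c(c1 = 1000, c2 = 500)
  m <- export_assembly_map(lens, list(c("c1", "-c2")), f)
  back <- read_assembly_map(f)
  expect_identical(back$scaffolds, list(c(1L, -2L)))
  expect_identical(back$entries$name, c("c1", "c2"))

  expect_error(export_assembly_map(lens, list("c9"), f), "unknown contig c9")

  f2 <- withr::local_tempfile()
  export_assembly_map(lens, list(), f2)
  expect_equal(length(read_assembly_map(f2)$scaffolds), 0)
})
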