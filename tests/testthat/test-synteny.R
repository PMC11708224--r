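hit <- function(q, s, bits, ident = 95) {
  data.frame(query_gene = q, subject_gene = s, bitscore = bits,
             identity_pct = ident, stringsAsFactors = FALSE)
}

test_that("reciprocal best hits keep mutual bests and break ties deterministically", {
  ab <- rbind(hit("a1", "b1", 300), hit("a1", "b2", 200),
              hit("a2", "b2", 250))
  ba <- rbind(hit("b1", "a1", 290), hit("b2", "a9", 260),
              hit("b2", "a2", 150))
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(rbh$gene_a, "a1")      # a2 dropped: b2's best is a9
  expect_equal(rbh$gene_b, "b1")

  # equal bitscores: higher identity wins
  ab2 <- rbind(hit("a1", "b1", 300, ident = 96), hit("a1", "b2", 300, ident = 97))
  ba2 <- rbind(hit("b2", "a1", 300), hit("b1", "a1", 300))
  expect_equal(reciprocal_best_hits(ab2, ba2)$gene_b, "b2")
  # equal bitscore and identity: lexicographically smaller subject
  ab3 <- rbind(hit("a1", "b9", 300), hit("a1", "b2", 300))
  ba3 <- rbind(hit("b2", "a1", 300), hit("b9", "a1", 300))
  expect_equal(reciprocal_best_hits(ab3, ba3)$gene_b, "b2")
})

test_that("RBH output is a bijection on random hit tables", {
  set.seed(5)
  for (rep in 1:20) {
    qa <- paste0("a", 1:30)
    qb <- paste0("b", 1:30)
    ab <- data.frame(query_gene = sample(qa, 120, TRUE),
                     subject_gene = sample(qb, 120, TRUE),
                     bitscore = round(runif(120, 50, 500)),
                     identity_pct = round(runif(120, 70, 100), 1))
    ba <- data.frame(query_gene = sample(qb, 120, TRUE),
                     subject_gene = sample(qa, 120, TRUE),
                     bitscore = round(runif(120, 50, 500)),
                     identity_pct = round(runif(120, 70, 100), 1))
    rbh <- reciprocal_best_hits(ab, ba)
    expect_equal(anyDuplicated(rbh$gene_a), 0)
    expect_equal(anyDuplicated(rbh$gene_b), 0)
  }
})

colinear_pairs <- function(n, chrom_b = "B1", reverse_b = FALSE) {
  pos <- seq(10000, by = 10000, length.out = n)
  data.frame(gene_a = paste0("g", seq_len(n)), gene_b = paste0("g", seq_len(n)),
             chrom_a = "A1", pos_a = pos, chrom_b = chrom_b,
             pos_b = if (reverse_b) rev(pos) else pos,
             bitscore = NA_real_, stringsAsFactors = FALSE)
}

test_that("cluster building finds colinear runs with orientation signs", {
  cl <- build_synteny_clusters(colinear_pairs(10))
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n, 10)
  expect_equal(cl$clusters$orientation, 1L)

  cl2 <- build_synteny_clusters(colinear_pairs(10, reverse_b = TRUE))
  expect_equal(cl2$clusters$orientation, -1L)

  cl3 <- build_synteny_clusters(colinear_pairs(4))
  expect_equal(nrow(cl3$clusters), 0)
})

test_that("cluster membership is invariant under coordinate scaling", {
  p <- rbind(colinear_pairs(12), {
    q <- colinear_pairs(8, chrom_b = "B2")
    q$chrom_a <- "A2"; q$gene_a <- paste0("h", 1:8); q$gene_b <- q$gene_a
    q
  })
  cl <- build_synteny_clusters(p)
  p2 <- p
  p2$pos_b <- p2$pos_b * 7.5
  cl2 <- build_synteny_clusters(p2)
  expect_equal(cl$clusters$n, cl2$clusters$n)
  expect_equal(cl$clusters$chrom_b, cl2$clusters$chrom_b)
  expect_equal(lapply(cl$members, `[[`, "gene_a"),
               lapply(cl2$members, `[[`, "gene_a"))
})

test_that("orthology naming distinguishes interleaved from disjoint dual signals", {
  # 80/20 with the minority interleaved: single assignment
  n <- 50
  pos <- seq(1e4, by = 1e4, length.out = n)
  b <- rep("B1", n)
  b[seq(5, n, by = 5)] <- "B2"          # every 5th gene to B2, interleaved
  p <- data.frame(gene_a = paste0("g", 1:n), gene_b = paste0("g", 1:n),
                  chrom_a = "A1", pos_a = pos, chrom_b = b,
                  pos_b = pos, bitscore = NA_real_)
  cl <- build_synteny_clusters(p, params = cluster_params(max_gap = 10))
  nm <- assign_chromosome_orthology(cl)
  expect_equal(nm$status, "assigned")
  expect_equal(nm$ortholog, "B1")

  # 55/45 in disjoint halves: dual orthology (fusion candidate)
  b2 <- c(rep("B1", 28), rep("B2", 22))
  p2 <- data.frame(gene_a = paste0("g", 1:n), gene_b = paste0("g", 1:n),
                   chrom_a = "A1", pos_a = pos, chrom_b = b2,
                   pos_b = c(pos[1:28], pos[29:50] - pos[28]),
                   bitscore = NA_real_)
  cl2 <- build_synteny_clusters(p2)
  nm2 <- assign_chromosome_orthology(cl2)
  expect_equal(nm2$status, "dual")
  expect_equal(nm2$ortholog, "B1")
  expect_equal(nm2$secondary, "B2")

  # chromosome without clustered genes reports unassigned
  nm3 <- assign_chromosome_orthology(cl2, chroms_a = c("A1", "A7"))
  expect_equal(nm3$status[nm3$chrom_a == "A7"], "unassigned")
})

test_that("planted rearrangements are called and colinear genomes are silent", {
  g <- generate_genome(genome_spec(seed = 19), with_sequence = FALSE)
  chroms <- names(g$lengths)
  iv <- inversion_interval(g, chroms[5], first_gene_idx = 25, n_genes = 30)
  plan <- rearrangement_plan(
    fusions = data.frame(chrom_a = chroms[8], chrom_b = chroms[11]),
    inversions = data.frame(chrom = chroms[5], start = iv[1], end = iv[2]))
  res <- apply_rearrangement_plan(g, plan)
  pairs <- ortholog_pairs_from_annotations(res$genome$genes, g$genes)
  cl <- build_synteny_clusters(pairs, genes_a = res$genome$genes)
  naming <- assign_chromosome_orthology(cl)
  calls <- detect_rearrangements(cl, naming, res$genome$lengths)

  fus <- calls[calls$kind == "fusion", ]
  expect_equal(nrow(fus), 1)
  expect_setequal(c(fus$chrom_b, fus$chrom_b2), chroms[c(8, 11)])
  inv <- calls[calls$kind == "inversion", ]
  expect_equal(nrow(inv), 1)
  expect_equal(inv$chrom_a, chroms[5])
  expect_gte(inv$start_a, iv[1] - 1e4)
  expect_lte(inv$end_a, iv[2] + 1e4)

  # identical genomes: no calls at all
  p0 <- ortholog_pairs_from_annotations(g$genes, g$genes)
  cl0 <- build_synteny_clusters(p0, genes_a = g$genes)
  calls0 <- detect_rearrangements(cl0, assign_chromosome_orthology(cl0),
                                  g$lengths)
  expect_equal(nrow(calls0), 0)
})

test_that("reciprocal terminal swaps pair into one end-swap call", {
  g <- generate_genome(genome_spec(seed = 23, gene_center_bias = 0,
                                   repeat_terminal_bias = 0),
                       with_sequence = FALSE)
  chroms <- names(g$lengths)
  s <- terminal_swap_length(g, chroms[1], chroms[3], 15)
  plan <- rearrangement_plan(terminal_translocations = data.frame(
    chrom_x = chroms[1], end_x = "end", chrom_y = chroms[3], end_y = "end",
    swap_length = s))
  res <- apply_rearrangement_plan(g, plan)
  pairs <- ortholog_pairs_from_annotations(res$genome$genes, g$genes)
  cl <- build_synteny_clusters(pairs, genes_a = res$genome$genes)
  naming <- assign_chromosome_orthology(cl)
  calls <- detect_rearrangements(cl, naming, res$genome$lengths)
  tr <- calls[calls$kind == "translocation", ]
  expect_equal(nrow(tr), 1)
  expect_match(tr$note, "end swap")
  expect_setequal(c(tr$chrom_a, tr$chrom_b), chroms[c(1, 3)])
})

test_that("rearrangement detection is deterministic", {
  g <- generate_genome(genome_spec(seed = 29), with_sequence = FALSE)
  plan <- rearrangement_plan(fusions = data.frame(
    chrom_a = names(g$lengths)[2], chrom_b = names(g$lengths)[9]))
  res <- apply_rearrangement_plan(g, plan)
  pairs <- ortholog_pairs_from_annotations(res$genome$genes, g$genes)
  run <- function() {
    cl <- build_synteny_clusters(pairs, genes_a = res$genome$genes)
    detect_rearrangements(cl, assign_chromosome_orthology(cl),
                          res$genome$lengths)
  }
  expect_identical(run(), run())
})
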