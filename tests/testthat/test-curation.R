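test_that("assembly map converts to AGP with correct coordinates", {
  agp <- toy_agp()
  r <- agp$rows
  expect_equal(r$object_beg, c(1, 1001, 1501, 1))
  expect_equal(r$object_end, c(1000, 1500, 2000, 300))
  expect_equal(r$component_type, c("W", "N", "W", "W"))
  expect_equal(r$orientation, c("+", NA, "-", "+"))
  expect_equal(r$gap_type[2], "scaffold")
  expect_equal(r$linkage_evidence[2], "proximity_ligation")
  # singleton becomes its own single-row object
  expect_equal(sum(r$object == "scaffold_2"), 1)

  m0 <- structure(list(entries = data.frame(name = c("a", "b"), id = 1:2,
                                            length = c(100, 200)),
                       scaffolds = list(c(1L, 2L))),
                  class = "assembly_map")
  nogap <- assembly_map_to_agp(m0, gap_length = 0)
  expect_equal(nogap$rows$component_type, c("W", "W"))
  expect_equal(nogap$rows$object_beg, c(1, 101))

  m0$entries$length[1] <- 0
  expect_error(assembly_map_to_agp(m0), "zero-length entry")
})

test_that("FASTA rebuild honours orientation and gaps", {
  fa <- build_fasta_from_agp(toy_agp(), toy_contigs)
  # c2 is all C; reverse-complemented it contributes G
  expect_equal(fa$sequence[fa$id == "scaffold_1"],
               paste0(strrep("A", 1000), strrep("N", 500), strrep("G", 500)))
  expect_equal(fa$sequence[fa$id == "scaffold_2"], strrep("G", 300))
  expect_equal(nchar(fa$sequence), agp_objects(toy_agp())$length)

  expect_error(build_fasta_from_agp(toy_agp(), toy_contigs[-1]),
               "missing contig c1")
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  expect_identical(revcomp(revcomp(s)), s)
})

test_that("empty edit list is the identity", {
  agp <- toy_agp()
  res <- apply_edits(agp, list())
  expect_identical(res$agp$rows, agp$rows)
  lift <- res$liftover
  expect_true(all(!lift$flipped))
  expect_identical(lift$old_start, lift$new_start)
  expect_identical(lift$old_object, lift$new_object)
})

test_that("reorient flips one row and marks the liftover interval", {
  agp <- toy_agp()
  res <- apply_edits(agp, list(list(op = "reorient", component = "c2")))
  r <- res$agp$rows
  expect_equal(r$orientation[r$component_id == "c2" & !is.na(r$component_id)], "+")
  expect_identical(r$object_beg, agp$rows$object_beg)
  lift <- res$liftover
  expect_equal(lift$flipped, c(FALSE, TRUE, FALSE))
  # sequence-level equivalence: rebuild after the edit equals editing the
  # rebuilt sequence directly
  before <- build_fasta_from_agp(agp, toy_contigs)
  after <- build_fasta_from_agp(res$agp, toy_contigs)
  manual <- paste0(substr(before$sequence[1], 1, 1500),
                   revcomp(substr(before$sequence[1], 1501, 2000)))
  expect_equal(after$sequence[1], manual)
})

test_that("move re-tiles both objects and shifts downstream coordinates", {
  agp <- toy_agp()
  res <- apply_edits(agp, list(list(op = "move", component = "c2",
                                    to = "scaffold_2", at = 1)))
  r <- res$agp$rows
  s1 <- r[r$object == "scaffold_1", ]
  expect_equal(nrow(s1), 1)          # gap collapsed with the move
  expect_equal(s1$object_end, 1000)
  s2 <- r[r$object == "scaffold_2", ]
  expect_equal(s2$component_id[!is.na(s2$component_id)], c("c2", "c3"))
  expect_equal(s2$object_end[nrow(s2)], 500 + 500 + 300)
  expect_error(apply_edits(agp, list(list(op = "move", component = "cX",
                                          to = "scaffold_2"))),
               "edit 1 \\(move\\): no such component cX")
})

test_that("split and join preserve content and honour naming convention", {
  agp <- toy_agp()
  res <- apply_edits(agp, list(
    list(op = "split", object = "scaffold_1", after = "c1",
         names = c("chrA", "chrB")),
    list(op = "join", objects = c("chrB", "scaffold_2"))))
  r <- res$agp$rows
  expect_setequal(unique(r$object), c("chrA", "chrB"))
  # joined object keeps the first (lower) name
  joined <- r[r$object == "chrB", ]
  expect_equal(joined$component_id[!is.na(joined$component_id)], c("c2", "c3"))
  # contig content multiset unchanged
  expect_setequal(r$component_id[r$component_type == "W"], c("c1", "c2", "c3"))
  # component spans unchanged
  w_old <- agp$rows[agp$rows$component_type == "W", ]
  w_new <- r[r$component_type == "W", ]
  m <- match(w_old$component_id, w_new$component_id)
  expect_equal(w_old$component_end - w_old$component_beg,
               w_new$component_end[m] - w_new$component_beg[m])
})

test_that("sequence content is conserved by edit scripts (hash check)", {
  agp <- toy_agp()
  edits <- list(list(op = "reorient", component = "c1"),
                list(op = "move", component = "c3", to = "scaffold_1", at = 2),
                list(op = "split", object = "scaffold_1", after = "c3",
                     names = c("p1", "p2")))
  res <- apply_edits(agp, edits)
  canon <- function(s) pmin(s, revcomp(s))   # identity up to revcomp
  extract <- function(a) {
    w <- a$rows[a$rows$component_type == "W", ]
    fa <- build_fasta_from_agp(a, toy_contigs)
    seqs <- stats::setNames(fa$sequence, fa$id)
    sort(canon(vapply(seq_len(nrow(w)), function(i)
      substr(seqs[[w$object[i]]], w$object_beg[i], w$object_end[i]),
      character(1))))
  }
  expect_identical(extract(agp), extract(res$agp))
})

test_that("liftover translates, flips and round-trips", {
  # unedited object: unchanged
  agp <- toy_agp()
  id_res <- apply_edits(agp, list(list(op = "reorient", component = "c2")))
  f <- feat("scaffold_2", 10, 20)
  expect_equal(liftover_features(f, id_res$liftover)$start, 10)

  # worked flip: interval 1501-2000 mapped flipped to 1-500
  map <- data.frame(old_object = "o", old_start = 1501, old_end = 2000,
                    new_object = "n", new_start = 1, new_end = 500,
                    flipped = TRUE, stringsAsFactors = FALSE)
  g <- feat("o", 1501, 1600, strand = "+")
  lifted <- liftover_features(g, map)
  expect_equal(lifted$start, 401)
  expect_equal(lifted$end, 500)
  expect_equal(lifted$strand, "-")
  expect_equal(lifted$seqid, "n")

  # round trip through the inverse map on many random features
  agp2 <- toy_agp()
  res <- apply_edits(agp2, list(
    list(op = "reorient", component = "c1"),
    list(op = "move", component = "c3", to = "scaffold_1", at = 1)))
  set.seed(11)
  w <- agp2$rows[agp2$rows$component_type == "W", ]
  k <- sample(nrow(w), 300, replace = TRUE)
  s <- floor(runif(300, w$object_beg[k], w$object_end[k] - 5))
  e <- pmin(s + sample(1:5, 300, replace = TRUE), w$object_end[k])
  feats <- do.call(rbind, lapply(seq_len(300), function(i)
    feat(w$object[k[i]], s[i], e[i], strand = sample(c("+", "-"), 1),
         id = paste0("f", i))))
  lifted <- liftover_features(feats, res$liftover)
  expect_equal(lifted$end - lifted$start, feats$end - feats$start)
  back <- liftover_features(lifted, invert_liftover(res$liftover))
  expect_equal(back$start, feats$start)
  expect_equal(back$end, feats$end)
  expect_equal(back$strand, feats$strand)
  expect_equal(nrow(back), nrow(feats))
})

test_that("liftover rejects boundary-spanning and gap features by default", {
  agp <- toy_agp()
  res <- apply_edits(agp, list(list(op = "reorient", component = "c2")))
  spanning <- feat("scaffold_1", 990, 1010)     # crosses c1 | gap boundary
  expect_error(liftover_features(spanning, res$liftover),
               "spans a mapped-interval boundary|unmapped gap")
  ongap <- feat("scaffold_1", 1100, 1200)
  expect_error(liftover_features(ongap, res$liftover), "unmapped gap")
  parts <- liftover_features(spanning, res$liftover, split_features = TRUE)
  expect_equal(nrow(parts), 1)   # only the mapped part survives as a piece
  expect_equal(gff_attr(parts, "ID"), "f1")
})

test_that("correcting a planted misassembly removes the rearrangement call", {
  g <- generate_genome(genome_spec(n_chromosomes = 1,
                                   chrom_length_range = c(250e3, 260e3),
                                   gene_count_per_chrom = 60,
                                   gene_center_bias = 0,
                                   repeat_count_per_chrom = 20, seed = 77))
  chrom <- names(g$lengths)
  truth_genes <- g$genes
  # contig c2 spans a 20-gene central block; cut clear of all features
  iv <- inversion_interval(g, chrom, first_gene_idx = 21, n_genes = 20)
  L <- g$lengths[[chrom]]
  rows <- data.frame(
    object = chrom, object_beg = c(1, iv[1], iv[2] + 1),
    object_end = c(iv[1] - 1, iv[2], L), part_number = 1:3,
    component_type = "W", component_id = c("c1", "c2", "c3"),
    component_beg = 1, component_end = c(iv[1] - 1, iv[2] - iv[1] + 1,
                                         L - iv[2]),
    orientation = "+", gap_length = NA_real_, gap_type = NA_character_,
    linkage = NA_character_, linkage_evidence = NA_character_,
    stringsAsFactors = FALSE)
  truth_agp <- new_agp(rows)

  # mis-assembled version: c2 scaffolded in the wrong orientation
  mis <- apply_edits(truth_agp, list(list(op = "reorient", component = "c2")))
  mis_genes <- liftover_features(truth_genes, mis$liftover)
  pairs <- ortholog_pairs_from_annotations(mis_genes, truth_genes)
  cl <- build_synteny_clusters(pairs, genes_a = mis_genes)
  naming <- assign_chromosome_orthology(cl)
  calls_before <- detect_rearrangements(cl, naming, g$lengths)
  expect_gte(nrow(calls_before), 1)

  # curation: flip c2 back, lift the annotation, re-run the synteny engine
  fix <- apply_edits(mis$agp, list(list(op = "reorient", component = "c2")))
  fixed_genes <- liftover_features(mis_genes, fix$liftover)
  pairs2 <- ortholog_pairs_from_annotations(fixed_genes, truth_genes)
  cl2 <- build_synteny_clusters(pairs2, genes_a = fixed_genes)
  calls_after <- detect_rearrangements(cl2, assign_chromosome_orthology(cl2),
                                       g$lengths)
  expect_lt(nrow(calls_after), nrow(calls_before))
  expect_equal(nrow(calls_after), 0)
})
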