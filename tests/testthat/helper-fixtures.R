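# Small shared fixtures, built in code at test time.

small_genome <- function(seed = 5, with_sequence = FALSE, ...) {
  generate_genome(genome_spec(n_chromosomes = 4,
                              chrom_length_range = c(150e3, 200e3),
                              gene_count_per_chrom = 30,
                              repeat_count_per_chrom = 40,
                              seed = seed, ...),
                  with_sequence = with_sequence)
}

# one scaffold of three oriented contigs with 500 bp gaps
toy_agp <- function() {
  m <- structure(list(
    entries = data.frame(name = c("c1", "c2", "c3"), id = 1:3,
                         length = c(1000, 500, 300),
                         stringsAsFactors = FALSE),
    scaffolds = list(c(1L, -2L), 3L)), class = "assembly_map")
  assembly_map_to_agp(m, gap_length = 500)
}

toy_contigs <- c(c1 = strrep("A", 1000), c2 = strrep("C", 500),
                 c3 = strrep("G", 300))

# minimal feature row
feat <- function(seqid, start, end, strand = "+", id = "f1",
                 type = "gene") {
  data.frame(seqid = seqid, source = "test", type = type, start = start,
             end = end, score = ".", strand = strand, phase = ".",
             attributes = paste0("ID=", id), stringsAsFactors = FALSE)
}

empty_ov <- function() {
  data.frame(qname = character(), qlen = numeric(), qstart = numeric(),
             qend = numeric(), strand = character(), tname = character(),
             tlen = numeric(), tstart = numeric(), tend = numeric(),
             nmatch = numeric(), alen = numeric(), mapq = numeric(),
             stringsAsFactors = FALSE)
}

# overlap row in the internal (1-based inclusive) convention
ovl <- function(qname, qlen, qstart, qend, tname, tlen, tstart, tend,
                strand = "+") {
  data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
             strand = strand, tname = tname, tlen = tlen, tstart = tstart,
             tend = tend, nmatch = qend - qstart + 1,
             alen = qend - qstart + 1, mapq = 60, stringsAsFactors = FALSE)
}
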