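# Hand-built fixtures shared across tests.

# A minimal two-chromosome annotation with one feature of each relevant
# biotype, including a two-exon gene on the minus strand.
tiny_features <- function() {
  feature_table(
    feature_id = c("geneA", "geneB", "pirna1", "mirna1", "rrna1", "tnC"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    strand = c("+", "-", "+", "+", "+", "-"),
    biotype = c("protein_coding", "protein_coding", "piRNA", "miRNA",
                "rRNA", "transposon"),
    exon_starts = list(100L, c(1000L, 1500L), 3000L, 100L, 1000L, 4000L),
    exon_ends = list(600L, c(1200L, 1800L), 3021L, 122L, 2500L, 4500L))
}

# One alignment helper with defaults suited to 22G reads.
aln1 <- function(read_id = "r1", chrom = "chr1", start = 200L, len = 22L,
                 strand = "-", fp = "G", n_loci = 1L) {
  alignment_table(read_id, chrom, start, start + len, strand, fp, n_loci)
}

small_truth <- function(seed = 1, ...) {
  build_truth(sim_config(n_protein_coding = 60L, n_pseudogene = 5L,
                         n_transposon = 8L, n_duplicated_pairs = 2L,
                         n_pirna = 15L, n_mirna = 4L, ...), seed)
}
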