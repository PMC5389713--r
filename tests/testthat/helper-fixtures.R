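# Hand-built genomic fixtures for the 5'-assignment tests.

# Ten non-overlapping intervals over two chromosomes; BED-style 0-based
# half-open coordinates throughout.
fixture_annotation <- function() {
  granges_from_bed_df(data.frame(
    chrom = c(rep("chr1", 6), rep("chr2", 4)),
    start = c(100, 200, 300, 500, 700, 900, 0, 150, 300, 450),
    end   = c(200, 300, 400, 600, 800, 1000, 100, 250, 400, 500),
    strand = "+",
    feature_class = c("exon", "intron", "exon", "intergenic", "intron",
                      "intergenic", "exon", "intron", "intergenic", "exon"),
    region_id = c("e1", "i1", "e2", "x1", "i3", "x3", "e3", "i2", "x2", "e4"),
    stringsAsFactors = FALSE))
}

# Thirty reads, both strands, each with its hand-assigned target feature
# (5' = start on plus, end - 1 on minus; NA = no covering interval).
fixture_reads <- function() {
  data.frame(
    chrom = c(rep("chr1", 15), rep("chr2", 12), "chr2", "chr1", "chr1"),
    start = c(150, 150, 100, 120, 200, 250, 399, 380, 450, 450, 650, 650,
              950, 850, 0,
              0, 50, 99, 100, 100, 200, 200, 350, 390, 460, 480, 249,
              150, 599, 600),
    end   = c(250, 250, 150, 200, 290, 350, 450, 460, 550, 550, 750, 750,
              1050, 950, 50,
              80, 160, 140, 150, 150, 320, 320, 420, 480, 470, 600, 260,
              250, 700, 700),
    strand = c("+", "-", "+", "-", "+", "-", "+", "-", "+", "-", "+", "-",
               "+", "-", "+",
               "+", "-", "+", "+", "-", "+", "-", "+", "-", "+", "-", "+",
               "-", "+", "-"),
    expected = c("e1", "i1", "e1", "e1", "i1", "e2", "e2", NA, NA, "x1",
                 NA, "i3", "x3", "x3", NA,
                 "e3", "i2", "e3", NA, NA, "i2", "x2", "x2", "e4", "e4",
                 NA, "i2", "i2", "x1", NA),
    stringsAsFactors = FALSE)
}
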