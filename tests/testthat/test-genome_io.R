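test_that("canonical vocabulary has the standard metazoan complement", {
  v <- canonical_vocabulary()
  expect_length(v$pcgs, 13)
  expect_length(v$rrnas, 2)
  expect_length(v$trnas, 22)
  expect_setequal(grep("^trn[LS][12]$", v$trnas, value = TRUE),
                  c("trnL1", "trnL2", "trnS1", "trnS2"))
})

test_that("normalize_label maps common annotation dialects", {
  cases <- list(
    list("COI", "COX1", "PCG"),
    list("cox1", "COX1", "PCG"),
    list("cytochrome c oxidase subunit I", "COX1", "PCG"),
    list("COIII", "COX3", "PCG"),
    list("nad4l", "ND4L", "PCG"),
    list("NADH dehydrogenase subunit 2", "ND2", "PCG"),
    list("cob", "CYTB", "PCG"),
    list("cytochrome b", "CYTB", "PCG"),
    list("ATPase6", "ATP6", "PCG"),
    list("atp8", "ATP8", "PCG"),
    list("16S ribosomal RNA", "rrnL", "rRNA"),
    list("12S rRNA", "rrnS", "rRNA"),
    list("l-rRNA", "rrnL", "rRNA"),
    list("trnM", "trnM", "tRNA"),
    list("tRNA-Phe", "trnF", "tRNA"),
    list("trnL(tag)", "trnL1", "tRNA"),
    list("trnL(taa)", "trnL2", "tRNA"),
    list("tRNA-Leu(UUR)", "trnL2", "tRNA"),
    list("trnS(uga)", "trnS2", "tRNA"),
    list("trnS(gct)", "trnS1", "tRNA"),
    list("trnS1", "trnS1", "tRNA"))
  for (cs in cases) {
    r <- normalize_label(cs[[1]])
    expect_equal(unname(r$label), cs[[2]], info = cs[[1]])
    expect_equal(unname(r$cls), cs[[3]], info = cs[[1]])
  }
})

test_that("unmappable names become unknown with the annotated class", {
  r <- normalize_label("hypothetical ORF", cls = "PCG")
  expect_equal(r$label, "unknown")
  expect_equal(r$cls, "PCG")
  # ambiguous leucine without anticodon is flagged, not guessed
  expect_equal(normalize_label("trnL")$label, "trnL?")
})

test_that("normalize_label is idempotent on canonical labels", {
  v <- canonical_vocabulary()
  for (lab in unlist(v)) {
    r <- normalize_label(lab)
    expect_equal(unname(r$label), lab)
  }
})

test_that("mitogenome validation enforces coordinate invariants", {
  expect_error(mitogenome("x", "ACGT",
    data.frame(label = "COX1", cls = "PCG", start = 0, end = 9, strand = 1)),
    "end out of")
  expect_error(mitogenome("x", "ACGT",
    data.frame(label = "COX1", cls = "PCG", start = 2, end = 1, strand = 1)),
    "end <= start")
  expect_error(mitogenome("x", strrep("A", 20),
    data.frame(label = "COX1", cls = "PCG", start = 15, end = 5, strand = 1,
               wraps = TRUE), topology = "linear"),
    "wrapping feature on a linear genome")
})

test_that("extract_cds honors strand, wrapping and incomplete-stop trimming", {
  g <- toy_genome()
  expect_equal(extract_cds(g, "COX1"), "ATGAAACCCGGGTTTACATAA")
  # minus-strand CDS comes back reverse-complemented to coding orientation
  expect_equal(extract_cds(g, "ND1"), "ATGTTTGGGAAATAA")
  # length-10 span -> one trailing base trimmed
  g2 <- mitogenome("t", "ATGAAATAACCCC",
    data.frame(label = "ND3", cls = "PCG", start = 0, end = 10, strand = 1))
  expect_equal(nchar(extract_cds(g2, "ND3")), 9)
  # wrapping CDS concatenates across the origin (10-base span, one base
  # trimmed to restore frame)
  gw <- mitogenome("w", paste0("AATAA", strrep("G", 20), "ATGAA"), # ATG at 25
    data.frame(label = "ND2", cls = "PCG", start = 25, end = 5, strand = 1,
               wraps = TRUE))
  expect_equal(extract_cds(gw, "ND2"), "ATGAAAATA")
  # degenerate CDS errors
  g3 <- mitogenome("d", "ATGAAATAACCCC",
    data.frame(label = "ND3", cls = "PCG", start = 0, end = 5, strand = 1))
  expect_error(extract_cds(g3, "ND3"), "degenerate")
})

test_that("GenBank coordinates convert between 1-based and internal 0-based", {
  s <- rand_seq(400)
  g <- mitogenome("conv", s,
    data.frame(label = "COX1", cls = "PCG",
               start = 99, end = 300, strand = -1))
  tf <- tempfile(fileext = ".gb")
  write_genbank(g, tf)
  txt <- readLines(tf)
  expect_true(any(grepl("complement(100..300)", txt, fixed = TRUE)))
  g2 <- read_genbank(tf)[[1]]
  expect_equal(g2$features$start, 99)
  expect_equal(g2$features$end, 300)
  expect_equal(g2$features$strand, -1L)
})

test_that("GenBank write/read round trip is lossless, including wraps", {
  set.seed(101)
  cfg <- synth_config(n_genomes = 2, seed = 5, trna_losses = "trnC")
  gs <- generate_genomes(cfg)$genomes
  # add one wrapping minus-strand feature to stress the location syntax
  gw <- mitogenome("wrapper", rand_seq(500),
    data.frame(label = c("COX1", "CYTB"), cls = "PCG",
               start = c(10, 450), end = c(100, 30), strand = c(1, -1),
               wraps = c(FALSE, TRUE)))
  all3 <- c(gs, list(wrapper = gw))
  tf <- tempfile(fileext = ".gb")
  write_genbank(all3, tf)
  back <- read_genbank(tf)
  expect_length(back, 3)
  for (id in names(all3)) {
    expect_identical(back[[id]]$sequence, all3[[id]]$sequence, info = id)
    expect_identical(back[[id]]$topology, all3[[id]]$topology, info = id)
    expect_identical(back[[id]]$features, all3[[id]]$features, info = id)
  }
})

test_that("malformed GenBank input raises informative errors", {
  tf <- tempfile()
  writeLines(c("NOT A HEADER", "//"), tf)
  expect_error(read_genbank(tf), "LOCUS")
  writeLines(c("LOCUS       x    10 bp    DNA     circular INV",
               "FEATURES             Location/Qualifiers",
               "     CDS             5..40",
               "                     /gene=\"COX1\"",
               "ORIGIN",
               "        1 acgtacgtac", "//"), tf)
  expect_error(read_genbank(tf), "beyond sequence bounds")
})

test_that("FASTA + feature-table round trip preserves all fields", {
  g <- toy_genome()
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_mito_fasta(g, fa)
  write_feature_table(g, tsv)
  g2 <- read_feature_table(fa, tsv)[[1]]
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features, g$features)
})

test_that("anchoring rotates and reflects so COX1 starts at 0 on plus", {
  g <- toy_genome()
  # rotate the toy genome arbitrarily, then reverse-complement: anchoring
  # must restore the original representation exactly
  ga <- anchor_genome(g)
  expect_equal(ga$features$label[1], "COX1")
  expect_equal(ga$features$start[1], 0)
  expect_equal(ga$features$strand[1], 1L)
  expect_identical(ga$sequence, g$sequence)
  g_rc <- mitocomp:::.revcomp_genome(mitocomp:::.rotate_genome(g, 37))
  gb <- anchor_genome(g_rc)
  expect_identical(gb$sequence, g$sequence)
  expect_identical(gb$features, g$features)
  # every gene's strand-corrected CDS is invariant under reorientation
  expect_equal(extract_cds(gb, "ND1"), extract_cds(g, "ND1"))
})
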