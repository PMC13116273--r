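test_that("shipped code table matches the reference invertebrate mito code", {
  code <- genetic_code_table(5)
  expect_length(code$sense, 62)
  expect_setequal(code$stops, c("TAA", "TAG"))
  expect_equal(sum(lengths(code$families)), 62)
  # independent oracle: Biostrings' registry of NCBI genetic codes
  ref <- Biostrings::getGeneticCode("5")
  for (cod in names(ref)) {
    expected <- ifelse(ref[[cod]] == "*", "*", ref[[cod]])
    expect_equal(unname(code$table[[cod]]), unname(expected), info = cod)
  }
  # the table-5 signature reassignments
  expect_equal(unname(code$table[c("AGA", "AGG", "ATA", "TGA")]),
               c("S", "S", "M", "W"))
})

test_that("codon_counts pools CDSs, excludes stops and ambiguous codons", {
  x <- codon_counts("ATGAAATAA")
  expect_equal(unname(x[c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(sum(x), 2L)
  expect_equal(unname(attr(x, "stop_counts")["TAA"]), 1L)
  # duplication doubles counts
  x2 <- codon_counts(c("ATGAAATAA", "ATGAAATAA"))
  expect_equal(unname(x2[c("ATG", "AAA")]), c(2L, 2L))
  # ambiguous codons excluded but tallied
  x3 <- codon_counts("ATGANATAA")
  expect_equal(attr(x3, "n_ambiguous"), 1L)
  expect_equal(sum(x3), 1L)
  expect_error(codon_counts(character()), "empty")
  expect_error(codon_counts("ATGA"))
})

test_that("codon sampling from a known profile is within sampling error", {
  set.seed(41)
  prof <- codon_bias_profile()
  code <- genetic_code_table(5)
  # overall codon probabilities: uniform amino acids x within-family profile
  aa_w <- rep(1 / 20, 20)
  names(aa_w) <- names(code$families)
  p <- setNames(numeric(62), code$sense)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    p[fam] <- aa_w[[aa]] * prof$codon_prob[fam]
  }
  cods <- sample(code$sense, 10000, replace = TRUE, prob = p)
  cds <- paste(cods, collapse = "")
  x <- codon_counts(cds)
  emp <- x / sum(x)
  expect_true(all(abs(emp - p) < 0.02))
})

test_that("rscu reproduces the defining identities", {
  code <- genetic_code_table(5)
  zero <- setNames(rep(0L, 62), code$sense)
  # equal use of the two Phe codons -> both exactly 1 (no bias)
  x <- zero; x[c("TTT", "TTC")] <- 10L
  r <- rscu(x)
  expect_equal(unname(r[c("TTT", "TTC")]), c(1, 1))
  # exclusive use of one Leu codon (6-codon family) -> 6, siblings 0
  x <- zero; x["TTA"] <- 7L
  r <- rscu(x)
  expect_equal(unname(r["TTA"]), 6)
  expect_equal(unname(r[setdiff(code$families$L, "TTA")]), rep(0, 5))
  # Val: GTA=8, others 0 -> 4.0
  x <- zero; x["GTA"] <- 8L
  expect_equal(unname(rscu(x)["GTA"]), 4)
  # unobserved families are missing, not zero
  x <- zero; x["TTT"] <- 1L
  expect_true(all(is.na(rscu(x)[code$families$G])))
  expect_error(rscu(zero - 1L), "negative")
})

test_that("family sums equal family sizes and values stay in range", {
  set.seed(42)
  code <- genetic_code_table(5)
  cfg <- synth_config(n_genomes = 3, seed = 43,
                      regime = c("globally_positive", "bimodal",
                                 "globally_negative"))
  gs <- generate_genomes(cfg)
  m <- rscu_matrix(gs$genomes)
  expect_equal(ncol(m), 62)
  for (i in seq_len(nrow(m))) {
    for (aa in names(code$families)) {
      fam <- code$families[[aa]]
      vals <- m[i, fam]
      if (all(is.na(vals))) next
      expect_equal(sum(vals), length(fam))
      expect_equal(mean(vals), 1)
      expect_true(all(vals >= 0 & vals <= length(fam)))
    }
  }
})

test_that("RSCU is invariant to CDS duplication", {
  set.seed(44)
  cfg <- synth_config(n_genomes = 1, seed = 45)
  g <- generate_genome(cfg, 1)$genome
  cds <- extract_cds(g, "COX1")
  r1 <- rscu(codon_counts(cds))
  r2 <- rscu(codon_counts(c(cds, cds, cds)))
  expect_equal(r1, r2)
})

test_that("A/T-rich profiles give RSCU > 1 for nearly all A/U-ending codons", {
  cfg <- synth_config(n_genomes = 4, seed = 46)
  gs <- generate_genomes(cfg)
  m <- rscu_matrix(gs$genomes)
  atend <- colnames(m)[substr(colnames(m), 3, 3) %in% c("A", "T")]
  for (i in seq_len(nrow(m))) {
    vals <- m[i, atend]
    vals <- vals[!is.na(vals)]
    expect_gte(mean(vals > 1), 0.9)
  }
})

test_that("uniform codon usage yields RSCU near 1 everywhere observed", {
  set.seed(47)
  code <- genetic_code_table(5)
  cods <- sample(code$sense, 60000, replace = TRUE)
  r <- rscu(codon_counts(paste(cods, collapse = "")))
  expect_true(all(abs(r - 1) < 0.15, na.rm = TRUE))
})

test_that("log10 view masks zeros and missing values", {
  m <- rbind(a = c(AAA = 2, AAG = 0), b = c(AAA = NA, AAG = 1))
  lm <- rscu_log10(m)
  expect_equal(lm["a", "AAA"], log10(2))
  expect_true(is.na(lm["a", "AAG"]))
  expect_true(is.na(lm["b", "AAA"]))
  expect_false(any(is.infinite(lm)))
})

test_that("RSCU matrix round trips through the report TSV", {
  cfg <- synth_config(n_genomes = 3, seed = 48)
  gs <- generate_genomes(cfg)
  m <- rscu_matrix(gs$genomes)
  dir <- tempfile(); dir.create(dir)
  rep <- compare_mitogenomes(gs$genomes)
  write_report(rep, dir)
  back <- read.table(file.path(dir, "rscu.tsv"), sep = "\t", header = TRUE,
                     check.names = FALSE)
  m2 <- as.matrix(back[, -1])
  rownames(m2) <- back$genome_id
  expect_equal(m2[rownames(m), colnames(m)], m, tolerance = 1e-4)
})

test_that("PCA is deterministic, sign-fixed and separates planted profiles", {
  # identical rows -> all scores zero
  m0 <- matrix(rep(c(1, 2, 0.5, 1.5), each = 4), nrow = 4,
               dimnames = list(paste0("g", 1:4), paste0("c", 1:4)))
  p0 <- rscu_pca(m0)
  expect_true(all(abs(p0$scores) < 1e-12))
  expect_true(all(p0$explained == 0))
  expect_error(rscu_pca(m0[1:2, ]), "at least 3")
  # explained variance is non-increasing and sums to <= 1
  set.seed(49)
  m1 <- matrix(rnorm(60), nrow = 6)
  p1 <- rscu_pca(m1)
  expect_true(all(diff(p1$explained) <= 1e-12))
  expect_lte(sum(p1$explained), 1 + 1e-12)
  # two planted codon-bias profiles separate on PC1 by sign
  profA <- codon_bias_profile(c(A = 0.55, T = 0.30, G = 0.09, C = 0.06), "A_end")
  profB <- codon_bias_profile(c(A = 0.30, T = 0.55, G = 0.09, C = 0.06), "T_end")
  gsA <- generate_genomes(synth_config(n_genomes = 5, seed = 50,
                                       codon_profile = profA))
  gsB <- generate_genomes(synth_config(n_genomes = 5, seed = 51,
                                       codon_profile = profB))
  genomes <- c(gsA$genomes, gsB$genomes)
  names(genomes) <- c(paste0("A", 1:5), paste0("B", 1:5))
  for (i in seq_along(genomes)) genomes[[i]]$id <- names(genomes)[i]
  m <- rscu_matrix(genomes)
  p <- rscu_pca(m)
  pc1 <- p$scores[, 1]
  sideA <- sign(pc1[1:5]); sideB <- sign(pc1[6:10])
  expect_true(all(sideA == sideA[1]))
  expect_true(all(sideB == sideB[1]))
  expect_true(sideA[1] != sideB[1])
})
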