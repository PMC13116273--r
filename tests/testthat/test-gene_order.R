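test_that("order extraction filters classes, anchors and reflects", {
  g <- toy_genome()
  o <- gene_order(g)  # all classes
  expect_equal(o$labels[1], "COX1")
  expect_equal(o$signs[1], 1L)
  expect_length(o$labels, 6)
  op <- gene_order(g, classes = "PCG")
  expect_equal(op$labels, c("COX1", "ND1", "ATP8"))
  ot <- gene_order(g, classes = "tRNA")
  expect_length(ot$labels, 2)
  # genome with COX1 on the minus strand: anchored order is reflected so
  # COX1 leads with +1
  g2 <- mitocomp:::.revcomp_genome(g)
  o2 <- gene_order(g2)
  expect_equal(o2$labels[1], "COX1")
  expect_equal(o2$signs[1], 1L)
  expect_equal(o2$labels, o$labels)
  expect_equal(o2$signs, o$signs)
  # unknown labels are excluded with a warning
  g3 <- toy_genome()
  g3$features$label[5] <- "unknown"
  expect_warning(o3 <- gene_order(g3), "non-canonical")
  expect_false("unknown" %in% o3$labels)
  # duplicated labels error
  g4 <- toy_genome()
  g4$features$label[2] <- "ATP8"
  expect_error(gene_order(g4), "ATP8")
})

test_that("adjacency sets have n (circular) or n-1 (linear) elements", {
  o <- new_gene_order("c", paste0("g", 1:3), rep(1L, 3), "circular")
  expect_length(adjacency_set(o), 3)
  ol <- new_gene_order("l", paste0("g", 1:3), rep(1L, 3), "linear")
  expect_length(adjacency_set(ol), 2)
  set.seed(20)
  for (i in 1:10) {
    o <- rand_order(sample(3:13, 1))
    expect_length(adjacency_set(o), length(o$labels))
  }
})

test_that("breakpoint distance matches the brute-force oracle", {
  a <- new_gene_order("a", paste0("g", 1:5), rep(1L, 5), "circular")
  b <- new_gene_order("b", paste0("g", c(1, 3, 2, 4, 5)), rep(1L, 5), "circular")
  expect_equal(breakpoint_distance(a, a), 0)
  # swapping one adjacent pair: strand-blind distance 2, strand-aware 3
  # (the reversed singleton also flips reading direction)
  expect_equal(breakpoint_distance(a, b, signed = FALSE), 2)
  expect_equal(breakpoint_distance(a, b, signed = FALSE), oracle_breakpoint(a, b, signed = FALSE))
  expect_equal(breakpoint_distance(a, b), oracle_breakpoint(a, b))
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:13, 1)
    x <- rand_order(n); y <- rand_order(n)
    expect_equal(breakpoint_distance(x, y), oracle_breakpoint(x, y))
    expect_equal(breakpoint_distance(x, y, signed = FALSE),
                 oracle_breakpoint(x, y, signed = FALSE))
  }
})

test_that("distance is a pseudometric invariant to rotation and reflection", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- rand_order(n); y <- rand_order(n)
    expect_equal(breakpoint_distance(x, x), 0)
    expect_equal(breakpoint_distance(x, y), breakpoint_distance(y, x))
    xr <- mitocomp:::.rotate_order(x, sample(n, 1))
    xf <- mitocomp:::.reflect_order(x)
    expect_equal(breakpoint_distance(xr, y), breakpoint_distance(x, y))
    expect_equal(breakpoint_distance(xf, y), breakpoint_distance(x, y))
    expect_equal(breakpoint_distance(x, xf), 0)
  }
})

test_that("mismatched gene sets raise an error naming the difference", {
  a <- new_gene_order("a", c("COX1", "ND1"), c(1L, 1L), "circular")
  b <- new_gene_order("b", c("COX1", "ND2"), c(1L, 1L), "circular")
  expect_error(breakpoint_distance(a, b), "ND1, ND2")
})

test_that("k random inversions yield distance at most 2k", {
  set.seed(23)
  base <- rand_order(13)
  for (trial in 1:200) {
    k <- sample(1:4, 1)
    o <- base
    for (j in seq_len(k)) {
      ij <- sort(sample(seq_along(o$labels), 2, replace = TRUE))
      o <- invert_block(o, ij[1], ij[2])
    }
    expect_lte(breakpoint_distance(base, o), 2 * k)
  }
})

test_that("rearranged segments localize inverted blocks", {
  tmpl <- ancestral_template()$order
  ref <- tmpl
  expect_equal(rearranged_segments(ref, ref), list())
  # single internal inversion -> one segment, exactly the inverted block
  t1 <- invert_block(ref, 5, 9)
  segs <- rearranged_segments(t1, ref)
  expect_length(segs, 1)
  expect_equal(segs[[1]],
               paste0(ifelse(t1$signs[5:9] > 0, "", "-"), t1$labels[5:9]))
  expect_gt(breakpoint_distance(t1, ref), 0)
  # a pure strand flip of one gene is itself a (one-gene) rearranged segment
  t2 <- ref
  t2$signs[10] <- -t2$signs[10]
  segs2 <- rearranged_segments(t2, ref)
  expect_length(segs2, 1)
  expect_equal(segs2[[1]], paste0("-", ref$labels[10]))
  # every non-anchor gene displaced (cyclic shift of positions 2..n) -> one
  # segment spanning all non-anchor genes
  n <- length(ref$labels)
  idx <- c(1, 3:n, 2)
  t3 <- new_gene_order("shuf", ref$labels[idx], ref$signs[idx], "circular")
  segs3 <- rearranged_segments(t3, ref)
  set.seed(24)
  expect_length(segs3, 1)
  expect_length(segs3[[1]], n - 1)
  # segments are empty iff the breakpoint distance is zero
  for (i in 1:10) {
    o <- ref
    k <- sample(0:3, 1)
    for (j in seq_len(k)) {
      ij <- sort(sample(2:n, 2, replace = TRUE))
      o <- invert_block(o, ij[1], ij[2])
    }
    d <- breakpoint_distance(o, ref)
    s <- rearranged_segments(o, ref)
    expect_equal(length(s) == 0, d == 0)
  }
})

test_that("gene-order TSV round trips", {
  tmpl <- ancestral_template()$order
  tf <- tempfile(fileext = ".tsv")
  write_gene_orders(list(tmpl), tf)
  back <- read_gene_orders(tf)[[1]]
  expect_equal(back$labels, tmpl$labels)
  expect_equal(back$signs, tmpl$signs)
  expect_equal(back$topology, tmpl$topology)
})

test_that("ancestral inference recovers shared and majority orders", {
  tmpl <- ancestral_template()$order
  keep <- tmpl$labels %in% canonical_vocabulary()$pcgs
  pcg <- new_gene_order("tmpl", tmpl$labels[keep], tmpl$signs[keep], "circular")

  mk <- function(id, o) { o$genome_id <- id; o }
  # all identical -> that order
  orders <- list(t1 = mk("t1", pcg), t2 = mk("t2", pcg), t3 = mk("t3", pcg),
                 out = mk("out", pcg))
  anc <- infer_ancestral_order(orders, tree = "((t1,t2,t3),out);",
                               outgroup = "out")
  expect_equal(breakpoint_distance(anc, pcg), 0)
  expect_false(attr(anc, "fallback"))

  # 3 ancestral + 1 heavily shuffled ingroup taxon; outgroup = template:
  # the ancestor stays the template (the M. inae-like configuration)
  set.seed(25)
  shuf <- pcg
  for (j in 1:6) {
    ij <- sort(sample(2:length(shuf$labels), 2, replace = TRUE))
    shuf <- invert_block(shuf, ij[1], ij[2])
  }
  orders2 <- list(t1 = mk("t1", pcg), t2 = mk("t2", pcg), t3 = mk("t3", pcg),
                  t4 = mk("t4", shuf), out = mk("out", pcg))
  anc2 <- infer_ancestral_order(orders2, tree = "((t1,t2,(t3,t4)),out);",
                                outgroup = "out")
  expect_equal(anc2$labels, pcg$labels)
  expect_equal(anc2$signs, pcg$signs)

  # simulation: 5 ingroup lineages, at most 2 rearranged, outgroup = truth
  for (rep in 1:10) {
    n_re <- sample(0:2, 1)
    ids <- paste0("s", 1:5)
    orders3 <- setNames(lapply(ids, function(id) mk(id, pcg)), ids)
    for (id in sample(ids, n_re)) {
      o <- orders3[[id]]
      for (j in seq_len(sample(1:2, 1))) {
        ij <- sort(sample(2:length(o$labels), 2, replace = TRUE))
        o <- invert_block(o, ij[1], ij[2])
      }
      orders3[[id]] <- o
    }
    orders3$out <- mk("out", pcg)
    anc3 <- infer_ancestral_order(orders3,
      tree = paste0("((", paste(ids, collapse = ","), "),out);"),
      outgroup = "out")
    expect_equal(anc3$labels, pcg$labels)
    expect_equal(anc3$signs, pcg$signs)
  }
})

test_that("ancestral inference validates its inputs", {
  pcg <- new_gene_order("x", c("COX1", "ND1", "ND2"), c(1L, 1L, 1L), "circular")
  expect_error(infer_ancestral_order(list(a = pcg), outgroup = "missing"),
               "outgroup")
  expect_error(infer_ancestral_order(list(a = pcg, out = pcg),
                                     tree = "(b,out);", outgroup = "out"),
               "missing tips")
})
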