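# Shared helpers: tiny hand-built genomes and independent oracles.

# random nucleotide string
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a small fully annotated toy genome: 3 PCGs, 2 tRNAs, 1 rRNA, circular.
# COX1 sits at the start on the plus strand; ND1 is on the minus strand.
toy_genome <- function(id = "toy") {
  cox1 <- "ATGAAACCCGGGTTTACATAA"             # 21 bp, 7 codons
  trnl2 <- strrep("AT", 10)                    # 20 bp
  nd1_cds <- "ATGTTTGGGAAATAA"                 # 15 bp CDS
  nd1 <- revcomp(nd1_cds)                      # minus strand on genome
  rrns <- strrep("AGCT", 10)                   # 40 bp
  trnk <- strrep("GA", 8)                      # 16 bp
  atp8 <- "ATGCACGTTCGATTCTAA"                 # 18 bp
  seqs <- c(cox1, trnl2, nd1, rrns, trnk, atp8)
  starts <- cumsum(c(0, head(nchar(seqs), -1)))
  features <- data.frame(
    label = c("COX1", "trnL2", "ND1", "rrnS", "trnK", "ATP8"),
    cls = c("PCG", "tRNA", "PCG", "rRNA", "tRNA", "PCG"),
    start = starts, end = starts + nchar(seqs),
    strand = c(1, 1, -1, -1, 1, 1), wraps = FALSE,
    stringsAsFactors = FALSE)
  mitogenome(id, paste(seqs, collapse = ""), features, "circular")
}

# character-by-character base tally, independent of base_counts()
oracle_counts <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  c(A = sum(ch == "A"), C = sum(ch == "C"), G = sum(ch == "G"),
    T = sum(ch == "T"), other = sum(!ch %in% c("A", "C", "G", "T")))
}

# Brute-force breakpoint distance oracle: counts conserved adjacencies by
# positional scan over order b (no canonical-key sets). For each consecutive
# signed pair of a, the pair is conserved if b contains it in reading order
# (same signs) or its mirror (reversed with negated signs).
oracle_breakpoint <- function(a, b, signed = TRUE) {
  stopifnot(a$topology == "circular", b$topology == "circular")
  n <- length(a$labels)
  pairs_of <- function(o) {
    nxt <- c(2:n, 1)
    lapply(1:n, function(i) list(l1 = o$labels[i], s1 = o$signs[i],
                                 l2 = o$labels[nxt[i]], s2 = o$signs[nxt[i]]))
  }
  pa <- pairs_of(a); pb <- pairs_of(b)
  conserved <- 0L
  for (p in pa) {
    hit <- FALSE
    for (q in pb) {
      if (signed) {
        if ((q$l1 == p$l1 && q$s1 == p$s1 && q$l2 == p$l2 && q$s2 == p$s2) ||
            (q$l1 == p$l2 && q$s1 == -p$s2 && q$l2 == p$l1 && q$s2 == -p$s1)) {
          hit <- TRUE; break
        }
      } else {
        if ((q$l1 == p$l1 && q$l2 == p$l2) || (q$l1 == p$l2 && q$l2 == p$l1)) {
          hit <- TRUE; break
        }
      }
    }
    if (hit) conserved <- conserved + 1L
  }
  n - conserved
}

# random signed circular order over n generic gene labels
rand_order <- function(n, id = "r") {
  labs <- paste0("g", sample.int(n))
  new_gene_order(id, labs, sample(c(-1L, 1L), n, replace = TRUE), "circular")
}

# all signed orders of labels 1..n with the first element fixed at (+g1)
all_signed_orders <- function(n) {
  labs <- paste0("g", 1:n)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  signings <- function(k) {
    if (k == 0) return(list(integer()))
    out <- list()
    for (s in signings(k - 1)) {
      out[[length(out) + 1]] <- c(1L, s)
      out[[length(out) + 1]] <- c(-1L, s)
    }
    out
  }
  out <- list()
  for (p in perms(labs[-1])) for (s in signings(n - 1)) {
    out[[length(out) + 1]] <-
      new_gene_order("e", c(labs[1], p), c(1L, s), "circular")
  }
  out
}
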