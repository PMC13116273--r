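# Deterministic generator of annotated velvet-worm-like mitogenomes with
# recorded ground truth.
#
# Each genome is laid out from the ancestral arthropod gene-order template
# (optionally rearranged by random signed inversions and with tRNA genes
# deleted), with gene lengths sampled within +/-10% of template lengths.
# PCG spans are filled with codons sampled from a per-group codon-bias
# profile (start ATG/ATA, stop TAA); rRNA/tRNA/intergenic spans are sampled
# per position to hit the A+T target and the regime's G:C imbalance. The
# regime (globally positive / globally negative / bimodal GC skew) is
# imposed on CDSs by tilting amino-acid weights (solved numerically so the
# expected CDS skew equals the target amplitude, leaving within-family
# synonymous codon probabilities -- hence RSCU truth -- untouched), and the
# residual is absorbed by the non-coding regions so the whole-genome skew
# hits the target.

#' The ancestral gene-order template
#'
#' Loads the bundled arthropod-like ancestral mitochondrial arrangement
#' (37 genes: 13 PCGs, 2 rRNAs, 22 tRNAs with strands), linearized at COX1.
#'
#' @return list with `order` (a `gene_order` with genome_id
#'   `"ancestral_template"`) and `lengths` (named integer vector of typical
#'   gene lengths).
#' @export
ancestral_template <- function() {
  path <- system.file("extdata", "ancestral_gene_order.tsv", package = "mitocomp")
  if (!nzchar(path) || !file.exists(path))
    stop("ancestral gene-order fixture missing from package installation")
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (nrow(tab) != 37) stop("corrupt ancestral gene-order fixture")
  tab <- tab[order(tab$position), ]
  ord <- new_gene_order("ancestral_template", tab$label,
                        ifelse(tab$strand == "+", 1L, -1L), "circular")
  list(order = ord, lengths = setNames(as.integer(tab$typical_length), tab$label))
}

#' Build a within-family codon-bias profile
#'
#' Each sense codon is weighted by the product of per-base preferences over
#' its three positions, then normalized within each synonymous family, so
#' the profile determines RSCU expectations directly. The default strongly
#' prefers A/T (mimicking the mutational A+T pressure of invertebrate
#' mitogenomes), which makes A/T-ending codons over-represented within
#' essentially every family and keeps coding regions A+T-rich.
#'
#' @param base_weights named numeric preferences for A/T/G/C.
#' @param name profile identifier recorded in the truth.
#' @return list with `name` and `codon_prob` (named vector over the 62 sense
#'   codons; probabilities normalized within each family).
#' @export
codon_bias_profile <- function(base_weights = c(A = 0.45, T = 0.40,
                                                G = 0.09, C = 0.06),
                               name = "AT_rich") {
  stopifnot(all(c("A", "T", "G", "C") %in% names(base_weights)),
            all(base_weights > 0))
  code <- genetic_code_table(5)
  b <- vapply(strsplit(code$sense, ""), function(ch)
    prod(base_weights[ch]), 0)
  w <- setNames(b, code$sense)
  for (fam in code$families) w[fam] <- w[fam] / sum(w[fam])
  list(name = name, codon_prob = w)
}

# expected per-codon (G - C) and (G + C) counts for each amino acid under
# the profile's within-family codon probabilities
.aa_skew_stats <- function(profile, code = genetic_code_table(5)) {
  cnt <- function(cods, base) vapply(strsplit(cods, ""), function(ch)
    sum(ch == base), 0)
  aas <- names(code$families)
  delta <- gamma <- setNames(numeric(length(aas)), aas)
  for (aa in aas) {
    fam <- code$families[[aa]]
    p <- profile$codon_prob[fam]
    gg <- cnt(fam, "G"); cc <- cnt(fam, "C")
    delta[aa] <- sum(p * (gg - cc))
    gamma[aa] <- sum(p * (gg + cc))
  }
  list(delta = delta, gamma = gamma)
}

# default amino-acid weights, loosely mimicking mitochondrial protein
# composition (hydrophobic-rich)
.DEFAULT_AA_W <- c(L = 0.16, I = 0.11, F = 0.10, S = 0.09, M = 0.07,
                   N = 0.06, K = 0.05, T = 0.05, A = 0.04, V = 0.06,
                   G = 0.05, P = 0.03, Y = 0.05, W = 0.02, C = 0.01,
                   H = 0.02, Q = 0.02, R = 0.01, D = 0.02, E = 0.02)

# Tilt amino-acid weights so the expected CDS GC skew equals `target`:
# w(t) = w0 * exp(t * delta_aa), solved for t by uniroot. Returns the
# tilted, normalized weights.
.tilt_aa_weights <- function(w0, stats, target) {
  f <- function(t) {
    w <- w0 * exp(t * stats$delta)
    w <- w / sum(w)
    sum(w * stats$delta) - target * sum(w * stats$gamma)
  }
  lohi <- c(-6, 6)
  flo <- f(lohi[1]); fhi <- f(lohi[2])
  t <- if (flo * fhi > 0) {
    if (abs(flo) < abs(fhi)) lohi[1] else lohi[2]  # target unreachable: clamp
  } else {
    uniroot(f, lohi, tol = 1e-8)$root
  }
  w <- w0 * exp(t * stats$delta)
  w / sum(w)
}

#' Synthetic-dataset configuration
#'
#' Defaults encode the statistical structure of onychophoran mitogenomes:
#' ~14.4-14.9 kb circular genomes, A+T content 0.77, GC-skew amplitude 0.15,
#' the full 37-gene complement minus configured tRNA losses.
#'
#' @param n_genomes number of genomes to generate.
#' @param seed integer seed; mandatory, all generation is deterministic
#'   given (seed, genome index).
#' @param at_content target A+T fraction of non-coding regions (default
#'   0.77).
#' @param regime `"globally_positive"`, `"globally_negative"` or
#'   `"bimodal"`; recycled over genomes.
#' @param amplitude target |GC skew| (default 0.15).
#' @param n_inversions number of random signed inversions applied to the
#'   template order per genome.
#' @param fixed_inversions list of `c(i, j)` template-position blocks to
#'   invert identically in every genome (applied before the random ones;
#'   used for shared derived arrangements).
#' @param trna_losses character vector of canonical tRNA labels to delete.
#' @param codon_profile a profile from [codon_bias_profile()].
#' @param aa_weights named amino-acid weights (before regime tilting).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genomes = 8, seed, at_content = 0.77,
                         regime = "bimodal", amplitude = 0.15,
                         n_inversions = 0, fixed_inversions = list(),
                         trna_losses = character(),
                         codon_profile = codon_bias_profile(),
                         aa_weights = .DEFAULT_AA_W) {
  if (missing(seed)) stop("synth_config requires an explicit seed")
  stopifnot(at_content > 0, at_content < 1, amplitude >= 0, amplitude < 1,
            all(regime %in% c("globally_positive", "globally_negative",
                              "bimodal")))
  bad <- setdiff(trna_losses, .TRNA_LABELS)
  if (length(bad))
    stop("non-canonical tRNA label(s) in trna_losses: ",
         paste(bad, collapse = ", "))
  structure(list(n_genomes = n_genomes, seed = as.integer(seed),
                 at_content = at_content, regime = regime,
                 amplitude = amplitude, n_inversions = n_inversions,
                 fixed_inversions = fixed_inversions,
                 trna_losses = trna_losses, codon_profile = codon_profile,
                 aa_weights = aa_weights),
            class = "synth_config")
}

# sample a non-coding region string with the given GC skew
.sample_noncoding <- function(len, at, s) {
  gc <- 1 - at
  s <- max(min(s, 0.95), -0.95)
  p <- c(A = at / 2, T = at / 2, G = gc * (1 + s) / 2, C = gc * (1 - s) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# sample a CDS of len bases (multiple of 3) in coding orientation
.sample_cds <- function(len, codon_prob_tilted) {
  ncod <- len / 3 - 2
  internal <- sample(names(codon_prob_tilted), ncod, replace = TRUE,
                     prob = codon_prob_tilted)
  paste0(sample(c("ATG", "ATA"), 1), paste(internal, collapse = ""), "TAA")
}

#' Generate one annotated synthetic mitogenome
#'
#' Deterministic given `(config$seed, genome_index)`. Applies
#' `n_inversions` random signed inversions to the ancestral template order
#' (preserving the COX1 anchor), deletes the configured tRNAs, and fills the
#' genome as described in [synth_config()].
#'
#' @param config a [synth_config()].
#' @param genome_index 1-based genome index (also selects the regime when
#'   `config$regime` is a vector).
#' @param id genome identifier (default `"synth<index>"`).
#' @return list with `genome` (a [mitogenome]) and `truth` (realized regime,
#'   applied inversions, deleted tRNAs, codon profile name, seed used).
#' @export
generate_genome <- function(config, genome_index = 1,
                            id = paste0("synth", genome_index)) {
  stopifnot(inherits(config, "synth_config"))
  seed_used <- (config$seed * 10007L + genome_index * 7919L) %% 2147483647L
  set.seed(seed_used)
  regime <- rep_len(config$regime, max(genome_index, length(config$regime)))[genome_index]
  amp <- config$amplitude
  tmpl <- ancestral_template()
  ord <- tmpl$order

  # rearrange: fixed inversions first (shared derived arrangements), then
  # random signed inversions; position 1 (COX1 anchor) is never touched
  inversions <- list()
  n <- length(ord$labels)
  for (ij in config$fixed_inversions) {
    stopifnot(ij[1] >= 2, ij[2] <= n, ij[1] <= ij[2])
    ord <- invert_block(ord, ij[1], ij[2])
    inversions[[length(inversions) + 1]] <- as.integer(ij)
  }
  if (config$n_inversions > 0) {
    for (k in seq_len(config$n_inversions)) {
      ij <- sort(sample(2:n, 2, replace = TRUE))
      ord <- invert_block(ord, ij[1], ij[2])
      inversions[[length(inversions) + 1]] <- ij
    }
  }

  # tRNA deletions
  keep <- !(ord$labels %in% config$trna_losses)
  labels <- ord$labels[keep]
  signs <- ord$signs[keep]
  cls <- .label_class(labels)

  # plan lengths: genes +/-10% of template, spacers 0-5 bp, a control region
  # (140-180 bp) after rrnS
  glen <- round(tmpl$lengths[labels] * runif(length(labels), 0.9, 1.1))
  glen[cls == "PCG"] <- pmax(6, round(glen[cls == "PCG"] / 3) * 3)
  spacer <- sample(0:5, length(labels), replace = TRUE)
  cr_after <- match("rrnS", labels)
  cr_len <- sample(140:180, 1)
  total <- sum(glen) + sum(spacer) + (if (!is.na(cr_after)) cr_len else 0)
  starts <- integer(length(labels))
  pos <- 0L
  for (i in seq_along(labels)) {
    starts[i] <- pos
    pos <- pos + glen[i] + spacer[i] +
      (if (!is.na(cr_after) && i == cr_after) cr_len else 0L)
  }
  mid <- starts + glen / 2
  region_sign <- switch(regime,
    globally_positive = rep(1, length(labels)),
    globally_negative = rep(-1, length(labels)),
    bimodal = ifelse(mid < total / 2, 1, -1))

  # CDS sequences: amino-acid weights tilted so expected coding-strand skew
  # matches the regional target (sign flipped for minus-strand genes, whose
  # reverse complement lands on the major strand)
  stats <- .aa_skew_stats(config$codon_profile)
  code <- genetic_code_table(5)
  tilt_cache <- list()
  tilted_codon_prob <- function(s_target) {
    key <- sprintf("%.6f", s_target)
    if (!is.null(tilt_cache[[key]])) return(tilt_cache[[key]])
    aw <- .tilt_aa_weights(config$aa_weights[names(code$families)], stats,
                           s_target)
    cp <- setNames(numeric(length(code$sense)), code$sense)
    for (aa in names(code$families)) {
      fam <- code$families[[aa]]
      cp[fam] <- aw[[aa]] * config$codon_profile$codon_prob[fam]
    }
    tilt_cache[[key]] <<- cp / sum(cp)
    tilt_cache[[key]]
  }

  region_seq <- character(length(labels))
  for (i in seq_along(labels)) {
    if (cls[i] == "PCG") {
      s_eff <- amp * region_sign[i] * signs[i]
      cds <- .sample_cds(glen[i], tilted_codon_prob(s_eff))
      region_seq[i] <- if (signs[i] > 0) cds else revcomp(cds)
    }
  }

  # realized CDS G/C contribution per half, then solve the non-coding skew
  # so each half (or the whole genome) hits the target
  nc_skew_for <- function(sel) {
    gsum <- csum <- 0
    for (i in which(sel & cls == "PCG")) {
      bc <- base_counts(region_seq[i])
      gsum <- gsum + bc[["G"]]; csum <- csum + bc[["C"]]
    }
    nc_len <- sum(glen[sel & cls != "PCG"]) + sum(spacer[sel]) +
      (if (!is.na(cr_after) && any(sel & seq_along(labels) == cr_after)) cr_len else 0)
    gc_nc <- (1 - config$at_content) * nc_len
    tgt <- amp * (if (all(region_sign[sel] > 0)) 1 else -1)
    if (gc_nc <= 0) return(0)
    need <- tgt * (gsum + csum + gc_nc) - (gsum - csum)
    need / gc_nc
  }
  s_nc <- numeric(length(labels))
  if (regime == "bimodal") {
    for (sgn in c(1, -1)) {
      sel <- region_sign == sgn
      if (any(sel)) s_nc[sel] <- nc_skew_for(sel)
    }
  } else {
    s_nc[] <- nc_skew_for(rep(TRUE, length(labels)))
  }

  for (i in seq_along(labels)) {
    if (cls[i] != "PCG")
      region_seq[i] <- .sample_noncoding(glen[i], config$at_content, s_nc[i])
  }

  # assemble: gene, spacer, (control region after rrnS)
  pieces <- character()
  for (i in seq_along(labels)) {
    pieces <- c(pieces, region_seq[i],
                if (spacer[i] > 0)
                  .sample_noncoding(spacer[i], config$at_content, s_nc[i]),
                if (!is.na(cr_after) && i == cr_after)
                  .sample_noncoding(cr_len, config$at_content, s_nc[i]))
  }
  sequence <- paste(pieces, collapse = "")

  feats <- data.frame(label = labels, cls = cls, start = starts,
                      end = starts + glen, strand = signs, wraps = FALSE,
                      stringsAsFactors = FALSE)
  genome <- mitogenome(id, sequence, feats, "circular")
  truth <- list(id = id, regime = regime, amplitude = amp,
                inversions = inversions, trna_losses = config$trna_losses,
                codon_profile = config$codon_profile$name,
                seed_used = seed_used, length = genome$length,
                at_content = config$at_content)
  list(genome = genome, truth = truth)
}

#' Generate a batch of synthetic mitogenomes
#'
#' @param config a [synth_config()].
#' @return list with `genomes` (named list of [mitogenome]s) and `truth`
#'   (named list of per-genome truth records).
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  out <- lapply(seq_len(config$n_genomes), function(i) generate_genome(config, i))
  genomes <- lapply(out, `[[`, "genome")
  truth <- lapply(out, `[[`, "truth")
  names(genomes) <- names(truth) <- vapply(genomes, `[[`, "", "id")
  list(genomes = genomes, truth = truth)
}

#' Generate a two-family synthetic dataset with an outgroup
#'
#' Emulates the family-level mitogenomic contrast seen in velvet worms:
#' group A ("derived") shares one fixed inversion set relative to the
#' ancestral template, a globally positive GC-skew regime and a reduced tRNA
#' complement; group B ("ancestral") keeps the template order, a bimodal
#' regime and a near-complete tRNA set; one outgroup genome keeps the
#' template order with a globally negative regime.
#'
#' @param seed integer seed.
#' @param n_per_family genomes per family (default 4).
#' @param profile_a,profile_b codon-bias profiles for the two families
#'   (default: the same A/T-rich profile, codon usage being conserved across
#'   families).
#' @return list with `genomes`, `truth`, `groups` (named character vector
#'   genome_id -> "A"/"B"/"outgroup"), `tree` (newick string: ingroup star +
#'   outgroup), `outgroup` (id).
#' @export
generate_two_family_dataset <- function(seed, n_per_family = 4,
                                        profile_a = codon_bias_profile(),
                                        profile_b = codon_bias_profile()) {
  losses_a <- c("trnC", "trnY", "trnS1", "trnE", "trnT", "trnP", "trnI", "trnQ")
  cfg_a <- synth_config(n_genomes = n_per_family, seed = seed,
                        regime = "globally_positive", n_inversions = 0,
                        fixed_inversions = .FAMA_INVERSIONS,
                        trna_losses = losses_a, codon_profile = profile_a)
  cfg_b <- synth_config(n_genomes = n_per_family, seed = seed + 1L,
                        regime = "bimodal", n_inversions = 0,
                        trna_losses = c("trnD", "trnG"),
                        codon_profile = profile_b)
  cfg_out <- synth_config(n_genomes = 1, seed = seed + 2L,
                          regime = "globally_negative")

  genomes <- list(); truth <- list()
  for (i in seq_len(n_per_family)) {
    gt <- generate_genome(cfg_a, i, id = paste0("famA_", i))
    genomes[[gt$genome$id]] <- gt$genome
    truth[[gt$genome$id]] <- gt$truth
  }
  for (i in seq_len(n_per_family)) {
    gt <- generate_genome(cfg_b, i, id = paste0("famB_", i))
    genomes[[gt$genome$id]] <- gt$genome
    truth[[gt$genome$id]] <- gt$truth
  }
  gt <- generate_genome(cfg_out, 1, id = "outgroup")
  genomes[[gt$genome$id]] <- gt$genome
  truth[[gt$genome$id]] <- gt$truth

  ids <- names(genomes)
  groups <- setNames(c(rep("A", n_per_family), rep("B", n_per_family),
                       "outgroup"), ids)
  ingroup <- ids[groups != "outgroup"]
  tree <- paste0("((", paste(ingroup, collapse = ","), "),outgroup);")
  list(genomes = genomes, truth = truth, groups = groups, tree = tree,
       outgroup = "outgroup")
}

# The fixed derived arrangement shared by every family-A genome: two block
# inversions on template positions (3..9 spans COX2..trnG, 23..30 spans
# ND6..rrnS), both containing PCGs so the derived state is visible in
# PCG-only orders.
.FAMA_INVERSIONS <- list(c(3L, 9L), c(23L, 30L))

#' Write a synthetic dataset to disk
#'
#' Emits a multi-record GenBank file, a groups TSV, a newick tree and a
#' truth JSON into `dir`.
#'
#' @param dataset result of [generate_two_family_dataset()] (or a list with
#'   `genomes` and `truth`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genbank(dataset$genomes, file.path(dir, "genomes.gb"))
  if (!is.null(dataset$groups)) {
    write.table(data.frame(genome_id = names(dataset$groups),
                           group = unname(dataset$groups)),
                file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(dataset$tree))
    writeLines(dataset$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
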