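# Relative synonymous codon usage under the invertebrate mitochondrial code.
#
# RSCU of codon j in a synonymous family of size n_i with counts x:
#   RSCU_j = x_j / (X_i / n_i),  X_i the family total.
# 1 = no bias; the family mean is always 1 and the family sum equals the
# family size for every observed family. Codons of unobserved amino acids
# are missing, not zero.

.code_cache <- new.env(parent = emptyenv())

#' The invertebrate mitochondrial genetic code (transl_table 5)
#'
#' Loads the shipped code table: the standard code with AGA/AGG -> Ser,
#' ATA -> Met, TGA -> Trp and stops TAA/TAG, giving 62 sense codons in 20
#' synonymous families.
#'
#' @param id genetic code id; only `5` is supported.
#' @return list with `table` (named character: codon -> one-letter amino
#'   acid, stops as `"*"`), `sense` (62 sense codons), `stops`, and
#'   `families` (named list: amino acid -> codon set).
#' @export
genetic_code_table <- function(id = 5) {
  if (!identical(as.integer(id), 5L))
    stop("only the invertebrate mitochondrial code (transl_table 5) is supported")
  if (!is.null(.code_cache$code5)) return(.code_cache$code5)
  path <- system.file("extdata", "transl_table_5.tsv", package = "mitocomp")
  if (!nzchar(path) || !file.exists(path))
    stop("genetic code table fixture missing from package installation")
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (nrow(tab) != 64 || sum(tab$is_stop) != 2)
    stop("corrupt genetic code table fixture")
  code <- setNames(ifelse(tab$is_stop == 1, "*", tab$aa), tab$codon)
  sense <- tab$codon[tab$is_stop == 0]
  fams <- split(sense, code[sense])
  out <- list(table = code, sense = sense,
              stops = tab$codon[tab$is_stop == 1], families = fams)
  .code_cache$code5 <- out
  out
}

#' Pooled codon counts of a set of coding sequences
#'
#' Splits each CDS into triplets and pools the counts. Stop codons and
#' codons containing ambiguous bases are excluded from the sense-codon
#' counts but reported in attributes `stop_counts` and `n_ambiguous`.
#'
#' @param cds_set character vector (or list) of coding sequences, each with
#'   length a multiple of 3 (as guaranteed by [extract_cds()]).
#' @param code a genetic code from [genetic_code_table()].
#' @return named integer vector over the 62 sense codons.
#' @examples
#' codon_counts("ATGAAATAA")
#' @export
codon_counts <- function(cds_set, code = genetic_code_table(5)) {
  cds_set <- unlist(cds_set)
  if (!length(cds_set)) stop("empty CDS set")
  stopifnot(all(nchar(cds_set) %% 3 == 0))
  cods <- unlist(lapply(toupper(cds_set), function(s) {
    n <- nchar(s)
    substring(s, seq(1, n, 3), seq(3, n, 3))
  }))
  clean <- grepl("^[ACGT]{3}$", cods)
  tab <- table(factor(cods[clean], levels = names(code$table)))
  out <- setNames(as.integer(tab[code$sense]), code$sense)
  attr(out, "stop_counts") <- setNames(as.integer(tab[code$stops]), code$stops)
  attr(out, "n_ambiguous") <- sum(!clean)
  out
}

#' Relative synonymous codon usage
#'
#' `RSCU_j = x_j / (X_i / n_i)` for codon `j` of family `i` with family size
#' `n_i` and total `X_i`. Codons of unobserved amino acids (`X_i = 0`) are
#' `NA` (missing, not zero); a codon used exclusively within its family gets
#' the family size.
#'
#' @param counts named counts over sense codons (as from [codon_counts()]).
#' @param code a genetic code from [genetic_code_table()].
#' @return named numeric vector of RSCU values over the 62 sense codons.
#' @examples
#' x <- codon_counts(strrep("TTTTTC", 10))
#' rscu(x)[c("TTT", "TTC")]
#' @export
rscu <- function(counts, code = genetic_code_table(5)) {
  stopifnot(all(code$sense %in% names(counts)))
  x <- counts[code$sense]
  if (any(x < 0)) stop("negative codon counts")
  out <- setNames(rep(NA_real_, length(code$sense)), code$sense)
  for (fam in code$families) {
    tot <- sum(x[fam])
    if (tot == 0) next
    out[fam] <- x[fam] / (tot / length(fam))
  }
  out
}

#' Species-by-codon RSCU matrix
#'
#' One row per genome: codon counts pooled over all extractable PCGs, then
#' converted to RSCU. Genomes without any extractable PCG are skipped with a
#' warning.
#'
#' @param genomes a [mitogenome] or list of them.
#' @param code a genetic code from [genetic_code_table()].
#' @return numeric matrix (genomes x 62 sense codons), `NA` for codons of
#'   amino acids unobserved in a genome.
#' @export
rscu_matrix <- function(genomes, code = genetic_code_table(5)) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1)
  rows <- list()
  for (g in genomes) {
    pcg_i <- which(g$features$cls == "PCG" &
                   g$features$label %in% .PCG_LABELS)
    cds <- character()
    for (i in pcg_i) {
      s <- tryCatch(extract_cds(g, i), error = function(e) NULL)
      if (!is.null(s)) cds <- c(cds, s)
    }
    if (!length(cds)) {
      warning("genome ", g$id, ": no extractable PCGs; row skipped")
      next
    }
    rows[[g$id]] <- rscu(codon_counts(cds, code), code)
  }
  if (!length(rows)) stop("no genome yielded an RSCU row")
  do.call(rbind, rows)
}

#' Masked log10 view of an RSCU matrix
#'
#' Presentation transform for heatmaps: log10 of the RSCU values with zeros
#' and missing cells masked as `NA` (never `-Inf`).
#'
#' @param mat matrix from [rscu_matrix()].
#' @return matrix of the same shape.
#' @export
rscu_log10 <- function(mat) {
  out <- mat
  out[!is.na(out) & out == 0] <- NA_real_
  log10(out)
}

#' Principal component analysis of an RSCU matrix
#'
#' Missing cells are imputed with the column mean, columns are centered (not
#' variance-scaled) and scores computed by singular value decomposition.
#' Component signs are fixed by forcing the largest-magnitude loading of
#' each component positive, so results are deterministic.
#'
#' @param mat matrix from [rscu_matrix()] with at least 3 rows.
#' @return list with `scores` (genomes x components), `loadings`,
#'   `explained` (variance fractions, non-increasing).
#' @export
rscu_pca <- function(mat) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 3) stop("PCA requires at least 3 genomes")
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (any(miss)) {
      cm <- mean(mat[!miss, j])
      mat[miss, j] <- if (is.nan(cm)) 0 else cm
    }
  }
  p <- prcomp(mat, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  explained <- if (tot > 0) p$sdev^2 / tot else rep(0, length(p$sdev))
  scores <- p$x
  loadings <- p$rotation
  for (k in seq_len(ncol(loadings))) {
    i_max <- which.max(abs(loadings[, k]))
    if (loadings[i_max, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, loadings = loadings, explained = explained)
}
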