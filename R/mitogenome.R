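# The annotated-mitogenome container and coordinate machinery.
#
# Coordinates are 0-based half-open internally; GenBank / feature-table I/O
# converts at the boundary. A feature that spans the origin of a circular
# genome is stored once with wraps = TRUE (start is its 0-based start, end the
# exclusive end of the wrapped tail, end <= start).

#' Construct an annotated mitogenome
#'
#' @param id record/species identifier (single string).
#' @param sequence nucleotide sequence, a single string over A/C/G/T/N
#'   (case-insensitive; other IUPAC letters are tolerated and treated as
#'   ambiguous by the composition functions).
#' @param features data.frame with columns `label` (canonical gene name or
#'   `"unknown"`), `cls` (`"PCG"`, `"tRNA"`, `"rRNA"`), `start` (0-based
#'   inclusive), `end` (0-based exclusive), `strand` (+1/-1) and optionally
#'   `wraps` (logical; features crossing the origin of a circular genome).
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `mitogenome`: a list with elements `id`,
#'   `sequence`, `topology`, `features` (sorted by `start`) and `length`.
#' @examples
#' g <- mitogenome("toy", "ATGAAATAAACGT",
#'   data.frame(label = "COX1", cls = "PCG", start = 0, end = 9, strand = 1))
#' g$length
#' @export
mitogenome <- function(id, sequence, features, topology = "circular") {
  stopifnot(is.character(id), length(id) == 1,
            is.character(sequence), length(sequence) == 1,
            topology %in% c("circular", "linear"))
  sequence <- toupper(sequence)
  if (is.null(features) || nrow(features) == 0) {
    features <- data.frame(label = character(), cls = character(),
                           start = integer(), end = integer(),
                           strand = integer(), wraps = logical())
  }
  if (is.null(features$wraps)) features$wraps <- FALSE
  features <- features[, c("label", "cls", "start", "end", "strand", "wraps")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.integer(features$strand)
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  g <- structure(list(id = id, sequence = sequence, topology = topology,
                      features = features, length = nchar(sequence)),
                 class = "mitogenome")
  validate_mitogenome(g)
  g
}

#' Validate a mitogenome object
#'
#' Checks the container invariants: stored length equals the sequence length,
#' feature coordinates lie within `[0, length]`, wrapping features occur only
#' on circular genomes, and strands are +1/-1.
#'
#' @param g a [mitogenome].
#' @return `g`, invisibly; errors describe the first violated invariant.
#' @export
validate_mitogenome <- function(g) {
  stopifnot(inherits(g, "mitogenome"))
  if (g$length != nchar(g$sequence))
    stop("length field does not match sequence length for ", g$id)
  f <- g$features
  if (nrow(f)) {
    if (any(is.na(f$start)) || any(is.na(f$end)))
      stop("NA coordinates in features of ", g$id)
    if (any(f$start < 0 | f$start >= g$length))
      stop("feature start out of [0, length) in ", g$id)
    if (any(f$end <= 0 | f$end > g$length))
      stop("feature end out of (0, length] in ", g$id)
    if (any(!f$wraps & f$end <= f$start))
      stop("non-wrapping feature with end <= start in ", g$id)
    if (any(f$wraps) && g$topology != "circular")
      stop("wrapping feature on a linear genome in ", g$id)
    if (!all(f$strand %in% c(-1L, 1L)))
      stop("feature strand must be +1 or -1 in ", g$id)
  }
  invisible(g)
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %d bp, %s, %d features (%d PCG, %d tRNA, %d rRNA)\n",
              x$id, x$length, x$topology, nrow(x$features),
              sum(x$features$cls == "PCG"), sum(x$features$cls == "tRNA"),
              sum(x$features$cls == "rRNA")))
  invisible(x)
}

# span length of features, wrap-aware
.feature_span <- function(g, f = g$features) {
  ifelse(f$wraps, (g$length - f$start) + f$end, f$end - f$start)
}

#' Reverse complement of a nucleotide string
#' @param s single nucleotide string.
#' @return the reverse complement (case preserved as upper).
#' @export
revcomp <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  chartr("ACGTUNRYSWKMBDHV", "TGCAANYRSWMKVHDB",
         paste(rev(strsplit(toupper(s), "", fixed = TRUE)[[1]]), collapse = ""))
}

# substring of the genome covering [start, end) with wrap handling
.span_seq <- function(g, start, end, wraps) {
  if (!wraps) return(substr(g$sequence, start + 1, end))
  paste0(substr(g$sequence, start + 1, g$length), substr(g$sequence, 1, end))
}

#' Extract the strand-corrected coding sequence of a protein-coding feature
#'
#' Returns the nucleotide sequence of a PCG feature read in coding
#' orientation: reverse-complemented when the feature is on the minus strand
#' and concatenated across the origin for wrapping features. Trailing 1-2
#' bases of an incomplete stop codon are trimmed so the result length is a
#' multiple of 3.
#'
#' @param genome a [mitogenome].
#' @param feature either a row index into `genome$features`, a canonical PCG
#'   label, or a one-row data.frame from `genome$features`.
#' @return a single nucleotide string with `nchar` a multiple of 3.
#' @examples
#' g <- mitogenome("toy", "ATGAAATAAACGT",
#'   data.frame(label = "COX1", cls = "PCG", start = 0, end = 9, strand = 1))
#' extract_cds(g, "COX1")
#' @export
extract_cds <- function(genome, feature) {
  stopifnot(inherits(genome, "mitogenome"))
  if (is.character(feature)) {
    i <- which(genome$features$label == feature & genome$features$cls == "PCG")
    if (length(i) != 1)
      stop("feature ", feature, " not found (or duplicated) in ", genome$id)
    f <- genome$features[i, ]
  } else if (is.numeric(feature)) {
    f <- genome$features[feature, ]
  } else {
    f <- as.data.frame(feature)
  }
  if (f$cls != "PCG") stop("extract_cds requires a PCG feature")
  s <- .span_seq(genome, f$start, f$end, isTRUE(f$wraps))
  if (f$strand < 0) s <- revcomp(s)
  extra <- nchar(s) %% 3
  if (extra > 0) s <- substr(s, 1, nchar(s) - extra)
  if (nchar(s) < 6)
    stop("degenerate CDS (<6 bases after trimming) for ", f$label,
         " in ", genome$id)
  s
}

# Reverse-complement a whole genome, remapping features.
.revcomp_genome <- function(g) {
  L <- g$length
  f <- g$features
  if (nrow(f)) {
    new_start <- ifelse(f$wraps, L - f$end, L - f$end)
    new_end <- L - f$start
    f$start <- as.integer(new_start)
    f$end <- as.integer(new_end)
    f$strand <- -f$strand
    # wraps flag is preserved: a wrapping span stays wrapping, coords above
    # already follow the reversed coordinate map x -> L - 1 - x
    f <- f[order(f$start), , drop = FALSE]
  }
  mitogenome(g$id, revcomp(g$sequence), f, g$topology)
}

# Rotate a circular genome so that position r becomes position 0.
.rotate_genome <- function(g, r) {
  stopifnot(g$topology == "circular")
  L <- g$length
  r <- r %% L
  if (r == 0) return(g)
  seq2 <- paste0(substr(g$sequence, r + 1, L), substr(g$sequence, 1, r))
  f <- g$features
  if (nrow(f)) {
    span <- .feature_span(g)
    new_start <- (f$start - r) %% L
    new_end <- new_start + span
    f$wraps <- new_end > L
    f$end <- as.integer(ifelse(f$wraps, new_end - L, new_end))
    f$start <- as.integer(new_start)
    f <- f[order(f$start), , drop = FALSE]
  }
  mitogenome(g$id, seq2, f, g$topology)
}

#' Re-orient a circular genome to start at COX1 on the plus strand
#'
#' Standardizes orientation for cross-species comparison: if COX1 lies on the
#' minus strand the whole genome is reverse-complemented, then the genome is
#' rotated so the COX1 feature starts at position 0. Linear genomes are
#' returned unchanged (with a warning if reorientation was impossible).
#'
#' @param g a [mitogenome] containing a COX1 feature.
#' @return the re-oriented [mitogenome].
#' @export
anchor_genome <- function(g) {
  stopifnot(inherits(g, "mitogenome"))
  i <- which(g$features$label == "COX1")
  if (length(i) == 0) stop("cannot anchor ", g$id, ": no COX1 feature")
  if (length(i) > 1) stop("cannot anchor ", g$id, ": duplicated COX1")
  if (g$topology != "circular") {
    warning("genome ", g$id, " is linear; returned unrotated")
    return(g)
  }
  if (g$features$strand[i] < 0) {
    g <- .revcomp_genome(g)
    i <- which(g$features$label == "COX1")
  }
  .rotate_genome(g, g$features$start[i])
}
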