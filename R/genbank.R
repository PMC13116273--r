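# GenBank flat-file, FASTA and feature-table I/O.
#
# GenBank records are parsed/written directly (LOCUS topology, CDS/tRNA/rRNA
# features with gene/product qualifiers, complement() and origin-spanning
# join() locations). Coordinates convert between GenBank 1-based inclusive
# and the internal 0-based half-open convention at this boundary; a join()
# across the origin collapses to one wrapping feature.

.GB_CLS_TO_KEY <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")
.GB_KEY_TO_CLS <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")

# ---- writing ---------------------------------------------------------------

.gb_location <- function(g, f) {
  loc <- if (isTRUE(f$wraps)) {
    sprintf("join(%d..%d,%d..%d)", f$start + 1, g$length, 1, f$end)
  } else {
    sprintf("%d..%d", f$start + 1, f$end)
  }
  if (f$strand < 0) loc <- sprintf("complement(%s)", loc)
  loc
}

.gb_record <- function(g) {
  lines <- character()
  lines <- c(lines, sprintf("LOCUS       %-16s %d bp    DNA     %-8s INV 01-JAN-2026",
                            g$id, g$length, g$topology))
  lines <- c(lines, sprintf("DEFINITION  %s mitochondrion.", g$id))
  lines <- c(lines, sprintf("ACCESSION   %s", g$id))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  lines <- c(lines, sprintf("     source          1..%d", g$length),
             sprintf("                     /organism=\"%s\"", g$id))
  f <- g$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      key <- .GB_CLS_TO_KEY[[f$cls[i]]]
      lines <- c(lines,
                 sprintf("     %-15s %s", key, .gb_location(g, f[i, ])),
                 sprintf("                     /gene=\"%s\"", f$label[i]))
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(g$sequence)
  starts <- seq(1, nchar(s), by = 60)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59, nchar(s)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", st, paste(groups, collapse = " ")))
  }
  c(lines, "//")
}

#' Write mitogenomes to a GenBank flat file
#'
#' @param genomes a [mitogenome] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_genbank()]
#' @export
write_genbank <- function(genomes, path) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  out <- unlist(lapply(genomes, .gb_record))
  writeLines(out, path)
  invisible(path)
}

# ---- reading ---------------------------------------------------------------

.parse_location <- function(loc, L, lineno) {
  strand <- 1L
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "..", fixed = TRUE)[[1]]))
    if (length(rng) != 2 || rng[[1]][2] != L || rng[[2]][1] != 1)
      stop("unsupported join() location near line ", lineno, ": ", loc)
    start <- rng[[1]][1] - 1L
    end <- rng[[2]][2]
    wraps <- TRUE
  } else {
    ab <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
    if (length(ab) != 2 || any(is.na(ab)))
      stop("malformed location near line ", lineno, ": ", loc)
    start <- ab[1] - 1L
    end <- ab[2]
  }
  list(start = start, end = end, strand = strand, wraps = wraps)
}

.parse_record <- function(lines, offset) {
  locus <- lines[1]
  if (!grepl("^LOCUS", locus))
    stop("malformed GenBank header at line ", offset, ": expected LOCUS")
  toks <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]]
  id <- toks[1]
  bp_i <- which(toks == "bp")
  if (length(bp_i) != 1 || bp_i < 2)
    stop("malformed LOCUS line at line ", offset, ": missing '<n> bp'")
  L <- as.integer(toks[bp_i - 1])
  topology <- if ("circular" %in% toks) "circular" else "linear"

  ori <- grep("^ORIGIN", lines)[1]
  if (is.na(ori)) stop("record ", id, ": missing ORIGIN section")
  seq_lines <- lines[(ori + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != L)
    stop("record ", id, ": LOCUS length ", L, " != sequence length ",
         nchar(sequence))

  feat_i <- grep("^FEATURES", lines)[1]
  feats <- list()
  if (!is.na(feat_i)) {
    block <- lines[(feat_i + 1):(ori - 1)]
    # a new feature starts at column 6 with a non-blank key
    is_key <- grepl("^ {5}\\S", block)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      hdr <- block[idx[k]]
      key <- sub("^\\s+", "", substr(hdr, 1, 20))
      key <- trimws(key)
      if (!key %in% names(.GB_KEY_TO_CLS)) next
      body_end <- if (k < length(idx)) idx[k + 1] - 1 else length(block)
      body <- block[idx[k]:body_end]
      loc <- trimws(substr(hdr, 21, nchar(hdr)))
      # location may continue on following lines until the first qualifier
      j <- 2
      while (j <= length(body) && !grepl("^\\s+/", body[j])) {
        loc <- paste0(loc, trimws(body[j])); j <- j + 1
      }
      quals <- body[grepl("^\\s+/", body)]
      getq <- function(name) {
        m <- grep(paste0("^\\s+/", name, "="), quals, value = TRUE)
        if (!length(m)) return(NA_character_)
        gsub("\"", "", sub(paste0("^\\s+/", name, "="), "", m[1]))
      }
      gene <- getq("gene")
      if (is.na(gene)) gene <- getq("product")
      anticodon <- getq("codon_anticodon")
      pl <- .parse_location(loc, L, offset + feat_i + idx[k] - 1)
      if (pl$end > L || pl$start >= L)
        stop("record ", id, ": feature beyond sequence bounds: ", loc)
      cls_annot <- .GB_KEY_TO_CLS[[key]]
      raw <- if (is.na(gene)) "unannotated" else gene
      if (!is.na(anticodon) && cls_annot == "tRNA" &&
          !grepl("\\(", raw))
        raw <- paste0(raw, "(", tolower(anticodon), ")")
      norm <- normalize_label(raw, cls_annot)
      cls <- if (is.na(norm$cls[1])) cls_annot else norm$cls[1]
      feats[[length(feats) + 1]] <- data.frame(
        label = norm$label[1], cls = cls, start = pl$start, end = pl$end,
        strand = pl$strand, wraps = pl$wraps, stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  if (!is.null(features) && any(features$label == "unknown"))
    warning("record ", id, ": ", sum(features$label == "unknown"),
            " feature(s) with unrecognized names kept as 'unknown'")
  mitogenome(id, sequence, features, topology)
}

#' Read annotated mitogenomes from a GenBank flat file
#'
#' Parses one [mitogenome] per LOCUS record. CDS/tRNA/rRNA features are kept;
#' gene names are normalized via [normalize_label()] (using the `/gene` then
#' `/product` qualifier); `complement()` and origin-spanning `join()`
#' locations are supported, the latter collapsing to a single wrapping
#' feature. Topology is taken from the LOCUS line.
#'
#' @param path path to a GenBank flat file (possibly multi-record).
#' @return a named list of [mitogenome] objects.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) stop("no GenBank record terminator (//) found in ", path)
  starts <- c(1, head(ends, -1) + 1)
  recs <- lapply(seq_along(ends), function(i) {
    chunk <- lines[starts[i]:ends[i]]
    chunk <- chunk[nzchar(trimws(chunk)) | grepl("^//", chunk)]
    .parse_record(chunk, starts[i])
  })
  names(recs) <- vapply(recs, `[[`, "", "id")
  recs
}

# ---- FASTA + feature table -------------------------------------------------

#' Write genome sequences to FASTA
#' @param genomes a [mitogenome] or list of them.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_mito_fasta <- function(genomes, path) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(ss) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a feature table
#'
#' Tab-separated table with columns `id`, `label`, `cls`, `start`, `end`,
#' `strand`, `topology`; coordinates are 1-based inclusive in the file (a
#' wrapping feature is written with end < start).
#'
#' @param genomes a [mitogenome] or list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genomes, path) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  rows <- do.call(rbind, lapply(genomes, function(g) {
    f <- g$features
    data.frame(id = g$id, label = f$label, cls = f$cls,
               start = f$start + 1L, end = f$end,
               strand = ifelse(f$strand > 0, "+", "-"),
               topology = g$topology, stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read mitogenomes from FASTA plus feature table
#'
#' @param fasta path to a FASTA of genome sequences (names = ids).
#' @param table path to a feature-table TSV as written by
#'   [write_feature_table()] (1-based inclusive coordinates; end < start
#'   marks an origin-wrapping feature).
#' @return a named list of [mitogenome] objects.
#' @export
read_feature_table <- function(fasta, table) {
  ss <- Biostrings::readDNAStringSet(fasta)
  tab <- read.table(table, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  lapply_names <- names(ss)
  out <- lapply(lapply_names, function(id) {
    f <- tab[tab$id == id, , drop = FALSE]
    topology <- if (nrow(f)) f$topology[1] else "circular"
    feats <- if (nrow(f)) {
      data.frame(label = f$label, cls = f$cls,
                 start = f$start - 1L, end = f$end,
                 strand = ifelse(f$strand == "+", 1L, -1L),
                 wraps = f$end <= f$start - 1L, stringsAsFactors = FALSE)
    } else NULL
    mitogenome(id, as.character(ss[[id]]), feats, topology)
  })
  names(out) <- lapply_names
  out
}
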