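# Canonical mitochondrial gene vocabulary and gene-name normalization.
#
# All downstream modules (gene order, tRNA scoring, RSCU) operate on one
# canonical set of labels: 13 protein-coding genes, 2 rRNAs and 22 tRNAs
# (leucine split into trnL1 (CUN) / trnL2 (UUR) and serine into trnS1 (AGN) /
# trnS2 (UCN), matching anticodon families).

.PCG_LABELS <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                 "COX1", "COX2", "COX3", "CYTB", "ATP6", "ATP8")
.RRNA_LABELS <- c("rrnL", "rrnS")
.TRNA_LABELS <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnE", "trnQ",
                  "trnG", "trnH", "trnI", "trnL1", "trnL2", "trnK", "trnM",
                  "trnF", "trnP", "trnS1", "trnS2", "trnT", "trnW", "trnY",
                  "trnV")

#' Canonical mitochondrial gene vocabulary
#'
#' The canonical label sets all analyses are expressed in: the 13 metazoan
#' mitochondrial protein-coding genes, the two rRNAs (`rrnL` = 16S,
#' `rrnS` = 12S) and the 22 canonical tRNAs with the leucine (CUN/UUR) and
#' serine (AGN/UCN) isoacceptors distinguished.
#'
#' @return A list with character vectors `pcgs` (13), `rrnas` (2),
#'   `trnas` (22).
#' @examples
#' lengths(canonical_vocabulary())
#' @export
canonical_vocabulary <- function() {
  list(pcgs = .PCG_LABELS, rrnas = .RRNA_LABELS, trnas = .TRNA_LABELS)
}

.AA3_TO_1 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C",
               glu = "E", gln = "Q", gly = "G", his = "H", ile = "I",
               leu = "L", lys = "K", met = "M", phe = "F", pro = "P",
               ser = "S", thr = "T", trp = "W", tyr = "Y", val = "V")

# maps a single-letter amino acid (other than L/S) to its canonical tRNA label
.aa_to_trna <- function(aa) {
  lab <- paste0("trn", aa)
  if (lab %in% .TRNA_LABELS) lab else NA_character_
}

# Disambiguate leucine/serine isoacceptors from an anticodon or codon-family
# token such as "tag", "uaa", "uur", "cun", "ucn", "agn".
.leu_ser_iso <- function(aa, token) {
  token <- tolower(gsub("[^a-zA-Z]", "", token))
  token <- chartr("u", "t", token)
  if (aa == "L") {
    if (token %in% c("ttr", "tta", "ttg")) return("trnL2")     # codon family UUR
    if (token %in% c("ctn", "ctt", "ctc", "cta", "ctg")) return("trnL1")
    if (nchar(token) == 3 && substr(token, 2, 3) == "aa") return("trnL2") # anticodon UAA/CAA
    if (nchar(token) == 3 && substr(token, 2, 3) == "ag") return("trnL1") # anticodon NAG
    return("trnL?")
  }
  if (aa == "S") {
    if (token %in% c("tcn", "tct", "tcc", "tca", "tcg")) return("trnS2") # codon family UCN
    if (token %in% c("agn", "agt", "agc", "aga", "agg", "agy", "agr")) return("trnS1")
    if (nchar(token) == 3 && substr(token, 2, 3) == "ga") return("trnS2") # anticodon UGA
    if (nchar(token) == 3 && substr(token, 2, 3) %in% c("ct", "cu")) return("trnS1") # anticodon NCU
    return("trnS?")
  }
  NA_character_
}

.normalize_one <- function(raw, cls = NA_character_) {
  stopifnot(is.character(raw), nzchar(raw))
  s <- trimws(raw)
  low <- tolower(s)
  compact <- gsub("[^a-z0-9()]", "", low)

  # already canonical?
  if (s %in% .PCG_LABELS) return(list(label = s, cls = "PCG"))
  if (s %in% .RRNA_LABELS) return(list(label = s, cls = "rRNA"))
  if (s %in% .TRNA_LABELS) return(list(label = s, cls = "tRNA"))

  # --- protein-coding genes -------------------------------------------------
  pcg <- NA_character_
  if (grepl("^(cox?|co)([123i]+)$", compact)) {
    m <- sub("^(cox?|co)", "", compact)
    n <- switch(m, "1" = 1, "i" = 1, "2" = 2, "ii" = 2, "3" = 3, "iii" = 3, NA)
    if (!is.na(n)) pcg <- paste0("COX", n)
  } else if (grepl("cytochromecoxidasesubunit", compact)) {
    m <- sub(".*subunit", "", compact)
    n <- switch(m, "1" = 1, "i" = 1, "2" = 2, "ii" = 2, "3" = 3, "iii" = 3, NA)
    if (!is.na(n)) pcg <- paste0("COX", n)
  } else if (grepl("^(nad|nd)(\\d)l?$", compact)) {
    num <- sub("^(nad|nd)", "", compact)
    pcg <- paste0("ND", toupper(num))
  } else if (grepl("nadhdehydrogenasesubunit", compact)) {
    pcg <- paste0("ND", toupper(sub(".*subunit", "", compact)))
  } else if (compact %in% c("cytb", "cob", "cb") || grepl("cytochromeb$", compact)) {
    pcg <- "CYTB"
  } else if (grepl("^atp(ase)?([68])$", compact) ||
             grepl("atpsynthase(f0)?subunit[68]$", compact)) {
    pcg <- paste0("ATP", sub(".*([68])$", "\\1", compact))
  }
  if (!is.na(pcg) && pcg %in% .PCG_LABELS) return(list(label = pcg, cls = "PCG"))

  # --- rRNAs ----------------------------------------------------------------
  if (grepl("^(rrnl|16s.*|lrrna|lsu.*|largesubunitribosomalrna)$", compact) ||
      grepl("^16s", compact))
    return(list(label = "rrnL", cls = "rRNA"))
  if (grepl("^(rrns|12s.*|srrna|ssu.*|smallsubunitribosomalrna)$", compact) ||
      grepl("^12s", compact))
    return(list(label = "rrnS", cls = "rRNA"))

  # --- tRNAs ----------------------------------------------------------------
  # forms: trnX, trnX1/2, trnX(nnn), trna-Xxx, trna-Xxx (NNN), tRNA-Leu(UUR)
  m <- regmatches(compact, regexec("^trn([a-z])([12]?)(\\(([a-z]{3})\\))?$", compact))[[1]]
  if (length(m)) {
    aa <- toupper(m[2]); iso <- m[3]; anti <- m[5]
    if (aa %in% c("L", "S")) {
      if (iso %in% c("1", "2")) {
        lab <- paste0("trn", aa, iso)
        return(list(label = lab, cls = "tRNA"))
      }
      lab <- .leu_ser_iso(aa, if (!is.na(anti) && nzchar(anti)) anti else "")
      return(list(label = lab, cls = "tRNA"))
    }
    lab <- .aa_to_trna(aa)
    if (!is.na(lab)) return(list(label = lab, cls = "tRNA"))
  }
  m <- regmatches(compact, regexec("^trna([a-z]{3})([12]?)(\\(([a-z]{3})\\))?$",
                                   compact))[[1]]
  if (length(m) && m[2] %in% names(.AA3_TO_1)) {
    aa <- .AA3_TO_1[[m[2]]]; iso <- m[3]; anti <- m[5]
    if (aa %in% c("L", "S")) {
      if (iso %in% c("1", "2"))
        return(list(label = paste0("trn", aa, iso), cls = "tRNA"))
      lab <- .leu_ser_iso(aa, if (!is.na(anti) && nzchar(anti)) anti else "")
      return(list(label = lab, cls = "tRNA"))
    }
    lab <- .aa_to_trna(aa)
    if (!is.na(lab)) return(list(label = lab, cls = "tRNA"))
  }

  list(label = "unknown",
       cls = if (is.na(cls) || !nzchar(cls)) NA_character_ else cls)
}

#' Normalize a gene or product name onto the canonical vocabulary
#'
#' Maps the common annotation dialects ("COI", "cox1", "cytochrome c oxidase
#' subunit I", "nad4l", "tRNA-Leu(UUR)", "trnS(uga)", "16S ribosomal RNA", ...)
#' onto the canonical labels of [canonical_vocabulary()]. Leucine and serine
#' tRNAs are disambiguated from an explicit 1/2 suffix, an anticodon triplet
#' or a codon-family token; if none is available the tRNA is labeled
#' `"trnL?"`/`"trnS?"` and excluded from presence scoring. Unmappable names
#' return label `"unknown"` with the annotated class carried through; the
#' function never raises on strange input.
#'
#' @param raw character vector of gene/product names.
#' @param cls optional character vector of annotated classes
#'   (`"PCG"`, `"tRNA"`, `"rRNA"`), recycled; used only for unknowns.
#' @return A data.frame with columns `label` and `cls`, one row per input.
#' @examples
#' normalize_label(c("COI", "trnS(uga)", "16S ribosomal RNA", "hypothetical ORF"),
#'                 cls = c(NA, NA, NA, "PCG"))
#' @export
normalize_label <- function(raw, cls = NA_character_) {
  stopifnot(length(raw) >= 1)
  cls <- rep_len(as.character(cls), length(raw))
  out <- mapply(function(r, k) .normalize_one(r, k), raw, cls, SIMPLIFY = FALSE)
  data.frame(label = vapply(out, `[[`, "", "label"),
             cls = vapply(out, `[[`, "", "cls"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# class of a canonical label ("unknown" and trnL?/trnS? -> NA)
.label_class <- function(label) {
  ifelse(label %in% .PCG_LABELS, "PCG",
         ifelse(label %in% .RRNA_LABELS, "rRNA",
                ifelse(label %in% .TRNA_LABELS, "tRNA", NA_character_)))
}
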