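# Nucleotide composition and strand-skew statistics.
#
# AT skew = (A - T)/(A + T), GC skew = (G - C)/(G + C), computed on the
# stored (major) strand. Windowed profiles are computed after COX1 anchoring
# so landscapes are comparable across species; windows whose denominator is
# zero are missing, never zero.

#' Count bases in a sequence
#'
#' Case-insensitive exact counts of A, C, G, T; every other character
#' (N and other IUPAC ambiguity codes) is counted in `other`.
#'
#' @param sequence a single nucleotide string.
#' @return an object of class `base_counts`: named integer vector with
#'   elements `A`, `C`, `G`, `T`, `other`.
#' @examples
#' base_counts("acgtN")
#' @export
base_counts <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) stop("empty sequence")
  x <- utf8ToInt(toupper(sequence))
  n <- length(x)
  cnt <- c(A = sum(x == 65L), C = sum(x == 67L), G = sum(x == 71L),
           T = sum(x == 84L))
  out <- c(cnt, other = n - sum(cnt))
  class(out) <- "base_counts"
  out
}

.as_counts <- function(x) {
  if (inherits(x, "base_counts")) return(x)
  if (is.character(x)) return(base_counts(x))
  stopifnot(is.numeric(x), all(c("A", "C", "G", "T") %in% names(x)))
  if (any(x < 0)) stop("negative base counts")
  x
}

#' AT skew
#'
#' `(A - T)/(A + T)` on the given counts (or sequence). Returns `NA` with a
#' warning when `A + T = 0` (undefined, not zero).
#'
#' @param x a `base_counts` object, a named count vector, or a sequence string.
#' @return numeric in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' at_skew(c(A = 3, C = 0, G = 0, T = 1))
#' @export
at_skew <- function(x) {
  x <- .as_counts(x)
  d <- x[["A"]] + x[["T"]]
  if (d == 0) {
    warning("AT skew undefined: no A or T bases")
    return(NA_real_)
  }
  (x[["A"]] - x[["T"]]) / d
}

#' GC skew
#'
#' `(G - C)/(G + C)` on the given counts (or sequence). Returns `NA` with a
#' warning when `G + C = 0`.
#'
#' @inheritParams at_skew
#' @return numeric in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' gc_skew(c(A = 0, C = 1, G = 3, T = 0))
#' @export
gc_skew <- function(x) {
  x <- .as_counts(x)
  d <- x[["G"]] + x[["C"]]
  if (d == 0) {
    warning("GC skew undefined: no G or C bases")
    return(NA_real_)
  }
  (x[["G"]] - x[["C"]]) / d
}

#' GC content (percent)
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguous bases are excluded from the
#' denominator. Errors on an all-ambiguous sequence.
#'
#' @inheritParams at_skew
#' @return percentage in `[0, 100]`.
#' @export
gc_content <- function(x) {
  x <- .as_counts(x)
  d <- x[["A"]] + x[["C"]] + x[["G"]] + x[["T"]]
  if (d == 0) stop("GC content undefined: no unambiguous bases")
  100 * (x[["G"]] + x[["C"]]) / d
}

# cumulative indicator counts used for O(1) window counting
.cum_counts <- function(sequence) {
  x <- utf8ToInt(toupper(sequence))
  list(A = cumsum(x == 65L), C = cumsum(x == 67L),
       G = cumsum(x == 71L), T = cumsum(x == 84L), n = length(x))
}

# counts in [s, s+w) (0-based) with circular wrap
.window_counts <- function(cc, s, w) {
  L <- cc$n
  e <- s + w
  take <- function(v) {
    if (e <= L) {
      (if (s == 0) v[e] else v[e] - v[s])
    } else {
      (v[L] - v[s]) + v[e - L]
    }
  }
  c(A = take(cc$A), C = take(cc$C), G = take(cc$G), T = take(cc$T))
}

#' Sliding-window skew profile
#'
#' Computes per-window GC and AT skews along the genome. By default the
#' genome is first re-oriented with [anchor_genome()] (COX1 first, plus
#' strand) so profiles are directly comparable across species. Windows
#' advance by `step`; circular genomes wrap past the origin (giving
#' `ceiling(length/step)` windows), linear genomes truncate the series at the
#' last full window. Windows with a zero denominator are recorded as missing
#' (`NA`), and excluded from `fraction_positive`.
#'
#' @param genome a [mitogenome].
#' @param window window size in bases (default 300).
#' @param step step size in bases (default 50).
#' @param anchor re-orient to COX1 first (default TRUE; set FALSE for genomes
#'   without COX1 or to profile the stored orientation).
#' @param hi,lo regime thresholds passed to [classify_regime()].
#' @return an object of class `skew_profile`: list with `genome_id`,
#'   `window`, `step`, `centers` (window midpoints, bases), `gc_skew`,
#'   `at_skew`, `fraction_positive` (share of sign-carrying windows with
#'   positive GC skew) and `regime`.
#' @export
sliding_window_profile <- function(genome, window = 300, step = 50,
                                   anchor = TRUE, hi = 0.75, lo = 0.25) {
  stopifnot(inherits(genome, "mitogenome"), step >= 1)
  if (window > genome$length)
    stop("window (", window, ") exceeds genome length (", genome$length, ")")
  if (anchor) genome <- anchor_genome(genome)
  L <- genome$length
  cc <- .cum_counts(genome$sequence)
  starts <- if (genome$topology == "circular") {
    seq(0, L - 1, by = step)
  } else {
    seq(0, L - window, by = step)
  }
  gc <- at <- numeric(length(starts))
  for (i in seq_along(starts)) {
    w <- .window_counts(cc, starts[i], window)
    gcd <- w[["G"]] + w[["C"]]
    atd <- w[["A"]] + w[["T"]]
    gc[i] <- if (gcd == 0) NA_real_ else (w[["G"]] - w[["C"]]) / gcd
    at[i] <- if (atd == 0) NA_real_ else (w[["A"]] - w[["T"]]) / atd
  }
  signed <- gc[!is.na(gc) & gc != 0]
  fp <- if (length(signed)) mean(signed > 0) else NA_real_
  p <- structure(list(genome_id = genome$id, window = window, step = step,
                      centers = starts + floor(window / 2),
                      gc_skew = gc, at_skew = at,
                      fraction_positive = fp, regime = NA_character_),
                 class = "skew_profile")
  p$regime <- tryCatch(classify_regime(p, hi = hi, lo = lo),
                       error = function(e) NA_character_)
  p
}

#' Classify the GC-skew regime of a windowed profile
#'
#' Let `f` be the fraction of sign-carrying windows (defined, nonzero GC
#' skew) that are positive. The regime is `"globally_positive"` if `f >= hi`,
#' `"globally_negative"` if `f <= lo`, otherwise `"bimodal"` (skew landscape
#' partitioned into positive and negative segments). Defaults `hi = 0.75`,
#' `lo = 0.25` separate the qualitative classes "predominantly positive",
#' "globally negative" and "partitioned almost equally".
#'
#' @param profile a `skew_profile` from [sliding_window_profile()].
#' @param hi,lo classification thresholds on the positive fraction.
#' @return one of `"globally_positive"`, `"globally_negative"`, `"bimodal"`.
#' @export
classify_regime <- function(profile, hi = 0.75, lo = 0.25) {
  stopifnot(inherits(profile, "skew_profile"), lo <= hi)
  gc <- profile$gc_skew
  if (all(is.na(gc))) stop("all windows undefined; cannot classify regime")
  signed <- gc[!is.na(gc) & gc != 0]
  f <- if (length(signed)) mean(signed > 0) else 0.5
  if (f >= hi) "globally_positive"
  else if (f <= lo) "globally_negative"
  else "bimodal"
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile> %s: %d windows (window=%d, step=%d), %s (f+=%.2f)\n",
              x$genome_id, length(x$centers), x$window, x$step,
              x$regime, x$fraction_positive))
  invisible(x)
}

#' @export
plot.skew_profile <- function(x, ...) {
  plot(x$centers, x$gc_skew, type = "l", col = "darkgreen",
       xlab = "position (bp, COX1-anchored)", ylab = "skew",
       main = x$genome_id, ylim = c(-1, 1), ...)
  lines(x$centers, x$at_skew, col = "purple")
  abline(h = 0, lty = 2, col = "grey50")
  legend("topright", c("GC skew", "AT skew"), lty = 1,
         col = c("darkgreen", "purple"), bty = "n", cex = 0.8)
  invisible(x)
}

#' Per-gene composition and skew table
#'
#' Gene-level alternative to the windowed profile: composition of every
#' annotated feature span on the major strand (strand-corrected sequences are
#' deliberately not used here, so the values describe the genome strand the
#' way a windowed profile does).
#'
#' @param genome a [mitogenome].
#' @param anchor re-orient to COX1 first (default TRUE).
#' @return data.frame with one row per feature: `label`, `cls`, `start`,
#'   `length`, `gc_percent`, `gc_skew`, `at_skew`.
#' @export
gene_composition <- function(genome, anchor = TRUE) {
  stopifnot(inherits(genome, "mitogenome"))
  if (anchor) genome <- anchor_genome(genome)
  f <- genome$features
  rows <- lapply(seq_len(nrow(f)), function(i) {
    s <- .span_seq(genome, f$start[i], f$end[i], isTRUE(f$wraps[i]))
    bc <- base_counts(s)
    data.frame(label = f$label[i], cls = f$cls[i], start = f$start[i],
               length = nchar(s),
               gc_percent = gc_content(bc),
               gc_skew = suppressWarnings(gc_skew(bc)),
               at_skew = suppressWarnings(at_skew(bc)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
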