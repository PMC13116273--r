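# Signed circular gene orders and rearrangement statistics.
#
# A gene order is a circular (or linear) signed permutation of canonical
# gene labels. Orders are canonically displayed anchored at COX1 on the plus
# strand; rearrangement is quantified by the breakpoint distance on signed
# adjacencies, where the adjacency (a -> b) is identified with its
# reading-direction mirror (-b -> -a), making the distance invariant to
# rotation and reflection of circular orders.

#' Construct a signed gene order
#'
#' @param genome_id identifier.
#' @param labels character vector of unique gene labels.
#' @param signs integer vector of +1/-1, same length.
#' @param topology `"circular"` or `"linear"`.
#' @param classes character vector recording which feature classes were
#'   included (metadata only).
#' @return object of class `gene_order`.
#' @export
new_gene_order <- function(genome_id, labels, signs,
                           topology = "circular",
                           classes = c("PCG", "rRNA", "tRNA")) {
  stopifnot(length(labels) == length(signs),
            all(signs %in% c(-1, 1)),
            topology %in% c("circular", "linear"))
  dup <- labels[duplicated(labels)]
  if (length(dup)) stop("duplicated gene label(s): ", paste(unique(dup), collapse = ", "))
  structure(list(genome_id = genome_id, labels = as.character(labels),
                 signs = as.integer(signs), topology = topology,
                 classes = classes),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (%s, %d genes): %s\n", x$genome_id, x$topology,
              length(x$labels),
              paste0(ifelse(x$signs > 0, "", "-"), x$labels, collapse = " ")))
  invisible(x)
}

#' @export
format.gene_order <- function(x, ...) {
  paste0(ifelse(x$signs > 0, "", "-"), x$labels, collapse = " ")
}

# Rotate a circular order so position i is first.
.rotate_order <- function(o, i) {
  n <- length(o$labels)
  if (i == 1 || o$topology != "circular") return(o)
  idx <- c(i:n, seq_len(i - 1))
  o$labels <- o$labels[idx]
  o$signs <- o$signs[idx]
  o
}

# Reflect an order: reverse gene sequence and negate all signs
.reflect_order <- function(o) {
  o$labels <- rev(o$labels)
  o$signs <- -rev(o$signs)
  o
}

# Anchor: rotate (and reflect if needed) so the anchor gene is first with +1
.anchor_order <- function(o, anchor = "COX1") {
  i <- match(anchor, o$labels)
  if (is.na(i)) stop("cannot anchor order of ", o$genome_id, ": ", anchor,
                     " not present")
  if (o$topology != "circular") {
    if (o$signs[i] < 0) o <- .reflect_order(o)
    return(o)
  }
  if (o$signs[i] < 0) {
    o <- .reflect_order(o)
    i <- match(anchor, o$labels)
  }
  .rotate_order(o, i)
}

#' Extract the signed gene order of an annotated genome
#'
#' Genes are taken in start-coordinate order, filtered to the requested
#' feature classes, with signs from strand. Features labeled `"unknown"` (or
#' undisambiguated `trnL?`/`trnS?`) are excluded with a warning. When
#' `anchor = TRUE` (default) the circular order is rotated so COX1 comes
#' first, reflecting the whole order (reversal + sign negation) if COX1 lies
#' on the minus strand, so the anchored order always starts `(COX1, +1)`.
#'
#' @param genome a [mitogenome].
#' @param classes feature classes to include (subset of PCG/rRNA/tRNA).
#' @param anchor logical; re-orient the genome to COX1 first (requires a
#'   COX1 feature in the genome, whatever classes are retained).
#' @return a `gene_order`.
#' @export
gene_order <- function(genome, classes = c("PCG", "rRNA", "tRNA"),
                       anchor = TRUE) {
  stopifnot(inherits(genome, "mitogenome"))
  if (anchor) genome <- anchor_genome(genome)
  f <- genome$features
  keep <- f$cls %in% classes
  drop_unknown <- keep & !(f$label %in% c(.PCG_LABELS, .RRNA_LABELS, .TRNA_LABELS))
  if (any(drop_unknown)) {
    warning("excluding ", sum(drop_unknown), " non-canonical feature(s) from the ",
            "gene order of ", genome$id)
    keep <- keep & !drop_unknown
  }
  f <- f[keep, , drop = FALSE]
  o <- new_gene_order(genome$id, f$label, f$strand, genome$topology, classes)
  # anchor_genome() already put COX1 first on plus; when COX1 itself is among
  # the retained classes, canonicalize the order representation too
  if (anchor && "COX1" %in% o$labels) o <- .anchor_order(o, "COX1")
  o
}

# canonical string keys for signed adjacencies; (a,sa)->(b,sb) is identified
# with (b,-sb)->(a,-sa)
.adj_keys_signed <- function(labels, signs, circular) {
  n <- length(labels)
  nxt <- if (circular) c(2:n, 1) else 2:n
  cur <- if (circular) 1:n else 1:(n - 1)
  sg <- function(l, s) paste0(ifelse(s > 0, "+", "-"), l)
  f1 <- paste(sg(labels[cur], signs[cur]), sg(labels[nxt], signs[nxt]))
  f2 <- paste(sg(labels[nxt], -signs[nxt]), sg(labels[cur], -signs[cur]))
  pmin(f1, f2)
}

.adj_keys_unsigned <- function(labels, circular) {
  n <- length(labels)
  nxt <- if (circular) c(2:n, 1) else 2:n
  cur <- if (circular) 1:n else 1:(n - 1)
  paste(pmin(labels[cur], labels[nxt]), pmax(labels[cur], labels[nxt]))
}

#' Adjacency set of a gene order
#'
#' The set of consecutive signed gene pairs; circular orders include the
#' wrap-around pair. In the strand-aware form (default) the adjacency
#' `(a -> b)` is identified with `(-b -> -a)`, so the set is invariant to
#' reflection; the strand-blind form reduces adjacencies to unordered label
#' pairs.
#'
#' @param order a `gene_order`.
#' @param signed strand-aware adjacencies (default TRUE).
#' @return character vector of canonical adjacency keys (length `n` for a
#'   circular order, `n - 1` for linear).
#' @export
adjacency_set <- function(order, signed = TRUE) {
  stopifnot(inherits(order, "gene_order"))
  if (length(order$labels) == 0) stop("empty gene order")
  circ <- order$topology == "circular"
  if (signed) .adj_keys_signed(order$labels, order$signs, circ)
  else .adj_keys_unsigned(order$labels, circ)
}

.check_comparable <- function(a, b) {
  stopifnot(inherits(a, "gene_order"), inherits(b, "gene_order"))
  if (a$topology != b$topology)
    stop("orders have different topologies")
  if (!setequal(a$labels, b$labels)) {
    d <- c(setdiff(a$labels, b$labels), setdiff(b$labels, a$labels))
    stop("orders have different gene sets; symmetric difference: ",
         paste(sort(unique(d)), collapse = ", "))
  }
}

#' Breakpoint distance between two gene orders
#'
#' Number of adjacencies of one order absent from the other:
#' `n - |A(a) intersect A(b)|` for circular orders of `n` genes
#' (`n - 1 - |.|` for linear). Zero iff the orders are identical up to
#' rotation and reflection. The strand-aware distance (default) counts a
#' strand flip without positional change as rearrangement; `signed = FALSE`
#' gives the strand-blind variant.
#'
#' @param a,b `gene_order`s over identical label sets and topology.
#' @param signed strand-aware (default TRUE).
#' @return non-negative integer.
#' @export
breakpoint_distance <- function(a, b, signed = TRUE) {
  .check_comparable(a, b)
  ka <- adjacency_set(a, signed)
  kb <- adjacency_set(b, signed)
  n <- length(a$labels)
  max_adj <- if (a$topology == "circular") n else n - 1
  max_adj - length(intersect(ka, kb))
}

#' Localize rearranged segments of a gene order
#'
#' Both orders are anchored at `(COX1, +1)` and aligned position by position;
#' a gene is displaced when its label or sign differs from the reference at
#' the same anchored position. Rearranged segments are the maximal runs of
#' displaced genes, reported as label intervals of the target order. The
#' result is empty iff the anchored orders coincide (equivalently,
#' [breakpoint_distance()] is 0).
#'
#' @param target,reference `gene_order`s over identical label sets.
#' @param anchor anchor gene label (default `"COX1"`).
#' @return list of character vectors, each the signed labels (e.g. `"-ND1"`)
#'   of one maximal rearranged run in target order.
#' @export
rearranged_segments <- function(target, reference, anchor = "COX1") {
  .check_comparable(target, reference)
  t0 <- .anchor_order(target, anchor)
  r0 <- .anchor_order(reference, anchor)
  displaced <- t0$labels != r0$labels | t0$signs != r0$signs
  if (!any(displaced)) return(list())
  runs <- rle(displaced)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segs <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    idx <- starts[k]:ends[k]
    segs[[length(segs) + 1]] <-
      paste0(ifelse(t0$signs[idx] > 0, "", "-"), t0$labels[idx])
  }
  segs
}

#' Apply a signed inversion to a gene order
#'
#' Reverses the block of positions `i..j` and negates its signs (positions in
#' the order's current linearization; use positions `>= 2` to preserve a
#' COX1 anchor).
#'
#' @param order a `gene_order`.
#' @param i,j 1-based block bounds, `i <= j`.
#' @return the inverted `gene_order`.
#' @export
invert_block <- function(order, i, j) {
  stopifnot(inherits(order, "gene_order"),
            i >= 1, j <= length(order$labels), i <= j)
  idx <- i:j
  order$labels[idx] <- rev(order$labels[idx])
  order$signs[idx] <- -rev(order$signs[idx])
  order
}

#' Write gene orders to TSV
#'
#' Columns: `genome_id`, `position` (1-based in the stored linearization),
#' `label`, `sign`, `cls`, `topology`.
#'
#' @param orders a `gene_order` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(orders, path) {
  if (inherits(orders, "gene_order")) orders <- list(orders)
  rows <- do.call(rbind, lapply(orders, function(o) {
    data.frame(genome_id = o$genome_id, position = seq_along(o$labels),
               label = o$labels, sign = o$signs,
               cls = .label_class(o$labels), topology = o$topology,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene orders from TSV written by [write_gene_orders()]
#' @param path input path.
#' @return named list of `gene_order`s.
#' @export
read_gene_orders <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$genome_id), function(d) {
    d <- d[order(d$position), ]
    cls <- unique(.label_class(d$label))
    new_gene_order(d$genome_id[1], d$label, d$sign, d$topology[1],
                   classes = cls[!is.na(cls)])
  })
  out[unique(tab$genome_id)]
}
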