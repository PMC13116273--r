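# tRNA repertoire scoring and conserved cluster detection.
#
# Presence/absence is scored against the canonical 22-tRNA complement.
# A tRNA cluster is a block of >= 2 consecutive tRNA genes (no intervening
# PCG/rRNA) with identical internal order and signs in every genome of a
# group; reflection-equivalent blocks are merged.

#' tRNA presence/absence matrix
#'
#' One row per genome, one column per canonical tRNA label; a cell is TRUE
#' iff a feature with that canonical label is annotated. Duplicated labels
#' are counted once (with a warning); undisambiguated `trnL?`/`trnS?` and
#' `unknown` features are excluded from scoring.
#'
#' @param genomes a [mitogenome] or list of them.
#' @return logical matrix (genomes x 22) with attribute `row_totals`.
#' @export
trna_presence <- function(genomes) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  ids <- vapply(genomes, `[[`, "", "id")
  m <- matrix(FALSE, nrow = length(genomes), ncol = length(.TRNA_LABELS),
              dimnames = list(ids, .TRNA_LABELS))
  for (i in seq_along(genomes)) {
    f <- genomes[[i]]$features
    labs <- f$label[f$cls == "tRNA" & f$label %in% .TRNA_LABELS]
    if (anyDuplicated(labs))
      warning("genome ", ids[i], ": duplicated tRNA label(s) counted once: ",
              paste(unique(labs[duplicated(labs)]), collapse = ", "))
    m[i, unique(labs)] <- TRUE
  }
  attr(m, "row_totals") <- rowSums(m)
  m
}

# maximal runs of consecutive tRNAs (>= min_len) in a full gene order;
# returns a list of data.frames with labels and signs
.trna_runs <- function(order, min_len = 2) {
  is_t <- .label_class(order$labels) == "tRNA"
  is_t[is.na(is_t)] <- FALSE
  n <- length(is_t)
  if (!any(is_t)) return(list())
  r <- rle(is_t)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    runs[[length(runs) + 1]] <- idx
  }
  # on a circular order a run may wrap: merge first and last runs if both
  # touch the boundary and the order is circular
  if (order$topology == "circular" && length(runs) >= 2) {
    first <- runs[[1]]; last <- runs[[length(runs)]]
    if (first[1] == 1 && last[length(last)] == n && !identical(first, last)) {
      runs[[1]] <- c(last, first)
      runs[[length(runs)]] <- NULL
    }
  }
  runs <- Filter(function(idx) length(idx) >= min_len, runs)
  lapply(runs, function(idx)
    data.frame(label = order$labels[idx], sign = order$signs[idx],
               stringsAsFactors = FALSE))
}

# canonical key of a signed block, merging reflection equivalents
.block_key <- function(labels, signs, ignore_strand = FALSE) {
  if (ignore_strand) {
    fwd <- paste(labels, collapse = ",")
    rev_ <- paste(rev(labels), collapse = ",")
    return(min(fwd, rev_))
  }
  fwd <- paste(paste0(ifelse(signs > 0, "+", "-"), labels), collapse = ",")
  refl <- paste(paste0(ifelse(-rev(signs) > 0, "+", "-"), rev(labels)),
                collapse = ",")
  min(fwd, refl)
}

# all contiguous sub-blocks of length >= 2 of a run, as keys
.run_subblock_keys <- function(run, ignore_strand = FALSE) {
  n <- nrow(run)
  keys <- character()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    keys <- c(keys, .block_key(run$label[i:j], run$sign[i:j], ignore_strand))
  unique(keys)
}

#' Conserved tRNA clusters shared within groups
#'
#' For each group of genomes, finds every maximal block of >= 2 consecutive
#' tRNA genes (no intervening PCG or rRNA gene) that occurs -- with identical
#' internal order and signs, up to reflection -- in every genome of the
#' group. Orders should be tRNA-inclusive full gene orders (all classes), as
#' produced by `gene_order(g)`; detection is on the COX1-anchored
#' orientation.
#'
#' @param orders named list of `gene_order`s covering all grouped genomes.
#' @param groups named character vector or data.frame (`genome_id`, `group`)
#'   mapping genome ids to group identifiers.
#' @param ignore_strand match clusters by label order only (default FALSE:
#'   strand-sensitive).
#' @return data.frame with one row per (group, cluster): columns `group`,
#'   `members` (comma-joined signed tRNA labels), `n_trnas`, and `genomes`
#'   (comma-joined member genome ids).
#' @export
shared_trna_clusters <- function(orders, groups, ignore_strand = FALSE) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$genome_id)
  stopifnot(!is.null(names(groups)))
  miss <- setdiff(names(groups), names(orders))
  if (length(miss)) stop("no gene order for: ", paste(miss, collapse = ", "))
  out <- list()
  for (grp in unique(groups)) {
    ids <- names(groups)[groups == grp]
    if (!length(ids)) stop("empty group ", grp)
    run_sets <- lapply(orders[ids], .trna_runs)
    key_sets <- lapply(run_sets, function(runs)
      unique(unlist(lapply(runs, .run_subblock_keys, ignore_strand))))
    shared <- Reduce(intersect, key_sets)
    if (!length(shared)) next
    # keep maximal shared blocks: enumerate candidate blocks from the first
    # genome's runs and drop blocks whose one-gene extension is also shared
    first_runs <- run_sets[[1]]
    kept <- list()
    for (run in first_runs) {
      n <- nrow(run)
      if (n < 2) next
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        key <- .block_key(run$label[i:j], run$sign[i:j], ignore_strand)
        if (!key %in% shared) next
        left_ok <- i > 1 &&
          .block_key(run$label[(i - 1):j], run$sign[(i - 1):j], ignore_strand) %in% shared
        right_ok <- j < n &&
          .block_key(run$label[i:(j + 1)], run$sign[i:(j + 1)], ignore_strand) %in% shared
        if (left_ok || right_ok) next  # extensible, not maximal
        members <- paste0(ifelse(run$sign[i:j] > 0, "", "-"), run$label[i:j])
        kept[[key]] <- members
      }
    }
    for (key in names(kept)) {
      out[[length(out) + 1]] <- data.frame(
        group = grp, members = paste(kept[[key]], collapse = ","),
        n_trnas = length(kept[[key]]),
        genomes = paste(ids, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(), members = character(),
                      n_trnas = integer(), genomes = character()))
  res <- do.call(rbind, out)
  res[order(res$group, -res$n_trnas, res$members), , drop = FALSE]
}
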