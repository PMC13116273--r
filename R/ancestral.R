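# Ancestral gene-order inference by adjacency parsimony.
#
# Adjacency presence/absence is treated as a character on a rooted species
# tree and resolved Fitch-style (intersection of child sets when nonempty,
# else union). The adjacency set at the ingroup root is then assembled
# greedily into one circular signed tour, preferring adjacencies shared with
# the outgroup, then higher ingroup support, ties broken lexicographically.
# If no full tour can be assembled the outgroup order is returned with a
# fallback flag.

# decode the canonical signed adjacency key back to (a, sa, b, sb)
.decode_adj <- function(key) {
  parts <- strsplit(key, " ", fixed = TRUE)[[1]]
  list(a = substring(parts[1], 2), sa = if (substr(parts[1], 1, 1) == "+") 1L else -1L,
       b = substring(parts[2], 2), sb = if (substr(parts[2], 1, 1) == "+") 1L else -1L)
}

# extremity ids: the adjacency (a,sa)->(b,sb) joins the right end of a
# (head if sa>0 else tail) to the left end of b (tail if sb>0 else head)
.right_ext <- function(g, s) paste0(g, if (s > 0) ":h" else ":t")
.left_ext <- function(g, s) paste0(g, if (s > 0) ":t" else ":h")

# Fitch bottom-up pass over a rooted ape tree; tip_sets is a named list of
# character vectors (adjacency keys). Returns the set at the root node.
.fitch_root_set <- function(tree, tip_sets) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tip_sets[[tree$tip.label[i]]]
  edges <- tree$edge
  for (node in unique(edges[, 1])) {
    kids <- edges[edges[, 1] == node, 2]
    kid_sets <- sets[kids]
    kid_sets <- kid_sets[!vapply(kid_sets, is.null, TRUE)]
    inter <- Reduce(intersect, kid_sets)
    sets[[node]] <- if (length(inter)) inter else unique(unlist(kid_sets))
  }
  root <- setdiff(edges[, 1], edges[, 2])[1]
  sets[[root]]
}

# Greedy circular tour assembly from scored adjacencies. cands is a
# data.frame with columns key, a, sa, b, sb already sorted by priority.
# Returns a gene_order over `genes` or NULL if no full tour was assembled.
.assemble_tour <- function(cands, genes, genome_id) {
  n <- length(genes)
  used_ext <- new.env(parent = emptyenv())
  succ <- new.env(parent = emptyenv())
  parent <- setNames(seq_len(n), genes)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  accepted <- 0L
  for (r in seq_len(nrow(cands))) {
    a <- cands$a[r]; sa <- cands$sa[r]; b <- cands$b[r]; sb <- cands$sb[r]
    e1 <- .right_ext(a, sa); e2 <- .left_ext(b, sb)
    if (!is.null(used_ext[[e1]]) || !is.null(used_ext[[e2]])) next
    ra <- findp(match(a, genes)); rb <- findp(match(b, genes))
    if (ra == rb && accepted < n - 1L) next  # would close a short cycle
    used_ext[[e1]] <- TRUE; used_ext[[e2]] <- TRUE
    parent[ra] <- rb
    # walking forward over e1 lands on b with sign sb; walking forward over
    # the mirror extremity of b lands on a with sign -sa
    succ[[e1]] <- c(b, sb)
    succ[[.right_ext(b, -sb)]] <- c(a, -sa)
    accepted <- accepted + 1L
    if (accepted == n) break
  }
  if (accepted != n) return(NULL)
  labels <- character(n); signs <- integer(n)
  cur <- genes[1]; s <- 1L
  for (i in seq_len(n)) {
    labels[i] <- cur; signs[i] <- s
    nx <- succ[[.right_ext(cur, s)]]
    if (is.null(nx)) return(NULL)
    cur <- nx[1]; s <- as.integer(nx[2])
  }
  if (anyDuplicated(labels)) return(NULL)
  new_gene_order(genome_id, labels, signs, "circular")
}

#' Infer an ancestral gene order by adjacency parsimony
#'
#' Reconstructs the gene order of the ingroup's last common ancestor from a
#' set of circular signed gene orders, a rooted species tree and an outgroup.
#' Adjacency presence is resolved Fitch-style over the ingroup tree
#' (intersection of child sets when nonempty, else union); the root set is
#' assembled greedily into one circular tour, preferring (1) adjacencies in
#' the Fitch root set, (2) adjacencies shared with the outgroup, (3) higher
#' ingroup support, ties broken lexicographically. If no complete tour can be
#' assembled, the outgroup order is returned with attribute
#' `fallback = TRUE`.
#'
#' @param orders named list of circular `gene_order`s (identical label sets)
#'   covering all ingroup taxa and the outgroup.
#' @param tree a rooted tree: an `ape::phylo`, a newick string, or a path to
#'   a newick file. Tip labels must include every id in `orders`. If missing,
#'   a star topology over the ingroup is assumed.
#' @param outgroup id of the outgroup taxon (must be in `orders`).
#' @return a `gene_order` (genome_id `"ancestor"`), anchored at COX1 when
#'   present, with attributes `fallback` (logical) and `support` (named
#'   vector: ingroup taxa containing each adjacency of the result).
#' @export
infer_ancestral_order <- function(orders, tree = NULL, outgroup) {
  stopifnot(is.list(orders), !is.null(names(orders)))
  if (!outgroup %in% names(orders))
    stop("outgroup '", outgroup, "' has no gene order")
  ref <- orders[[1]]
  for (o in orders) .check_comparable(ref, o)
  if (ref$topology != "circular")
    stop("ancestral inference requires circular orders")
  ingroup_ids <- setdiff(names(orders), outgroup)
  if (!length(ingroup_ids)) stop("no ingroup taxa")

  keysets <- lapply(orders, adjacency_set, signed = TRUE)

  # resolve the tree over the ingroup
  if (is.null(tree)) {
    tree <- ape::read.tree(text = paste0("(", paste(ingroup_ids, collapse = ","), ");"))
  } else if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(ingroup_ids, tree$tip.label)
  if (length(miss))
    stop("tree is missing tips: ", paste(miss, collapse = ", "))
  drop <- setdiff(tree$tip.label, ingroup_ids)
  if (length(drop)) {
    if (length(ingroup_ids) == 1) {
      root_set <- keysets[[ingroup_ids]]
    } else {
      tree <- ape::drop.tip(tree, drop)
      root_set <- .fitch_root_set(tree, keysets[ingroup_ids])
    }
  } else {
    root_set <- if (length(ingroup_ids) == 1) keysets[[ingroup_ids]]
                else .fitch_root_set(tree, keysets[ingroup_ids])
  }

  pool_keys <- unique(unlist(keysets))
  support <- vapply(pool_keys, function(k)
    sum(vapply(keysets[ingroup_ids], function(s) k %in% s, TRUE)), 0L)
  in_root <- pool_keys %in% root_set
  in_out <- pool_keys %in% keysets[[outgroup]]
  dec <- lapply(pool_keys, .decode_adj)
  cands <- data.frame(key = pool_keys,
                      a = vapply(dec, `[[`, "", "a"),
                      sa = vapply(dec, `[[`, 1L, "sa"),
                      b = vapply(dec, `[[`, "", "b"),
                      sb = vapply(dec, `[[`, 1L, "sb"),
                      stringsAsFactors = FALSE)
  ord <- order(-in_root, -in_out, -support, pool_keys)
  cands <- cands[ord, , drop = FALSE]

  genes <- sort(ref$labels)
  anc <- .assemble_tour(cands, genes, "ancestor")
  fallback <- is.null(anc)
  if (fallback) {
    anc <- orders[[outgroup]]
    anc$genome_id <- "ancestor"
  }
  if ("COX1" %in% anc$labels) anc <- .anchor_order(anc, "COX1")
  anc_keys <- adjacency_set(anc, signed = TRUE)
  attr(anc, "fallback") <- fallback
  attr(anc, "support") <- setNames(
    vapply(anc_keys, function(k)
      sum(vapply(keysets[ingroup_ids], function(s) k %in% s, TRUE)), 0L),
    anc_keys)
  anc
}
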