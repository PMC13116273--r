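# Pipeline orchestration: composition -> gene order -> tRNA -> codon usage.
#
# compare_mitogenomes() runs every stage over a genome set and returns one
# classed result object; stages are independent, so a failing stage is
# recorded as a warning without aborting the others.

#' Run the full comparative mitogenomics pipeline
#'
#' Computes, for a set of annotated mitogenomes: a per-genome composition
#' table (length, GC%, AT/GC skew, gene-class counts, GC-skew regime);
#' COX1-anchored sliding-window skew profiles; PCG-only signed gene orders
#' with the pairwise breakpoint-distance matrix and, when a tree and
#' outgroup are supplied, the inferred ancestral gene order and per-genome
#' rearranged segments; the tRNA presence matrix and (when groups are
#' supplied) conserved shared tRNA clusters; and the RSCU matrix with PCA.
#'
#' @param genomes a list of [mitogenome] objects (>= 2), or a path to a
#'   GenBank flat file.
#' @param groups optional named character vector or data.frame
#'   (`genome_id`, `group`) for cluster detection.
#' @param tree optional rooted newick tree (string, file or `phylo`)
#'   covering all genomes, for ancestral inference.
#' @param outgroup optional id of the outgroup genome (required for
#'   ancestral inference; excluded from ingroup summaries).
#' @param window,step windowing for skew profiles (bases).
#' @param regime_hi,regime_lo thresholds for [classify_regime()].
#' @param order_classes feature classes used for rearrangement analysis
#'   (default PCG-only).
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return object of class `mito_report`; see the elements `composition`,
#'   `profiles`, `orders`, `distances`, `ancestral`, `segments`,
#'   `trna_presence`, `clusters`, `rscu`, `pca`, `manifest`, `stage_warnings`.
#' @export
compare_mitogenomes <- function(genomes, groups = NULL, tree = NULL,
                                outgroup = NULL, window = 300, step = 50,
                                regime_hi = 0.75, regime_lo = 0.25,
                                order_classes = "PCG", seed = NULL) {
  if (is.character(genomes) && length(genomes) == 1)
    genomes <- read_genbank(genomes)
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 2)
  ids <- vapply(genomes, `[[`, "", "id")
  names(genomes) <- ids
  warnings_log <- list()
  note <- function(stage, msg) {
    warnings_log[[length(warnings_log) + 1]] <<- list(stage = stage,
                                                      message = msg)
  }
  run_stage <- function(stage, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      note(stage, paste("stage failed:", conditionMessage(e)))
      NULL
    })
  }

  # -- composition + skew profiles ------------------------------------------
  profiles <- run_stage("composition", lapply(genomes, function(g)
    sliding_window_profile(g, window = window, step = step,
                           hi = regime_hi, lo = regime_lo)))
  composition <- run_stage("composition", {
    rows <- lapply(genomes, function(g) {
      bc <- base_counts(g$sequence)
      f <- g$features
      prof <- if (!is.null(profiles)) profiles[[g$id]] else NULL
      data.frame(id = g$id, length_bp = g$length,
                 gc_percent = gc_content(bc),
                 at_skew = at_skew(bc), gc_skew = gc_skew(bc),
                 n_pcg = sum(f$cls == "PCG" & f$label %in% .PCG_LABELS),
                 n_trna = sum(f$cls == "tRNA" & f$label %in% .TRNA_LABELS),
                 n_rrna = sum(f$cls == "rRNA" & f$label %in% .RRNA_LABELS),
                 regime = if (is.null(prof)) NA_character_ else prof$regime,
                 fraction_positive = if (is.null(prof)) NA_real_
                                     else prof$fraction_positive,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  # -- gene order -----------------------------------------------------------
  orders <- run_stage("gene_order", lapply(genomes, gene_order,
                                           classes = order_classes))
  full_orders <- run_stage("gene_order", lapply(genomes, gene_order))
  distances <- run_stage("gene_order", {
    if (is.null(orders)) stop("no orders")
    n <- length(orders)
    d <- matrix(0L, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
      dij <- breakpoint_distance(orders[[i]], orders[[j]])
      d[i, j] <- d[j, i] <- dij
    }
    d
  })
  ancestral <- segments <- NULL
  if (!is.null(outgroup)) {
    ancestral <- run_stage("ancestral", {
      if (!outgroup %in% ids) stop("outgroup ", outgroup, " not among genomes")
      infer_ancestral_order(orders, tree, outgroup)
    })
    if (!is.null(ancestral)) {
      segments <- run_stage("ancestral", {
        segs <- lapply(orders[setdiff(ids, outgroup)], function(o)
          rearranged_segments(o, ancestral))
        segs
      })
    }
  } else if (!is.null(tree)) {
    note("ancestral", "tree given without outgroup; ancestral stage skipped")
  }

  # -- tRNA -----------------------------------------------------------------
  presence <- run_stage("trna", trna_presence(genomes))
  clusters <- NULL
  if (!is.null(groups)) {
    clusters <- run_stage("trna", {
      if (is.null(full_orders)) stop("no tRNA-inclusive orders")
      grp <- if (is.data.frame(groups)) setNames(groups$group, groups$genome_id)
             else groups
      grp <- grp[names(grp) %in% ids & grp != "outgroup"]
      shared_trna_clusters(full_orders, grp)
    })
  }

  # -- codon usage ----------------------------------------------------------
  rscu_m <- run_stage("codon_usage", rscu_matrix(genomes))
  pca <- if (!is.null(rscu_m) && nrow(rscu_m) >= 3)
    run_stage("codon_usage", rscu_pca(rscu_m)) else NULL

  manifest <- list(
    package = "mitocomp",
    version = as.character(utils::packageVersion("mitocomp")),
    n_genomes = length(genomes), genome_ids = ids,
    params = list(window = window, step = step, regime_hi = regime_hi,
                  regime_lo = regime_lo, order_classes = order_classes,
                  outgroup = outgroup, seed = seed))

  structure(list(composition = composition, profiles = profiles,
                 orders = orders, full_orders = full_orders,
                 distances = distances, ancestral = ancestral,
                 segments = segments, trna_presence = presence,
                 clusters = clusters, rscu = rscu_m, pca = pca,
                 manifest = manifest, stage_warnings = warnings_log),
            class = "mito_report")
}

#' @export
print.mito_report <- function(x, ...) {
  cat("<mito_report>", x$manifest$n_genomes, "genomes\n")
  if (!is.null(x$composition)) {
    cat("  regimes:", paste(sprintf("%s=%s", x$composition$id,
                                    x$composition$regime), collapse = ", "),
        "\n")
  }
  if (!is.null(x$ancestral)) {
    cat("  ancestral order",
        if (isTRUE(attr(x$ancestral, "fallback"))) "(outgroup fallback):"
        else "(assembled):", format(x$ancestral), "\n")
  }
  if (!is.null(x$pca))
    cat(sprintf("  RSCU PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
                100 * x$pca$explained[1], 100 * x$pca$explained[2]))
  if (length(x$stage_warnings))
    cat("  ", length(x$stage_warnings), "stage warning(s); see $stage_warnings\n")
  invisible(x)
}

#' @export
summary.mito_report <- function(object, ...) {
  cat("Composition (per genome):\n")
  print(object$composition, digits = 3)
  if (!is.null(object$distances)) {
    cat("\nPairwise breakpoint distances (", paste(object$manifest$params$order_classes,
                                                   collapse = "+"), " orders):\n", sep = "")
    print(object$distances)
  }
  if (!is.null(object$segments)) {
    cat("\nRearranged segments vs inferred ancestor:\n")
    for (id in names(object$segments)) {
      s <- object$segments[[id]]
      cat("  ", id, ": ", if (!length(s)) "none"
          else paste(vapply(s, paste, "", collapse = " "), collapse = " | "),
          "\n", sep = "")
    }
  }
  if (!is.null(object$trna_presence)) {
    cat("\ntRNA counts:\n")
    print(attr(object$trna_presence, "row_totals"))
  }
  invisible(object)
}

#' @export
plot.mito_report <- function(x, which = c("skew", "pca"), ...) {
  which <- match.arg(which)
  if (which == "skew") {
    profs <- x$profiles
    if (is.null(profs)) stop("no skew profiles in report")
    old <- par(mfrow = c(length(profs), 1), mar = c(2, 4, 2, 1))
    on.exit(par(old))
    for (p in profs) plot(p)
  } else {
    if (is.null(x$pca)) stop("no PCA in report")
    sc <- x$pca$scores
    plot(sc[, 1], sc[, 2],
         xlab = sprintf("PC1 (%.1f%%)", 100 * x$pca$explained[1]),
         ylab = sprintf("PC2 (%.1f%%)", 100 * x$pca$explained[2]),
         main = "RSCU PCA", pch = 19, ...)
    text(sc[, 1], sc[, 2], rownames(sc), pos = 3, cex = 0.7)
  }
  invisible(x)
}

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e9, format(x, scientific = FALSE),
                sprintf("%.4f", x)))
}

.write_tsv_fixed <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a report bundle to disk
#'
#' Emits `composition.tsv`, `skew_profiles.tsv`, `gene_orders.tsv`,
#' `rearrangement.json`, `trna_presence.tsv`, `trna_clusters.json`,
#' `rscu.tsv`, `rscu_pca.tsv` and `manifest.json` into `dir` (stages absent
#' from the report are skipped). Numeric values are written with 4 decimal
#' places.
#'
#' @param report a `mito_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mito_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  if (!is.null(report$composition))
    .write_tsv_fixed(report$composition, fp("composition.tsv"))
  if (!is.null(report$profiles)) {
    long <- do.call(rbind, lapply(report$profiles, function(p)
      data.frame(genome_id = p$genome_id, window_center = p$centers,
                 gc_skew = p$gc_skew, at_skew = p$at_skew,
                 stringsAsFactors = FALSE)))
    .write_tsv_fixed(long, fp("skew_profiles.tsv"))
  }
  if (!is.null(report$full_orders))
    write_gene_orders(report$full_orders, fp("gene_orders.tsv"))
  if (!is.null(report$distances)) {
    rearr <- list(
      distances = report$distances,
      ancestral = if (!is.null(report$ancestral)) list(
        order = format(report$ancestral),
        fallback = isTRUE(attr(report$ancestral, "fallback"))) else NULL,
      rearranged_segments = if (!is.null(report$segments))
        lapply(report$segments, function(s) lapply(s, paste, collapse = " "))
        else NULL)
    jsonlite::write_json(rearr, fp("rearrangement.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, matrix = "rowmajor")
  }
  if (!is.null(report$trna_presence)) {
    m <- report$trna_presence
    df <- data.frame(genome_id = rownames(m), 1L * m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, fp("trna_presence.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(report$clusters))
    jsonlite::write_json(report$clusters, fp("trna_clusters.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$rscu)) {
    df <- data.frame(genome_id = rownames(report$rscu), report$rscu,
                     check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv_fixed(df, fp("rscu.tsv"))
  }
  if (!is.null(report$pca)) {
    sc <- data.frame(genome_id = rownames(report$pca$scores),
                     report$pca$scores, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .write_tsv_fixed(sc, fp("rscu_pca.tsv"))
    ev <- data.frame(component = paste0("PC", seq_along(report$pca$explained)),
                     explained = report$pca$explained)
    .write_tsv_fixed(ev, fp("rscu_pca_variance.tsv"))
  }
  manifest <- c(report$manifest,
                list(stage_warnings = report$stage_warnings))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
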