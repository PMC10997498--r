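# The chemical-space branch: PCA embedding of ligand fingerprints, annotated
# with best/worst-in-class labels from the ranking branch.

#' PCA embedding of a fingerprint set
#'
#' Centered principal component analysis of the deduplicated fingerprint
#' matrix. Duplicate structures (identical canonical SMILES) are embedded once
#' and mapped back to every identifier, so an over-screened ligand cannot
#' dominate the axes. Components are ordered by explained variance, keeping the
#' standard PCA reading of the axes: highest variance on x, second highest on
#' y.
#'
#' @param fps a \code{\link{fingerprint_set}}.
#' @param n_components number of components to keep (default 2).
#' @return object of class \code{hte_embedding}: \code{coordinates}
#'   (data.frame: id, smiles, pc1, pc2, ..., label), and
#'   \code{explained_variance_ratio} (non-increasing, each in [0, 1]).
#' @export
pca_embed <- function(fps, n_components = 2) {
  stopifnot(inherits(fps, "fingerprint_set"))
  smiles <- attr(fps, "smiles")
  m <- unclass(fps)
  attr(m, "smiles") <- NULL; attr(m, "failed") <- NULL
  attr(m, "radius") <- NULL
  storage.mode(m) <- "double"
  uniq <- !duplicated(smiles)
  if (sum(uniq) < 3) {
    stop("PCA embedding needs at least 3 unique structures (got ",
         sum(uniq), ")")
  }
  mu <- m[uniq, , drop = FALSE]
  keep_dims <- apply(mu, 2, stats::var) > 0
  pc <- stats::prcomp(mu[, keep_dims, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  # map unique-structure coordinates back to every identifier
  pos <- match(smiles, smiles[uniq])
  coords <- pc$x[pos, seq_len(k), drop = FALSE]
  df <- data.frame(id = names(smiles), smiles = unname(smiles),
                   stringsAsFactors = FALSE)
  for (j in seq_len(k)) df[[paste0("pc", j)]] <- unname(coords[, j])
  df$label <- "unranked"
  rownames(df) <- NULL
  structure(list(coordinates = df,
                 explained_variance_ratio = unname(evr[seq_len(k)]),
                 n_unique = sum(uniq)),
            class = "hte_embedding")
}

#' @export
print.hte_embedding <- function(x, ...) {
  cat("Chemical-space embedding:", nrow(x$coordinates), "structure(s),",
      x$n_unique, "unique\n")
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_along(x$explained_variance_ratio),
                    100 * x$explained_variance_ratio), collapse = ", "), "\n")
  tab <- table(x$coordinates$label)
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# resolve a ranking level identifier to a canonical SMILES: the identifier may
# itself be a SMILES, or an alias-dictionary name
.resolve_level_smiles <- function(levels, aliases) {
  hit <- match(tolower(trimws(levels)), tolower(trimws(aliases$name)))
  out <- ifelse(!is.na(hit) & nzchar(aliases$smiles[hit]),
                aliases$smiles[hit], levels)
  canonical_smiles(out)
}

#' Annotate an embedding with best/worst-in-class labels
#'
#' Transfers the Tukey-ranking classes onto the embedded structures. Ranking
#' levels are resolved to structures through the reagent alias dictionary (or
#' taken as SMILES directly); levels that cannot be resolved to an embedded
#' structure are reported in the \code{unresolved} attribute, never silently
#' dropped. Structures absent from the ranking stay \code{"unranked"}.
#'
#' @param emb an \code{hte_embedding}.
#' @param ranking a \code{tukey_ranking} (typically of the ligand category).
#' @param aliases reagent alias dictionary.
#' @return the embedding with \code{label} filled in (best / worst / neutral /
#'   insufficient data / unranked).
#' @export
annotate_embedding <- function(emb, ranking,
                               aliases = default_reagent_aliases()) {
  stopifnot(inherits(emb, "hte_embedding"), inherits(ranking, "tukey_ranking"))
  lv <- ranking$entries$level
  lv_smiles <- .resolve_level_smiles(lv, aliases)
  unresolved <- character(0)
  for (i in seq_along(lv)) {
    target <- emb$coordinates$smiles == lv_smiles[i] |
      emb$coordinates$id == lv[i]
    if (is.na(lv_smiles[i]) || !any(target, na.rm = TRUE)) {
      unresolved <- c(unresolved, lv[i])
      next
    }
    emb$coordinates$label[which(target)] <- ranking$entries$class[i]
  }
  attr(emb, "unresolved") <- unresolved
  emb
}

#' Scatter plot of a chemical-space embedding
#'
#' @param x an \code{hte_embedding}.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{x}.
#' @export
plot.hte_embedding <- function(x, ...) {
  pal <- c(best = "#1b7837", worst = "#b2182b", neutral = "grey55",
           "insufficient data" = "grey80", unranked = "grey85")
  co <- x$coordinates
  col <- pal[co$label]
  col[is.na(col)] <- "grey70"
  graphics::plot(co$pc1, co$pc2, pch = 19, col = col,
                 xlab = sprintf("PC1 (%.1f%%)",
                                100 * x$explained_variance_ratio[1]),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * x$explained_variance_ratio[2]), ...)
  lab <- co$label %in% c("best", "worst")
  if (any(lab)) {
    graphics::text(co$pc1[lab], co$pc2[lab], co$id[lab], pos = 3, cex = 0.7)
  }
  graphics::legend("topright", legend = names(pal), col = pal, pch = 19,
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' Tanimoto similarity heat-map ordering
#'
#' Orders a Tanimoto matrix by hierarchical-clustering leaf order (average
#' linkage on 1 - similarity) so that similar structures sit together in the
#' heat-map; the ordering is returned for reproducibility.
#'
#' @param tm symmetric Tanimoto matrix.
#' @return list with \code{order} (integer permutation) and \code{matrix}
#'   (reordered).
#' @export
tanimoto_heatmap_order <- function(tm) {
  if (nrow(tm) < 3) return(list(order = seq_len(nrow(tm)), matrix = tm))
  hc <- stats::hclust(stats::as.dist(1 - tm), method = "average")
  list(order = hc$order, matrix = tm[hc$order, hc$order, drop = FALSE])
}
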