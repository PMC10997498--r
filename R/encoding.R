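# One-hot encoding of reaction variables and correlation-based column merging.

.variable_categories <- c("halide", "nucleophile", "substrate",
                          "catalyst_metal", "catalyst_system", "ligand",
                          "base", "solvent", "additive", "temperature_bin")

# the record column a category reads its levels from
.category_values <- function(records, category) {
  switch(category,
    temperature_bin = ifelse(is.na(records$temperature), NA_character_,
                             formatC(records$temperature, format = "g")),
    catalyst_system = ifelse(is.na(records$catalyst_metal) &
                               is.na(records$ligand), NA_character_,
                             paste(ifelse(is.na(records$catalyst_metal), "",
                                          records$catalyst_metal),
                                   ifelse(is.na(records$ligand), "",
                                          records$ligand), sep = " | ")),
    records[[category]]
  )
}

#' One-hot encode reaction variables
#'
#' Builds a binary design matrix with one column per observed level per
#' variable category. A record where a role is absent gets an all-zero row
#' segment for that category, so within each (unmerged) category every row sums
#' to 0 or 1. \code{temperature_bin} bins temperature to the observed discrete
#' set points (HTE screens run at few fixed temperatures);
#' \code{catalyst_system} encodes the metal--ligand pair as a single level.
#'
#' @param records reaction table.
#' @param categories variable categories to encode; subset of
#'   halide, nucleophile, substrate, catalyst_metal, catalyst_system, ligand,
#'   base, solvent, additive, temperature_bin.
#' @return object of class \code{hte_design}: list with \code{matrix} (0/1,
#'   rows = reactions), \code{column_meta} (data.frame: name, category, level,
#'   merged_from list-column) and \code{row_ids}.
#' @export
one_hot_encode <- function(records, categories) {
  if (length(categories) == 0) stop("empty category list")
  bad <- setdiff(categories, .variable_categories)
  if (length(bad)) stop("unknown variable categories: ",
                        paste(bad, collapse = ", "))
  cols <- list()
  meta <- list()
  for (cat in categories) {
    v <- .category_values(records, cat)
    levs <- sort(unique(v[!is.na(v)]))
    for (lv in levs) {
      nm <- paste0(cat, "=", lv)
      cols[[nm]] <- as.integer(!is.na(v) & v == lv)
      meta[[nm]] <- data.frame(name = nm, category = cat, level = lv,
                               stringsAsFactors = FALSE)
    }
  }
  mat <- if (length(cols)) {
    do.call(cbind, cols)
  } else {
    matrix(integer(0), nrow = nrow(records), ncol = 0)
  }
  cm <- if (length(meta)) do.call(rbind, meta) else
    data.frame(name = character(0), category = character(0),
               level = character(0), stringsAsFactors = FALSE)
  rownames(cm) <- NULL
  cm$merged_from <- replicate(nrow(cm), character(0), simplify = FALSE)
  structure(list(matrix = mat, column_meta = cm,
                 row_ids = records$reaction_id),
            class = "hte_design")
}

#' @export
print.hte_design <- function(x, ...) {
  cat("HTE design matrix:", nrow(x$matrix), "reactions x",
      ncol(x$matrix), "indicator columns\n")
  tab <- table(x$column_meta$category)
  if (length(tab)) {
    cat("  levels per category:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  merged <- sum(lengths(x$column_meta$merged_from) > 0)
  if (merged) cat("  merged columns:", merged, "\n")
  invisible(x)
}

#' Pairwise Pearson correlation of design-matrix columns
#'
#' On binary indicator columns Pearson's r is the phi coefficient. Constant
#' (all-0 or all-1) columns have undefined correlation and are dropped first
#' with a warning.
#'
#' @param dm an \code{hte_design}.
#' @return symmetric correlation matrix over the non-constant columns.
#' @export
design_correlation <- function(dm) {
  m <- dm$matrix
  if (ncol(m) < 2) stop("correlation needs at least 2 columns")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " constant column(s) from correlation: ",
            paste(colnames(m)[v == 0], collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  if (ncol(m) < 2) stop("fewer than 2 non-constant columns")
  stats::cor(m)
}

# connected components over an undirected adjacency (logical) matrix
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      if (comp[a] > 0) next
      comp[a] <- cur
      queue <- c(queue, which(adj[a, ] & comp == 0))
    }
  }
  comp
}

#' Merge highly correlated design columns
#'
#' Columns whose absolute pairwise Pearson correlation meets the threshold are
#' combined. Merging is applied to the connected components of the
#' \eqn{|r| \ge} threshold graph (so the result is independent of column
#' order). Within a component, members positively correlated with the
#' component's reference column (its first column in name order) are unioned by
#' logical OR; anti-correlated members carry the same information as the
#' complement of that union, so they are absorbed rather than OR'd (OR-ing a
#' column with its own complement would yield a constant, information-free
#' indicator -- the common case being the two levels of a binary category).
#' Provenance of every absorbed column is kept in \code{merged_from}. The
#' default threshold of 0.85 reflects standard practice of collapsing reagents
#' that almost always co-occur (for example a catalyst that is only ever run in
#' one solvent).
#'
#' @param dm an \code{hte_design}.
#' @param threshold correlation threshold in (0, 1].
#' @return a merged \code{hte_design}; idempotent at a fixed threshold.
#' @export
merge_correlated <- function(dm, threshold = 0.85) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  m <- dm$matrix
  if (ncol(m) < 2) return(dm)
  v <- apply(m, 2, stats::var)
  varying <- which(v > 0)
  if (length(varying) < 2) return(dm)
  cc <- suppressWarnings(stats::cor(m[, varying, drop = FALSE]))
  adj <- abs(cc) >= threshold
  diag(adj) <- FALSE
  if (!any(adj)) return(dm)
  comp <- .components(adj | t(adj))
  keep_cols <- list()
  keep_meta <- list()
  # untouched columns (constant, or singleton components) pass through
  done <- rep(FALSE, ncol(m))
  for (k in sort(unique(comp))) {
    members <- varying[comp == k]
    if (length(members) == 1) next
    # order-independent reference: first member by column name
    members <- members[order(colnames(m)[members])]
    ref <- members[1]
    aligned <- members[vapply(members, function(j) {
      suppressWarnings(stats::cor(m[, ref], m[, j])) > 0
    }, logical(1))]
    merged <- as.integer(rowSums(m[, aligned, drop = FALSE]) > 0)
    cats <- unique(dm$column_meta$category[aligned])
    origins <- unlist(lapply(members, function(j) {
      mf <- dm$column_meta$merged_from[[j]]
      if (length(mf)) mf else dm$column_meta$name[j]
    }))
    lvl <- paste(dm$column_meta$level[aligned], collapse = "+")
    cat_lab <- if (length(cats) == 1) cats else "merged"
    nm <- paste0(cat_lab, "=", lvl)
    keep_cols[[nm]] <- merged
    keep_meta[[nm]] <- list(name = nm, category = cat_lab, level = lvl,
                            merged_from = sort(origins))
    done[members] <- TRUE
  }
  ord_names <- c(colnames(m)[!done], names(keep_cols))
  new_mat <- cbind(m[, !done, drop = FALSE], do.call(cbind, keep_cols))
  colnames(new_mat) <- ord_names
  cm_old <- dm$column_meta[!done, , drop = FALSE]
  cm_new <- data.frame(
    name = vapply(keep_meta, `[[`, "", "name"),
    category = vapply(keep_meta, `[[`, "", "category"),
    level = vapply(keep_meta, `[[`, "", "level"),
    stringsAsFactors = FALSE
  )
  cm_new$merged_from <- lapply(keep_meta, `[[`, "merged_from")
  cm <- rbind(cm_old, cm_new)
  # deterministic column order: by category then name
  ord <- order(cm$category, cm$name)
  cm <- cm[ord, , drop = FALSE]
  rownames(cm) <- NULL
  structure(list(matrix = new_mat[, cm$name, drop = FALSE],
                 column_meta = cm, row_ids = dm$row_ids),
            class = "hte_design")
}

#' Serialize a design matrix
#'
#' Writes the binary matrix in MatrixMarket-like triplet CSV form plus a JSON
#' column-metadata sidecar.
#'
#' @param dm an \code{hte_design}.
#' @param path_prefix files are written as \code{<prefix>_matrix.csv} and
#'   \code{<prefix>_columns.json}.
#' @return the two paths, invisibly.
#' @export
write_design <- function(dm, path_prefix) {
  idx <- which(dm$matrix == 1L, arr.ind = TRUE)
  trip <- data.frame(row = idx[, 1], col = idx[, 2], value = 1L)
  p1 <- paste0(path_prefix, "_matrix.csv")
  p2 <- paste0(path_prefix, "_columns.json")
  utils::write.csv(trip, p1, row.names = FALSE)
  jsonlite::write_json(
    list(n_rows = nrow(dm$matrix), row_ids = dm$row_ids,
         columns = dm$column_meta),
    p2, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(p1, p2))
}
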