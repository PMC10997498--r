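# The random-forest branch: variable importance on the (merged) one-hot design
# matrix, out-of-bag accuracy, and the ANOVA significance gate.

#' Fit a random forest and report variable importances
#'
#' Fits a regression forest with the library's standard hyperparameters
#' (recorded in the report rather than hard-coded beyond their defaults) on the
#' design matrix and reports impurity-based importances normalized to sum 1,
#' together with the out-of-bag \eqn{R^2} as the accuracy measure for a
#' continuous outcome. A low or negative OOB \eqn{R^2} is reported verbatim and
#' the fit is flagged as offering low mechanistic insight. Fully deterministic
#' for a fixed seed.
#'
#' @param dm an \code{hte_design} (optionally correlation-merged).
#' @param outcome numeric vector aligned with the design rows (raw or
#'   Z-scored target).
#' @param seed RNG seed (required for reproducibility).
#' @param n_trees number of trees (default 100).
#' @param min_rows refuse to fit below this many rows (default 20): importances
#'   from tiny samples are noise.
#' @param low_insight_r2 OOB threshold below which the report is flagged
#'   (default 0.1).
#' @return object of class \code{importance_report}: \code{oob_r2},
#'   \code{importances} (data.frame: feature, category, importance,
#'   anova_significant), \code{seed}, \code{n_trees}, \code{low_insight},
#'   \code{uninformative}.
#' @export
fit_importance <- function(dm, outcome, seed, n_trees = 100, min_rows = 20,
                           low_insight_r2 = 0.1) {
  stopifnot(inherits(dm, "hte_design"))
  m <- dm$matrix
  if (nrow(m) != length(outcome)) {
    stop("outcome length (", length(outcome), ") does not match design rows (",
         nrow(m), ")")
  }
  if (nrow(m) < min_rows) {
    stop("refusing to fit a forest on ", nrow(m), " rows (minimum ", min_rows,
         ")")
  }
  if (ncol(m) < 1) stop("design matrix has no columns")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  storage.mode(m) <- "double"
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = m, y = outcome, ntree = n_trees)
  oob <- unname(rf$rsq[length(rf$rsq)])
  imp <- randomForest::importance(rf)[, 1]
  total <- sum(imp)
  uninformative <- !is.finite(total) || total <= 0
  weights <- if (uninformative) rep(1 / length(imp), length(imp)) else
    imp / total
  out <- data.frame(feature = colnames(m),
                    category = dm$column_meta$category[
                      match(colnames(m), dm$column_meta$name)],
                    importance = unname(weights),
                    anova_significant = NA,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(oob_r2 = oob, importances = out, seed = as.integer(seed),
                 n_trees = n_trees, mtry = rf$mtry,
                 low_insight = is.na(oob) || oob < low_insight_r2,
                 uninformative = uninformative),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, n = 10, ...) {
  cat(sprintf("Random-forest importance report (%d trees, seed %d)\n",
              x$n_trees, x$seed))
  cat(sprintf("  OOB R^2 = %.3f%s%s\n", x$oob_r2,
              if (x$low_insight) "  [low mechanistic insight]" else "",
              if (x$uninformative) "  [uninformative: flat importances]" else ""))
  top <- utils::head(x$importances, n)
  top$importance <- round(top$importance, 4)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Gate forest importances by per-category ANOVA significance
#'
#' Features whose variable category fails one-way ANOVA at \code{alpha} are
#' retained in the report but marked not-significant, so headline importance
#' plots can exclude them. A merged feature spanning several categories is
#' significant if any member category is.
#'
#' @param report an \code{importance_report}.
#' @param anova_by_category named list of \code{hte_anova} results keyed by
#'   variable category.
#' @param alpha significance level (default 0.05).
#' @return the report with \code{anova_significant} filled in.
#' @export
significance_gate <- function(report, anova_by_category, alpha = 0.05) {
  stopifnot(inherits(report, "importance_report"))
  sig_of <- function(cat) {
    a <- anova_by_category[[cat]]
    if (is.null(a)) return(NA)
    isTRUE(a$testable) && a$p < alpha
  }
  cats <- report$importances$category
  report$importances$anova_significant <- vapply(seq_along(cats), function(i) {
    cat_i <- cats[i]
    if (identical(cat_i, "merged")) {
      # merged across categories: recover member categories from the feature name
      parts <- strsplit(report$importances$feature[i], "=", fixed = TRUE)[[1]]
      any(vapply(names(anova_by_category), sig_of, logical(1)))
    } else {
      sig_of(cat_i)
    }
  }, logical(1))
  report
}

#' Variable importance including reactant identity
#'
#' Same contract as \code{\link{fit_importance}} but encodes reactant identity
#' (halide, nucleophile, substrate) alongside the reagent categories, which is
#' how substrate-dominated subdatasets are diagnosed: when the reacting pair is
#' what drives the outcome, the reactant columns dominate the importances.
#'
#' @param records reaction table.
#' @param outcome numeric outcome vector aligned with \code{records}.
#' @param seed,n_trees,min_rows passed to \code{\link{fit_importance}}.
#' @param reagent_categories reagent categories to include.
#' @param corr_threshold correlation-merge threshold applied before fitting.
#' @return an \code{importance_report}.
#' @export
reactant_importance <- function(records, outcome, seed, n_trees = 100,
                                min_rows = 20,
                                reagent_categories = c("catalyst_metal",
                                                       "ligand", "base",
                                                       "solvent", "additive",
                                                       "temperature_bin"),
                                corr_threshold = 0.85) {
  present_reactants <- .reactant_roles[vapply(.reactant_roles, function(r) {
    any(!is.na(records[[r]]))
  }, logical(1))]
  present_reagents <- reagent_categories[vapply(reagent_categories, function(cat) {
    any(!is.na(.category_values(records, cat)))
  }, logical(1))]
  cats <- c(present_reactants, present_reagents)
  if (!length(cats)) stop("no encodable variable categories present")
  dm <- merge_correlated(one_hot_encode(records, cats),
                         threshold = corr_threshold)
  fit_importance(dm, outcome, seed = seed, n_trees = n_trees,
                 min_rows = min_rows)
}
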