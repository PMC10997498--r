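# The Z-score / ANOVA / Tukey branch: normalize outcomes within substrate
# groups, test each variable category, rank reagent levels best-to-worst.

#' Z-score normalize outcomes within groups
#'
#' Normalizes the target outcome within each group so that reagent effects are
#' comparable across substrates of very different intrinsic reactivity:
#' \eqn{z = (y - \bar y_g) / s_g} with the sample standard deviation
#' (\eqn{n - 1} denominator). Singleton groups and groups with zero variance
#' map all members to \eqn{z = 0}, which keeps sparse substrates in the
#' analysis without biasing group means. The default grouping unit is the
#' reacting pair; it is pluggable because per-plate or per-target-product
#' normalization may suit other datasets.
#'
#' @param records reaction table with an \code{outcome} column.
#' @param grouping either \code{"pair"} (reacting pair, default),
#'   \code{"target_product"}, or a function mapping the reaction table to a
#'   character vector of group keys.
#' @return data.frame with \code{reaction_id}, \code{group_key}, \code{z},
#'   rows aligned with \code{records}.
#' @export
zscore_normalize <- function(records, grouping = "pair") {
  key <- if (is.function(grouping)) {
    grouping(records)
  } else if (identical(grouping, "pair")) {
    reacting_pairs(records)
  } else if (identical(grouping, "target_product")) {
    records$target_product_id
  } else {
    stop("grouping must be 'pair', 'target_product' or a function")
  }
  z <- numeric(nrow(records))
  for (idx in split(seq_len(nrow(records)), key)) {
    y <- records$outcome[idx]
    s <- stats::sd(y)
    if (length(y) < 2 || is.na(s) || s == 0) {
      z[idx] <- 0
    } else {
      z[idx] <- (y - mean(y)) / s
    }
  }
  data.frame(reaction_id = records$reaction_id, group_key = key, z = z,
             stringsAsFactors = FALSE)
}

# z values split by the level of one variable category; drops NA levels
.z_by_level <- function(records, z, category) {
  v <- .category_values(records, category)
  ok <- !is.na(v)
  split(z[ok], v[ok])
}

#' One-way ANOVA across the levels of a variable category
#'
#' Classic one-way fixed-effects ANOVA (\code{F = MS_between / MS_within}) on
#' the normalized outcome, fitted with \code{stats::aov}. Degenerate inputs are
#' handled explicitly: with zero within-group variance but unequal means the
#' result is \eqn{p = 0}, flagged \code{degenerate}; with fewer than two
#' usable levels the category is reported not-testable rather than an error.
#'
#' @param z_by_level named list: level -> numeric vector of z values.
#' @param alpha significance level (default 0.05).
#' @param category optional label carried into the result.
#' @return object of class \code{hte_anova} with \code{F}, \code{df_between},
#'   \code{df_within}, \code{p}, \code{significant}, \code{degenerate},
#'   \code{testable}, \code{reason}.
#' @export
anova_oneway <- function(z_by_level, alpha = 0.05, category = NULL) {
  z_by_level <- z_by_level[lengths(z_by_level) > 0]
  k <- length(z_by_level)
  N <- sum(lengths(z_by_level))
  res <- list(variable_category = category, F = NA_real_,
              df_between = k - 1L, df_within = N - k, p = NA_real_,
              significant = FALSE, degenerate = FALSE, testable = TRUE,
              alpha = alpha, reason = NULL)
  if (k < 2) {
    res$testable <- FALSE
    res$reason <- "fewer than 2 levels with observations"
    return(structure(res, class = "hte_anova"))
  }
  if (N <= k) {
    res$testable <- FALSE
    res$reason <- "no residual degrees of freedom"
    return(structure(res, class = "hte_anova"))
  }
  y <- unlist(z_by_level, use.names = FALSE)
  g <- factor(rep(names(z_by_level), lengths(z_by_level)))
  ssw <- sum(vapply(z_by_level, function(v) sum((v - mean(v))^2), numeric(1)))
  gm <- mean(y)
  ssb <- sum(lengths(z_by_level) *
               (vapply(z_by_level, mean, numeric(1)) - gm)^2)
  eps <- 1e-12 * max(1, sum(y^2))
  if (ssw <= eps) {
    if (ssb <= eps) {
      res$F <- 0; res$p <- 1
    } else {
      res$F <- Inf; res$p <- 0
      res$significant <- TRUE
      res$degenerate <- TRUE
      res$reason <- "zero within-group variance with unequal means"
    }
    return(structure(res, class = "hte_anova"))
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  res$F <- tab[["F value"]][1]
  res$p <- tab[["Pr(>F)"]][1]
  res$significant <- res$p < alpha
  structure(res, class = "hte_anova")
}

#' @export
print.hte_anova <- function(x, ...) {
  if (!x$testable) {
    cat("One-way ANOVA", if (!is.null(x$variable_category))
      paste0("[", x$variable_category, "]"), ": not testable (",
      x$reason, ")\n", sep = " ")
    return(invisible(x))
  }
  cat(sprintf("One-way ANOVA%s: F(%d, %d) = %.4g, p = %.4g%s%s\n",
              if (!is.null(x$variable_category))
                paste0(" [", x$variable_category, "]") else "",
              x$df_between, x$df_within, x$F, x$p,
              if (x$significant) " *" else "",
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise level comparisons with studentized-range (Tukey--Kramer)
#' adjusted p-values, computed with \code{stats::TukeyHSD} on the one-way fit;
#' unbalanced group sizes are handled by the Kramer correction. Levels with no
#' observations are excluded with a warning. With zero within-group variance
#' the comparisons are degenerate: pairs with different means get adjusted
#' p = 0, equal means p = 1.
#'
#' @param z_by_level named list: level -> numeric vector of z values.
#' @param alpha significance level (annotates the \code{significant} column).
#' @return data.frame of class \code{hte_tukey}: \code{level1}, \code{level2},
#'   \code{diff} (level1 - level2), \code{lwr}, \code{upr}, \code{p_adj},
#'   \code{significant}.
#' @export
tukey_hsd <- function(z_by_level, alpha = 0.05) {
  empty <- lengths(z_by_level) == 0
  if (any(empty)) {
    warning("excluding level(s) with no observations: ",
            paste(names(z_by_level)[empty], collapse = ", "))
    z_by_level <- z_by_level[!empty]
  }
  k <- length(z_by_level)
  if (k < 2) stop("Tukey HSD needs at least 2 levels with observations")
  y <- unlist(z_by_level, use.names = FALSE)
  g <- factor(rep(names(z_by_level), lengths(z_by_level)))
  ssw <- sum(vapply(z_by_level, function(v) sum((v - mean(v))^2), numeric(1)))
  eps <- 1e-12 * max(1, sum(y^2))
  pairs <- utils::combn(names(z_by_level), 2)
  if (ssw <= eps || sum(lengths(z_by_level)) <= k) {
    means <- vapply(z_by_level, mean, numeric(1))
    d <- means[pairs[1, ]] - means[pairs[2, ]]
    out <- data.frame(level1 = pairs[1, ], level2 = pairs[2, ], diff = d,
                      lwr = d, upr = d,
                      p_adj = ifelse(abs(d) <= sqrt(eps), 1, 0),
                      stringsAsFactors = FALSE)
    out$significant <- out$p_adj < alpha
    class(out) <- c("hte_tukey", "data.frame")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- stats::aov(y ~ g)
  tk <- stats::TukeyHSD(fit)$g
  # TukeyHSD enumerates combn(levels, 2) as "second-first" rows, in that
  # order; reconstruct the pair labels from the level set instead of parsing
  # rownames (level names may themselves contain "-")
  cmb <- utils::combn(levels(g), 2)
  stopifnot(nrow(tk) == ncol(cmb))
  out <- data.frame(
    level1 = cmb[2, ], level2 = cmb[1, ],
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
  out$significant <- out$p_adj < alpha
  class(out) <- c("hte_tukey", "data.frame")
  attr(out, "degenerate") <- FALSE
  out
}

#' Rank reagent levels best-to-worst within a variable category
#'
#' Implements the ranking recipe of the ANOVA--Tukey branch: the category must
#' first pass one-way ANOVA at \code{alpha} (otherwise every level is labelled
#' neutral and the ranking carries a not-significant flag); the "outlier"
#' levels are those with at least one significant Tukey pairwise comparison;
#' outliers are labelled \code{best} when their mean Z-score is positive and
#' \code{worst} when negative, and the table is ranked by mean Z-score
#' (descending), ties broken by larger n, then level name. Levels observed
#' fewer than \code{min_n} times are reported as \code{insufficient data} and
#' never labelled best/worst.
#'
#' @param z_by_level named list: level -> numeric vector of z values.
#' @param alpha significance level (default 0.05).
#' @param min_n minimum observations for a level to be rankable (default 5).
#' @param category optional label.
#' @return object of class \code{tukey_ranking}: list with \code{anova},
#'   \code{entries} (data.frame: level, n, mean_z, class, n_significant_pairs),
#'   \code{pairs} (the Tukey table or NULL), \code{category}.
#' @export
rank_reagents <- function(z_by_level, alpha = 0.05, min_n = 5,
                          category = NULL) {
  z_by_level <- z_by_level[lengths(z_by_level) > 0]
  an <- anova_oneway(z_by_level, alpha = alpha, category = category)
  lv <- names(z_by_level)
  n <- lengths(z_by_level)
  mean_z <- vapply(z_by_level, mean, numeric(1))
  entries <- data.frame(level = lv, n = as.integer(n), mean_z = unname(mean_z),
                        class = "neutral", n_significant_pairs = 0L,
                        stringsAsFactors = FALSE)
  pairs <- NULL
  if (an$testable && an$significant && length(z_by_level) >= 2) {
    pairs <- tukey_hsd(z_by_level, alpha = alpha)
    sig <- pairs[pairs$significant, , drop = FALSE]
    n_sig <- vapply(lv, function(l) {
      sum(sig$level1 == l) + sum(sig$level2 == l)
    }, integer(1))
    entries$n_significant_pairs <- unname(n_sig)
    outlier <- n_sig > 0
    entries$class[outlier & entries$mean_z > 0] <- "best"
    entries$class[outlier & entries$mean_z < 0] <- "worst"
  }
  entries$class[entries$n < min_n] <- "insufficient data"
  ord <- order(-entries$mean_z, -entries$n, entries$level)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(category = category, anova = an, entries = entries,
                 pairs = pairs, alpha = alpha, min_n = min_n),
            class = "tukey_ranking")
}

#' @export
print.tukey_ranking <- function(x, digits = 3, ...) {
  cat("Reagent ranking", if (!is.null(x$category))
    paste0("[", x$category, "]"), "\n")
  print(x$anova)
  e <- x$entries
  e$mean_z <- round(e$mean_z, digits)
  print(e, row.names = FALSE)
  invisible(x)
}

#' Serialize a ranking report
#' @param ranking a \code{tukey_ranking} (or list of them).
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  strip <- function(r) {
    list(category = r$category,
         anova = unclass(r$anova)[c("F", "df_between", "df_within", "p",
                                    "significant", "degenerate", "testable")],
         entries = r$entries,
         pairs = if (!is.null(r$pairs)) as.data.frame(r$pairs) else NULL)
  }
  obj <- if (inherits(ranking, "tukey_ranking")) strip(ranking) else
    lapply(ranking, strip)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
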