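# Pipeline orchestration: run all three analysis branches over every
# analysable subreactome, plus the zero-yield and temporal ablations.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its documented valid range.
#' The defaults are the framework's canonical settings: significance at
#' alpha = 0.05, correlation merging at 0.85, subdatasets require more than 80
#' reactions and at least 2 unique reacting pairs, 2048-bit radius-2
#' fingerprints, Z-score normalization within reacting pairs, and a 100-tree
#' regression forest on the Z-scored target.
#'
#' @param alpha ANOVA/Tukey significance level, in (0, 1).
#' @param corr_threshold correlation-merge threshold, in (0, 1].
#' @param min_reactions subdataset inclusion: strict lower bound on reactions.
#' @param min_pairs subdataset inclusion: minimum unique reacting pairs.
#' @param fp_bits,fp_radius fingerprint parameters.
#' @param grouping Z-score normalization group: "pair", "target_product" or a
#'   function of the reaction table.
#' @param seed RNG seed for the forest.
#' @param n_trees trees per forest.
#' @param target forest target: "z" (Z-scored, default, consistent with the
#'   ANOVA branch) or "raw" yield.
#' @param min_level_n minimum observations for a level to be rankable.
#' @param categories reagent variable categories to rank and encode.
#' @param reactant_categories reactant identity categories for the forest.
#' @param branches analysis branches to run (subset of "ranking",
#'   "importance", "chemspace").
#' @return object of class \code{hitea_config}.
#' @export
hitea_config <- function(alpha = 0.05, corr_threshold = 0.85,
                         min_reactions = 80, min_pairs = 2,
                         fp_bits = 2048, fp_radius = 2,
                         grouping = "pair", seed = 1, n_trees = 100,
                         target = c("z", "raw"), min_level_n = 5,
                         categories = c("catalyst_metal", "ligand", "base",
                                        "solvent", "additive",
                                        "temperature_bin"),
                         reactant_categories = c("halide", "nucleophile",
                                                 "substrate"),
                         branches = c("ranking", "importance", "chemspace")) {
  target <- match.arg(target)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (corr_threshold <= 0 || corr_threshold > 1) {
    stop("corr_threshold must be in (0, 1]")
  }
  if (min_reactions < 0 || min_pairs < 1) stop("invalid inclusion thresholds")
  if (fp_bits < 16 || fp_radius < 0) stop("invalid fingerprint parameters")
  if (n_trees < 1) stop("n_trees must be >= 1")
  bad <- setdiff(branches, c("ranking", "importance", "chemspace"))
  if (length(bad)) stop("unknown branches: ", paste(bad, collapse = ", "))
  structure(list(alpha = alpha, corr_threshold = corr_threshold,
                 min_reactions = min_reactions, min_pairs = min_pairs,
                 fp_bits = fp_bits, fp_radius = fp_radius,
                 grouping = grouping, seed = as.integer(seed),
                 n_trees = n_trees, target = target,
                 min_level_n = min_level_n, categories = categories,
                 reactant_categories = reactant_categories,
                 branches = branches),
            class = "hitea_config")
}

# analyse one subreactome with all requested branches
.analyse_subreactome <- function(sub, config, aliases) {
  recs <- sub$records
  z <- zscore_normalize(recs, config$grouping)$z
  target <- if (config$target == "z") z else recs$outcome

  rankings <- list()
  anovas <- list()
  if ("ranking" %in% config$branches || "importance" %in% config$branches) {
    for (cat in config$categories) {
      zl <- .z_by_level(recs, z, cat)
      if (length(zl) == 0) next
      rk <- rank_reagents(zl, alpha = config$alpha,
                          min_n = config$min_level_n, category = cat)
      rankings[[cat]] <- rk
      anovas[[cat]] <- rk$anova
    }
  }

  importance <- NULL
  if ("importance" %in% config$branches) {
    importance <- tryCatch({
      rep_ <- reactant_importance(
        recs, target, seed = config$seed, n_trees = config$n_trees,
        reagent_categories = config$categories,
        corr_threshold = config$corr_threshold)
      significance_gate(rep_, anovas, alpha = config$alpha)
    }, error = function(e) {
      structure(list(error = conditionMessage(e)), class = "hitea_skipped")
    })
  }

  embedding <- NULL
  if ("chemspace" %in% config$branches) {
    ligands <- unique(recs$ligand[!is.na(recs$ligand)])
    if (length(ligands) >= 3) {
      lig_smiles <- .resolve_level_smiles(ligands, aliases)
      ok <- !is.na(lig_smiles)
      if (sum(ok) >= 3) {
        fps <- fingerprint_set(stats::setNames(lig_smiles[ok], ligands[ok]),
                               radius = config$fp_radius,
                               n_bits = config$fp_bits)
        embedding <- tryCatch({
          emb <- pca_embed(fps)
          if (!is.null(rankings$ligand)) {
            emb <- annotate_embedding(emb, rankings$ligand, aliases)
          }
          attr(emb, "unresolved_ligands") <- ligands[!ok]
          emb
        }, error = function(e) NULL)
      }
    }
  }

  diversity <- if ("chemspace" %in% config$branches) {
    diversity_summary(sub, radius = config$fp_radius, n_bits = config$fp_bits)
  } else NULL

  list(reaction_class = sub$reaction_class, subclass = sub$subclass,
       n_reactions = nrow(recs), n_pairs = length(sub$unique_pairs),
       rankings = rankings, anovas = anovas, importance = importance,
       embedding = embedding, diversity = diversity)
}

#' Run the full reactome analysis
#'
#' Cleans the dataset, splits it into reaction-class/substrate-subclass
#' subreactomes, applies the inclusion rule, and runs the three analysis
#' branches on every analysable subreactome: reagent ranking (Z-score /
#' ANOVA / Tukey), random-forest variable importance gated by ANOVA, and the
#' ligand chemical-space embedding. Deterministic for a fixed config and seed.
#'
#' @param records reaction table (see \code{\link{parse_reactions}} /
#'   \code{\link{generate_campaign}}).
#' @param config a \code{\link{hitea_config}}.
#' @param clean run \code{\link{clean_dataset}} first (default TRUE).
#' @param aliases reagent alias dictionary.
#' @return object of class \code{hitea}: list with \code{subreactomes} (one
#'   analysis bundle per analysable subreactome), \code{skipped} (excluded
#'   subdatasets with reasons), \code{cleanup}, \code{config}.
#' @export
hitea <- function(records, config = hitea_config(), clean = TRUE,
                  aliases = default_reagent_aliases()) {
  stopifnot(inherits(config, "hitea_config"), is.data.frame(records))
  cleanup <- NULL
  if (clean) {
    cl <- clean_dataset(records, aliases = aliases)
    records <- cl$records
    cleanup <- cl
  }
  subs <- split_subreactomes(records)
  selected <- select_subdatasets(subs, min_reactions = config$min_reactions,
                                 min_pairs = config$min_pairs)
  skipped <- attr(selected, "skipped")
  results <- lapply(selected, .analyse_subreactome, config = config,
                    aliases = aliases)
  if (!length(results)) {
    message("no analyzable subdatasets after the inclusion rule")
  }
  structure(list(subreactomes = results, skipped = skipped,
                 cleanup = cleanup, config = config,
                 n_records = nrow(records)),
            class = "hitea")
}

#' @export
print.hitea <- function(x, ...) {
  cat("HTE reactome analysis:", x$n_records, "reactions,",
      length(x$subreactomes), "analysable subreactome(s),",
      length(x$skipped), "skipped\n")
  for (r in x$subreactomes) {
    cat(sprintf("  %s / %s: %d reactions, %d pairs", r$reaction_class,
                r$subclass, r$n_reactions, r$n_pairs))
    if (inherits(r$importance, "importance_report")) {
      cat(sprintf(", OOB R^2 = %.2f", r$importance$oob_r2))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.hitea <- function(object, ...) {
  bw <- best_worst(object)
  cat("Best/worst-in-class reagents across",
      length(object$subreactomes), "subreactome(s):\n")
  if (nrow(bw)) print(bw, row.names = FALSE) else cat("  (none)\n")
  invisible(bw)
}

#' @export
plot.hitea <- function(x, which = 1, ...) {
  if (!length(x$subreactomes)) {
    stop("nothing to plot: no analysable subreactomes")
  }
  r <- x$subreactomes[[which]]
  has_emb <- inherits(r$embedding, "hte_embedding")
  if (inherits(r$importance, "importance_report")) {
    if (has_emb) {
      old <- graphics::par(mfrow = c(1, 2))
      on.exit(graphics::par(old))
    }
    imp <- utils::head(r$importance$importances, 12)
    sig <- isTRUE(imp$anova_significant)
    graphics::barplot(rev(imp$importance), names.arg = rev(imp$feature),
                      horiz = TRUE, las = 1, cex.names = 0.6,
                      col = rev(ifelse(!is.na(imp$anova_significant) &
                                         imp$anova_significant,
                                       "#2166ac", "grey70")),
                      xlab = "importance",
                      main = paste(r$reaction_class, "/", r$subclass))
  }
  if (has_emb) plot(r$embedding, main = "ligand space")
  invisible(x)
}

#' Collect best/worst labels from a pipeline result
#'
#' @param bundle a \code{hitea} object.
#' @param classes which label classes to keep.
#' @return data.frame: subreactome, category, level, n, mean_z, class.
#' @export
best_worst <- function(bundle, classes = c("best", "worst")) {
  rows <- list()
  for (r in bundle$subreactomes) {
    sub_id <- paste(r$reaction_class, r$subclass, sep = " / ")
    for (rk in r$rankings) {
      e <- rk$entries[rk$entries$class %in% classes, , drop = FALSE]
      if (!nrow(e)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subreactome = sub_id, category = rk$category, level = e$level,
        n = e$n, mean_z = e$mean_z, class = e$class, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(subreactome = character(0), category = character(0),
                      level = character(0), n = integer(0),
                      mean_z = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Zero-yield ablation
#'
#' Runs the pipeline on the full dataset and on the dataset with all 0%-yield
#' reactions removed (mimicking a literature-style dataset that only reports
#' successes), and summarizes every best/worst label change between the two
#' runs.
#'
#' @param records reaction table.
#' @param config a \code{\link{hitea_config}}.
#' @param ... passed to \code{\link{hitea}}.
#' @return object of class \code{hitea_ablation}: \code{full} and
#'   \code{ablated} bundles, \code{comparison} (one row per level whose label
#'   differs, with direction), \code{n_zero_removed}.
#' @export
ablate_zero_yield <- function(records, config = hitea_config(), ...) {
  full <- hitea(records, config, ...)
  keep <- records$outcome > 0
  ablated <- hitea(records[keep, , drop = FALSE], config, ...)
  lab_full <- best_worst(full, classes = c("best", "worst", "neutral",
                                           "insufficient data"))
  lab_abl <- best_worst(ablated, classes = c("best", "worst", "neutral",
                                             "insufficient data"))
  key <- function(d) paste(d$subreactome, d$category, d$level, sep = "|")
  all_keys <- union(key(lab_full), key(lab_abl))
  lf <- lab_full$class[match(all_keys, key(lab_full))]
  la <- lab_abl$class[match(all_keys, key(lab_abl))]
  lf[is.na(lf)] <- "absent"; la[is.na(la)] <- "absent"
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  comparison <- data.frame(
    subreactome = vapply(parts, `[`, "", 1),
    category = vapply(parts, `[`, "", 2),
    level = vapply(parts, `[`, "", 3),
    label_full = lf, label_ablated = la,
    changed = lf != la, stringsAsFactors = FALSE)
  comparison <- comparison[order(comparison$subreactome, comparison$category,
                                 comparison$level), , drop = FALSE]
  rownames(comparison) <- NULL
  structure(list(full = full, ablated = ablated, comparison = comparison,
                 n_zero_removed = sum(!keep)),
            class = "hitea_ablation")
}

#' @export
print.hitea_ablation <- function(x, ...) {
  cat("Zero-yield ablation:", x$n_zero_removed, "0%-yield reactions removed\n")
  ch <- x$comparison[x$comparison$changed, , drop = FALSE]
  cat(nrow(ch), "best/worst/neutral label change(s):\n")
  if (nrow(ch)) print(ch, row.names = FALSE)
  invisible(x)
}

#' Temporal segregation analysis
#'
#' Splits the dataset at the given boundary dates, re-runs the full pipeline
#' (inclusion rule included) independently per period, and tabulates the drift
#' of best/worst labels over periods; a level unused in a period is reported
#' \code{"absent"}.
#'
#' @param records reaction table with timestamps.
#' @param boundaries one or more boundary dates; k boundaries give k+1 periods.
#' @param config a \code{\link{hitea_config}}.
#' @param ... passed to \code{\link{hitea}}.
#' @return object of class \code{hitea_temporal}: \code{bundles} (one per
#'   period, possibly empty), \code{drift} (level x period label table),
#'   \code{periods}.
#' @export
temporal_split <- function(records, boundaries, config = hitea_config(), ...) {
  if (any(is.na(records$timestamp))) {
    stop("temporal split requires timestamps on every record")
  }
  boundaries <- sort(as.Date(boundaries))
  breaks <- c(as.Date("0001-01-01"), boundaries, as.Date("9999-12-31"))
  period <- cut(records$timestamp, breaks = breaks, right = FALSE,
                labels = FALSE)
  labels <- vapply(seq_len(length(boundaries) + 1), function(p) {
    if (p == 1) paste0("< ", boundaries[1])
    else if (p > length(boundaries)) paste0(">= ", boundaries[p - 1])
    else paste0("[", boundaries[p - 1], ", ", boundaries[p], ")")
  }, "")
  bundles <- lapply(seq_along(labels), function(p) {
    recs <- records[period == p, , drop = FALSE]
    if (!nrow(recs)) return(structure(list(empty = TRUE), class = "hitea"))
    hitea(recs, config, ...)
  })
  names(bundles) <- labels

  rows <- list()
  for (p in seq_along(bundles)) {
    b <- bundles[[p]]
    if (isTRUE(b$empty)) next
    lab <- best_worst(b, classes = c("best", "worst", "neutral",
                                     "insufficient data"))
    if (nrow(lab)) {
      lab$period <- labels[p]
      rows[[length(rows) + 1L]] <- lab
    }
  }
  drift <- NULL
  if (length(rows)) {
    long <- do.call(rbind, rows)
    key <- unique(long[c("subreactome", "category", "level")])
    drift <- key
    for (p in labels) {
      sub <- long[long$period == p, , drop = FALSE]
      m <- match(paste(key$subreactome, key$category, key$level),
                 paste(sub$subreactome, sub$category, sub$level))
      drift[[p]] <- ifelse(is.na(m), "absent", sub$class[m])
    }
    rownames(drift) <- NULL
  }
  structure(list(bundles = bundles, drift = drift, periods = labels),
            class = "hitea_temporal")
}

#' @export
print.hitea_temporal <- function(x, ...) {
  cat("Temporal segregation into", length(x$periods), "period(s):",
      paste(x$periods, collapse = " | "), "\n")
  if (!is.null(x$drift)) print(x$drift, row.names = FALSE)
  invisible(x)
}

# strip an analysis bundle down to JSON-serializable pieces
.report_list <- function(r) {
  list(
    reaction_class = r$reaction_class, subclass = r$subclass,
    n_reactions = r$n_reactions, n_pairs = r$n_pairs,
    rankings = lapply(r$rankings, function(rk) {
      list(category = rk$category,
           anova = unclass(rk$anova)[c("F", "df_between", "df_within", "p",
                                       "significant", "degenerate",
                                       "testable")],
           entries = rk$entries)
    }),
    importance = if (inherits(r$importance, "importance_report")) {
      list(oob_r2 = r$importance$oob_r2, seed = r$importance$seed,
           n_trees = r$importance$n_trees,
           low_insight = r$importance$low_insight,
           importances = r$importance$importances)
    },
    embedding = if (inherits(r$embedding, "hte_embedding")) {
      list(coordinates = r$embedding$coordinates,
           explained_variance_ratio = r$embedding$explained_variance_ratio)
    },
    diversity = if (!is.null(r$diversity)) {
      list(unique_counts = as.list(r$diversity$unique_counts),
           n_pairs = r$diversity$n_pairs)
    })
}

#' Write a report bundle to a directory
#'
#' Emits \code{config.json}, one JSON file per subreactome, and a top-level
#' markdown summary. Every number in the markdown is also present in a JSON
#' field; the rendered report performs no computation of its own.
#'
#' @param bundle a \code{hitea} object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_hitea_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(bundle$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  md <- c("# HTE reactome report", "",
          sprintf("- reactions analysed: %d", bundle$n_records),
          sprintf("- analysable subreactomes: %d",
                  length(bundle$subreactomes)),
          sprintf("- skipped subdatasets: %d", length(bundle$skipped)), "")
  for (i in seq_along(bundle$subreactomes)) {
    r <- bundle$subreactomes[[i]]
    slug <- gsub("[^A-Za-z0-9]+", "_",
                 paste(r$reaction_class, r$subclass, sep = "_"))
    jsonlite::write_json(.report_list(r),
                         file.path(dir, paste0("subreactome_", slug, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    md <- c(md, sprintf("## %s / %s", r$reaction_class, r$subclass),
            sprintf("- %d reactions, %d unique reacting pairs",
                    r$n_reactions, r$n_pairs))
    if (inherits(r$importance, "importance_report")) {
      md <- c(md, sprintf("- forest OOB R^2: %.3f%s", r$importance$oob_r2,
                          if (r$importance$low_insight)
                            " (low mechanistic insight)" else ""))
    }
    bw <- best_worst(structure(list(subreactomes = list(r)),
                               class = "hitea"))
    if (nrow(bw)) {
      md <- c(md, "- best/worst-in-class:",
              sprintf("    - %s [%s]: %s (mean z = %.2f, n = %d)",
                      bw$level, bw$category, bw$class, bw$mean_z, bw$n))
    }
    md <- c(md, "")
  }
  if (length(bundle$skipped)) {
    md <- c(md, "## Skipped subdatasets", "")
    for (s in bundle$skipped) {
      md <- c(md, sprintf("- %s / %s: %s", s$reaction_class, s$subclass,
                          s$reason))
    }
  }
  writeLines(md, file.path(dir, "summary.md"))
  if (!is.null(bundle$cleanup)) {
    write_cleanup_log(bundle$cleanup, file.path(dir, "cleanup_log.json"))
  }
  invisible(dir)
}
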