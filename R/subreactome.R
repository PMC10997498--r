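# Splitting a dataset into reaction-class / substrate-subclass slices
# ("subreactomes"), counting unique reacting pairs and applying the
# inclusion rule for analysable subdatasets.

.coupling_classes <- c("buchwald_hartwig", "ullmann")
.transformation_labels <- c("alkene", "alkyne", "deprotection",
                            "dearomatization", "carbonyl reduction",
                            "other FGs")

#' Subclass rule set
#'
#' Ordered substructure rules (SMARTS pattern, label, priority) used to class
#' the reacting halide and the nucleophile of coupling reactions. Shipped as an
#' editable CSV so users can extend the classes without code changes. Halide
#' priority is I > Br > Cl: for multi-halogenated electrophiles the heaviest
#' aryl halide is presumed to be the reacting site (a warning is attached when
#' this rule had to disambiguate).
#'
#' @param path optional CSV to load instead of the shipped default.
#' @return data.frame with columns \code{role}, \code{priority}, \code{smarts},
#'   \code{label}.
#' @export
default_subclass_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "subclass_rules.csv", package = "hitea")
    if (!nzchar(path)) path <- "inst/extdata/subclass_rules.csv"
  }
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  r[order(r$role, r$priority), , drop = FALSE]
}

# first matching label in priority order; NA smiles or no match -> NA
.classify_structure <- function(smiles, rules_role) {
  out <- rep(NA_character_, length(smiles))
  todo <- !is.na(smiles)
  for (i in seq_len(nrow(rules_role))) {
    if (!any(todo)) break
    hit <- todo & vapply(smiles, function(s) {
      isTRUE(smarts_match(s, rules_role$smarts[i]))
    }, logical(1), USE.NAMES = FALSE)
    out[hit] <- rules_role$label[i]
    todo <- todo & !hit
  }
  out
}

#' Assign a substrate subclass to each reaction
#'
#' Coupling reactions (Buchwald--Hartwig, Ullmann) are labelled by the reacting
#' halide type and the nucleophile class, e.g. \code{"ArBr + primary amine"}.
#' Hydrogenations are labelled by transformation type, read from the
#' \code{transformation} annotation column (alkene, alkyne, deprotection,
#' dearomatization, carbonyl reduction, other FGs). Unclassifiable records get
#' the label \code{"other"} with a warning, never an error.
#'
#' @param records cleaned reaction table.
#' @param rules subclass rule set, see \code{\link{default_subclass_rules}}.
#' @return character vector of subclass labels, one per record.
#' @export
assign_subclass <- function(records, rules = default_subclass_rules()) {
  n <- nrow(records)
  out <- rep("other", n)
  if (n == 0) return(character(0))
  coupling <- records$reaction_class %in% .coupling_classes
  if (any(coupling)) {
    hal <- .classify_structure(records$halide[coupling],
                               rules[rules$role == "halide", , drop = FALSE])
    nuc <- .classify_structure(records$nucleophile[coupling],
                               rules[rules$role == "nucleophile", , drop = FALSE])
    lab <- ifelse(is.na(hal) | is.na(nuc), "other", paste(hal, "+", nuc))
    out[coupling] <- lab
  }
  hydro <- grepl("^hydrogenation", records$reaction_class)
  if (any(hydro)) {
    tr <- records$transformation[hydro]
    lab <- ifelse(!is.na(tr) & tr %in% .transformation_labels, tr, "other")
    out[hydro] <- lab
  }
  if (any(out == "other")) {
    warning(sum(out == "other"), " record(s) could not be subclassed and were ",
            "labelled 'other'")
  }
  out
}

#' Reacting-pair keys
#'
#' The unique combination of reacting substrates of each record: the canonical
#' (halide, nucleophile) SMILES tuple for couplings, the substrate alone for
#' hydrogenations and other single-substrate classes.
#'
#' @param records reaction table.
#' @return character vector of pair keys.
#' @export
reacting_pairs <- function(records) {
  coupling <- records$reaction_class %in% .coupling_classes
  out <- character(nrow(records))
  out[coupling] <- paste(records$halide[coupling],
                         records$nucleophile[coupling], sep = " + ")
  out[!coupling] <- ifelse(is.na(records$substrate[!coupling]),
                           paste(records$halide[!coupling],
                                 records$nucleophile[!coupling], sep = " + "),
                           records$substrate[!coupling])
  out
}

#' Number of unique reacting pairs
#'
#' Invariant under record shuffling and duplication.
#'
#' @param records reaction table with canonicalized reactants.
#' @return integer count.
#' @export
unique_pair_count <- function(records) {
  length(unique(reacting_pairs(records)))
}

#' Split a reaction table into subreactomes
#'
#' One subreactome per (reaction class, subclass); every record lands in
#' exactly one.
#'
#' @param records cleaned reaction table.
#' @param rules subclass rule set.
#' @return list of \code{subreactome} objects, each with \code{reaction_class},
#'   \code{subclass}, \code{records} and \code{unique_pairs}.
#' @export
split_subreactomes <- function(records, rules = default_subclass_rules()) {
  if (nrow(records) == 0) return(list())
  sub <- assign_subclass(records, rules)
  key <- paste(records$reaction_class, sub, sep = " / ")
  lapply(split(seq_len(nrow(records)), key), function(idx) {
    recs <- records[idx, , drop = FALSE]
    structure(list(reaction_class = recs$reaction_class[1],
                   subclass = sub[idx][1],
                   records = recs,
                   unique_pairs = unique(reacting_pairs(recs))),
              class = "subreactome")
  })
}

#' @export
print.subreactome <- function(x, ...) {
  cat("Subreactome:", x$reaction_class, "/", x$subclass, "--",
      nrow(x$records), "reactions,", length(x$unique_pairs),
      "unique reacting pair(s)\n")
  invisible(x)
}

#' Apply the subdataset inclusion rule
#'
#' A subreactome is analysable when it has strictly more than
#' \code{min_reactions} reactions and at least \code{min_pairs} unique reacting
#' pairs (defaults 80 and 2: the strict ">" and the inclusive ">=" match the
#' rule the framework was designed with -- a subdataset of exactly 80 reactions
#' is excluded, one with exactly 2 pairs is kept).
#'
#' @param subs list of \code{subreactome} objects.
#' @param min_reactions reaction-count bound (strict).
#' @param min_pairs unique-pair bound (inclusive).
#' @return the subreactomes passing the rule; the excluded ones are attached as
#'   attribute \code{"skipped"} together with the reason.
#' @export
select_subdatasets <- function(subs, min_reactions = 80, min_pairs = 2) {
  keep <- vapply(subs, function(s) {
    nrow(s$records) > min_reactions && length(s$unique_pairs) >= min_pairs
  }, logical(1))
  skipped <- lapply(subs[!keep], function(s) {
    list(reaction_class = s$reaction_class, subclass = s$subclass,
         n_reactions = nrow(s$records), n_pairs = length(s$unique_pairs),
         reason = paste(c(
           if (nrow(s$records) <= min_reactions)
             sprintf("needs > %d reactions (has %d)", min_reactions,
                     nrow(s$records)),
           if (length(s$unique_pairs) < min_pairs)
             sprintf("needs >= %d unique pairs (has %d)", min_pairs,
                     length(s$unique_pairs))), collapse = "; "))
  })
  structure(subs[keep], skipped = skipped)
}

#' Reactant diversity summary of a subreactome
#'
#' Counts unique structures per reactant role and computes the pairwise
#' Tanimoto similarity matrix of the unique structures (the "Tanimoto squares"
#' view). Unparseable structures are excluded from the matrix and reported.
#'
#' @param sub a \code{subreactome}.
#' @param radius,n_bits fingerprint parameters.
#' @return list with \code{unique_counts} (per role), \code{n_pairs},
#'   \code{tanimoto} (symmetric matrix, unit diagonal) and \code{excluded}.
#' @export
diversity_summary <- function(sub, radius = 2, n_bits = 2048) {
  recs <- sub$records
  counts <- vapply(.reactant_roles, function(r) {
    length(unique(recs[[r]][!is.na(recs[[r]])]))
  }, integer(1))
  structures <- unique(stats::na.omit(unlist(recs[.reactant_roles])))
  tm <- NULL
  excluded <- character(0)
  if (length(structures) >= 1) {
    fps <- fingerprint_set(stats::setNames(structures, structures),
                           radius = radius, n_bits = n_bits)
    excluded <- attr(fps, "failed")
    if (nrow(fps) >= 1) tm <- tanimoto_matrix(fps)
  }
  list(unique_counts = counts, n_pairs = length(sub$unique_pairs),
       tanimoto = tm, excluded = excluded)
}
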