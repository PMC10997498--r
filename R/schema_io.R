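# Reaction-record data model, CSV schema and dataset cleanup.
#
# A reaction table is a plain data.frame with one row per HTE well and the
# canonical columns below. Reactant columns hold canonical SMILES; reagent
# columns hold level identifiers (names or SMILES); `flags` accumulates
# semicolon-separated curation flags, never silently dropping a row.

.reactant_roles <- c("halide", "nucleophile", "substrate")
.reagent_roles  <- c("catalyst_metal", "ligand", "base", "solvent", "additive")
.record_columns <- c("reaction_id", "reaction_class", "timestamp",
                     "target_product_id", .reactant_roles, .reagent_roles,
                     "temperature", "outcome", "transformation", "flags")

#' Column mapping for the reaction CSV schema
#'
#' Maps the canonical record fields to the column names used in an input CSV.
#' Fields mapped to \code{NA} are treated as absent from the file.
#'
#' @param ... overrides, e.g. \code{outcome = "yield_pct"}.
#' @return named list (class \code{hte_schema}).
#' @export
hte_schema <- function(...) {
  s <- list(
    id = "reaction_id", class = "reaction_class", date = "timestamp",
    product = "target_product_id",
    halide = "halide", nucleophile = "nucleophile", substrate = "substrate",
    catalyst_metal = "catalyst_metal", ligand = "ligand", base = "base",
    solvent = "solvent", additive = "additive",
    temperature = "temperature", outcome = "outcome",
    transformation = "transformation"
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(s))
  if (length(bad)) stop("unknown schema fields: ", paste(bad, collapse = ", "))
  s[names(dots)] <- dots
  structure(s, class = "hte_schema")
}

# temperature strings commonly found in HTE exports
.temperature_aliases <- c("rt" = 25, "r.t." = 25, "room temp" = 25,
                          "room temperature" = 25, "ambient" = 25,
                          "reflux" = NA_real_)

.parse_temperature <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- suppressWarnings(as.numeric(x))
  hit <- !is.na(match(x, names(.temperature_aliases)))
  out[hit] <- .temperature_aliases[x[hit]]
  out
}

.add_flag <- function(flags, idx, what) {
  flags[idx] <- ifelse(nzchar(flags[idx]), paste(flags[idx], what, sep = ";"),
                       what)
  flags
}

#' Read an HTE reaction CSV into a reaction table
#'
#' Reads a UTF-8 CSV with a header row, maps columns through a schema, parses
#' temperatures (string set points such as \code{"rt"} are resolved through a
#' small dictionary before the missing-temperature filter ever sees them) and
#' canonicalizes all reactant SMILES. Rows with unparseable structures are
#' flagged \code{invalid_structure:<role>}, never dropped.
#'
#' @param path CSV file path.
#' @param schema an \code{\link{hte_schema}} column mapping.
#' @param canonicalize canonicalize reactant SMILES (default TRUE).
#' @return reaction table (\code{data.frame}); zero rows (with a warning) for
#'   an empty file.
#' @export
parse_reactions <- function(path, schema = hte_schema(), canonicalize = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0) {
    warning("empty reaction file: ", path)
    return(empty_reactions())
  }
  mandatory <- c("class", "temperature", "outcome")
  for (f in mandatory) {
    col <- schema[[f]]
    if (is.na(col) || !col %in% names(raw)) {
      stop("schema error: mandatory column '", col, "' (field '", f,
           "') not present in ", path)
    }
  }
  has_reactant <- any(vapply(.reactant_roles, function(r) {
    !is.na(schema[[r]]) && schema[[r]] %in% names(raw)
  }, logical(1)))
  if (!has_reactant) {
    stop("schema error: no reactant column (halide/nucleophile/substrate) in ",
         path)
  }

  grab <- function(field) {
    col <- schema[[field]]
    if (!is.na(col) && col %in% names(raw)) {
      v <- trimws(raw[[col]])
      v[v == ""] <- NA_character_
      v
    } else rep(NA_character_, nrow(raw))
  }

  rec <- data.frame(
    reaction_id = grab("id"),
    reaction_class = grab("class"),
    timestamp = as.Date(grab("date"), optional = TRUE),
    target_product_id = grab("product"),
    stringsAsFactors = FALSE
  )
  if (all(is.na(rec$reaction_id))) {
    rec$reaction_id <- sprintf("rxn_%05d", seq_len(nrow(raw)))
  }
  for (r in .reactant_roles) rec[[r]] <- grab(r)
  for (r in .reagent_roles)  rec[[r]] <- grab(r)
  rec$temperature <- .parse_temperature(grab("temperature"))
  rec$outcome <- suppressWarnings(as.numeric(grab("outcome")))
  rec$transformation <- grab("transformation")
  rec$flags <- ""

  if (canonicalize) {
    for (r in .reactant_roles) {
      present <- !is.na(rec[[r]])
      if (!any(present)) next
      can <- canonical_smiles(rec[[r]][present])
      bad <- is.na(can)
      rec$flags <- .add_flag(rec$flags, which(present)[bad],
                             paste0("invalid_structure:", r))
      rec[[r]][present][!bad] <- can[!bad]
    }
  }
  if (anyDuplicated(rec$reaction_id[!is.na(rec$reaction_id)])) {
    dup <- duplicated(rec$reaction_id)
    rec$reaction_id[dup] <- paste0(rec$reaction_id[dup], "_dup",
                                   seq_len(sum(dup)))
    warning("non-unique reaction_id values were suffixed to restore uniqueness")
  }
  rec
}

#' An empty reaction table with the canonical columns
#' @return zero-row data.frame.
#' @export
empty_reactions <- function() {
  rec <- data.frame(reaction_id = character(0), reaction_class = character(0),
                    stringsAsFactors = FALSE)
  rec$timestamp <- as.Date(character(0))
  rec$target_product_id <- character(0)
  for (r in c(.reactant_roles, .reagent_roles)) rec[[r]] <- character(0)
  rec$temperature <- numeric(0)
  rec$outcome <- numeric(0)
  rec$transformation <- character(0)
  rec$flags <- character(0)
  rec
}

#' Reagent alias dictionary
#'
#' Maps reagent level identifiers (trade or shorthand names) to structures
#' where one exists. A reagent whose identifier neither parses as SMILES nor
#' appears here is treated as "nonsensical" by \code{\link{clean_dataset}}.
#' The table ships as \code{inst/extdata/reagent_aliases.csv} and is editable.
#'
#' @return data.frame with columns \code{name}, \code{smiles} (may be empty
#'   for well-known reagents without a useful connection table).
#' @export
default_reagent_aliases <- function() {
  path <- system.file("extdata", "reagent_aliases.csv", package = "hitea")
  if (!nzchar(path)) path <- "inst/extdata/reagent_aliases.csv"
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Precatalyst lookup table
#'
#' Deterministic mapping from single-entity precatalysts (for example
#' \code{"BrettPhos Pd G1"}) to a (metal source, ligand) pair. Shipped as an
#' editable CSV; unknown precatalysts are never guessed.
#'
#' @return data.frame with columns \code{label}, \code{metal_source},
#'   \code{ligand}.
#' @export
default_precatalysts <- function() {
  path <- system.file("extdata", "precatalysts.csv", package = "hitea")
  if (!nzchar(path)) path <- "inst/extdata/precatalysts.csv"
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Split a raw catalyst label into metal source and ligand
#'
#' Labels of the form \code{"metal / ligand"} are split on the slash;
#' single-token labels are looked up in the precatalyst table; anything else
#' passes through as a bare metal source with no ligand and a warning.
#'
#' @param raw_catalyst_label non-empty catalyst string.
#' @param precatalyst_table lookup table, see \code{\link{default_precatalysts}}.
#' @return list with \code{metal_source}, \code{ligand} (NA when absent) and
#'   \code{is_precatalyst}.
#' @export
split_catalyst_system <- function(raw_catalyst_label,
                                  precatalyst_table = default_precatalysts()) {
  lab <- trimws(raw_catalyst_label)
  if (length(lab) != 1 || is.na(lab) || !nzchar(lab)) {
    stop("catalyst label must be a single non-empty string")
  }
  if (grepl("/", lab, fixed = TRUE)) {
    parts <- trimws(strsplit(lab, "/", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) >= 2) {
      return(list(metal_source = parts[1], ligand = parts[2],
                  is_precatalyst = FALSE))
    }
    lab <- parts[1]
  }
  hit <- match(lab, precatalyst_table$label)
  if (!is.na(hit)) {
    return(list(metal_source = precatalyst_table$metal_source[hit],
                ligand = precatalyst_table$ligand[hit],
                is_precatalyst = TRUE))
  }
  if (grepl("\\s", lab)) {
    warning("unknown multi-token catalyst label '", lab,
            "' passed through as metal source with no ligand")
  }
  list(metal_source = lab, ligand = NA_character_, is_precatalyst = FALSE)
}

# reagent identifiers that parse as SMILES or appear in the alias dictionary
# are sensible; everything else is flagged
.sensible_reagent <- function(levels, aliases) {
  known <- tolower(trimws(levels)) %in% tolower(trimws(aliases$name))
  out <- known
  out[!known] <- is_valid_smiles(levels[!known])
  out
}

#' Clean a reaction table
#'
#' Applies the curation rules for HTE exports, in order: (1) remove rows with
#' missing temperature; (2) remove exact duplicate rows (identical on every
#' field except \code{reaction_id} -- replicate wells that differ in outcome
#' are real data and are kept); (3) flag reagent identifiers that neither parse
#' as SMILES nor appear in the alias dictionary ("nonsensical"; removed only
#' under \code{strict = TRUE}); (4) flag rows whose reaction class implies a
#' mandatory role that is absent (cross-couplings with no catalyst or base).
#' Flagged rows are recorded for manual review, mirroring curation practice
#' where non-standard profiles are inspected rather than auto-corrected.
#'
#' Cleaning is idempotent and conserves records:
#' \code{nrow(input) == nrow(output) + sum(removals)}.
#'
#' @param records reaction table.
#' @param strict also remove rows with nonsensical reagents (default FALSE).
#' @param aliases reagent alias dictionary.
#' @return list (class \code{hte_cleanup}) with elements \code{records} and
#'   \code{log} (counts + flagged ids with reasons).
#' @export
clean_dataset <- function(records, strict = FALSE,
                          aliases = default_reagent_aliases()) {
  n_in <- nrow(records)
  log <- list(removed_missing_temperature = 0L, removed_duplicates = 0L,
              removed_nonsensical = 0L, flagged_for_review = list())
  if (n_in == 0) {
    return(structure(list(records = records, log = log, n_input = 0L),
                     class = "hte_cleanup"))
  }
  keep <- !is.na(records$temperature)
  log$removed_missing_temperature <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  ident <- records[setdiff(names(records), "reaction_id")]
  dup <- duplicated(ident)
  log$removed_duplicates <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  if (nrow(records)) {
    bad_rows <- rep(FALSE, nrow(records))
    for (r in .reagent_roles) {
      lv <- records[[r]]
      present <- !is.na(lv)
      if (!any(present)) next
      ok <- .sensible_reagent(lv[present], aliases)
      bad <- which(present)[!ok]
      if (length(bad)) {
        records$flags <- .add_flag(records$flags, bad,
                                   paste0("nonsensical_reagent:", r))
        bad_rows[bad] <- TRUE
      }
    }
    if (strict) {
      log$removed_nonsensical <- sum(bad_rows)
      records <- records[!bad_rows, , drop = FALSE]
    }
  }

  if (nrow(records)) {
    coupling <- records$reaction_class %in% c("buchwald_hartwig", "ullmann")
    no_cat <- coupling & is.na(records$catalyst_metal) & is.na(records$ligand)
    no_base <- coupling & is.na(records$base)
    for (i in which(no_cat | no_base)) {
      reason <- paste(c(if (no_cat[i]) "missing_catalyst",
                        if (no_base[i]) "missing_base"), collapse = ";")
      records$flags <- .add_flag(records$flags, i, "profile_review")
      log$flagged_for_review[[length(log$flagged_for_review) + 1L]] <-
        list(reaction_id = records$reaction_id[i], reason = reason)
    }
  }

  n_removed <- log$removed_missing_temperature + log$removed_duplicates +
    log$removed_nonsensical
  stopifnot(n_in == nrow(records) + n_removed)
  structure(list(records = records, log = log, n_input = n_in),
            class = "hte_cleanup")
}

#' @export
print.hte_cleanup <- function(x, ...) {
  cat("HTE dataset cleanup:", x$n_input, "records in,",
      nrow(x$records), "out\n")
  cat("  removed (missing temperature):", x$log$removed_missing_temperature,
      "\n  removed (exact duplicates):   ", x$log$removed_duplicates,
      "\n  removed (nonsensical, strict):", x$log$removed_nonsensical,
      "\n  flagged for review:           ", length(x$log$flagged_for_review),
      "\n")
  invisible(x)
}

#' Write a reaction table back to CSV
#' @param records reaction table.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_reactions <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a cleanup log as JSON
#' @param cleanup an \code{hte_cleanup} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_cleanup_log <- function(cleanup, path) {
  jsonlite::write_json(
    c(list(n_input = cleanup$n_input, n_output = nrow(cleanup$records)),
      cleanup$log),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
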