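# Seeded synthetic HTE campaign generator with planted ground truth.
#
# The generator emulates the documented structure of real HTE campaign
# exports: sparse non-combinatorial designs (a seeded subset of the reagent
# cross is actually run), substrate-dependent baseline reactivity, additive
# reagent main effects, uncalibrated yield noise, a point mass of 0%-yield
# failures, and optional temporal drift in reagent availability.

#' Specify a synthetic HTE campaign
#'
#' The yield model is additive with clipping plus a failure point mass:
#' \deqn{y = clip(baseline(pair) + \sum_c effect(level_c) + \epsilon, 0, 100)}
#' with \eqn{\epsilon \sim N(0, noise\_sd)}, and with probability
#' \code{failure_rate} the outcome is replaced by exactly 0 (a hard failure).
#' Low-baseline substrates with strongly negative reagents are additionally
#' clipped to 0, so failures concentrate where chemistry says they should.
#'
#' @param reaction_class one of buchwald_hartwig, ullmann,
#'   hydrogenation_heterogeneous, hydrogenation_homogeneous, other.
#' @param pairs data.frame of reacting pairs with columns \code{halide},
#'   \code{nucleophile} and/or \code{substrate} (SMILES), \code{baseline}
#'   (mean yield in [0, 100]) and optional \code{transformation}.
#' @param reagent_levels named list (by category: catalyst_metal, ligand, base,
#'   solvent, additive) of data.frames with columns \code{level} and
#'   \code{effect} (yield points); every category must contain at least one
#'   zero-effect reference level.
#' @param sparsity fraction of the full reagent cross actually run per pair,
#'   in (0, 1].
#' @param n_replicates replicate wells per sampled combination.
#' @param failure_rate probability of a hard 0% failure, in [0, 1].
#' @param noise_sd yield noise standard deviation (> 0), in yield points.
#' @param temperatures observed discrete temperature set points (deg C).
#' @param temporal_drift optional list with \code{periods} (vector of period
#'   start dates, length P) and \code{availability} (named list:
#'   category -> level x P logical matrix); levels are only sampled in periods
#'   where they are available.
#' @param seed master RNG seed.
#' @return object of class \code{campaign_spec}.
#' @export
campaign_spec <- function(reaction_class, pairs, reagent_levels,
                          sparsity = 1, n_replicates = 1, failure_rate = 0,
                          noise_sd = 10, temperatures = c(80, 100),
                          temporal_drift = NULL, seed = 1) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1,
            all(pairs$baseline >= 0 & pairs$baseline <= 100))
  if (!(sparsity > 0 && sparsity <= 1)) stop("sparsity must be in (0, 1]")
  if (!(failure_rate >= 0 && failure_rate <= 1)) {
    stop("failure_rate must be in [0, 1]")
  }
  if (!(noise_sd > 0)) stop("noise_sd must be > 0")
  if (!length(reagent_levels)) stop("at least one reagent category required")
  bad <- setdiff(names(reagent_levels), .reagent_roles)
  if (length(bad)) stop("unknown reagent categories: ",
                        paste(bad, collapse = ", "))
  for (cat in names(reagent_levels)) {
    rl <- reagent_levels[[cat]]
    stopifnot(is.data.frame(rl), all(c("level", "effect") %in% names(rl)))
    if (!any(rl$effect == 0)) {
      stop("category '", cat, "' needs a zero-effect reference level")
    }
  }
  structure(list(reaction_class = reaction_class, pairs = pairs,
                 reagent_levels = reagent_levels, sparsity = sparsity,
                 n_replicates = n_replicates, failure_rate = failure_rate,
                 noise_sd = noise_sd, temperatures = temperatures,
                 temporal_drift = temporal_drift, seed = as.integer(seed)),
            class = "campaign_spec")
}

# substream seeds derived from the master seed (recorded in the ground truth)
.substream <- function(seed, offset) (as.numeric(seed) * 7 + offset) %% 2147483647

#' Generate a synthetic HTE campaign
#'
#' Fully reproducible from \code{spec$seed}: identical specs give identical
#' record tables. Returns the reaction table in the package's canonical schema
#' (round-trips through \code{\link{clean_dataset}} with an empty log) plus the
#' planted ground truth.
#'
#' @param spec a \code{\link{campaign_spec}}.
#' @return list with \code{records} (reaction table) and \code{truth}:
#'   \code{levels} (data.frame: category, level, effect, intended_class),
#'   \code{latent} (pre-noise mean per record), \code{seeds} (substream seeds).
#' @export
generate_campaign <- function(spec) {
  stopifnot(inherits(spec, "campaign_spec"))
  cats <- names(spec$reagent_levels)
  grid <- expand.grid(lapply(spec$reagent_levels, function(rl) {
    seq_len(nrow(rl))
  }), KEEP.OUT.ATTRS = FALSE)
  n_combo <- nrow(grid)
  n_take <- max(1L, ceiling(spec$sparsity * n_combo))

  drift <- spec$temporal_drift
  periods <- if (is.null(drift)) as.Date("2014-01-01") else
    as.Date(drift$periods)
  period_end <- c(periods[-1] - 1, periods[length(periods)] + 364)

  seeds <- c(design = .substream(spec$seed, 1), noise = .substream(spec$seed, 2),
             failure = .substream(spec$seed, 3), dates = .substream(spec$seed, 4))

  # design: which combinations run, per pair and period
  set.seed(seeds[["design"]])
  rows <- list()
  for (p in seq_len(nrow(spec$pairs))) {
    for (per in seq_along(periods)) {
      g <- grid
      if (!is.null(drift)) {
        for (cat in intersect(names(drift$availability), cats)) {
          av <- drift$availability[[cat]][, per]
          ok_levels <- which(av)
          g <- g[g[[cat]] %in% ok_levels, , drop = FALSE]
        }
      }
      if (!nrow(g)) next
      take <- min(n_take, nrow(g))
      sel <- g[sample.int(nrow(g), take), , drop = FALSE]
      sel <- sel[rep(seq_len(nrow(sel)), each = spec$n_replicates), ,
                 drop = FALSE]
      sel$pair <- p
      sel$period <- per
      rows[[length(rows) + 1L]] <- sel
    }
  }
  if (!length(rows)) stop("infeasible design: no combinations after sparsity")
  des <- do.call(rbind, rows)
  n <- nrow(des)

  # replicate wells of one combination get distinct dates (sampled without
  # replacement within the replicate group), so no two synthetic records are
  # ever byte-identical: the presets are clean by construction
  set.seed(seeds[["dates"]])
  combo_grp <- rep(seq_len(n %/% max(1L, spec$n_replicates) + 1L),
                   each = spec$n_replicates, length.out = n)
  ts_num <- numeric(n)
  for (idx in split(seq_len(n), combo_grp)) {
    per <- des$period[idx[1]]
    span <- as.numeric(period_end[per]) - as.numeric(periods[per]) + 1
    ts_num[idx] <- as.numeric(periods[per]) +
      sample.int(span, length(idx), replace = FALSE) - 1
  }
  ts <- as.Date(ts_num, origin = "1970-01-01")
  temp <- spec$temperatures[1 + (seq_len(n) %% length(spec$temperatures))]

  latent <- spec$pairs$baseline[des$pair]
  for (cat in cats) {
    latent <- latent + spec$reagent_levels[[cat]]$effect[des[[cat]]]
  }
  set.seed(seeds[["noise"]])
  y <- pmin(100, pmax(0, latent + stats::rnorm(n, 0, spec$noise_sd)))
  set.seed(seeds[["failure"]])
  failed <- stats::runif(n) < spec$failure_rate
  y[failed] <- 0

  grab_pair <- function(col) {
    if (col %in% names(spec$pairs)) as.character(spec$pairs[[col]])[des$pair]
    else rep(NA_character_, n)
  }
  rec <- data.frame(
    reaction_id = sprintf("syn_%06d", seq_len(n)),
    reaction_class = spec$reaction_class,
    stringsAsFactors = FALSE)
  rec$timestamp <- ts
  rec$target_product_id <- sprintf("P%03d", des$pair)
  rec$halide <- grab_pair("halide")
  rec$nucleophile <- grab_pair("nucleophile")
  rec$substrate <- grab_pair("substrate")
  for (r in .reagent_roles) {
    rec[[r]] <- if (r %in% cats) {
      spec$reagent_levels[[r]]$level[des[[r]]]
    } else rep(NA_character_, n)
  }
  rec$temperature <- temp
  rec$outcome <- round(y, 2)
  rec$transformation <- grab_pair("transformation")
  rec$flags <- ""
  rownames(rec) <- NULL

  truth_levels <- do.call(rbind, lapply(cats, function(cat) {
    rl <- spec$reagent_levels[[cat]]
    data.frame(category = cat, level = rl$level, effect = rl$effect,
               intended_class = ifelse(rl$effect >= 1.5 * spec$noise_sd, "best",
                                ifelse(rl$effect <= -1.5 * spec$noise_sd,
                                       "worst", "neutral")),
               stringsAsFactors = FALSE)
  }))
  list(records = rec,
       truth = list(levels = truth_levels, latent = latent,
                    failed = failed, seeds = seeds))
}

# -- presets ------------------------------------------------------------------

.buchwald_pairs <- function() {
  # 29 unique reacting pairs spread over coupling subclasses, "wide but
  # shallow"; baselines differ per pair to emulate substrate-dependent
  # reactivity
  hal <- list(
    ArBr = c("Brc1ccccc1", "Brc1ccc(C)cc1", "Brc1cccnc1", "Brc1ccc(OC)cc1"),
    ArCl = c("Clc1ccccc1", "Clc1ccc(C)cc1", "Clc1ccncc1"),
    ArI = c("Ic1ccccc1", "Ic1ccc(C)cc1"))
  nuc <- list(
    `primary amine` = c("NCCCC", "NCc1ccccc1", "Nc1ccccc1", "NC1CCCCC1",
                        "NCCO", "NCCc1ccccc1"),
    `secondary amine` = c("C1CCNCC1", "O1CCNCC1", "CNCc1ccccc1"),
    amide = c("NC(=O)c1ccccc1", "CC(N)=O"),
    `aromatic nitrogen` = c("c1cc[nH]n1", "c1ccc2[nH]ccc2c1", "c1c[nH]cn1"),
    `primary alcohol` = c("OCc1ccccc1", "CCCCO"),
    `secondary alcohol` = c("CC(C)O", "OC1CCCCC1", "CC(O)c1ccccc1"))
  p <- rbind(
    data.frame(halide = hal$ArBr[1:3], nucleophile = nuc$`primary amine`[1:3]),
    data.frame(halide = hal$ArBr[c(1, 2, 4)],
               nucleophile = nuc$`secondary amine`[1:3]),
    data.frame(halide = hal$ArBr[1:2], nucleophile = nuc$amide[1:2]),
    data.frame(halide = hal$ArBr[1:3],
               nucleophile = nuc$`aromatic nitrogen`[1:3]),
    data.frame(halide = hal$ArBr[1:2], nucleophile = nuc$`primary alcohol`[1:2]),
    data.frame(halide = hal$ArBr[1:3],
               nucleophile = nuc$`secondary alcohol`[1:3]),
    data.frame(halide = rep(hal$ArCl[1:3], 2),
               nucleophile = nuc$`primary amine`[1:6]),
    data.frame(halide = hal$ArCl[1:2], nucleophile = nuc$`secondary amine`[1:2]),
    data.frame(halide = hal$ArI[1:2], nucleophile = nuc$`primary alcohol`[1:2]),
    data.frame(halide = hal$ArI[1:2], nucleophile = nuc$`secondary amine`[1:2]),
    data.frame(halide = hal$ArI[1], nucleophile = nuc$amide[1])
  )
  p$baseline <- seq(30, 70, length.out = nrow(p))
  p
}

.preset_specs <- function(seed = 1) {
  list(
    buchwald_like = campaign_spec(
      reaction_class = "buchwald_hartwig",
      pairs = .buchwald_pairs(),
      reagent_levels = list(
        catalyst_metal = data.frame(level = "Pd(OAc)2", effect = 0,
                                    stringsAsFactors = FALSE),
        ligand = data.frame(
          level = c("BrettPhos", "SPhos", "XPhos", "PCy3", "PnBu3"),
          effect = c(15, 0, 0, 0, -15), stringsAsFactors = FALSE),
        base = data.frame(
          level = c("Cs2CO3", "K3PO4", "KOtBu", "P4-t-Bu"),
          effect = c(15, 0, 0, -15), stringsAsFactors = FALSE),
        solvent = data.frame(
          level = c("dioxane", "toluene", "THF"),
          effect = c(0, 0, 0), stringsAsFactors = FALSE)),
      sparsity = 0.75, n_replicates = 2, failure_rate = 0.05, noise_sd = 10,
      temperatures = c(80, 100), seed = seed),

    ullmann_like = campaign_spec(
      reaction_class = "ullmann",
      pairs = {
        p <- rbind(
          data.frame(halide = c("Ic1ccccc1", "Ic1ccc(C)cc1", "Ic1ccccc1"),
                     nucleophile = c("c1cc[nH]n1", "c1cc[nH]n1", "c1c[nH]cn1"),
                     stringsAsFactors = FALSE),
          data.frame(halide = c("Ic1ccccc1", "Ic1ccc(C)cc1"),
                     nucleophile = c("CC(C)O", "OC1CCCCC1")),
          data.frame(halide = c("Brc1ccccc1", "Brc1ccc(C)cc1"),
                     nucleophile = c("OCC=C", "OCC=C")),
          data.frame(halide = c("Ic1ccccc1", "Ic1ccc(C)cc1"),
                     nucleophile = c("CCCCO", "OCc1ccccc1")))
        p$baseline <- seq(35, 65, length.out = nrow(p))
        p
      },
      reagent_levels = list(
        catalyst_metal = data.frame(level = "CuI", effect = 0,
                                    stringsAsFactors = FALSE),
        ligand = data.frame(
          level = c("phenanthroline", "DMEDA", "trans-DACH", "DMPAO"),
          effect = c(15, 0, 0, -15), stringsAsFactors = FALSE),
        base = data.frame(
          level = c("K3PO4", "Cs2CO3", "K2CO3"),
          effect = c(0, 0, 0), stringsAsFactors = FALSE),
        solvent = data.frame(
          level = c("dioxane", "DMAc", "toluene"),
          effect = c(15, 0, -15), stringsAsFactors = FALSE)),
      sparsity = 0.9, n_replicates = 4, failure_rate = 0.05, noise_sd = 10,
      temperatures = c(100), seed = seed),

    hydrogenation_like = campaign_spec(
      reaction_class = "hydrogenation_heterogeneous",
      pairs = {
        subs <- rbind(
          data.frame(substrate = c("C=Cc1ccccc1", "CCCCC=C", "C1CCC=CC1"),
                     transformation = "alkene", stringsAsFactors = FALSE),
          data.frame(substrate = c(
            "O=C(OCc1ccccc1)NCC", "O=C(OCc1ccccc1)NC1CCCCC1",
            "O=C(OCc1ccccc1)NCc1ccccc1", "OCc1ccccc1",
            "CCOCc1ccccc1", "CCCOCc1ccccc1", "O=C(OCc1ccccc1)NCCC",
            "COCc1ccccc1", "CC(C)OCc1ccccc1"),
            transformation = "deprotection"),
          data.frame(substrate = c("c1ccncc1", "Cc1ccncc1", "c1ccc2ncccc2c1",
                                   "Cc1cccnc1", "CCc1ccncc1"),
                     transformation = "dearomatization"),
          data.frame(substrate = c("CC(=O)c1ccccc1", "CCC(C)=O",
                                   "O=C1CCCCC1", "CC(=O)CC(C)C"),
                     transformation = "carbonyl reduction"))
        subs$baseline <- rep(seq(35, 65, length.out = 7),
                             length.out = nrow(subs))
        subs
      },
      reagent_levels = list(
        catalyst_metal = data.frame(
          level = c("Pd(OH)2/C", "Pd/C 10%", "Pd/C 5%", "PtO2"),
          effect = c(15, 0, 0, -15), stringsAsFactors = FALSE),
        additive = data.frame(
          level = c("none", "AcOH", "zinc dust"),
          effect = c(0, 0, -15), stringsAsFactors = FALSE),
        solvent = data.frame(
          level = c("MeOH", "EtOH", "EtOAc"),
          effect = c(0, 0, 0), stringsAsFactors = FALSE)),
      sparsity = 0.8, n_replicates = 1, failure_rate = 0.05, noise_sd = 10,
      temperatures = c(25, 50), seed = seed),

    # difficult, failure-dominated chemistry: baselines sit just above 0, so
    # a strongly negative reagent drives its wells to exactly 0 via clipping.
    # The 0% outcomes ARE the evidence for the worst-in-class reagents here,
    # which is what the zero-yield ablation probes.
    high_failure = campaign_spec(
      reaction_class = "buchwald_hartwig",
      pairs = data.frame(
        halide = c("Brc1ccccc1", "Brc1ccc(C)cc1", "Brc1cccnc1"),
        nucleophile = c("NCCCC", "NCc1ccccc1", "NC1CCCCC1"),
        baseline = c(12, 15, 18), stringsAsFactors = FALSE),
      reagent_levels = list(
        catalyst_metal = data.frame(level = "Pd(OAc)2", effect = 0,
                                    stringsAsFactors = FALSE),
        ligand = data.frame(
          level = c("BrettPhos", "SPhos", "PnBu3"),
          effect = c(25, 0, -30), stringsAsFactors = FALSE),
        base = data.frame(
          level = c("Cs2CO3", "K3PO4", "KOtBu"),
          effect = c(0, 0, 0), stringsAsFactors = FALSE),
        solvent = data.frame(level = c("dioxane", "toluene"),
                             effect = c(0, 0), stringsAsFactors = FALSE)),
      sparsity = 1, n_replicates = 6, failure_rate = 0.3, noise_sd = 10,
      temperatures = c(100), seed = seed),

    temporal_drift = campaign_spec(
      reaction_class = "buchwald_hartwig",
      pairs = data.frame(
        halide = c("Brc1ccccc1", "Brc1ccc(C)cc1"),
        nucleophile = c("NCCCC", "NCc1ccccc1"),
        baseline = c(45, 55), stringsAsFactors = FALSE),
      reagent_levels = list(
        catalyst_metal = data.frame(level = "Pd(OAc)2", effect = 0,
                                    stringsAsFactors = FALSE),
        ligand = data.frame(
          level = c("BrettPhos", "SPhos", "XPhos"),
          effect = c(15, 0, -15), stringsAsFactors = FALSE),
        base = data.frame(level = c("Cs2CO3", "K3PO4"), effect = c(0, 0),
                          stringsAsFactors = FALSE),
        solvent = data.frame(level = c("dioxane", "toluene"), effect = c(0, 0),
                             stringsAsFactors = FALSE)),
      sparsity = 1, n_replicates = 5, failure_rate = 0.02, noise_sd = 10,
      temperatures = c(80, 100),
      temporal_drift = list(
        periods = as.Date(c("2014-01-01", "2015-01-01")),
        availability = list(
          ligand = matrix(c(TRUE, TRUE, FALSE,   # period 1: no XPhos
                            TRUE, TRUE, TRUE),   # period 2: all
                          ncol = 2,
                          dimnames = list(c("BrettPhos", "SPhos", "XPhos"),
                                          NULL)))),
      seed = seed))
}

#' Named preset campaign specifications
#'
#' Ships fixtures mirroring the structure of the four reaction classes the
#' framework was designed around: \code{"buchwald_like"} (wide but shallow; 29
#' unique reacting pairs across many coupling subclasses),
#' \code{"ullmann_like"} (narrow but deep; 9 pairs), and
#' \code{"hydrogenation_like"} (transformation-typed substrates). Two further
#' presets support the ablation studies: \code{"high_failure"} (low baselines
#' and a large 0%-failure point mass) and \code{"temporal_drift"} (a ligand
#' only available in the second screening period).
#'
#' @param seed master seed threaded into every spec.
#' @return named list of \code{campaign_spec} objects.
#' @export
preset_fixtures <- function(seed = 1) .preset_specs(seed)

#' Generate a preset campaign by name
#'
#' @param name preset name, see \code{\link{preset_fixtures}}.
#' @param seed master seed.
#' @return list with \code{records} and \code{truth}, as
#'   \code{\link{generate_campaign}}.
#' @export
preset_campaign <- function(name, seed = 1) {
  specs <- .preset_specs(seed)
  if (!name %in% names(specs)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(specs), collapse = ", "))
  }
  generate_campaign(specs[[name]])
}

#' Compare recovered best/worst labels against planted ground truth
#'
#' For every analysable subreactome and every reagent category with planted
#' non-neutral levels, checks whether the ranking branch assigned the intended
#' class to each planted level observed in that subreactome.
#'
#' @param bundle a \code{hitea} result computed on a generated campaign.
#' @param truth the \code{truth} element of \code{\link{generate_campaign}}.
#' @return data.frame with one row per (subreactome, category, planted level):
#'   \code{intended_class}, \code{observed_class}, \code{hit}.
#' @export
planted_recovery <- function(bundle, truth) {
  planted <- truth$levels[truth$levels$intended_class != "neutral", ,
                          drop = FALSE]
  rows <- list()
  for (r in bundle$subreactomes) {
    sub_id <- paste(r$reaction_class, r$subclass, sep = " / ")
    for (i in seq_len(nrow(planted))) {
      cat_i <- planted$category[i]
      rk <- r$rankings[[cat_i]]
      if (is.null(rk)) next
      m <- match(planted$level[i], rk$entries$level)
      if (is.na(m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subreactome = sub_id, category = cat_i, level = planted$level[i],
        intended_class = planted$intended_class[i],
        observed_class = rk$entries$class[m],
        hit = rk$entries$class[m] == planted$intended_class[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(subreactome = character(0), category = character(0),
                      level = character(0), intended_class = character(0),
                      observed_class = character(0), hit = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a campaign (records + ground-truth manifest) to disk
#'
#' @param campaign result of \code{\link{generate_campaign}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reactions(campaign$records, file.path(dir, "reactions.csv"))
  jsonlite::write_json(
    list(levels = campaign$truth$levels,
         seeds = as.list(campaign$truth$seeds)),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
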