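# Independent textbook-formula oracles for one-way ANOVA and Tukey-Kramer,
# written from the sums-of-squares definitions. They share no code with the
# package implementation (which goes through aov()/TukeyHSD()).

oracle_anova <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  F <- msb / msw
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Tukey-Kramer: q = |mi - mj| / sqrt(MSE/2 * (1/ni + 1/nj)), p from the
# studentized range distribution with k groups and N - k df
oracle_tukey <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                    numeric(1))) / (N - k)
  pairs <- utils::combn(names(groups), 2)
  p_adj <- apply(pairs, 2, function(pr) {
    d <- abs(means[pr[1]] - means[pr[2]])
    se <- sqrt(mse / 2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
    stats::ptukey(d / se, nmeans = k, df = N - k, lower.tail = FALSE)
  })
  data.frame(level1 = pairs[1, ], level2 = pairs[2, ], p_adj = p_adj,
             stringsAsFactors = FALSE)
}

# match a package tukey table (level1/level2 in either order) against the
# oracle and return max |p difference|
tukey_p_gap <- function(pkg, oracle) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(pkg$level1, pkg$level2), key(oracle$level1, oracle$level2))
  stopifnot(!anyNA(m))
  max(abs(pkg$p_adj - oracle$p_adj[m]))
}

# minimal reaction table builder for unit tests
make_records <- function(n, class = "buchwald_hartwig",
                         halide = "Brc1ccccc1", nucleophile = "NCCCC",
                         substrate = NA_character_,
                         ligand = NA_character_, base = NA_character_,
                         solvent = NA_character_, additive = NA_character_,
                         catalyst_metal = NA_character_,
                         temperature = 100, outcome = 50,
                         timestamp = as.Date("2014-06-01"),
                         transformation = NA_character_) {
  rec <- data.frame(
    reaction_id = sprintf("t%04d", seq_len(n)),
    reaction_class = rep_len(class, n), stringsAsFactors = FALSE)
  rec$timestamp <- rep_len(timestamp, n)
  rec$target_product_id <- rep_len("P001", n)
  rec$halide <- rep_len(halide, n)
  rec$nucleophile <- rep_len(nucleophile, n)
  rec$substrate <- rep_len(substrate, n)
  rec$catalyst_metal <- rep_len(catalyst_metal, n)
  rec$ligand <- rep_len(ligand, n)
  rec$base <- rep_len(base, n)
  rec$solvent <- rep_len(solvent, n)
  rec$additive <- rep_len(additive, n)
  rec$temperature <- rep_len(temperature, n)
  rec$outcome <- rep_len(outcome, n)
  rec$transformation <- rep_len(transformation, n)
  rec$flags <- ""
  rec
}

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
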