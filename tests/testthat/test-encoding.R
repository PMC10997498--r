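# One-hot encoding and correlation merging.

enc_records <- function(bases, additive = NA_character_) {
  rec <- make_records(length(bases), catalyst_metal = "Pd(OAc)2")
  rec$base <- bases
  rec$additive <- rep_len(additive, length(bases))
  rec$outcome <- seq_along(bases)
  rec
}

test_that("one-hot encoding has one column per level, row sums <= 1", {
  rec <- enc_records(rep(c("A", "B", "C"), length.out = 10))
  dm <- one_hot_encode(rec, "base")
  expect_equal(ncol(dm$matrix), 3)
  expect_true(all(dm$matrix %in% c(0L, 1L)))
  expect_equal(unname(rowSums(dm$matrix)), rep(1, 10))
  expect_error(one_hot_encode(rec, character(0)), "empty")
})

test_that("absent roles give all-zero row segments and counting is right", {
  rec <- enc_records(c("A", "A", "B", "C"), additive = "AcOH")
  rec$additive[2] <- NA
  dm <- one_hot_encode(rec, c("base", "additive"))
  expect_equal(sum(dm$matrix[, "base=A"]), 2)
  add_cols <- dm$column_meta$name[dm$column_meta$category == "additive"]
  expect_equal(sum(dm$matrix[2, add_cols]), 0)
  # within one category, each row sums to <= 1
  base_cols <- dm$column_meta$name[dm$column_meta$category == "base"]
  expect_true(all(rowSums(dm$matrix[, base_cols, drop = FALSE]) <= 1))
})

test_that("pairwise correlations match the direct formula", {
  rec <- enc_records(c("A", "A", "B", "B"))
  rec$additive <- c("X", "Y", "X", "Y")
  dm <- one_hot_encode(rec, c("base", "additive"))
  cc <- design_correlation(dm)
  expect_equal(unname(diag(cc)), rep(1, ncol(cc)))
  # complementary indicators are perfectly anti-correlated
  expect_equal(unname(cc["base=A", "base=B"]), -1)
  # orthogonal design: [1,1,0,0] vs [1,0,1,0]
  expect_equal(unname(cc["base=A", "additive=X"]), 0)
  one_col <- one_hot_encode(enc_records(rep("A", 4))["base" == "base", ],
                            "base")
  expect_error(design_correlation(one_col), "2 columns")
})

test_that("correlated columns merge into OR-unioned components", {
  # CuI and dioxane always co-occur -> identical indicator columns
  rec <- enc_records(rep(c("K3PO4", "Cs2CO3"), 5))
  rec$solvent <- ifelse(rec$base == "K3PO4", "dioxane", "toluene")
  rec$catalyst_metal <- ifelse(rec$base == "K3PO4", "CuI", "Pd(OAc)2")
  dm <- one_hot_encode(rec, c("catalyst_metal", "base", "solvent"))
  merged <- merge_correlated(dm, threshold = 0.85)
  expect_lt(ncol(merged$matrix), ncol(dm$matrix))
  mf <- merged$column_meta$merged_from
  merged_cols <- which(lengths(mf) > 0)
  expect_true(length(merged_cols) >= 1)
  expect_true(any(vapply(mf[merged_cols], function(x) {
    all(c("catalyst_metal=CuI", "solvent=dioxane") %in% x)
  }, logical(1))))
  # merged indicator is the OR of its members
  j <- merged_cols[1]
  expect_true(all(merged$matrix[, merged$column_meta$name[j]] %in% c(0L, 1L)))
})

test_that("merging is transitive over components and order-independent", {
  set.seed(23)
  x <- rbinom(30, 1, 0.4)
  y <- rbinom(30, 1, 0.4)
  m <- cbind(`base=A` = x, `base=B` = 1L - x, `solvent=S1` = x,
             `solvent=S2` = y)
  cm <- data.frame(name = colnames(m),
                   category = c("base", "base", "solvent", "solvent"),
                   level = c("A", "B", "S1", "S2"), stringsAsFactors = FALSE)
  cm$merged_from <- replicate(4, character(0), simplify = FALSE)
  dm <- structure(list(matrix = m, column_meta = cm,
                       row_ids = sprintf("r%02d", 1:30)),
                  class = "hte_design")
  merged <- merge_correlated(dm)
  # {A, B, S1} form one transitive component (A = S1, B = 1 - A); the merged
  # indicator equals A (B absorbed as the complement), S2 passes through
  expect_equal(ncol(merged$matrix), 2)
  mf <- merged$column_meta$merged_from
  comp <- mf[[which(lengths(mf) > 0)]]
  expect_setequal(comp, c("base=A", "base=B", "solvent=S1"))
  merged_col <- merged$column_meta$name[lengths(mf) > 0]
  expect_equal(unname(merged$matrix[, merged_col]), unname(x))

  # column order does not change the component decomposition
  perm <- c(4, 2, 3, 1)
  dm_perm <- dm
  dm_perm$matrix <- dm$matrix[, perm]
  dm_perm$column_meta <- dm$column_meta[perm, ]
  merged_perm <- merge_correlated(dm_perm)
  expect_setequal(
    unname(vapply(merged$column_meta$merged_from, paste, "", collapse = ",")),
    unname(vapply(merged_perm$column_meta$merged_from, paste, "",
                  collapse = ",")))
  expect_identical(sort(merged$column_meta$name),
                   sort(merged_perm$column_meta$name))
})

test_that("merging is idempotent and leaves uncorrelated designs unchanged", {
  set.seed(11)
  rec <- make_records(40, catalyst_metal = "Pd(OAc)2")
  rec$base <- sample(c("A", "B", "C"), 40, replace = TRUE)
  rec$solvent <- sample(c("S1", "S2"), 40, replace = TRUE)
  dm <- one_hot_encode(rec, c("base", "solvent"))
  m1 <- merge_correlated(dm)
  m2 <- merge_correlated(m1)
  expect_identical(m1$column_meta$name, m2$column_meta$name)
  expect_identical(m1$matrix, m2$matrix)
  # no remaining pre-merge pair at or above threshold
  cc <- suppressWarnings(design_correlation(m1))
  off <- abs(cc[upper.tri(cc)])
  expect_true(all(off < 0.85 | is.na(off)))
  expect_error(merge_correlated(dm, threshold = 0), "threshold")
  expect_error(merge_correlated(dm, threshold = 1.2), "threshold")
})
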