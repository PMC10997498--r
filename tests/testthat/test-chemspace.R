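# PCA embedding of fingerprints and best/worst annotation.

# synthetic fingerprint set: two tight clusters whose centers differ in 100
# fixed bits, individual members jittered by 2 bits
cluster_fps <- function(n_per = 5, n_bits = 512, seed = 1) {
  set.seed(seed)
  base <- rbinom(n_bits, 1, 0.3)
  centerA <- base
  centerB <- base
  flip <- sample(n_bits, 100)
  centerB[flip] <- 1 - centerB[flip]
  jitter <- function(v) {
    j <- sample(n_bits, 2)
    v[j] <- 1 - v[j]
    v
  }
  m <- rbind(t(replicate(n_per, jitter(centerA))),
             t(replicate(n_per, jitter(centerB))))
  rownames(m) <- c(paste0("A", seq_len(n_per)), paste0("B", seq_len(n_per)))
  structure(m,
            smiles = stats::setNames(rownames(m), rownames(m)),
            failed = character(0), radius = 2,
            class = c("fingerprint_set", "matrix"))
}

test_that("explained variance ratios are sorted and in [0, 1]", {
  fps <- fingerprint_set(c(a = "c1ccccc1", b = "C1CCCCC1", c = "CCO",
                           d = "CCCCN"))
  emb <- pca_embed(fps)
  evr <- emb$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0 & evr <= 1))
  expect_lte(sum(evr), 1 + 1e-9)
})

test_that("PC1 separates constructed clusters by more than their spread", {
  fps <- cluster_fps()
  emb <- pca_embed(fps)
  co <- emb$coordinates
  a <- co$pc1[grepl("^A", co$id)]
  b <- co$pc1[grepl("^B", co$id)]
  gap <- abs(mean(a) - mean(b))
  spread <- max(stats::sd(a), stats::sd(b))
  expect_gt(gap, spread)
})

test_that("duplicate structures embed at identical coordinates", {
  fps <- fingerprint_set(c(x = "c1ccccc1", y = "C1CCCCC1", z = "CCO",
                           x2 = "c1ccccc1"))
  emb <- pca_embed(fps)
  co <- emb$coordinates
  expect_equal(co$pc1[co$id == "x"], co$pc1[co$id == "x2"])
  expect_equal(co$pc2[co$id == "x"], co$pc2[co$id == "x2"])
  expect_equal(emb$n_unique, 3)
})

test_that("fewer than 3 unique structures is a cardinality error", {
  fps <- fingerprint_set(c(a = "c1ccccc1", b = "c1ccccc1", c = "CCO"))
  expect_error(pca_embed(fps), "3 unique")
})

test_that("mirroring the data flips coordinates only up to per-axis sign", {
  set.seed(8)
  m <- matrix(stats::rbinom(8 * 200, 1, 0.5), nrow = 8)
  rownames(m) <- paste0("m", 1:8)
  fps <- structure(m, smiles = stats::setNames(rownames(m), rownames(m)),
                   failed = character(0), radius = 2,
                   class = c("fingerprint_set", "matrix"))
  emb <- pca_embed(fps)
  mm <- m[, apply(m, 2, stats::var) > 0]
  mirrored <- -scale(mm, center = TRUE, scale = FALSE)
  pc2 <- stats::prcomp(mirrored, center = TRUE, scale. = FALSE)
  for (j in 1:2) {
    ours <- emb$coordinates[[paste0("pc", j)]]
    theirs <- unname(pc2$x[, j])
    expect_true(isTRUE(all.equal(ours, theirs, tolerance = 1e-6)) ||
                  isTRUE(all.equal(ours, -theirs, tolerance = 1e-6)))
  }
})

test_that("annotation transfers ranking labels and reports the unresolved", {
  fps <- fingerprint_set(c(
    PPh3 = "c1ccc(cc1)P(c1ccccc1)c1ccccc1",
    PCy3 = "C1CCC(CC1)P(C1CCCCC1)C1CCCCC1",
    PtBu3 = "CC(C)(C)P(C(C)(C)C)C(C)(C)C"))
  emb <- pca_embed(fps)
  rk <- structure(list(
    category = "ligand",
    entries = data.frame(level = c("PPh3", "PCy3", "Ghostline"),
                         n = c(30L, 30L, 30L), mean_z = c(0.8, -0.5, 0),
                         class = c("best", "worst", "neutral"),
                         n_significant_pairs = c(2L, 1L, 0L),
                         stringsAsFactors = FALSE)),
    class = "tukey_ranking")
  ann <- annotate_embedding(emb, rk)
  co <- ann$coordinates
  expect_identical(co$label[co$id == "PPh3"], "best")
  expect_identical(co$label[co$id == "PCy3"], "worst")
  expect_identical(co$label[co$id == "PtBu3"], "unranked")
  expect_true("Ghostline" %in% attr(ann, "unresolved"))
})

test_that("all-neutral rankings produce all-neutral labels", {
  fps <- fingerprint_set(c(a = "CCO", b = "CCCO", c = "CCCCO"))
  emb <- pca_embed(fps)
  rk <- structure(list(
    category = "ligand",
    entries = data.frame(level = c("CCO", "CCCO", "CCCCO"),
                         n = 10L, mean_z = 0, class = "neutral",
                         n_significant_pairs = 0L, stringsAsFactors = FALSE)),
    class = "tukey_ranking")
  ann <- annotate_embedding(emb, rk)
  expect_true(all(ann$coordinates$label == "neutral"))
})

test_that("best-in-class ligands cluster more tightly than a random subset", {
  # planted campaign where the best ligands share the biaryl phosphine
  # scaffold and the worst are trialkyl phosphines
  lig <- c(PPh3 = "c1ccc(cc1)P(c1ccccc1)c1ccccc1",
           PTol3 = "Cc1ccc(cc1)P(c1ccc(C)cc1)c1ccc(C)cc1",
           PAn3 = "COc1ccc(cc1)P(c1ccc(OC)cc1)c1ccc(OC)cc1",
           PArF3 = "Fc1ccc(cc1)P(c1ccc(F)cc1)c1ccc(F)cc1",
           PCy3 = "C1CCC(CC1)P(C1CCCCC1)C1CCCCC1",
           PtBu3 = "CC(C)(C)P(C(C)(C)C)C(C)(C)C",
           PnBu3 = "CCCCP(CCCC)CCCC",
           PEt3 = "CCP(CC)CC")
  labels <- rep(c("best", "worst"), each = 4)
  fps <- fingerprint_set(lig)
  emb <- pca_embed(fps)
  co <- emb$coordinates
  xy <- as.matrix(co[, c("pc1", "pc2")])
  dmat <- as.matrix(stats::dist(xy))
  mean_pd <- function(idx) mean(dmat[idx, idx][upper.tri(dmat[idx, idx])])
  best_idx <- which(labels == "best")
  obs <- mean_pd(best_idx)
  # exact permutation distribution over all equal-size subsets
  all_subsets <- utils::combn(length(lig), length(best_idx))
  perm <- apply(all_subsets, 2, mean_pd)
  p_perm <- mean(perm <= obs)
  expect_lt(p_perm, 0.05)
})
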