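# Chemistry primitives: SMILES canonicalization, substructure matching and
# Morgan-type circular fingerprints. OpenBabel (via ChemmineR/ChemmineOB) does
# the structure perception; the circular hashing itself is implemented here.

# session caches -- canonicalization and structure perception are by far the
# most frequently repeated operations in a pipeline run
.chem_cache <- new.env(parent = emptyenv())

.cache_get <- function(key) {
  if (exists(key, envir = .chem_cache, inherits = FALSE)) {
    get(key, envir = .chem_cache, inherits = FALSE)
  } else NULL
}
.cache_set <- function(key, value) {
  assign(key, value, envir = .chem_cache)
  value
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the OpenBabel canonical form. Canonicalization is
#' idempotent: \code{canonical_smiles(canonical_smiles(s))} equals
#' \code{canonical_smiles(s)}. Strings that fail to parse are returned as
#' \code{NA} (callers flag them; they are never silently dropped).
#'
#' @param smiles character vector of SMILES strings (NA allowed).
#' @return character vector of canonical SMILES, \code{NA} where the input
#'   was \code{NA}, empty, or unparseable.
#' @examples
#' \donttest{
#' canonical_smiles(c("OCC", "c1ccccc1", "C1CC"))  # last one is invalid -> NA
#' }
#' @export
canonical_smiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  todo <- which(!is.na(smiles) & nzchar(smiles))
  for (i in todo) {
    s <- smiles[[i]]
    key <- paste0("can|", s)
    hit <- .cache_get(key)
    if (is.null(hit)) {
      res <- tryCatch(
        ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
        error = function(e) ""
      )
      res <- sub("[ \t\r\n]+$", "", res)
      hit <- if (nzchar(res)) res else NA_character_
      .cache_set(key, hit)
    }
    out[[i]] <- hit
  }
  out
}

#' Test whether SMILES strings parse
#'
#' @param smiles character vector.
#' @return logical vector; \code{FALSE} for NA/empty/unparseable strings.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

# Parse one SMILES into an atom/bond connectivity list (cached).
# Returns NULL for unparseable input.
.mol_graph <- function(smiles) {
  key <- paste0("mol|", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(if (identical(hit, FALSE)) NULL else hit)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || !methods::is(sdf, "SDFset") || length(sdf) < 1) {
    .cache_set(key, FALSE)
    return(NULL)
  }
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  deg <- integer(n)
  bosum <- numeric(n)
  nbr <- vector("list", n)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (b in seq_len(nrow(bb))) {
      a1 <- bb[b, 1]; a2 <- bb[b, 2]; bo <- bb[b, 3]
      deg[a1] <- deg[a1] + 1L; deg[a2] <- deg[a2] + 1L
      bosum[a1] <- bosum[a1] + bo; bosum[a2] <- bosum[a2] + bo
      nbr[[a1]] <- rbind(nbr[[a1]], c(a2, bo))
      nbr[[a2]] <- rbind(nbr[[a2]], c(a1, bo))
    }
  }
  .cache_set(key, list(elem = elem, degree = deg, bosum = bosum, nbr = nbr))
}

# Deterministic 31-polynomial string hash modulo 2^31 - 1 (exact in doubles).
.str_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

#' Morgan-type circular fingerprint
#'
#' Hashes circular atom neighbourhoods of increasing radius into a fixed-length
#' bit vector, in the spirit of ECFP/Morgan fingerprints. Atom invariants are
#' (element, heavy-atom degree, bond-order sum); at each iteration an atom's
#' identifier is rehashed together with the sorted (bond order, neighbour
#' identifier) pairs of its neighbours. All identifiers collected at radii
#' 0..\code{radius} are folded modulo \code{n_bits}. The encoding is fully
#' deterministic for a fixed (radius, n_bits); it is not bit-compatible with
#' other toolkits' Morgan implementations.
#'
#' @param smiles a single SMILES string (canonicalized internally, so two
#'   spellings of the same molecule give identical fingerprints).
#' @param radius neighbourhood radius (default 2).
#' @param n_bits fingerprint length in bits (default 2048).
#' @return integer vector of 0/1 of length \code{n_bits}.
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  stopifnot(length(smiles) == 1, radius >= 0, n_bits >= 16)
  can <- canonical_smiles(smiles)
  if (is.na(can)) {
    stop("cannot fingerprint unparseable SMILES: '", smiles, "'")
  }
  key <- paste0("fp|", radius, "|", n_bits, "|", can)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  g <- .mol_graph(can)
  if (is.null(g)) stop("cannot fingerprint unparseable SMILES: '", smiles, "'")
  n <- length(g$elem)
  ids <- vapply(seq_len(n), function(a) {
    .str_hash(paste(g$elem[a], g$degree[a], g$bosum[a], sep = "|"))
  }, numeric(1))
  all_ids <- ids
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(a) {
        nb <- g$nbr[[a]]
        if (is.null(nb)) return(.str_hash(paste0("t|", ids[a])))
        parts <- sort(paste(nb[, 2], ids[nb[, 1]], sep = ":"))
        .str_hash(paste(c(ids[a], parts), collapse = ";"))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  fp <- integer(n_bits)
  fp[unique(all_ids %% n_bits) + 1] <- 1L
  .cache_set(key, fp)
}

#' Fingerprint a set of structures
#'
#' @param smiles character vector of SMILES; names (if any) are used as ligand
#'   identifiers, otherwise the SMILES themselves.
#' @param radius,n_bits passed to \code{\link{morgan_fingerprint}}.
#' @return an object of class \code{fingerprint_set}: a 0/1 matrix with one row
#'   per input entry (identical canonical SMILES give identical rows), with
#'   attributes \code{smiles} (canonical) and \code{failed} (identifiers whose
#'   structures did not parse; they are excluded from the matrix, not dropped
#'   silently).
#' @export
fingerprint_set <- function(smiles, radius = 2, n_bits = 2048) {
  ids <- names(smiles)
  if (is.null(ids)) ids <- as.character(smiles)
  can <- canonical_smiles(as.character(smiles))
  ok <- !is.na(can)
  mat <- matrix(0L, nrow = sum(ok), ncol = n_bits,
                dimnames = list(ids[ok], NULL))
  uc <- unique(can[ok])
  fps <- lapply(uc, morgan_fingerprint, radius = radius, n_bits = n_bits)
  names(fps) <- uc
  for (i in seq_along(which(ok))) {
    mat[i, ] <- fps[[can[ok][i]]]
  }
  structure(mat,
            smiles = stats::setNames(can[ok], ids[ok]),
            failed = ids[!ok],
            radius = radius,
            class = c("fingerprint_set", "matrix"))
}

#' Tanimoto similarity of two bit vectors
#'
#' \code{|intersection| / |union|} of the on-bits; two empty fingerprints have
#' similarity 0 by convention.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Pairwise Tanimoto matrix
#'
#' @param fps a \code{fingerprint_set} (or plain 0/1 matrix, rows = molecules).
#' @return symmetric matrix with unit diagonal.
#' @export
tanimoto_matrix <- function(fps) {
  m <- unclass(fps)
  attr(m, "smiles") <- NULL; attr(m, "failed") <- NULL; attr(m, "radius") <- NULL
  storage.mode(m) <- "double"
  inter <- m %*% t(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  diag(out) <- 1
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

# Count SMARTS matches for each SMILES (vectorized over smiles, cached).
# Unparseable SMILES yield NA.
.smarts_count <- function(smiles, smarts) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_real_)
    key <- paste0("sm|", smarts, "|", s)
    hit <- .cache_get(key)
    if (!is.null(hit)) return(hit)
    g <- .mol_graph(s)
    if (is.null(g)) return(.cache_set(key, NA_real_))
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)),
                    error = function(e) NULL)
    if (is.null(sdf)) return(.cache_set(key, NA_real_))
    n <- tryCatch(
      suppressWarnings(as.numeric(ChemmineR::smartsSearchOB(sdf, smarts))[1]),
      error = function(e) NA_real_
    )
    .cache_set(key, n)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Match a SMARTS pattern against SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @param smarts a single SMARTS pattern.
#' @return logical vector (\code{NA} where the structure does not parse).
#' @export
smarts_match <- function(smiles, smarts) {
  .smarts_count(smiles, smarts) > 0
}
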