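#' Parse SMILES into an SDF set, rejecting unparseable records
#'
#' @param smiles Character vector of SMILES.
#' @param ids Character ids (default "m1", "m2", ...).
#' @return List with `sdf` (a `ChemmineR::SDFset` of the valid records),
#'   `valid` (logical per input), `rejected` (data.frame id/smiles/reason).
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  sdf <- suppressWarnings(tryCatch(ChemmineR::smiles2sdf(smiles),
                                   error = function(e) NULL))
  if (is.null(sdf) || length(sdf) != length(smiles)) {
    # batch parse failed somewhere: fall back to per-molecule parsing
    parsed <- lapply(smiles, function(s) {
      suppressWarnings(tryCatch(ChemmineR::smiles2sdf(s),
                                error = function(e) NULL))
    })
    ok <- !vapply(parsed, is.null, logical(1))
    ok[ok] <- vapply(parsed[ok], function(x) {
      nrow(ChemmineR::atomblock(x[[1]])) > 0
    }, logical(1))
    good <- parsed[ok]
    sdf <- if (length(good) > 1) do.call(c, good)
           else if (length(good) == 1) good[[1]] else NULL
  } else {
    ok <- vapply(seq_along(sdf), function(i) {
      nrow(ChemmineR::atomblock(sdf[[i]])) > 0
    }, logical(1))
    sdf <- if (any(ok)) sdf[which(ok)] else NULL
  }
  if (!is.null(sdf)) ChemmineR::cid(sdf) <- ids[ok]
  list(sdf = sdf, valid = ok,
       rejected = data.frame(id = ids[!ok], smiles = smiles[!ok],
                             reason = rep("unparseable SMILES", sum(!ok))))
}

#' Featurize molecules as binary fingerprints
#'
#' Computes 1024-bit path-based binary fingerprints (OpenBabel FP2) from
#' SMILES. The fingerprint is a graph property of the molecule, so any two
#' SMILES spellings of the same structure give identical vectors. The
#' featurizer is deliberately a plain function from SMILES to a numeric
#' matrix so alternative embeddings can be plugged into the surrogate.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional ids used as rownames.
#' @return List with `features` (0/1 matrix, one row per valid molecule),
#'   and `rejected` (data.frame of unparseable records with reasons).
#' @export
featurize <- function(smiles, ids = NULL) {
  p <- parse_smiles(smiles, ids)
  if (is.null(p$sdf)) {
    return(list(features = matrix(0, 0, 1024), rejected = p$rejected))
  }
  fp <- suppressWarnings(ChemmineR::fingerprintOB(p$sdf, "FP2"))
  m <- fp@fpma
  storage.mode(m) <- "integer"
  rownames(m) <- ChemmineR::cid(p$sdf)
  colnames(m) <- paste0("fp", seq_len(ncol(m)))
  list(features = m, rejected = p$rejected)
}

#' Tanimoto similarity matrix of binary fingerprints
#'
#' @param fp 0/1 matrix, molecules in rows.
#' @param fp2 Optional second matrix; default similarity of `fp` with itself.
#' @return Similarity matrix in [0, 1].
#' @export
tanimoto_matrix <- function(fp, fp2 = fp) {
  common <- tcrossprod(fp, fp2)
  n1 <- rowSums(fp); n2 <- rowSums(fp2)
  un <- outer(n1, n2, "+") - common
  s <- common / un
  s[un == 0] <- 1  # two empty fingerprints: treat as identical
  s
}

#' Leader-style (Butina) Tanimoto clustering
#'
#' Classic sphere-exclusion clustering on binary-fingerprint Tanimoto
#' similarity: the unassigned molecule with the most neighbours at
#' similarity >= cutoff becomes the next cluster centroid and claims all
#' its unassigned neighbours, so every member has similarity >= cutoff to
#' its centroid by construction. Centroids are flagged for purchase-list
#' export.
#'
#' @param fp 0/1 fingerprint matrix with rownames as ids (e.g. from
#'   [featurize()]).
#' @param cutoff Tanimoto similarity cutoff (default 0.78).
#' @return data.frame with `id`, `cluster` (integer, by decreasing size
#'   order of formation), `is_centroid`.
#' @export
tanimoto_cluster <- function(fp, cutoff = 0.78) {
  n <- nrow(fp)
  if (n == 0) stop("empty input")
  ids <- rownames(fp)
  if (is.null(ids)) ids <- paste0("m", seq_len(n))
  S <- tanimoto_matrix(fp)
  nbr <- S >= cutoff
  cluster <- rep(NA_integer_, n)
  centroid <- rep(FALSE, n)
  k <- 0L
  counts <- rowSums(nbr)
  while (anyNA(cluster)) {
    k <- k + 1L
    free <- which(is.na(cluster))
    cnt <- vapply(free, function(i) sum(nbr[i, free]), numeric(1))
    # most neighbours; ties by id order for determinism
    c_i <- free[which.max(cnt)]
    members <- free[nbr[c_i, free]]
    cluster[members] <- k
    centroid[c_i] <- TRUE
  }
  data.frame(id = ids, cluster = cluster, is_centroid = centroid,
             stringsAsFactors = FALSE)
}

# ---- CNS MPO ----------------------------------------------------------

# piecewise-linear desirability: 1 on [lo_ideal, hi_ideal] shoulders to 0
# outside [lo_zero, hi_zero]; monotone pieces for one-sided criteria.
mpo_desir <- function(x, ideal_hi, zero_hi, ideal_lo = -Inf, zero_lo = -Inf) {
  ifelse(x <= ideal_hi & x >= ideal_lo, 1,
    ifelse(x >= zero_hi | x <= zero_lo, 0,
      ifelse(x > ideal_hi, (zero_hi - x) / (zero_hi - ideal_hi),
             (x - zero_lo) / (ideal_lo - zero_lo))))
}

#' CNS multiparameter optimization (MPO) desirability score
#'
#' Computes the six-component CNS MPO score (0-6): the sum of
#' piecewise-linear desirability functions of clogP, clogD, molecular
#' weight, TPSA, hydrogen-bond-donor count and the most basic pKa. Because
#' no logD or pKa predictor is bundled, the computed logP stands in for
#' logD and pKa comes from a SMARTS-based most-basic-centre proxy (basic
#' aliphatic amines 10.5, amidine/guanidine 12.5, aromatic amine 4.6,
#' basic azine nitrogen 5.2, otherwise no basic centre, pKa 0); both
#' proxies are declared in the output.
#'
#' Desirability pieces: logP full desirability up to 3, zero at 5; logD up
#' to 2, zero at 4; MW up to 360 Da, zero at 500; TPSA ideal 40-90 A^2,
#' zero at 20 and 120; HBD up to 0.5, zero at 3.5; pKa up to 8, zero at 10.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional ids.
#' @param threshold Pass mark on the 0-6 scale (default 4).
#' @return data.frame with the descriptors, each component score, `mpo`
#'   total, and `pass`; attribute `proxies` records the stand-ins used.
#'   Unparseable molecules are excluded (listed in attribute `rejected`).
#' @export
cns_mpo <- function(smiles, ids = NULL, threshold = 4) {
  p <- parse_smiles(smiles, ids)
  if (is.null(p$sdf)) stop("no valid molecules")
  props <- ChemmineR::propOB(p$sdf)
  hbd <- props$HBD
  logp <- props$logP
  mw <- props$MW
  tpsa <- props$TPSA
  pka <- pka_proxy(p$sdf)
  sc <- data.frame(
    id = ChemmineR::cid(p$sdf),
    logP = logp, logD = logp, MW = mw, TPSA = tpsa, HBD = hbd, pKa = pka,
    d_logP = mpo_desir(logp, 3, 5),
    d_logD = mpo_desir(logp, 2, 4),
    d_MW = mpo_desir(mw, 360, 500),
    d_TPSA = mpo_desir(tpsa, 90, 120, ideal_lo = 40, zero_lo = 20),
    d_HBD = mpo_desir(hbd, 0.5, 3.5),
    d_pKa = mpo_desir(pka, 8, 10),
    stringsAsFactors = FALSE)
  sc$mpo <- with(sc, d_logP + d_logD + d_MW + d_TPSA + d_HBD + d_pKa)
  sc$pass <- sc$mpo >= threshold
  attr(sc, "proxies") <- c(logD = "computed logP", pKa = "SMARTS basic-centre classes")
  attr(sc, "rejected") <- p$rejected
  sc
}

# crude most-basic-pKa classes from substructure matches
pka_proxy <- function(sdf) {
  n <- length(sdf)
  count <- function(sm) {
    res <- tryCatch(ChemmineR::smartsSearchOB(sdf, sm, uniqueMatches = FALSE),
                    error = function(e) rep(0L, n))
    as.numeric(res)
  }
  amidine <- count("[NX3][CX3]=[NX2]")          # amidine/guanidine ~12.5
  aliph <- count("[NX3;H2,H1,H0;!$(NC=O);!$(Na);!$(N[#6]=[#7,#8,#16])&!$(Nc)]")
  azine <- count("[nX2;$(n1ccccc1)]")            # pyridine-like n ~5.2
  aniline <- count("[NX3;H2,H1][c]")             # aromatic amine ~4.6
  pka <- rep(0, n)
  pka[aniline > 0] <- 4.6
  pka[azine > 0] <- 5.2
  pka[aliph > 0] <- 10.5
  pka[amidine > 0] <- 12.5
  pka
}
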