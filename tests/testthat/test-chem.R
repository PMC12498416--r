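test_that("featurization is deterministic and canonicalization-invariant", {
  f1 <- featurize(c("c1ccccc1", "C1=CC=CC=C1", "CCO"))
  expect_identical(f1$features[1, ], f1$features[2, ])  # kekule == aromatic
  f2 <- featurize(c("c1ccccc1", "C1=CC=CC=C1", "CCO"))
  expect_identical(f1$features, f2$features)
  # structurally disjoint molecules share no bits (brute-force comparison)
  a <- f1$features[1, ]; b <- f1$features[3, ]
  expect_equal(sum(a & b) / sum(a | b), 0)
})

test_that("unparseable SMILES are rejected with a reason", {
  f <- suppressWarnings(featurize(c("CCO", "C1CC((("), c("ok", "bad")))
  expect_identical(rownames(f$features), "ok")
  expect_identical(f$rejected$id, "bad")
  expect_match(f$rejected$reason, "unparseable")
})

test_that("tanimoto matrix matches a brute-force loop", {
  lib <- shared_library()
  fp <- lib$features[1:12, ]
  S <- tanimoto_matrix(fp)
  for (i in c(1, 5, 12)) for (j in c(2, 7)) {
    expect_equal(S[i, j],
                 sum(fp[i, ] & fp[j, ]) / sum(fp[i, ] | fp[j, ]))
  }
  expect_true(all(diag(S) == 1))
})

test_that("butina clusters are sound against the full similarity matrix", {
  lib <- shared_library()
  fp <- lib$features[1:50, ]
  cl <- tanimoto_cluster(fp, cutoff = 0.78)
  S <- tanimoto_matrix(fp)
  for (i in seq_len(nrow(cl))) {
    cid <- cl$id[cl$is_centroid & cl$cluster == cl$cluster[i]]
    expect_gte(S[cl$id[i], cid], 0.78)
  }
  # exactly one centroid per cluster
  expect_identical(sum(cl$is_centroid), max(cl$cluster))
})

test_that("duplicates collapse and dissimilar molecules stay singletons", {
  dup <- featurize(c("CCO", "OCC", "CCO"), c("a", "b", "c"))$features
  cl <- tanimoto_cluster(dup, cutoff = 0.78)
  expect_identical(length(unique(cl$cluster)), 1L)
  far <- featurize(c("CCO", "c1ccccc1", "S=C=S", "CCCCCCCC"),
                   c("a", "b", "c", "d"))$features
  cl2 <- tanimoto_cluster(far, cutoff = 0.78)
  expect_identical(max(cl2$cluster), 4L)
  expect_true(all(cl2$is_centroid))
})

test_that("cns_mpo matches a hand-computed desirability table", {
  smis <- c("Cn1cnc2c1c(=O)n(C)c(=O)n2C",     # caffeine: all six ideal
            "CCO", "c1ccccc1",
            "CC(=O)Nc1ccc(O)cc1",
            "CCN(CC)CCNC(=O)c1ccc(N)cc1",     # basic amine -> pKa penalty
            "Clc1ccc(cc1)c1ccc(Cl)cc1c1ccccc1")  # too greasy
  sc <- cns_mpo(smis)
  expect_equal(sc$mpo[1], 6)
  expect_equal(sc$d_logP[6], 0)   # logP far beyond 5
  expect_equal(sc$d_pKa[5], 0)    # aliphatic amine proxy pKa 10.5
  expect_false(sc$pass[6])
  # recompute each component by explicit piecewise interpolation
  lin <- function(x, x1, x0) pmin(1, pmax(0, (x0 - x) / (x0 - x1)))
  expect_equal(sc$d_logP, lin(sc$logP, 3, 5))
  expect_equal(sc$d_logD, lin(sc$logD, 2, 4))
  expect_equal(sc$d_MW, lin(sc$MW, 360, 500))
  expect_equal(sc$d_HBD, lin(sc$HBD, 0.5, 3.5))
  expect_equal(sc$d_pKa, lin(sc$pKa, 8, 10))
  tpsa_ref <- pmin(lin(sc$TPSA, 90, 120), lin(-sc$TPSA, -40, -20))
  expect_equal(sc$d_TPSA, tpsa_ref)
  expect_equal(sc$mpo, with(sc, d_logP + d_logD + d_MW + d_TPSA +
                              d_HBD + d_pKa))
  # pass threshold honoured
  expect_identical(sc$pass, sc$mpo >= 4)
})
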