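# Descriptor provider and the three pair-combination operators.

test_that("descriptor vectors have the declared fixed length and order", {
  ds <- descriptor_set()
  expect_length(ds$names, 60)
  d <- compute_descriptors(c(m = "C"))
  expect_equal(ncol(d), 61)  # drug_id + 60 descriptors
  expect_identical(names(d)[-1], ds$names)
  expect_true(all(is.finite(as.matrix(d[, -1]))))
})

test_that("descriptors are invariant under SMILES respelling", {
  d <- compute_descriptors(c(
    a = "CCO", b = "OCC",
    c = "c1ccccc1O", d = "Oc1ccccc1",
    e = "CC(=O)Nc1ccc(O)cc1", f = "Oc1ccc(NC(C)=O)cc1"
  ))
  m <- as.matrix(d[, -1])
  expect_equal(m[1, ], m[2, ])
  expect_equal(m[3, ], m[4, ])
  expect_equal(m[5, ], m[6, ])
})

test_that("malformed SMILES raise a parse error naming the string", {
  err <- expect_error(compute_descriptors("C(("),
                      class = "ddihybrid_parse_error")
  expect_match(conditionMessage(err), "C((", fixed = TRUE)
  expect_error(compute_descriptors("C1CC"), class = "ddihybrid_parse_error")
  expect_error(compute_descriptors("CC)O"), class = "ddihybrid_parse_error")
  expect_error(canonicalize_smiles(""), class = "ddihybrid_parse_error")
})

test_that("chemically sensible values come out for known molecules", {
  d <- compute_descriptors(c(benzene = "c1ccccc1", ethanol = "CCO"))
  benzene <- as.list(d[1, ])
  expect_equal(benzene$nAromRing, 1)
  expect_equal(benzene$nAromAtom, 6)
  expect_equal(benzene$MW, 78.11, tolerance = 1e-3)
  ethanol <- as.list(d[2, ])
  expect_equal(ethanol$nHBD, 1)
  expect_equal(ethanol$nRing, 0)
  expect_equal(ethanol$Wiener, 4)  # path graph on 3 heavy atoms
})

test_that("combination operators reproduce hand-computed examples", {
  fa <- c(x = 2, y = 3)
  fb <- c(x = 5, y = 7)
  expect_equal(unname(cross_product_features(fa, fb)), c(10, 14, 15, 21))
  expect_equal(names(cross_product_features(fa, fb)),
               c("A:x*B:x", "A:x*B:y", "A:y*B:x", "A:y*B:y"))
  expect_equal(unname(concat_features(fa, fb)), c(2, 3, 5, 7))
  expect_equal(unname(sum_product_features(fa, fb)), c(7, 10, 10, 21))
})

test_that("operators match the brute-force double loop for p <= 5", {
  set.seed(42)
  for (p in 1:5) {
    for (rep in 1:5) {
      fa <- setNames(rnorm(p), paste0("v", seq_len(p)))
      fb <- setNames(rnorm(p), paste0("v", seq_len(p)))
      expect_equal(unname(cross_product_features(fa, fb)),
                   oracle_cross(fa, fb))
      expect_equal(unname(concat_features(fa, fb)),
                   c(unname(fa), unname(fb)))
      expect_equal(unname(sum_product_features(fa, fb)),
                   oracle_sum_product(fa, fb))
    }
  }
})

test_that("operator feature counts are p^2, 2p, 2p for any p", {
  for (p in c(1, 3, 60)) {
    fa <- setNames(runif(p), paste0("v", seq_len(p)))
    expect_length(cross_product_features(fa, fa), p^2)
    expect_length(concat_features(fa, fa), 2 * p)
    expect_length(sum_product_features(fa, fa), 2 * p)
  }
})

test_that("cross product of swapped arguments is the transpose permutation", {
  set.seed(7)
  for (rep in 1:10) {
    p <- sample(2:6, 1)
    nms <- paste0("v", seq_len(p))
    fa <- setNames(rnorm(p), nms)
    fb <- setNames(rnorm(p), nms)
    ab <- matrix(cross_product_features(fa, fb), p, p, byrow = TRUE)
    ba <- matrix(cross_product_features(fb, fa), p, p, byrow = TRUE)
    expect_equal(ab, t(ba))
  }
})

test_that("sum and product blocks are symmetric under argument swap", {
  set.seed(8)
  p <- 5
  nms <- paste0("v", 1:p)
  fa <- setNames(rnorm(p), nms)
  fb <- setNames(rnorm(p), nms)
  s1 <- sum_product_features(fa, fb)
  s2 <- sum_product_features(fb, fa)
  expect_equal(unname(s1), unname(s2))
})

test_that("zero vectors annihilate products", {
  fa <- setNames(numeric(4), paste0("v", 1:4))
  fb <- setNames(rnorm(4), paste0("v", 1:4))
  expect_true(all(cross_product_features(fa, fb) == 0))
  expect_true(all(sum_product_features(fa, fa) == 0))
})

test_that("length mismatches raise dimension errors", {
  fa <- c(a = 1, b = 2)
  fb <- c(a = 1, b = 2, c = 3)
  expect_error(cross_product_features(fa, fb),
               class = "ddihybrid_dimension_error")
  expect_error(concat_features(fa, fb),
               class = "ddihybrid_dimension_error")
  expect_error(sum_product_features(fa, fb),
               class = "ddihybrid_dimension_error")
})

test_that("pair_feature_matrix matches the vector-level operators", {
  drugs <- tiny_drug_table()
  desc <- compute_descriptors(drugs)
  pairs <- tiny_pair_table()
  for (mode in c("cross_product", "concat", "sum_product")) {
    pf <- pair_feature_matrix(pairs, desc, mode)
    fa <- unlist(desc[desc$drug_id == pairs$victim_id[1], -1])
    fb <- unlist(desc[desc$drug_id == pairs$perpetrator_id[1], -1])
    ref <- switch(mode,
      cross_product = cross_product_features(fa, fb),
      concat = concat_features(fa, fb),
      sum_product = sum_product_features(fa, fb)
    )
    expect_equal(unlist(pf[1, -(1:2)]), ref)
  }
  expect_error(
    pair_feature_matrix(tibble::tibble(victim_id = "zz",
                                       perpetrator_id = "d1"), desc),
    class = "ddihybrid_schema_error"
  )
})
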