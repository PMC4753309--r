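test_that("copy-number correction divides then renormalises", {
  m <- matrix(c(100, 50), 2, dimnames = list(c("A", "B"), "s1"))
  mc <- MatCommunity(m, copy_number = c(2, 1))
  expect_equal(unname(abundances(relativeAbundance(mc))[, 1]), c(0.5, 0.5))
  # uniform copy numbers = plain normalisation
  mc1 <- MatCommunity(toy_counts(), copy_number = 1)
  expect_equal(abundances(relativeAbundance(mc1)),
               sweep(toy_counts(), 2, colSums(toy_counts()), "/"))
  single <- MatCommunity(matrix(7, 1, dimnames = list("A", "s1")))
  expect_equal(unname(abundances(relativeAbundance(single))[, 1]), 1)
  expect_true(all(abs(colSums(abundances(relativeAbundance(
    MatCommunity(toy_counts(), copy_number = c(3, 1, 2))))) - 1) < 1e-12))
  zero <- MatCommunity(matrix(c(1, 0), 1, dimnames = list("A", c("s1", "s2"))))
  expect_error(relativeAbundance(zero), "all-zero")
  expect_error(relativeAbundance(genCommunityTable(osp)), "counts mode")
})

test_that("brayCurtis matches the element-wise oracle", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 2)), 1)        # disjoint support
  expect_equal(brayCurtis(c(10, 0), c(5, 5)), 0.5)
  withr::with_seed(7, {
    for (i in 1:50) {
      x <- runif(10, 0, 5); y <- runif(10, 0, 5)
      expect_equal(brayCurtis(x, y), bray_oracle(x, y), tolerance = 1e-12)
    }
  })
  expect_error(brayCurtis(1:3, 1:4), "equal length")
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(brayCurtis(c(-1, 2), c(1, 2)), ">= 0")
})

test_that("brayCurtisMatrix is a proper dissimilarity over samples", {
  d <- brayCurtisMatrix(genCommunityTable(osp))
  m <- as.matrix(d)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  # counts tables are corrected first: equal column totals cancel
  mc <- MatCommunity(toy_counts())
  expect_equal(as.matrix(brayCurtisMatrix(mc))[1, 2],
               bray_oracle(abundances(relativeAbundance(mc))[, 1],
                           abundances(relativeAbundance(mc))[, 2]),
               tolerance = 1e-12)
})

test_that("clusterDendrogram joins closest pairs first, deterministically", {
  d2 <- as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  t2 <- clusterDendrogram(d2)
  expect_equal(t2$height, 0.4)
  m3 <- matrix(c(0, 0.1, 0.9,
                 0.1, 0, 0.8,
                 0.9, 0.8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- clusterDendrogram(m3)
  first <- rownames(m3)[-t3$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  ident <- clusterDendrogram(as.dist(matrix(0, 2, 2,
    dimnames = list(c("x", "y"), c("x", "y")))))
  expect_equal(ident$height, 0)
  expect_error(clusterDendrogram(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("dendrogram heights are monotone (ultrametric linkages)", {
  withr::with_seed(11, {
    for (i in 1:10) {
      p <- matrix(rexp(60), nrow = 6,
                  dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
      p <- sweep(p, 2, colSums(p), "/")
      mc <- MatCommunity(p, mode = "proportions")
      for (link in c("complete", "average")) {
        tr <- clusterDendrogram(brayCurtisMatrix(mc), linkage = link)
        expect_true(all(diff(tr$height) >= -1e-12))
      }
    }
  })
})

test_that("decline rate and extrapolation follow the linear model", {
  expect_equal(declineRate(c(15, 70), c(65, 10)), 1)    # 55 points / 55 d
  expect_equal(declineRate(c(0, 10, 20), rep(12, 3)), 0)
  expect_equal(extrapolateDecline(1, 70, 31, 100), 1)   # 31 - 30
  expect_equal(extrapolateDecline(1, 70, 20, 100), 0)   # floored
  # generator's rod taxon declines at the configured 1%/day
  a <- abundances(genCommunityTable(osp, times = c(10, 30, 50)))
  expect_equal(declineRate(c(10, 30, 50), 100 * a["Hydrogenobaculum", ]), 1,
               tolerance = 1e-9)
})

test_that("primerBias flags the amplicon's over- and under-calls", {
  mm <- matureMatAbundance()
  pb <- primerBias(mm[, "osp_itag"] / 100, mm[, "osp_illumina"] / 100)
  hb <- pb[pb$taxon == "Hydrogenobaculum", ]
  expect_equal(hb$ratio, 24.2 / 3, tolerance = 1e-9)    # 8.07, over
  expect_identical(hb$flag, "over")
  my <- pb[pb$taxon == "M_yellowstonensis", ]
  expect_equal(my$ratio, 0.51 / 16, tolerance = 1e-9)   # 0.032, under
  expect_identical(my$flag, "under")
  expect_identical(pb$flag[pb$taxon == "NAG3"], "absent")
  same <- primerBias(c(A = 0.6, B = 0.4), c(A = 0.6, B = 0.4))
  expect_true(all(same$ratio == 1) && all(same$flag == "equal"))
  # MatCommunity route with matched samples
  ct <- genCommunityTable(osp, times = c(4, 40))
  pb2 <- primerBias(ct, ct)
  expect_true(all(pb2$ratio[!is.na(pb2$ratio)] == 1))
})

test_that("classifyStage applies the rule cascade", {
  expect_identical(as.character(classifyStage(
    matState(5, 0, FALSE, 0.95))), "I")
  expect_identical(as.character(classifyStage(
    matState(20, 0.7, TRUE, 0.9))), "II")
  expect_identical(as.character(classifyStage(
    matState(40, 3, TRUE, 0.7))), "III")
  expect_identical(as.character(classifyStage(
    matState(30, 0.5, TRUE, 0.6))), "III")   # heterotrophs >= 0.25
  expect_identical(as.character(classifyStage(
    matState(100, 15, TRUE, 0.4))), "IV")
  expect_error(matState(10, -1), "depth")
})

test_that("stage classification is monotone in mat depth", {
  withr::with_seed(3, {
    for (i in 1:25) {
      litho <- runif(1)
      fe <- sample(c(TRUE, FALSE), 1)
      depths <- sort(runif(8, 0, 12))
      stages <- vapply(depths, function(d)
        as.integer(classifyStage(matState(30, d, fe, litho))), integer(1))
      expect_true(all(diff(stages) >= 0))
    }
  })
})
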