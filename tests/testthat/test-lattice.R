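test_that("subset enumeration follows binomial counts in deterministic order", {
  e42 <- enumerate_subsets(4, 2)
  expect_equal(sum(e42$degree == 2), choose(4, 2))
  expect_equal(nrow(enumerate_subsets(4, 4)), 15)
  expect_equal(sum(enumerate_subsets(21, 2)$degree == 2), 210)
  expect_identical(e42$key[e42$degree == 2][1:3], c("1,2", "1,3", "1,4"))
  expect_error(enumerate_subsets(3, 4), "kmax")
  # explicit index vectors are used as-is, not expanded
  expect_equal(enumerate_subsets(c(5L, 7L), 1)$key, c("5", "7"))
})

test_that("the Borromean structure carries the hand-computed H and I maps", {
  st <- info_structure(gen_borromean())
  td <- tidy(st)
  expect_equal(sort(td$H), c(1, 1, 1, 2, 2, 2, 2))
  expect_equal(sort(td$I), c(-1, 0, 0, 0, 1, 1, 1))
  expect_equal(td$I[td$key == "1,2,3"], -1)
})

test_that("structure values agree with brute-force state sums for small n", {
  for (seed in 1:6) {
    card <- if (seed %% 2 == 0) 3 else 2
    jd <- gen_random_dirichlet(4, cardinality = card, seed = seed + 700)
    st <- info_structure(jd)
    for (i in seq_len(nrow(st$subsets))) {
      s <- st$subsets$vars[[i]]
      expect_equal(st$subsets$H[i],
                   oracle_H(oracle_marginal(jd$prob, s)), tolerance = 1e-9)
      expect_equal(st$subsets$I[i], oracle_Ik_statesum(jd$prob, s),
                   tolerance = 1e-9)
    }
  }
})

test_that("structures estimated from data match the plug-in joint", {
  rows <- sample_matrix(gen_borromean(), 200, seed = 11)
  st <- info_structure(rows)
  jd <- empirical_joint(rows)
  expect_equal(structure_value_H <- tidy(st)$H[tidy(st)$key == "1,2,3"],
               entropy(jd), tolerance = 1e-12)
  expect_identical(st$m, 200L)
})

test_that("the complexity cap refuses oversized requests unless forced", {
  rows <- sample_matrix(gen_independent(5), 30, seed = 3)
  expect_error(info_structure(rows, max_subsets = 10), "cap")
  expect_s3_class(info_structure(rows, max_subsets = 10, force = TRUE),
                  "info_structure")
})

test_that("landscapes group values with conserved degeneracy", {
  st <- info_structure(gen_independent(5))
  li <- landscape(st, "information")
  # iid independent: all values at degree >= 2 are 0 with full degeneracy
  for (k in 2:5) {
    at_k <- li[li$degree == k, ]
    expect_equal(nrow(at_k), 1L)
    expect_equal(at_k$value, 0)
    expect_equal(at_k$count, choose(5, k))
  }
  le <- landscape(info_structure(gen_redundant(4)), "entropy")
  expect_equal(unique(le$value), 1)            # all degrees share H1
  for (k in 1:4) {
    expect_equal(sum(le$count[le$degree == k]), choose(4, k))
  }
  lb <- landscape(info_structure(gen_borromean()), "information")
  expect_equal(lb$value[lb$degree == 3], -1)
})

test_that("degeneracy counts always sum to choose(n, k)", {
  for (seed in 1:4) {
    jd <- gen_random_dirichlet(4, seed = seed + 800)
    st <- info_structure(jd)
    for (kind in c("entropy", "information")) {
      ls <- landscape(st, kind)
      tab <- tapply(ls$count, ls$degree, sum)
      expect_equal(as.integer(tab), choose(4, 1:4))
    }
  }
})

test_that("landscapes are invariant under variable relabeling", {
  jd <- gen_random_dirichlet(4, seed = 900)
  perm <- c(3, 1, 4, 2)
  jp <- joint_dist(aperm(jd$prob, perm), cardinalities = rep(2, 4))
  for (kind in c("entropy", "information")) {
    a <- landscape(info_structure(jd), kind)
    b <- landscape(info_structure(jp), kind)
    expect_equal(dplyr::arrange(tibble::as_tibble(a), degree, value),
                 dplyr::arrange(tibble::as_tibble(b), degree, value),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("entropy chains sit inside the Shannonian cone", {
  for (seed in 1:5) {
    jd <- gen_random_dirichlet(4, seed = seed + 1000)
    st <- info_structure(jd)
    ord <- sample(1:4)
    for (j in 2:4) {
      hk <- entropy(st, ord[seq_len(j - 1)])
      hk1 <- entropy(st, ord[seq_len(j)])
      expect_gte(hk1, hk - 1e-10)
      expect_lte(hk1, hk + entropy(st, ord[j]) + 1e-10)
    }
  }
})

test_that("mean paths average the landscape and satisfy H = U - G", {
  st <- info_structure(gen_borromean())
  mp <- mean_paths(st)
  expect_equal(mp$I_mean, c(1, 0, -1))
  expect_equal(attr(mp, "critical_dimension"), 3L)
  expect_equal(attr(mp, "U_hom") - attr(mp, "G_hom"), attr(mp, "H_hom"),
               tolerance = 1e-9)
  # fully redundant: <Ik> = H1 at every degree, no critical dimension
  mr <- mean_paths(info_structure(gen_redundant(4)))
  expect_equal(mr$I_mean, rep(1, 4))
  expect_true(is.na(attr(mr, "critical_dimension")))
  # independent: <I2> = 0 and no minimum
  mi <- mean_paths(info_structure(gen_independent(3)))
  expect_equal(mi$I_mean[2], 0)
  expect_true(is.na(attr(mi, "critical_dimension")))
  # the homogeneous identity holds on random structures too
  for (seed in 1:5) {
    m <- mean_paths(info_structure(gen_random_dirichlet(4,
                                                        seed = seed + 1100)))
    expect_equal(attr(m, "U_hom") - attr(m, "G_hom"), attr(m, "H_hom"),
                 tolerance = 1e-9)
    expect_equal(m$H_mean[1], m$I_mean[1])
  }
})
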