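borromean <- gen_borromean()

test_that("entropy matches closed forms on canonical distributions", {
  expect_equal(entropy(joint_dist(c(0.5, 0.5), 2)), 1)
  expect_equal(entropy(joint_dist(c(1, 0), 2)), 0)
  expect_equal(entropy(borromean), 2)          # four equiprobable atoms
  expect_equal(entropy(borromean, subset = 2), 1)
  expect_equal(entropy(unit_dist()), 0)
})

test_that("KL divergence is zero at equality and catches support violations", {
  p <- joint_dist(c(1, 0), 2)
  q <- joint_dist(c(0.5, 0.5), 2)
  expect_equal(kl_divergence(q, q), 0)
  expect_equal(kl_divergence(p, q), 1)
  expect_identical(kl_divergence(q, p), Inf)
})

test_that("total correlation equals the KL divergence to the product law", {
  tc <- total_correlation(borromean, 1:3)
  expect_equal(tc, 1)                          # 3 x 1 - 2
  prod_law <- gen_independent(3)               # uniform marginals
  expect_equal(kl_divergence(borromean, prod_law), tc)
  expect_equal(total_correlation(gen_redundant(3), 1:3), 2)  # 3 - 1
  expect_equal(total_correlation(gen_independent(4), 1:4), 0)
  expect_error(total_correlation(borromean, 1), "two variables")
})

test_that("mutual information reproduces hand values and the state-sum", {
  expect_equal(mutual_information(borromean, c(1, 2)), 0)   # pairwise indep
  expect_equal(mutual_information(borromean, 1:3), -1)      # synergy
  expect_equal(mutual_information(gen_redundant(2), 1:2), 1)
  expect_equal(mutual_information(gen_independent(2), 1:2), 0)
  expect_equal(mutual_information(borromean, integer(0)), 0)
  for (seed in 1:10) {
    jd <- gen_random_dirichlet(4, seed = seed)
    expect_equal(mutual_information(jd, 1:3),
                 oracle_Ik_statesum(jd$prob, 1:3), tolerance = 1e-9)
    expect_equal(mutual_information(jd, 1:4),
                 oracle_Ik_statesum(jd$prob, 1:4), tolerance = 1e-9)
    expect_equal(mutual_information(jd, c(2, 4)),
                 oracle_Ik_statesum(jd$prob, c(2, 4)), tolerance = 1e-9)
  }
})

test_that("conditional entropy follows H(A,B) - H(B)", {
  ind <- gen_independent(2)
  expect_equal(conditional_entropy(ind, 1, 2), entropy(ind, 1))
  expect_equal(conditional_entropy(gen_redundant(2), 1, 2), 0)
  expect_equal(conditional_entropy(borromean, 1, c(2, 3)), 0)  # XOR-determined
  expect_equal(conditional_entropy(borromean, 1), 1)
  expect_error(conditional_entropy(borromean, 1, 1), "disjoint")
})

test_that("conditional mutual information matches the state-by-state sum", {
  expect_equal(conditional_mutual_information(borromean, c(1, 2), 3), 1)
  expect_equal(conditional_mutual_information(gen_independent(3), c(1, 2), 3), 0)
  for (seed in 1:10) {
    jd <- gen_random_dirichlet(3, cardinality = 2, seed = seed + 30)
    got <- conditional_mutual_information(jd, c(1, 2), 3)
    expect_equal(got, oracle_cmi2_statesum(jd$prob, 1, 2, 3),
                 tolerance = 1e-9)
    expect_gte(got, -1e-12)                    # classic CMI is non-negative
  }
})

test_that("pseudo-volumes vanish on identity and add on independence", {
  expect_equal(pseudo_volume(gen_redundant(2), 1:2), 0)
  ind <- gen_independent(2)
  expect_equal(pseudo_volume(ind, 1:2), entropy(ind, 1) + entropy(ind, 2))
  expect_equal(pseudo_volume(borromean, 1:3), 3)   # 2 - (-1)
  expect_equal(pseudo_volume(borromean, 1), 0)
})

test_that("V2 obeys the triangle inequality on random triples", {
  for (seed in 1:20) {
    jd <- gen_random_dirichlet(3, cardinality = 2, seed = seed + 200)
    d12 <- pseudo_volume(jd, c(1, 2))
    d13 <- pseudo_volume(jd, c(1, 3))
    d23 <- pseudo_volume(jd, c(2, 3))
    expect_lte(d12, d13 + d23 + 1e-9)
    expect_lte(d13, d12 + d23 + 1e-9)
    expect_lte(d23, d12 + d13 + 1e-9)
  }
})

test_that("elementary energies are extensive marginal surprisals", {
  E <- elementary_energies(borromean)
  expect_equal(as.numeric(E), rep(3, 8))       # every state costs 3 bits
  expect_equal(as.numeric(elementary_energies(gen_independent(2))),
               rep(2, 4))
  point <- joint_dist(c(1, 0, 0, 0), c(2, 2))
  Ep <- elementary_energies(point)
  expect_equal(as.numeric(Ep)[1], 0)
  expect_true(all(is.infinite(as.numeric(Ep)[-1])))  # impossible coordinates
})

test_that("energy decomposition satisfies H = U - G with G the total correlation", {
  ed <- energy_decomposition(borromean)
  expect_equal(ed$U, 3)
  expect_equal(ed$G, 1)
  expect_equal(ed$H, 2)
  cases <- c(list(gen_independent(3), gen_redundant(4)),
             random_joints(8, 4, seed0 = 300))
  for (jd in cases) {
    ed <- energy_decomposition(jd)
    expect_equal(ed$H, ed$U - ed$G, tolerance = 1e-9)
    expect_gte(ed$G, -1e-12)
    expect_equal(ed$G, total_correlation(jd, jd$vars$index),
                 tolerance = 1e-9)
    # U as the probability-weighted elementary energies
    E <- as.numeric(elementary_energies(jd))
    p <- as.numeric(jd$prob)
    expect_equal(sum(p[p > 0] * E[p > 0]), ed$U, tolerance = 1e-9)
  }
})

test_that("independent product laws have zero free energy", {
  ed <- energy_decomposition(gen_independent(4, marginal = c(0.2, 0.8)))
  expect_equal(ed$G, 0, tolerance = 1e-12)
  expect_equal(ed$H, ed$U)
})

test_that("information rate divides entropy by degree", {
  expect_equal(information_rate(entropy(gen_independent(4)), 4), 1)
  expect_equal(information_rate(entropy(gen_redundant(4)), 4), 1 / 4)
  expect_equal(information_rate(entropy(borromean), 3), 2 / 3)
  expect_error(information_rate(1, 0), ">= 1")
})

test_that("chain rules hold on random distributions", {
  for (seed in 1:25) {
    nvar <- 3 + seed %% 3                      # n in 3..5
    jd <- gen_random_dirichlet(nvar, seed = seed + 400)
    full <- seq_len(nvar)
    # H(A, B) = H(A) + A.H(B)
    a <- full[1:(nvar - 1)]
    b <- nvar
    expect_equal(entropy(jd, full),
                 entropy(jd, a) + conditional_entropy(jd, b, a),
                 tolerance = 1e-9)
    # I(k-1) - I(k) = Xk.I(k-1)
    expect_equal(
      mutual_information(jd, a) - mutual_information(jd, full),
      conditional_mutual_information(jd, a, b),
      tolerance = 1e-9
    )
  }
})

test_that("inclusion-exclusion duality recovers Hn from the Ik", {
  for (jd in c(list(borromean, gen_redundant(3)),
               random_joints(10, 4, seed0 = 500))) {
    full <- jd$vars$index
    acc <- 0
    for (k in seq_along(full)) {
      for (T in combn(seq_along(full), k, simplify = FALSE)) {
        acc <- acc + (-1)^(k - 1) * mutual_information(jd, full[T])
      }
    }
    expect_equal(acc, entropy(jd, full), tolerance = 1e-9)
  }
})

test_that("Matsuda sign equivalence links conditional information to Ik ordering", {
  for (seed in 1:15) {
    jd <- gen_random_dirichlet(4, seed = seed + 600)
    for (sub in list(1:3, 1:4, c(1, 2, 4))) {
      a <- sub[-length(sub)]
      x <- sub[length(sub)]
      cmi <- conditional_mutual_information(jd, a, x)
      gap <- mutual_information(jd, a) - mutual_information(jd, sub)
      expect_equal(cmi, gap, tolerance = 1e-9)
      if (abs(cmi) > 1e-9) expect_identical(cmi > 0, gap > 0)
    }
  }
})

test_that("mutual independence is equivalent to vanishing Ik at all degrees", {
  # product laws: every I of size >= 2 vanishes
  jd <- gen_independent(4, marginal = c(0.3, 0.7))
  for (k in 2:4) {
    for (T in combn(4, k, simplify = FALSE)) {
      expect_equal(mutual_information(jd, T), 0, tolerance = 1e-12)
    }
  }
  # conversely a perturbed product law violates some Ik
  p <- as.numeric(gen_independent(3)$prob)
  p[1] <- p[1] + 0.05
  p[8] <- p[8] - 0.05
  pert <- joint_dist(p, c(2, 2, 2))
  any_dep <- any(vapply(2:3, function(k) {
    any(vapply(combn(3, k, simplify = FALSE), function(T) {
      abs(mutual_information(pert, T)) > 1e-6
    }, logical(1)))
  }, logical(1)))
  expect_true(any_dep)
})
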