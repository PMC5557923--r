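test_that("alpha metrics match trivial cases and the brute-force oracle", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # 2 species at distance d -> d, whatever the abundances
  expect_equal(alpha_pw(c(a = 5, b = 1), D), 1)
  expect_equal(alpha_nn(c(a = 5, b = 1), D), 1)
  # all pairwise distances equal -> that constant, whatever the abundances
  Dc <- matrix(0.7, 3, 3, dimnames = dimnames(D)); diag(Dc) <- 0
  expect_equal(alpha_pw(c(a = 9, b = 1, c = 4), Dc), 0.7)
  # 3-species chain, equal abundances: each nearest neighbour at 1
  Dch <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, dimnames = dimnames(D))
  expect_equal(alpha_nn(c(a = 1, b = 1, c = 1), Dch), 1)
  # stated-weight example against the explicit double loop
  ab <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(alpha_pw(ab, D), oracle_pw(ab, D))
  expect_equal(alpha_nn(ab, D), oracle_nn(ab, D))
  # single species -> undefined, not an error
  expect_true(is.na(alpha_pw(c(a = 2), D)))
  # species not in the distance matrix -> error
  expect_error(alpha_pw(c(a = 1, z = 1), D), "absent")
})

test_that("beta metrics match trivial cases and the brute-force oracle", {
  D <- random_dist(6, seed = 8)
  sp <- rownames(D)
  # identical single-species communities -> 0
  expect_equal(beta_dpw(setNames(1, sp[1]), setNames(3, sp[1]), D), 0)
  expect_equal(beta_dnn(setNames(1, sp[1]), setNames(3, sp[1]), D), 0)
  # disjoint single-species communities -> their distance
  expect_equal(beta_dpw(setNames(1, sp[1]), setNames(1, sp[2]), D), D[1, 2])
  expect_equal(beta_dnn(setNames(1, sp[1]), setNames(1, sp[2]), D), D[1, 2])
  # identical communities -> Dnn = 0
  a <- c(2, 1, 4); names(a) <- sp[1:3]
  expect_equal(beta_dnn(a, a, D), 0)
  # 2x2 example vs the explicit min-scan oracle
  x <- setNames(c(1, 3), sp[1:2]); y <- setNames(c(2, 5), sp[3:4])
  expect_equal(beta_dpw(x, y, D), oracle_dpw(x, y, D))
  expect_equal(beta_dnn(x, y, D), oracle_dnn(x, y, D))
  expect_error(beta_dpw(setNames(numeric(0), character(0)), a, D), "non-empty")
})

test_that("metrics agree with oracles and invariants on random instances", {
  set.seed(42)
  D <- random_dist(12)
  sp <- rownames(D)
  for (i in 1:15) {
    a <- random_abund(sp)
    b <- random_abund(sp)
    expect_equal(alpha_pw(a, D), oracle_pw(a, D), tolerance = 1e-12)
    expect_equal(alpha_nn(a, D), oracle_nn(a, D), tolerance = 1e-12)
    expect_equal(beta_dpw(a, b, D), oracle_dpw(a, b, D), tolerance = 1e-12)
    expect_equal(beta_dnn(a, b, D), oracle_dnn(a, b, D), tolerance = 1e-12)
    # nearest neighbour can never exceed the weighted mean pair distance
    expect_lte(alpha_nn(a, D), alpha_pw(a, D) + 1e-12)
    expect_lte(beta_dnn(a, b, D), beta_dpw(a, b, D) + 1e-12)
    # uniform abundance rescaling changes nothing
    expect_equal(alpha_pw(a * 7, D), alpha_pw(a, D), tolerance = 1e-12)
    expect_equal(beta_dnn(a * 0.1, b * 3, D), beta_dnn(a, b, D), tolerance = 1e-12)
    # adding a zero-abundance species changes nothing
    extra <- setdiff(sp, names(a))[1]
    if (!is.na(extra)) {
      a2 <- c(a, setNames(0, extra))
      expect_equal(alpha_pw(a2, D), alpha_pw(a, D), tolerance = 1e-12)
    }
    # symmetry of the pair
    expect_equal(beta_dpw(a, b, D), beta_dpw(b, a, D), tolerance = 1e-12)
    expect_equal(beta_dnn(a, b, D), beta_dnn(b, a, D), tolerance = 1e-12)
  }
})

test_that("metrics agree with picante on its matching definitions", {
  set.seed(7)
  D <- random_dist(10)
  sp <- rownames(D)
  comm <- rbind(
    s1 = setNames(c(5, 3, 2, 0, 0, 1, 0, 0, 0, 0), sp),
    s2 = setNames(c(0, 1, 0, 4, 2, 0, 0, 3, 0, 0), sp)
  )
  a1 <- comm[1, ][comm[1, ] > 0]; a2 <- comm[2, ][comm[2, ] > 0]
  expect_equal(alpha_nn(a1, D),
               picante::mntd(comm, D, abundance.weighted = TRUE)[1],
               tolerance = 1e-10)
  expect_equal(beta_dpw(a1, a2, D),
               as.numeric(picante::comdist(comm, D, abundance.weighted = TRUE)),
               tolerance = 1e-10)
  expect_equal(beta_dnn(a1, a2, D),
               as.numeric(picante::comdistnt(comm, D, abundance.weighted = TRUE)),
               tolerance = 1e-10)
})

test_that("alpha_dispersion flags undefined communities and matches scalars", {
  D <- random_dist(8, seed = 2)
  sp <- rownames(D)
  comm <- rbind(
    s1 = setNames(c(1, 2, 3, 0, 0, 0, 0, 0), sp),
    s2 = setNames(c(0, 0, 0, 0, 0, 0, 0, 9), sp)
  )
  out <- alpha_dispersion(comm, D)
  expect_equal(nrow(out), 4)
  expect_false(out$defined[out$sample == "s2" & out$metric == "PW"])
  a1 <- comm[1, ][comm[1, ] > 0]
  expect_equal(out$value[out$sample == "s1" & out$metric == "PW"],
               alpha_pw(a1, D))
})

test_that("beta_within_group enumerates within-group pairs correctly", {
  hier <- toy_hier(lakes_per_region = 3, strata = 1, plots = 3)
  set.seed(4)
  sp <- sprintf("sp%02d", 1:6)
  comm <- matrix(rpois(nrow(hier) * 6, 3) + 1, nrow(hier), 6,
                 dimnames = list(hier$plot, sp))
  D <- random_dist(6)
  dimnames(D) <- list(sp, sp)

  # 3 plots per stratum -> C(3,2) = 3 pairs per stratum group
  bw <- beta_within_group(comm, hier, "plot", D)
  per_group <- table(bw$group[bw$metric == "Dpw"])
  expect_true(all(per_group == 3))

  # 2 regions -> exactly 1 between-region pair
  br <- beta_within_group(comm, hier, "region", D)
  expect_equal(sum(br$metric == "Dpw"), 1)

  # consistency with direct calls on manually pooled units
  lakes <- pool_to_scale(comm, hier, "lake")
  bl <- beta_within_group(comm, hier, "lake", D)
  row1 <- bl[bl$metric == "Dpw", ][1, ]
  expect_equal(
    row1$value,
    beta_dpw(lakes[row1$unit_a, ], lakes[row1$unit_b, ], D)
  )
  row2 <- bl[bl$metric == "Dnn", ][1, ]
  expect_equal(
    row2$value,
    beta_dnn(lakes[row2$unit_a, ], lakes[row2$unit_b, ], D)
  )
})
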