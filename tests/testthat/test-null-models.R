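test_that("taxa_shuffle relabels without changing the distance multiset", {
  D <- random_dist(6, seed = 1)
  # identity permutation returns the input
  expect_equal(taxa_shuffle(D, perm = 1:6), D, ignore_attr = TRUE)
  set.seed(2)
  Ds <- taxa_shuffle(D)
  expect_equal(dimnames(Ds), dimnames(D))
  expect_equal(sort(as.vector(Ds)), sort(as.vector(D)))
  # with 3 species the 6 permutations enumerate exactly the 6 relabelings
  D3 <- random_dist(3, seed = 3)
  pm <- perms(3)
  shuffled <- apply(pm, 1, function(p) taxa_shuffle(D3, perm = p),
                    simplify = FALSE)
  manual <- apply(pm, 1, function(p) {
    out <- D3[p, p]; dimnames(out) <- dimnames(D3); out
  }, simplify = FALSE)
  for (k in 1:6) expect_equal(shuffled[[k]], manual[[k]], ignore_attr = TRUE)
})

test_that("sampled null moments converge to exhaustive enumeration", {
  D <- random_dist(5, seed = 10)
  sp <- rownames(D)
  ab <- setNames(c(4, 2, 1), sp[1:3])
  n_iter <- 4000
  for (metric in list(
    list(fn = alpha_pw, one = function(Dp) oracle_pw(ab, Dp)),
    list(fn = alpha_nn, one = function(Dp) oracle_nn(ab, Dp))
  )) {
    exact <- exhaustive_null(metric$one, D)
    nd <- null_distribution(metric$fn, ab, D, n_iter = n_iter, seed = 5)
    se_mean <- exact$sd / sqrt(n_iter)
    se_sd <- exact$sd / sqrt(2 * n_iter)
    expect_lt(abs(nd$mean - exact$mean), 3 * se_mean)
    expect_lt(abs(nd$sd - exact$sd), 3 * se_sd)
  }
  # beta pair
  a <- setNames(c(3, 1), sp[1:2]); b <- setNames(c(2, 2), sp[3:4])
  exact <- exhaustive_null(function(Dp) oracle_dpw(a, b, Dp), D)
  nd <- null_distribution(beta_dpw, list(a, b), D, n_iter = n_iter, seed = 6)
  expect_lt(abs(nd$mean - exact$mean), 3 * exact$sd / sqrt(n_iter))
  expect_lt(abs(nd$sd - exact$sd), 3 * exact$sd / sqrt(2 * n_iter))
})

test_that("null_distribution is reproducible and degenerates on the full pool", {
  D <- random_dist(5, seed = 4)
  ab <- setNames(rep(1, 5), rownames(D)) # whole pool, equal abundances
  nd <- null_distribution(alpha_pw, ab, D, n_iter = 50, seed = 1)
  expect_equal(nd$sd, 0)
  expect_true(is.na(ses(alpha_pw(ab, D), nd)))

  ab2 <- setNames(c(3, 1, 2), rownames(D)[1:3])
  n1 <- null_distribution(alpha_nn, ab2, D, n_iter = 99, seed = 7)
  n2 <- null_distribution(alpha_nn, ab2, D, n_iter = 99, seed = 7)
  expect_identical(n1$values, n2$values)
})

test_that("SES standardizes correctly and is scale-invariant", {
  expect_equal(ses(2, 2, 0.5), 0)
  expect_equal(ses(1, 2, 0.5), -2)
  expect_true(is.na(ses(1, 1, 0)))
  # multiplying all distances by c > 0 multiplies obs, null mean and SD by c
  D <- random_dist(6, seed = 9)
  ab <- setNames(c(1, 2, 3), rownames(D)[1:3])
  obs1 <- alpha_pw(ab, D); nd1 <- null_distribution(alpha_pw, ab, D, 199, seed = 3)
  obs2 <- alpha_pw(ab, 10 * D); nd2 <- null_distribution(alpha_pw, ab, 10 * D, 199, seed = 3)
  expect_equal(ses(obs1, nd1), ses(obs2, nd2), tolerance = 1e-10)
})

test_that("Wilcoxon departure has exact behaviour in hand-checkable cases", {
  # symmetric +/- pairs: statistic at the null centre, p = 1
  w <- wilcoxon_departure(c(-1, 1, -2, 2, -3, 3))
  expect_equal(w$p_value, 1)
  expect_equal(w$direction, "none")
  # n = 6 all negative: two-sided exact p = 2/2^6 = 1/32
  w2 <- wilcoxon_departure(c(-0.5, -1, -1.5, -2, -2.5, -3))
  expect_equal(w2$p_value, 1 / 32)
  expect_equal(w2$direction, "clustered")
  expect_equal(w2$stars, "*")
  expect_error(wilcoxon_departure(c(-1, 1, 2)), "at least 5")
  expect_error(wilcoxon_departure(rep(0, 6)), "zero")
})

test_that("ses_dispersion is deterministic and propagates undefined values", {
  scen <- scenario(seed = 21, lakes_per_region = 2, strata_per_lake = 2,
                   plots_per_stratum = 2, pool_size = 15, lambda = 0,
                   target_richness = 4)
  tr <- generate_traits(scen)
  sv <- generate_survey(scen, tr)
  dend <- build_dendrogram(gower_distance(tr))
  s1 <- ses_dispersion(sv$community, sv$hier, dend, scales = c("plot", "lake"),
                       n_iter = 99, seed = 5)
  s2 <- ses_dispersion(sv$community, sv$hier, dend, scales = c("plot", "lake"),
                       n_iter = 99, seed = 5)
  expect_equal(s1, s2)
  expect_error(ses_dispersion(sv$community, sv$hier, dend, n_iter = 99),
               "seed")
  # single-species plots are undefined for alpha, and flagged, not dropped
  rich <- richness_profile(sv$community)
  singles <- rich$sample[rich$richness == 1]
  if (length(singles)) {
    sub <- s1[s1$scale == "plot" & s1$metric == "PW" & s1$unit %in% singles, ]
    expect_true(all(!sub$defined))
  }
  # observed column matches a direct metric call
  row <- s1[s1$scale == "lake" & s1$metric == "Dpw", ][1, ]
  lakes <- pool_to_scale(sv$community, sv$hier, "lake")
  un <- strsplit(row$unit, "|", fixed = TRUE)[[1]]
  expect_equal(row$observed,
               beta_dpw(lakes[un[1], ], lakes[un[2], ], dend))
})

test_that("SES is centred near zero with unit spread under random assembly", {
  set.seed(33)
  D <- random_dist(20)
  sp <- rownames(D)
  n_comm <- 60
  comm <- t(vapply(seq_len(n_comm), function(i) {
    ab <- setNames(numeric(20), sp)
    pick <- sample(20, sample(3:8, 1))
    ab[pick] <- rlnorm(length(pick))
    ab
  }, numeric(20)))
  rownames(comm) <- sprintf("c%02d", seq_len(n_comm))
  hier <- tibble::tibble(plot = rownames(comm), depth_stratum = "d1",
                         water_depth_m = 0.5, lake = "L1", region = "R1",
                         elevation_m = 10)
  st <- ses_dispersion(comm, hier, D, scales = "plot", metrics = c("PW", "NN"),
                       n_iter = 999, seed = 13)
  for (m in c("PW", "NN")) {
    x <- st$ses[st$metric == m & st$defined]
    expect_lt(abs(mean(x)), 3 / sqrt(length(x))) # SES ~ mean 0, SD ~ 1
    expect_gt(sd(x), 0.6)
    expect_lt(sd(x), 1.5)
  }
})

test_that("summarize_departure groups correctly and supports BH adjustment", {
  ses_tbl <- tibble::tibble(
    trait_metric = rep(c("t1", "t2"), each = 8),
    scale = "plot", metric = "PW",
    unit = rep(sprintf("p%d", 1:8), 2),
    group = "g", observed = 1, null_mean = 1, null_sd = 1,
    ses = c(rnorm(8, -2, 0.1), rnorm(8, 0, 0.1)),
    defined = TRUE
  )
  out <- summarize_departure(ses_tbl)
  expect_equal(nrow(out), 2)
  expect_equal(out$direction[out$trait_metric == "t1"], "clustered")
  out_bh <- summarize_departure(ses_tbl, adjust = "BH")
  expect_true(all(out_bh$p_adjusted >= out$p_value, na.rm = TRUE))
  # cells with too few values yield NA results, not an error
  out_small <- summarize_departure(ses_tbl[1:3, ])
  expect_true(is.na(out_small$p_value))
})
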