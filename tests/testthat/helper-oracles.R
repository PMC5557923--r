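# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can validate the fast implementations.

# all permutations of 1:n as a matrix (n! rows)
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

oracle_pw <- function(abund, D) {
  abund <- abund[abund > 0]
  sp <- names(abund)
  if (length(sp) < 2) return(NA_real_)
  f <- abund / sum(abund)
  num <- 0; den <- 0
  for (i in sp) for (j in sp) {
    if (i == j) next
    num <- num + f[[i]] * f[[j]] * D[i, j]
    den <- den + f[[i]] * f[[j]]
  }
  num / den
}

oracle_nn <- function(abund, D) {
  abund <- abund[abund > 0]
  sp <- names(abund)
  if (length(sp) < 2) return(NA_real_)
  f <- abund / sum(abund)
  out <- 0
  for (i in sp) {
    mn <- Inf
    for (j in sp) if (j != i && D[i, j] < mn) mn <- D[i, j]
    out <- out + f[[i]] * mn
  }
  out
}

oracle_dpw <- function(a, b, D) {
  a <- a[a > 0]; b <- b[b > 0]
  fa <- a / sum(a); fb <- b / sum(b)
  out <- 0
  for (i in names(fa)) for (j in names(fb)) {
    out <- out + fa[[i]] * fb[[j]] * D[i, j]
  }
  out
}

oracle_dnn <- function(a, b, D) {
  a <- a[a > 0]; b <- b[b > 0]
  fa <- a / sum(a); fb <- b / sum(b)
  s1 <- 0
  for (i in names(fa)) s1 <- s1 + fa[[i]] * min(D[i, names(fb)])
  s2 <- 0
  for (j in names(fb)) s2 <- s2 + fb[[j]] * min(D[names(fa), j])
  (s1 + s2) / 2
}

# per-trait loop Gower, independent of the vectorized implementation
oracle_gower <- function(traits, types) {
  n <- nrow(traits)
  d <- matrix(0, n, n, dimnames = list(traits$species, traits$species))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    contribs <- numeric(0)
    for (tr in names(types)) {
      x <- traits[[tr]]
      if (types[[tr]] == "continuous") {
        rng <- max(x) - min(x)
        contribs <- c(contribs, if (rng == 0) 0 else abs(x[i] - x[j]) / rng)
      } else {
        if (length(unique(x)) == 1) contribs <- c(contribs, 0)
        else contribs <- c(contribs, as.numeric(x[i] != x[j]))
      }
    }
    d[i, j] <- mean(contribs)
  }
  d
}

# exact null moments by enumerating every relabelling of the pool
exhaustive_null <- function(metric_fn, D) {
  n <- nrow(D)
  pm <- perms(n)
  vals <- apply(pm, 1, function(p) {
    Dp <- D[p, p]
    dimnames(Dp) <- dimnames(D)
    metric_fn(Dp)
  })
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

random_dist <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::runif(n * 3), n)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(sprintf("sp%02d", 1:n), sprintf("sp%02d", 1:n))
  d
}

random_abund <- function(species, k = NULL) {
  if (is.null(k)) k <- sample(2:length(species), 1)
  sp <- sample(species, k)
  stats::setNames(stats::rlnorm(k), sp)
}

toy_traits <- function(n = 10, seed = 1) {
  scen <- fundisp::scenario(seed = seed, pool_size = max(n, 18),
                            richness_range = c(1, 18))
  tr <- fundisp::generate_traits(scen)
  out <- tr[seq_len(n), ]
  attr(out, "trait_types") <- attr(tr, "trait_types")
  out
}

toy_hier <- function(n_regions = 2, lakes_per_region = 2, strata = 2, plots = 2) {
  fundisp::generate_survey(
    fundisp::scenario(seed = 99, n_regions = n_regions,
                      lakes_per_region = lakes_per_region,
                      strata_per_lake = strata, plots_per_stratum = plots,
                      pool_size = 20)
  )$hier
}
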