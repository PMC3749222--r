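# synthetic STR/SNP data generation

test_that("star simulation is deterministic and respects mu = 0", {
  cfg0 <- sim_config("star", n = 10, T_g = 500, mu = 0, seed = 4)
  sim0 <- simulate_star(cfg0)
  ht <- to_minht(sim0$profiles)
  expect_true(all(sweep(unclass(ht), 2, cfg0$founder) == 0))

  cfg <- sim_config("star", n = 20, T_g = 300, mu = 0.01, seed = 9)
  a <- simulate_star(cfg)
  b <- simulate_star(cfg)
  expect_identical(as.data.frame(a$profiles), as.data.frame(b$profiles))
  c2 <- simulate_star(sim_config("star", n = 20, T_g = 300, mu = 0.01,
                                 seed = 10))
  expect_false(identical(as.data.frame(a$profiles),
                         as.data.frame(c2$profiles)))
})

test_that("star simulation matches E[ASD] = mu * T at large n", {
  cfg <- sim_config("star", n = 2000, T_g = 1000, mu = 6.9e-4, seed = 7)
  sim <- simulate_star(cfg)
  ht <- to_minht(sim$profiles)
  a <- asd(ht, center = sim$truth$founder)
  # SE of the mean over 7 loci x 2000 samples: Var[(x-f)^2] ~ 2(muT)^2 + muT
  muT <- cfg$mu * cfg$T_g
  se <- sqrt((2 * muT^2 + muT) / (2000 * 7))
  expect_lt(abs(a$mean_asd - muT), 3 * se)
})

test_that("population structure in the star model follows the divergence setting", {
  cfg <- sim_config("star", n = 5, populations = 3, divergence = 0,
                    T_g = 0, mu = 0.5, seed = 2)
  sim <- simulate_star(cfg)
  # with zero divergence and zero depth every sample is the founder
  expect_true(all(sweep(unclass(to_minht(sim$profiles)), 2,
                        cfg$founder) == 0))
  expect_equal(table(sim$profiles$population),
               table(rep(c("pop1", "pop2", "pop3"), each = 5)))
})

test_that("coalescent pairwise ASD matches 4 Ne mu in expectation", {
  mu <- 0.01; Ne <- 50
  reps <- 400
  pair_asd <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_coalescent(sim_config("coalescent", n = 2, Ne = Ne,
                                          mu = mu, seed = r))
    h <- to_minht(sim$profiles)
    pair_asd[r] <- mean((h[1, ] - h[2, ])^2)
  }
  expect_lt(abs(mean(pair_asd) - 4 * Ne * mu),
            3 * sd(pair_asd) / sqrt(reps))
})

test_that("a tiny coalescent stays near the founder", {
  sim <- simulate_coalescent(sim_config("coalescent", n = 2, Ne = 1,
                                        mu = 6.9e-4, seed = 1))
  h <- to_minht(sim$profiles)
  expect_true(all(abs(sweep(unclass(h), 2, sim$truth$founder)) <= 1))
})

test_that("SNPs placed on a branch are derived in exactly that clade", {
  for (s in 1:5) {
    cfg <- sim_config("coalescent", n = 8, Ne = 100, mu = 6.9e-4, seed = s)
    sim0 <- simulate_coalescent(cfg)
    # place a marker above the first internal node (leaves n+1 = 9)
    cfg$snp_branches <- c(M3 = 9L)
    sim <- simulate_coalescent(cfg)
    # same seed -> same tree; derived set = leaves below node 9
    below <- function(parent, v, n) {
      if (v <= n) return(v)
      unlist(lapply(which(parent == v), below, parent = parent, n = n))
    }
    leaves <- sort(below(sim$truth$parent, 9L, 8L))
    expect_equal(sort(which(sim$truth$derived[, "M3"])), leaves)
    expect_gte(length(leaves), 2)
    expect_lt(length(leaves), 8)
  }
})

test_that("anomaly injection is reproducible and closed under the filter", {
  sim <- simulate_star(sim_config("star", n = 100, T_g = 200, seed = 6))
  # zero rates: identity
  x0 <- inject_anomalies(sim$profiles, c(microvariant = 0, duplication = 0),
                         seed = 8)
  expect_equal(attr(x0, "n_injected"),
               c(microvariant = 0L, duplication = 0L))
  attr(x0, "n_injected") <- NULL
  expect_identical(as.data.frame(x0), as.data.frame(sim$profiles))
  # rate 1 micro-variants: the atypical filter excludes every sample
  x1 <- inject_anomalies(sim$profiles, c(microvariant = 1), seed = 8)
  expect_equal(unname(attr(x1, "n_injected")["microvariant"]), 100)
  f <- filter_atypical(x1)
  expect_equal(nrow(f$kept), 0)
  expect_true(all(f$report$reason == "micro-variant"))
  # intermediate rate: binomial count, reproducible under the same seed
  xa <- inject_anomalies(sim$profiles, c(microvariant = 0.1,
                                         duplication = 0.05), seed = 12)
  xb <- inject_anomalies(sim$profiles, c(microvariant = 0.1,
                                         duplication = 0.05), seed = 12)
  expect_identical(as.data.frame(xa), as.data.frame(xb))
  expect_identical(attr(xa, "n_injected"), attr(xb, "n_injected"))
  n_mv <- attr(xa, "n_injected")["microvariant"]
  expect_gte(n_mv, qbinom(0.0005, 100, 0.1))
  expect_lte(n_mv, qbinom(0.9995, 100, 0.1))
})

test_that("substream seeding isolates operations from each other", {
  cfg <- sim_config("star", n = 10, T_g = 100, seed = 5)
  sim1 <- simulate_star(cfg)
  # running an unrelated stochastic op in between must not change results
  invisible(simulate_snp_calls(q_tree(), n = 5, seed = 5))
  sim2 <- simulate_star(cfg)
  expect_identical(as.data.frame(sim1$profiles),
                   as.data.frame(sim2$profiles))
})

test_that("simulated datasets round-trip through the table writer", {
  sim <- simulate_star(sim_config("star", n = 8, T_g = 150, seed = 3))
  dir <- tempfile("simout")
  p <- write_sim(sim, dir)
  back <- read_str_table(p, profile_catalog(sim$profiles))
  expect_equal(to_minht(back), to_minht(sim$profiles))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
})
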