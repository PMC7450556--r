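test_that("radial targets are a linear monotone map of degree rank", {
  expect_equal(assign_radial_targets(c(1, -1), r_min = 2, r_max = 8),
               c(2, 8))
  expect_equal(assign_radial_targets(c(1, 0, -1), r_min = 2, r_max = 8),
               c(2, 5, 8))
  expect_warning(
    mid <- assign_radial_targets(c(0.5, 0.5, 0.5), r_min = 2, r_max = 8),
    "constant")
  expect_equal(mid, rep(5, 3))
  # permutation equivariance
  withr::with_seed(9, {
    deg <- rnorm(25)
    perm <- sample(25)
    expect_equal(assign_radial_targets(deg)[perm],
                 assign_radial_targets(deg[perm]))
  })
})

test_that("random initialization is seeded, confined, and bond-exact", {
  bt <- toy_bins() # 2 chains, 5 beads
  rs <- restraint_set(rep(5, bt$n_bins), confinement_radius = 10)
  c1 <- initialize_random_conformation(bt, rs, seed = 11)
  c2 <- initialize_random_conformation(bt, rs, seed = 11)
  expect_identical(c1$coords, c2$coords)
  c3 <- initialize_random_conformation(bt, rs, seed = 12)
  expect_false(identical(c1$coords, c3$coords))
  expect_true(all(sqrt(rowSums(c1$coords^2)) <= 10 + 1e-12))
  # sequential distances equal bond_length within chains only
  d12 <- sqrt(sum((c1$coords[1, ] - c1$coords[2, ])^2))
  d23 <- sqrt(sum((c1$coords[2, ] - c1$coords[3, ])^2))
  expect_equal(c(d12, d23), c(1, 1))
  expect_equal(c1$chain_breaks, c(1L, 4L))
})

test_that("energy matches a term-by-term brute-force oracle and is rigid-motion invariant", {
  bt <- toy_bins()
  withr::with_seed(21, {
    tg <- runif(bt$n_bins, 2, 9)
    rs <- restraint_set(tg, bond_k = 1.3, radial_k = 0.7)
    conf <- initialize_random_conformation(bt, rs, seed = 5)
    conf$coords <- conf$coords + matrix(rnorm(bt$n_bins * 3), ncol = 3)
  })
  x <- conf$coords
  oracle <- 0
  for (pair in list(c(1, 2), c(2, 3), c(4, 5))) { # bonds skip the chain break
    d <- sqrt(sum((x[pair[1], ] - x[pair[2], ])^2))
    oracle <- oracle + 1.3 * (d - 1)^2
  }
  for (i in 1:5)
    oracle <- oracle + 0.7 * (sqrt(sum(x[i, ]^2)) - rs$radial_targets[i])^2
  expect_equal(conformation_energy(conf, rs), oracle, tolerance = 1e-9)

  # rotation + reflection leave the energy unchanged
  th <- 0.83
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, -1), 3, 3)
  conf_rot <- conf
  conf_rot$coords <- conf$coords %*% rot
  expect_equal(conformation_energy(conf_rot, rs),
               conformation_energy(conf, rs), tolerance = 1e-9)
})

test_that("energy is zero exactly at satisfied restraints; unit stretch costs bond_k", {
  bt <- bin_table(c(c1 = 1e6), 5e5) # one chain, 2 beads
  rs <- restraint_set(c(3, 3), bond_length = 1, bond_k = 1, radial_k = 1)
  conf <- initialize_random_conformation(bt, rs, seed = 1)
  # both beads on the radius-3 sphere, one bond length apart
  conf$coords <- rbind(c(3, 0, 0), c(3 * cos(a <- 2 * asin(0.5 / 3)),
                                     3 * sin(a), 0))
  expect_equal(conformation_energy(conf, rs), 0, tolerance = 1e-12)
  # stretch the bond by 1
  conf2 <- conf
  conf2$coords <- rbind(c(0, 3, 0), c(0, 3, 2)) # d = 2 = bond_length + 1
  rs2 <- restraint_set(c(3, sqrt(13)), bond_length = 1, bond_k = 1,
                       radial_k = 1)
  expect_equal(conformation_energy(conf2, rs2), 1.0, tolerance = 1e-9)
})

test_that("optimization never increases energy and leaves optima fixed", {
  bt <- toy_bins()
  rs <- restraint_set(rep(4, bt$n_bins))
  init <- initialize_random_conformation(bt, rs, seed = 3)
  opt <- optimize_conformation(init, rs)
  expect_lte(opt$energy, init$energy)
  again <- optimize_conformation(opt, rs)
  expect_lte(again$energy, opt$energy)
  expect_equal(again$energy, opt$energy, tolerance = 1e-3)
})

test_that("bond-only objective drives sequential distances to bond_length", {
  bt <- bin_table(c(c1 = 1.5e6), 5e5) # 3 beads, one chain
  rs <- restraint_set(rep(5, 3), radial_k = 1e-9, bond_k = 1)
  init <- initialize_random_conformation(bt, rs, seed = 8)
  init$coords <- init$coords * 1.7 # break the exact bonds
  opt <- optimize_conformation(init, rs, max_iter = 20000, tol = 1e-12)
  d <- sqrt(rowSums((opt$coords[-1, ] - opt$coords[-3, ])^2))
  expect_true(all(abs(d - 1) < 0.01))
})

test_that("converged chains satisfy radial targets and longer budgets never hurt", {
  bt <- bin_table(c(c1 = 1e7), 5e5) # 20 beads
  deg <- sin(seq(0, 3, length.out = 20))
  tg <- assign_radial_targets(deg)
  rs <- restraint_set(tg)
  opt <- optimize_conformation(
    initialize_random_conformation(bt, rs, seed = 2), rs)
  r <- sqrt(rowSums(opt$coords^2))
  expect_gte(mean(abs(r - tg) / tg <= 0.1), 0.9)

  e_small <- sapply(1:10, function(s)
    optimize_conformation(initialize_random_conformation(bt, rs, seed = s),
                          rs, max_iter = 30, tol = 0)$energy)
  e_large <- sapply(1:10, function(s)
    optimize_conformation(initialize_random_conformation(bt, rs, seed = s),
                          rs, max_iter = 300, tol = 0)$energy)
  expect_true(all(e_large <= e_small + 1e-12))
  expect_lt(mean(e_large), mean(e_small))
})

test_that("ensembles are deterministic, seeded per replica, and beat random inits", {
  bt <- toy_bins()
  rs <- restraint_set(rep(4, bt$n_bins))
  e1 <- generate_ensemble(bt, rs, n_replicas = 5, base_seed = 100)
  e2 <- generate_ensemble(bt, rs, n_replicas = 5, base_seed = 100)
  expect_identical(lapply(e1$replicas, `[[`, "coords"),
                   lapply(e2$replicas, `[[`, "coords"))
  expect_equal(vapply(e1$replicas, `[[`, integer(1), "seed"), 101:105)
  expect_equal(formals(generate_ensemble)$n_replicas, 300L)

  init_energy <- mean(sapply(101:105, function(s)
    initialize_random_conformation(bt, rs, seed = s)$energy))
  expect_true(all(vapply(e1$replicas, `[[`, numeric(1), "energy") <
                  init_energy))
})

test_that("higher-degree beads end nearer the nuclear center", {
  bt <- bin_table(c(c1 = 8e6, c2 = 7e6), 5e5) # 30 beads
  deg <- c(sin(seq(0, 3, length.out = 16)), cos(seq(0, 3, length.out = 14)))
  tg <- assign_radial_targets(deg)
  rs <- restraint_set(tg)
  ens <- generate_ensemble(bt, rs, n_replicas = 5, base_seed = 7)
  r <- mean_bead_radius(ens)
  expect_lte(cor(r, deg, method = "spearman"), -0.8)
})

test_that("ensemble XYZ + JSON round-trip preserves coordinates and metadata", {
  bt <- toy_bins()
  rs <- restraint_set(rep(4, bt$n_bins), radial_k = 2.5)
  ens <- generate_ensemble(bt, rs, n_replicas = 3, base_seed = 50)
  dir <- tempfile()
  write_ensemble(ens, dir)
  back <- read_ensemble(dir)
  expect_equal(length(back$replicas), 3)
  for (i in 1:3)
    expect_equal(back$replicas[[i]]$coords, ens$replicas[[i]]$coords,
                 tolerance = 1e-12)
  expect_equal(back$restraints$radial_k, 2.5)
  expect_equal(back$bins$n_bins, bt$n_bins)
  expect_equal(vapply(back$replicas, `[[`, numeric(1), "energy"),
               vapply(ens$replicas, `[[`, numeric(1), "energy"),
               tolerance = 1e-12)
})
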