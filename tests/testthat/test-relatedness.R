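test_that("classical inbreeding and coancestry values are reproduced", {
  # full-sib mating, unrelated non-inbred grandparents
  ped <- mk_ped(c("gs", "gd", "s", "d", "x"),
                c(NA, NA, "gs", "gs", "s"), c(NA, NA, "gd", "gd", "d"))
  F <- inbreeding(ped)
  expect_equal(unname(F[c("gs", "gd", "s", "d")]), rep(0, 4))
  expect_equal(unname(F["x"]), 0.25)
  f <- coancestry(ped, c("gs", "gd", "s", "x"))
  expect_equal(f["gs", "gd"], 0)              # unrelated founders
  expect_equal(f["gs", "gs"], 0.5)            # non-inbred self-coancestry
  expect_equal(f["gs", "s"], 0.25)            # parent-offspring
  expect_equal(f["x", "x"], (1 + 0.25) / 2)   # inbred self-coancestry
})

test_that("Meuwissen-Luo F and AR match the dense tabular oracle", {
  for (s in c(1, 2)) {
    ped <- random_ped(n = if (s == 1) 220 else 450,
                      n_founders = 40, missing = 0.08, seed = s)
    A <- tabular_A(ped)
    expect_lt(max(abs(inbreeding(ped) - (diag(A) - 1))), 1e-12)
    expect_lt(max(abs(average_relatedness(ped) - rowMeans(A))), 1e-10)
    # indirect product agrees on an arbitrary vector
    set.seed(s)
    x <- stats::rnorm(nrow(ped))
    expect_lt(max(abs(relationship_product(ped, x) - drop(A %*% x))), 1e-9)
    # exact mean coancestry equals the dense mean
    expect_equal(mean_coancestry(ped), mean(A) / 2, tolerance = 1e-12)
    # A is positive semidefinite
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("coancestry submatrices agree with the oracle", {
  ped <- random_ped(120, seed = 3)
  A <- tabular_A(ped)
  ids <- sample(ped$id, 15)
  expect_equal(coancestry(ped, ids), A[ids, ids] / 2, tolerance = 1e-12)
})

test_that("single founders and unrelated sets have textbook AR", {
  one <- mk_ped("solo")
  expect_equal(unname(average_relatedness(one)), 1)
  many <- mk_ped(letters[1:5])
  expect_equal(unname(average_relatedness(many)), rep(1 / 5, 5))
})

test_that("rates of inbreeding and coancestry follow their closed forms", {
  expect_equal(rate_of_inbreeding(0, 7), 0)
  expect_equal(rate_of_inbreeding(0.25, 2), 0.25)
  expect_equal(rate_of_inbreeding(0.25, 3), 1 - sqrt(0.75))
  expect_equal(rate_of_inbreeding(0.1, 0.5), 0.1)  # t <= 1 convention
  expect_error(rate_of_inbreeding(1, 3), "< 1")

  expect_equal(rate_of_coancestry(0, 4, 2), 0)
  expect_equal(rate_of_coancestry(0.25, 2, 2), 1 - sqrt(0.75))
  expect_equal(rate_of_coancestry(0.13, 5, 2),
               rate_of_coancestry(0.13, 2, 5))  # symmetry
  expect_error(rate_of_coancestry(0.1, 0, 0), "> 0")
})

test_that("non-random mating degree reproduces the printed studbook values", {
  expect_equal(round(nonrandom_mating(0.0844, 0.0072), 2), 0.08)
  expect_equal(round(nonrandom_mating(0.0289, 0.0213), 2), 0.01)
  expect_equal(nonrandom_mating(0.05, 0.05), 0)
  expect_error(nonrandom_mating(0.1, 1), "< 1")
})

test_that("mean coancestry can exclude self-pairs", {
  ped <- random_ped(80, seed = 4)
  A <- tabular_A(ped)
  n <- nrow(A)
  expect_equal(mean_coancestry(ped, include_self = FALSE),
               mean(A[row(A) != col(A)]) / 2, tolerance = 1e-12)
})

test_that("GCI is the reciprocal squared founder-contribution sum", {
  ped <- mk_ped(c("f1", "f2", "x"), c(NA, NA, "f1"), c(NA, NA, "f2"))
  expect_equal(unname(genetic_conservation_index(ped, "x")), 2)
  expect_equal(unname(genetic_conservation_index(ped, "f1")), 1)

  ped4 <- mk_ped(c("g1", "g2", "g3", "g4", "s", "d", "x"),
                 c(NA, NA, NA, NA, "g1", "g3", "s"),
                 c(NA, NA, NA, NA, "g2", "g4", "d"))
  expect_equal(unname(genetic_conservation_index(ped4, "x")), 4)

  # both parents the same founder (selfing-like loop via phantom sexes)
  df <- data.frame(id = c("f", "x"), sire = c(NA, "f"), dam = c(NA, "f"),
                   sex = c("unknown", "unknown"))
  pedf <- as_pedigree(df)
  expect_equal(unname(genetic_conservation_index(pedf, "x")), 1)
})

test_that("founder contributions sum to the traced pedigree fraction", {
  ped <- random_ped(150, missing = 0.2, seed = 6)
  fa <- founder_accounting(ped, ped$id)
  expect_lte(sum(fa$founder_probabilities$q), 1 + 1e-12)
  full <- simulate_purebred(sim_config(n_founders_per_breed = 10,
                                       n_generations = 3,
                                       missing_parent_rate = 0, seed = 8))
  fa2 <- founder_accounting(full, full$id[full$generation == 3])
  expect_equal(sum(fa2$founder_probabilities$q), 1, tolerance = 1e-12)
})

test_that("diversity summary is internally consistent", {
  ped <- simulate_purebred(sim_config(n_founders_per_breed = 20,
                                      n_generations = 4, seed = 12))
  ds <- diversity_summary(ped)
  pop <- ds$population
  expect_equal(pop$alpha,
               1 - (1 - pop$mean_F) / (1 - pop$mean_coancestry))
  expect_lte(pop$pct_highly_inbred, pop$pct_inbred)
  expect_equal(pop$mean_F, mean(ds$individuals$F))
  expect_gte(pop$max_F, max(ds$individuals$F))
})
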