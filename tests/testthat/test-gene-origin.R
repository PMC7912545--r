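test_that("founder accounting applies the half-founder convention", {
  ped <- mk_ped(c("f1", "f2", "h", "x"),
                c(NA, NA, "f1", "h"), c(NA, NA, NA, "f2"))
  acc <- founder_accounting(ped, "x")
  expect_equal(acc$n_founders, 2)
  expect_equal(acc$base_population, 3)      # f1, f2, h
  expect_equal(acc$actual_base, 2.5)        # h counts one half
  q <- stats::setNames(acc$founder_probabilities$q,
                       acc$founder_probabilities$id)
  expect_equal(unname(q["f2"]), 0.5)
  expect_equal(unname(q["f1"]), 0.25)       # via h; h's unknown dam lost

  # reference = the founders themselves
  acc2 <- founder_accounting(ped, c("f1", "f2"))
  expect_equal(acc2$founder_probabilities$q, c(0.5, 0.5))
})

test_that("effective founders follows 1/sum q^2", {
  expect_equal(effective_founders(rep(1 / 7, 7)), 7)
  expect_equal(effective_founders(c(0.75, 0.25)), 1.6)
  expect_equal(effective_founders(c(0.5, 0.3, 0.2)), 1 / 0.38)
  expect_error(effective_founders(c(0, 0)), "zero")
  # more unequal contributions, same founder count -> smaller fe
  expect_lt(effective_founders(c(0.9, 0.05, 0.05)),
            effective_founders(c(0.4, 0.3, 0.3)))
})

test_that("marginal ancestor selection matches the gene-origin walk oracle", {
  # chain pedigree: two founders, their offspring line down to x
  ped <- mk_ped(c("f1", "f2", "m", "c", "x"),
                c(NA, NA, "f1", "f1", "c"), c(NA, NA, "f2", "f2", "m"))
  res <- effective_ancestors(ped, "x")
  orc <- oracle_ancestors(ped, "x")
  expect_equal(res$marginal_contributions$id, orc$ids)
  expect_equal(res$marginal_contributions$p, orc$p, tolerance = 1e-12)
  expect_equal(res$marginal_contributions$p[1], 0.5)  # a parent first

  # random small pedigrees: greedy sequence equals the oracle sequence
  for (s in 1:4) {
    rped <- random_ped(n = 14, n_founders = 4, missing = 0.15, seed = s)
    ref <- rped$id[10:14]
    res <- effective_ancestors(rped, ref)
    orc <- oracle_ancestors(rped, ref)
    expect_equal(res$marginal_contributions$id, orc$ids)
    expect_equal(res$marginal_contributions$p, orc$p, tolerance = 1e-10)
  }
})

test_that("unrelated founders are their own ancestors with p = 1/n", {
  ped <- mk_ped(letters[1:6])
  res <- effective_ancestors(ped, letters[1:6])
  expect_equal(res$fa, 6)
  expect_equal(res$marginal_contributions$p, rep(1 / 6, 6))
})

test_that("a ubiquitous sire takes a marginal contribution of at least 1/2", {
  ped <- mk_ped(c("S", "d1", "d2", "d3", "o1", "o2", "o3"),
                c(NA, NA, NA, NA, "S", "S", "S"),
                c(NA, NA, NA, NA, "d1", "d2", "d3"))
  res <- effective_ancestors(ped, c("o1", "o2", "o3"))
  expect_equal(res$marginal_contributions$id[1], "S")
  expect_gte(res$marginal_contributions$p[1], 0.5)
  expect_equal(res$marginal_contributions$p[1],
               walk_prob(ped, c("o1", "o2", "o3"), "S"))
})

test_that("analytic fg equals textbook values and bounds hold", {
  ped <- mk_ped(letters[1:5])
  expect_equal(founder_genome_equivalents(ped, letters[1:5]), 5)
  one <- mk_ped("z")
  expect_equal(founder_genome_equivalents(one, "z"), 1)
  expect_error(founder_genome_equivalents(ped, letters[1:5],
                                          method = "gene_drop", n_reps = 10),
               "unstable")
})

test_that("gene-drop fg converges on the analytic value", {
  ped <- simulate_purebred(sim_config(n_founders_per_breed = 25,
                                      n_generations = 4, seed = 21))
  ref <- ped$id[ped$generation == 4]
  fga <- founder_genome_equivalents(ped, ref)
  fgd <- founder_genome_equivalents(ped, ref, method = "gene_drop",
                                    n_reps = 10000, seed = 2)
  se <- attr(fgd, "se")
  # compare on the identity-probability scale where the SE lives
  expect_lt(abs(attr(fgd, "mean_identity") - 1 / (2 * fga)), 3 * se)
  # Monte-Carlo error shrinks with replicates
  f1k <- founder_genome_equivalents(ped, ref, method = "gene_drop",
                                    n_reps = 1000, seed = 3)
  expect_lt(se, attr(f1k, "se") / 2)
})

test_that("diversity losses and Nef follow the gene-origin identities", {
  dl <- diversity_losses(fe = 37.67, fg = 7.90)
  expect_equal(dl$GD, 1 - 1 / (2 * 7.90))
  expect_equal(round(dl$Nef, 2), 10.00)
  expect_equal(dl$loss_drift, dl$GD_star - dl$GD)
  expect_error(diversity_losses(fe = 5, fg = 9), "fe < fg")
  dl2 <- diversity_losses(fe = 8, fg = 8)
  expect_true(is.infinite(dl2$Nef) && dl2$no_nonfounder_bottleneck)
})

test_that("inbreeding partition sums to mean F with symmetric loops", {
  # full sibs: common grandsire and granddam contribute 0.125 each
  ped <- mk_ped(c("gs", "gd", "s", "d", "x"),
                c(NA, NA, "gs", "gs", "s"), c(NA, NA, "gd", "gd", "d"))
  part <- partition_inbreeding(ped, "x")
  expect_equal(sort(part$contributions$contribution), c(0.125, 0.125))
  expect_equal(sum(part$contributions$contribution), part$mean_F)

  # non-inbred reference -> empty partition
  ped0 <- mk_ped(c("a", "b", "c"), c(NA, NA, "a"), c(NA, NA, "b"))
  expect_equal(nrow(partition_inbreeding(ped0, "c")$contributions), 0)

  # simulated pedigree: partition total equals the Meuwissen-Luo mean F
  ped1 <- random_ped(100, n_founders = 10, missing = 0, seed = 9)
  part1 <- partition_inbreeding(ped1, ped1$id)
  expect_equal(sum(part1$contributions$contribution),
               mean(inbreeding(ped1)), tolerance = 1e-8)
})

test_that("fg <= fa <= fe on simulated pedigrees", {
  for (s in 1:5) {
    ped <- simulate_purebred(sim_config(n_founders_per_breed = 15,
                                        n_generations = 4,
                                        missing_parent_rate = 0.05,
                                        seed = 30 + s))
    rep <- gene_origin_report(ped, ped$id[ped$generation == 4])
    expect_lte(rep$fg, rep$fa + 1e-9)
    expect_lte(rep$fa, rep$fe + 1e-9)
  }
})
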