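test_that("diversity indices match hand-evaluated values", {
  expect_equal(shannon(c(10)), 0)
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon(c(25, 13, 27, 12, 23)), 1.557779391842, tolerance = 1e-10)
  expect_equal(shannon(c(0, 5, 0, 5)), log(2))  # zeros contribute nothing

  expect_equal(pielou(c(3, 3, 3)), 1)
  expect_equal(pielou(c(25, 13, 27, 12, 23)), 1.557779391842 / log(5),
               tolerance = 1e-10)
  expect_error(pielou(c(10)), class = "nema_undefined_evenness")

  expect_equal(simpson_dominance(c(10)), 1)
  expect_equal(simpson_dominance(c(5, 5, 5, 5)), 0.25)
  expect_equal(simpson_dominance(c(25, 13, 27, 12, 23)), 0.2196,
               tolerance = 1e-12)

  expect_error(shannon(c(0, 0)), class = "nema_undefined_composition")
  expect_error(simpson_dominance(numeric(0)), class = "nema_undefined_composition")
})

test_that("guild ratio indices follow their defining formulas", {
  # printed-composition check: channel ratio from guild marginals
  expect_equal(round(ncr(guild_cp_tally(Ba2 = 40.31, Fu2 = 13.42)), 2), 0.75)
  expect_equal(round(ncr(guild_cp_tally(Ba2 = 47.14, Fu2 = 14.91)), 2), 0.76)
  expect_equal(ncr(guild_cp_tally(Ba2 = 7, Fu2 = 7)), 0.5)
  expect_error(ncr(guild_cp_tally(Pp3 = 5)), class = "nema_undefined_channel")

  expect_equal(wi(guild_cp_tally(Ba2 = 3, Fu2 = 2, Pp3 = 5)), 1)
  expect_equal(wi(guild_cp_tally(Ba2 = 47.14, Fu2 = 14.91, Pp3 = 14.10)),
               4.400709, tolerance = 1e-6)
  expect_error(wi(guild_cp_tally(Ba2 = 5)), class = "nema_undefined_wi")
})

test_that("maturity and plant-parasite indices weight c-p classes correctly", {
  expect_equal(maturity_index(guild_cp_tally(Ba2 = 12)), 2)
  expect_equal(maturity_index(guild_cp_tally(Ba2 = 5, Op5 = 5)), 3.5)
  expect_equal(maturity_index(guild_cp_tally(Ba2 = 10, Fu2 = 5, Op4 = 5)),
               (2 * 10 + 2 * 5 + 4 * 5) / 20)
  # plant parasites never enter MI
  expect_equal(maturity_index(guild_cp_tally(Ba2 = 10, Pp5 = 100)), 2)
  expect_error(maturity_index(guild_cp_tally(Pp3 = 5)), class = "nema_undefined_mi")

  expect_equal(ppi(guild_cp_tally(Pp3 = 9)), 3)
  expect_equal(ppi(guild_cp_tally(Pp2 = 5, Pp3 = 5)), 2.5)
  expect_equal(ppi(guild_cp_tally(Pp2 = 5, Pp3 = 5, Ba2 = 10),
                   mode = "paper_literal"), 1.25)
  expect_error(ppi(guild_cp_tally(Ba2 = 5)), class = "nema_undefined_ppi")
})

test_that("faunal components implement both formula dialects", {
  fc <- faunal_components(guild_cp_tally(Ba1 = 10, Ba2 = 10))
  expect_equal(fc$b, 8)    # 0.8 * Ba2
  expect_equal(fc$e, 32)   # 3.2 * Ba1
  expect_equal(fc$s, 0)

  lit <- faunal_components(guild_cp_tally(Pp1 = 10, Pp2 = 10, Fu2 = 5),
                           mode = "paper_literal")
  expect_equal(lit$b, 0.8 * (10 + 5))
  expect_equal(lit$e, 3.2 * 10 + 0.8 * 5)

  empty <- faunal_components(guild_cp_tally())
  expect_equal(c(empty$b, empty$e, empty$s), c(0, 0, 0))

  for (mode in c("canonical", "paper_literal")) {
    fc5 <- faunal_components(guild_cp_tally(Op5 = 4), mode = mode)
    expect_equal(fc5$s, 20)  # 4 x W5
    expect_equal(c(fc5$b, fc5$e), c(0, 0))
  }
})

test_that("enrichment and structure indices are bounded percentages", {
  fc <- faunal_components(guild_cp_tally(Ba1 = 10, Ba2 = 10))
  expect_equal(enrichment_index(fc), 80)  # 100 * 32 / 40
  expect_equal(structure_index(list(b = 8, e = 0, s = 20)), 100 * 20 / 28)
  expect_equal(enrichment_index(list(b = 5, e = 0, s = 0)), 0)
  expect_equal(enrichment_index(list(b = 0, e = 3, s = 0)), 100)
  expect_equal(structure_index(list(b = 5, e = 0, s = 0)), 0)
  expect_equal(structure_index(list(b = 0, e = 0, s = 3)), 100)
  expect_error(enrichment_index(list(b = 0, e = 0, s = 1)),
               class = "nema_undefined_ei")
  expect_error(structure_index(list(b = 0, e = 1, s = 0)),
               class = "nema_undefined_si")
})

test_that("faunal profile quadrants split at 50/50 with a lower-tie rule", {
  expect_equal(as.character(faunal_profile_quadrant(80, 20)), "A")
  expect_equal(as.character(faunal_profile_quadrant(80, 80)), "B")
  expect_equal(as.character(faunal_profile_quadrant(20, 80)), "C")
  expect_equal(as.character(faunal_profile_quadrant(20, 20)), "D")
  q <- faunal_profile_quadrant(50, 50)
  expect_equal(as.character(q), "D")
  expect_true(attr(q, "boundary"))
  expect_error(faunal_profile_quadrant(NA, 20), class = "nema_undefined_quadrant")
})

test_that("indices are invariant to taxon order and uniform count scaling", {
  set.seed(42)
  for (i in 1:25) {
    n <- rpois(6, 8) + 1
    expect_equal(shannon(n), shannon(rev(n)))
    expect_equal(shannon(n), shannon(5L * n))
    expect_equal(simpson_dominance(n), simpson_dominance(sample(n)))
    m <- random_tally_matrix() + 1  # strictly positive: all indices defined
    t1 <- new_tally_for_test(m)
    t2 <- new_tally_for_test(3 * m)
    for (f in list(ncr, wi, maturity_index, ppi)) {
      expect_equal(f(t1), f(t2))
    }
    expect_equal(enrichment_index(faunal_components(t1)),
                 enrichment_index(faunal_components(t2)))
  }
})

test_that("per-sample index table aggregates replicates with SE and letters", {
  tax <- default_taxonomy()
  mk <- function(trt, rep_i, counts) {
    data.frame(sample_id = sprintf("%s_%d", trt, rep_i),
               genus = names(counts), count = as.integer(counts))
  }
  base_counts <- c(Acrobeloides = 10L, Rotylenchus = 6L, Aphelenchus = 4L,
                   Eudorylaimus = 3L)
  counts <- rbind(mk("CK", 1, base_counts), mk("CK", 2, base_counts),
                  mk("CK", 3, base_counts),
                  mk("A", 1, base_counts * 2L), mk("A", 2, base_counts * 2L),
                  mk("A", 3, base_counts * 2L))
  meta <- data.frame(sample_id = unique(counts$sample_id),
                     treatment = rep(c("CK", "A"), each = 3),
                     depth_layer = "0-5", replicate = rep(1:3, 2),
                     fresh_mass_g = 60, water_content = 0.4)
  m <- community_matrix(counts, meta, tax)
  it <- index_table(m)
  pt <- it$per_treatment
  # identical replicates: SE = 0 for every defined index
  expect_true(all(pt$se[pt$n_defined == 3] == 0))
  # doubling all counts leaves every index unchanged: identical group means
  for (idx in unique(pt$index)) {
    expect_equal(pt$mean[pt$index == idx & pt$treatment == "CK"],
                 pt$mean[pt$index == idx & pt$treatment == "A"])
  }

  # single replicate: mean = value, SE undefined
  one <- community_matrix(mk("CK", 1, base_counts),
                          meta[1, , drop = FALSE], tax)
  it1 <- index_table(one)
  expect_true(all(is.na(it1$per_treatment$se)))
  expect_equal(it1$per_treatment$mean[it1$per_treatment$index == "NCR"],
               10 / 14)
})

test_that("treatment means equal an independent per-sample recomputation", {
  sim <- generate_dataset(sim_config(rng_seed = 5))
  pooled <- pool_layers(sim)
  it <- index_table(pooled)
  ps <- it$per_sample
  for (trt in unique(ps$treatment)) {
    v <- ps$NCR[ps$treatment == trt]
    # brute force: recompute NCR per replicate from raw counts
    ids <- pooled$meta$sample_id[pooled$meta$treatment == trt]
    direct <- vapply(ids, function(id) {
      cts <- sample_counts(pooled, id)
      g <- oracle_guild_sums(unclass(tally_guild_cp(cts, pooled$taxonomy)))
      g[["Ba"]] / (g[["Ba"]] + g[["Fu"]])
    }, numeric(1))
    expect_equal(mean(v), mean(direct), tolerance = 1e-12)
    row <- it$per_treatment[it$per_treatment$treatment == trt &
                              it$per_treatment$index == "NCR", ]
    expect_equal(row$mean, mean(direct), tolerance = 1e-12)
    expect_equal(row$se, sd(direct) / sqrt(length(direct)), tolerance = 1e-12)
  }
})
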