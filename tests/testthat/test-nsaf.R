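test_that("pseudocounted NSAF matches hand-computed values", {
  design <- toy_design()
  # one protein: normalization is trivially 1 everywhere
  one <- toy_records(matrix(c(0, 3, 9, 0, 0, 5), nrow = 1))
  expect_equal(unname(compute_nsaf(one, design)[1, ]), rep(1, 6))

  # two proteins, (SpC, L) = (0, 100) and (3, 200) in sample P1:
  # numerators 1/100 and 4/200 -> shares 1/3 and 2/3
  two <- toy_records(rbind(c(0, 0, 0, 0, 0, 0), c(3, 3, 3, 3, 3, 3)),
                     length_aa = c(100L, 200L))
  nsaf <- compute_nsaf(two, design)
  expect_equal(unname(nsaf[, "P1"]), c(1 / 3, 2 / 3))

  # equal counts, equal lengths: perfect symmetry
  eq <- toy_records(rbind(c(2, 4, 1, 0, 2, 2), c(2, 4, 1, 0, 2, 2)))
  expect_equal(unname(compute_nsaf(eq, design)), matrix(0.5, 2, 6),
               ignore_attr = TRUE)
})

test_that("every sample column sums to one and entries stay positive", {
  for (seed in 1:5) {
    sim <- simulate_pulldown(simulation_config(n_background = 80L,
                                               n_spiked_P = 5L,
                                               n_spiked_NP = 5L,
                                               seed = seed))
    nsaf <- compute_nsaf(sim$records, sim$design)
    expect_lt(max(abs(colSums(nsaf) - 1)), 1e-9)
    expect_true(all(nsaf > 0))
    expect_true(all(nsaf <= 1))
  }
})

test_that("row permutation permutes values without changing them", {
  design <- toy_design()
  set.seed(11)
  rec <- toy_records(matrix(rpois(60, 4), nrow = 10),
                     length_aa = sample(100:900, 10))
  nsaf <- compute_nsaf(rec, design)
  perm <- sample(10)
  nsaf_p <- compute_nsaf(rec[perm, ], design)
  expect_equal(nsaf_p, nsaf[perm, ])
})

test_that("pseudocount effect vanishes as counts grow", {
  design <- toy_design()
  base_counts <- matrix(c(8, 6, 9, 2, 3, 2,
                          1, 2, 1, 7, 9, 6,
                          4, 4, 5, 4, 3, 5), nrow = 3, byrow = TRUE)
  lengths <- c(150L, 400L, 900L)
  # pseudocount-free NSAF of the scaled table is scale-invariant
  plain <- sweep(base_counts / lengths, 2, colSums(base_counts / lengths), "/")
  err <- sapply(c(1, 10, 100, 1000), function(c_mult) {
    rec <- toy_records(base_counts * c_mult, length_aa = lengths)
    max(abs(compute_nsaf(rec, design) - plain))
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[4], 1e-3)
})

test_that("zero-count proteins keep strictly positive abundance", {
  design <- toy_design()
  rec <- toy_records(rbind(c(0, 0, 0, 0, 0, 0), c(50, 60, 40, 55, 45, 50)),
                     length_aa = c(300L, 300L))
  nsaf <- compute_nsaf(rec, design)
  expect_true(all(nsaf[1, ] > 0))
})

test_that("detected-set normalization is selectable and behaves as documented", {
  design <- toy_design()
  rec <- toy_records(rbind(c(0, 2, 2, 2, 2, 2), c(3, 3, 3, 3, 3, 3)),
                     length_aa = c(100L, 100L))
  det <- compute_nsaf(rec, design, normalization = "detected")
  # P1: only protein 2 detected -> its own share is 1; the undetected
  # protein still gets pseudocount mass relative to that denominator
  expect_equal(unname(det[2, "P1"]), 1)
  expect_equal(unname(det[1, "P1"]), (1 / 100) / (4 / 100))
  # elsewhere both detected -> identical to union normalization
  expect_equal(det[, "P2"], compute_nsaf(rec, design)[, "P2"])
})

test_that("degenerate inputs are rejected", {
  design <- toy_design()
  empty <- toy_records(matrix(1, 1, 6))[0, ]
  expect_error(compute_nsaf(empty, design), "no proteins")
  expect_error(condition_means(matrix(1, 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("P1", "NP1"))),
                               design),
               "lacks sample")
})

test_that("condition means average replicates within each condition", {
  design <- toy_design()
  rec <- toy_records(rbind(c(1, 2, 3, 4, 5, 6), c(9, 8, 7, 6, 5, 4)),
                     length_aa = c(200L, 200L))
  nsaf <- compute_nsaf(rec, design)
  m <- condition_means(nsaf, design)
  expect_equal(m$mean_P, rowMeans(nsaf[, c("P1", "P2", "P3")]),
               ignore_attr = TRUE)
  expect_equal(m$mean_NP, rowMeans(nsaf[, c("NP1", "NP2", "NP3")]),
               ignore_attr = TRUE)
  expect_true(all(m$mean_P > 0 & m$mean_NP > 0))
  # all-identical samples collapse the two condition means
  same <- toy_records(matrix(rep(c(3, 5), 6), nrow = 2), length_aa = c(100L, 300L))
  ms <- condition_means(compute_nsaf(same, design), design)
  expect_equal(ms$mean_P, ms$mean_NP)
})
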