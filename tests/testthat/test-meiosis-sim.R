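t_parent <- function(r = eb4) nucleus("T", r, "A")
n_parent <- function(r = eb4) nucleus("N", r, "a")

test_that("forced segregation patterns give the textbook octets", {
  set.seed(11)
  for (i in 1:5) {
    alt <- simulate_meiosis_octet(t_parent(), n_parent(), eb4,
                                  cross_params(p_alt = 1))
    expect_equal(sort(octet_genotypes(alt, eb4)), rep(c("N", "T"), each = 4))
    adj <- simulate_meiosis_octet(t_parent(), n_parent(), eb4,
                                  cross_params(p_alt = 0))
    expect_equal(sort(octet_genotypes(adj, eb4)), rep(c("Df", "Dp"), each = 4))
  }
  ## isosequential crosses are unaffected by the pattern
  nn <- simulate_meiosis_octet(nucleus("N", eb4, "A"), n_parent(), eb4,
                               cross_params(p_alt = 0))
  expect_equal(octet_genotypes(nn, eb4), rep("N", 8))
})

test_that("octets always hold 4 mat A + 4 mat a, in pole blocks", {
  set.seed(12)
  for (i in 1:10) {
    oct <- simulate_meiosis_octet(t_parent(), n_parent(), eb4,
                                  cross_params(c_donor = 0.5,
                                               c_recipient = 0.5))
    mats <- vapply(oct$nuclei, `[[`, "", "mat")
    expect_equal(sum(mats == "A"), 4L)
    expect_equal(sum(mats == "a"), 4L)
    ## first-division segregation of mat: uniform within each pole lineage
    expect_length(unique(mats[1:4]), 1L)
    expect_length(unique(mats[5:8]), 1L)
  }
})

test_that("same-mating-type crosses are refused", {
  expect_error(
    simulate_meiosis_octet(t_parent(), nucleus("N", eb4, "A"), eb4),
    "cross refused")
})

test_that("a single donor interstitial crossover yields 2T + 2N + 2Dp + 2Df", {
  set.seed(13)
  for (p_alt in c(1, 0)) {
    for (i in 1:5) {
      oct <- simulate_meiosis_octet(
        t_parent(), n_parent(), eb4,
        cross_params(p_alt = p_alt, c_donor = 1, c_recipient = 0))
      expect_equal(sort(octet_genotypes(oct, eb4)),
                   sort(rep(c("T", "N", "Dp", "Df"), 2)))
    }
  }
})

test_that("octet compositions match brute-force chromatid enumeration", {
  set.seed(14)
  for (pattern in c("alt", "adj")) for (cd in c(FALSE, TRUE))
    for (cr in c(FALSE, TRUE)) {
      expected <- enumerate_octet_compositions(pattern, cd, cr)
      params <- cross_params(p_alt = as.numeric(pattern == "alt"),
                             c_donor = as.numeric(cd),
                             c_recipient = as.numeric(cr))
      seen <- unique(vapply(1:40, function(i)
        octet_key(simulate_meiosis_octet(t_parent(), n_parent(), eb4,
                                         params), eb4), ""))
      expect_true(all(seen %in% expected),
                  label = sprintf("%s cd=%d cr=%d: seen within enumeration",
                                  pattern, cd, cr))
      expect_setequal(seen, expected)
    }
})

test_that("tetrasperma packaging pairs nonsister nuclei of opposite mat", {
  set.seed(15)
  params <- cross_params(species = "tetrasperma")
  for (i in 1:10) {
    oct <- simulate_meiosis_octet(t_parent(), n_parent(), eb4, params)
    asc <- package_ascospores(oct, params)
    expect_length(asc$spores, 4L)
    for (sp in asc$spores) {
      expect_length(sp$nuclei, 2L)
      expect_setequal(vapply(sp$nuclei, `[[`, "", "mat"), c("A", "a"))
    }
  }
})

test_that("replacement and anomaly conserve the eight nuclei", {
  set.seed(16)
  all_replaced <- cross_params(species = "tetrasperma", replacement_prob = 1)
  oct <- simulate_meiosis_octet(t_parent(), n_parent(), eb4, all_replaced)
  asc <- package_ascospores(oct, all_replaced)
  expect_length(asc$spores, 8L)
  expect_true(all(vapply(asc$spores, function(s) length(s$nuclei), 0L) == 1L))
  for (i in 1:20) {
    params <- cross_params(species = "tetrasperma",
                           replacement_prob = 0.5, anomaly_prob = 1)
    oct <- simulate_meiosis_octet(t_parent(), n_parent(), eb4, params)
    asc <- package_ascospores(oct, params)
    expect_equal(sum(vapply(asc$spores, function(s) length(s$nuclei), 0L)), 8L)
    expect_true(all(vapply(asc$spores, function(s) length(s$nuclei), 0L) >= 1L))
  }
})

test_that("ascus scoring reproduces the black:white diagnostics", {
  set.seed(17)
  ## IT x N adjacent-1: 4 Dp viable + 4 Df inviable
  adj <- package_ascospores(
    simulate_meiosis_octet(t_parent(), n_parent(), eb4, cross_params(p_alt = 0)),
    cross_params(p_alt = 0))
  expect_equal(score_ascus(adj)[c("n_black", "n_white")],
               list(n_black = 4L, n_white = 4L))
  expect_equal(score_ascus(adj)$tally_class, "4:4")
  ## RT x N: alternate all black, adjacent-1 all white
  rt_t <- nucleus("T", demo_rt, "A"); rt_n <- nucleus("N", demo_rt, "a")
  adj_rt <- package_ascospores(
    simulate_meiosis_octet(rt_t, rt_n, demo_rt, cross_params(p_alt = 0)),
    cross_params(p_alt = 0))
  expect_equal(score_ascus(adj_rt)$n_black, 0L)
  expect_equal(score_ascus(adj_rt)$tally_class, "0:8")
  alt_rt <- package_ascospores(
    simulate_meiosis_octet(rt_t, rt_n, demo_rt, cross_params(p_alt = 1)),
    cross_params(p_alt = 1))
  expect_equal(score_ascus(alt_rt)$n_black, 8L)
  ## tetrasperma spore-count classes
  tet <- cross_params(species = "tetrasperma")
  asc <- package_ascospores(
    simulate_meiosis_octet(t_parent(), n_parent(), eb4, tet), tet)
  expect_equal(score_ascus(asc)$tally_class, "4")
})

test_that("cross tallies are seed-reproducible and class-complete", {
  tal1 <- simulate_cross_tally(t_parent(), n_parent(), eb4, 300, seed = 21)
  tal2 <- simulate_cross_tally(t_parent(), n_parent(), eb4, 300, seed = 21)
  expect_identical(as.data.frame(tal1), as.data.frame(tal2))
  ## c = 0: only 8:0 and 4:4 occur
  expect_setequal(tal1$class, c("8:0", "4:4"))
  expect_equal(sum(tal1$n), 300L)
  ## isosequential: 100% 8:0
  nn <- simulate_cross_tally(nucleus("N", eb4, "A"), n_parent(), eb4, 50,
                             seed = 22)
  expect_identical(nn$class, "8:0")
  expect_equal(nn$pct, 100)
  ## interstitial crossover opens the 6:2 class
  co <- simulate_cross_tally(t_parent(), n_parent(), eb4, 400,
                             params = cross_params(c_donor = 0.3), seed = 23)
  expect_true("6:2" %in% co$class)
})

test_that("black fraction and alternate-rate recovery match closed forms", {
  ## E[black fraction] for IT x N, crassa, c = 0: p_alt * 1 + (1 - p_alt)/2
  tal <- simulate_cross_tally(t_parent(), n_parent(), eb4, 2000, seed = 31)
  black <- sum(vapply(seq_len(nrow(tal)), function(i) {
    bw <- as.integer(strsplit(tal$class[i], ":")[[1]])
    bw[1] * tal$n[i]
  }, 0)) / (8 * sum(tal$n))
  expect_lt(abs(black - 0.75), 0.02)  # ~3.5 Monte-Carlo SEs
  est <- estimate_alternate_rate(tal)
  expect_lt(abs(est$estimate - 0.5), 3 * est$se)
  ## a biased p_alt is recovered too
  tal7 <- simulate_cross_tally(t_parent(), n_parent(), eb4, 2000,
                               params = cross_params(p_alt = 0.7), seed = 32)
  est7 <- estimate_alternate_rate(tal7)
  expect_lt(abs(est7$estimate - 0.7), 3 * est7$se)
})
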