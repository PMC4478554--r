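test_that("balanced split probability matches the exact binomial", {
  expect_equal(balanced_split_probability(6, 0), 0.03125)
  expect_equal(balanced_split_probability(5, 5), 1)
  expect_equal(balanced_split_probability(0, 0), 1)
  ## cross-check against binom.test on non-degenerate splits
  for (ns in list(c(8, 2), c(10, 3), c(12, 0))) {
    bt <- stats::binom.test(ns[1], sum(ns), 0.5)$p.value
    expect_equal(balanced_split_probability(ns[1], ns[2]), min(1, bt),
                 tolerance = 1e-12)
  }
  ## symmetry and monotonicity in |n1 - n2| at fixed total
  for (n in c(6, 11, 20)) {
    ps <- vapply(0:n, function(k)
      balanced_split_probability(k, n - k), 0)
    expect_equal(ps, rev(ps))
    expect_true(all(diff(ps[seq_len(floor(n / 2) + 1)]) >= 0))
  }
})

test_that("single-class Dp derivatives with junction-forced Df give a clean call", {
  ## 25 self-steriles, all mat A, all B,C: the A junction in heterokaryon DNA
  ## must sit in an undetected (inviable-as-homokaryon) Df nucleus
  obs <- make_obs("1E1", c("A", "B", "C"),
                  list(list(n = 25, mat = "A", junctions = "B,C")))
  call <- infer_heterokaryon_genotype(obs, eb4)
  expect_identical(format(call), "[Df a + Dp A]")
  expect_length(call$flags, 0L)
})

test_that("both homokaryon classes give the [N + T] call directly", {
  obs <- make_obs("2E1", c("A", "B", "C"),
                  list(list(n = 5, mat = "a", junctions = "."),
                       list(n = 5, mat = "A", junctions = "A,B,C")))
  call <- infer_heterokaryon_genotype(obs, eb4)
  expect_identical(format(call), "[N a + T A]")
  expect_length(call$flags, 0L)
})

test_that("six single-class T derivatives give [T + Df] with the alternative flagged", {
  obs <- make_obs("3E1", c("A", "B", "C"),
                  list(list(n = 6, mat = "a", junctions = "A,B,C")))
  call <- infer_heterokaryon_genotype(obs, eb4)
  expect_identical(format(call), "[T a + Df A]")
  expect_true(any(grepl("\\[T a \\+ N A\\] not excluded", call$flags)))
  expect_equal(call$skew_p, 0.03125)
  ## at n >= n_min with a significant skew the flag disappears
  obs25 <- make_obs("x", c("A", "B", "C"),
                    list(list(n = 25, mat = "a", junctions = "A,B,C")))
  expect_length(infer_heterokaryon_genotype(obs25, eb4)$flags, 0L)
})

test_that("A-only derivatives reveal a third (Df) nucleus: the triple heterokaryon", {
  obs <- make_obs("3I1", c("A", "B"),
                  list(list(n = 2, mat = "a", junctions = "A,B"),
                       list(n = 5, mat = "A", junctions = "."),
                       list(n = 2, mat = "A", junctions = "A")))
  call <- infer_heterokaryon_genotype(obs, ibj5)
  expect_identical(format(call), "[T a + N A + Df A]")
  expect_equal(nrow(call$nuclei), 3L)
})

test_that("a single informative derivative leaves the partner undetermined", {
  obs <- make_obs("1I4", c("A", "B"),
                  list(list(n = 1, mat = "A", junctions = "A,B")))
  call <- infer_heterokaryon_genotype(obs, ibj5)
  expect_identical(format(call), "[? a + T A]")
  expect_true(any(grepl("undetermined", call$flags)))
})

test_that("no self-sterile derivatives means no call", {
  obs <- make_obs("13E1", c("A", "B", "C"),
                  list(list(n = 16, mat = "het", junctions = NA_character_,
                            self_fertile = TRUE)))
  call <- infer_heterokaryon_genotype(obs, eb4)
  expect_identical(format(call), "ND")
})

test_that("mat-only evidence is flagged as such", {
  obs <- make_obs("m1", c("A", "B", "C"),
                  list(list(n = 6, mat = "a", junctions = NA_character_),
                       list(n = 6, mat = "A", junctions = NA_character_)))
  call <- infer_heterokaryon_genotype(obs, eb4)
  expect_true(any(grepl("mat-only", call$flags)))
  expect_setequal(call$nuclei$type, c("T", "N"))
  ## single mat class: [Dp + Df] indicated, flagged when weak
  obs1 <- make_obs("m2", c("A", "B", "C"),
                   list(list(n = 6, mat = "a", junctions = NA_character_)))
  call1 <- infer_heterokaryon_genotype(obs1, eb4)
  expect_identical(format(call1), "[Dp a + Df A]")
  expect_true(any(grepl("not excluded", call1$flags)))
})

test_that("derivative junctions outside the heterokaryon pattern are a data error", {
  expect_error(
    make_obs("bad", c("B", "C"),
             list(list(n = 1, mat = "A", junctions = "A,B,C"))),
    "data error")
})

test_that("an A-only pattern is never called a viable Df homokaryon", {
  obs <- make_obs("x", c("A", "B"),
                  list(list(n = 4, mat = "a", junctions = "A,B"),
                       list(n = 3, mat = "A", junctions = "A")))
  call <- infer_heterokaryon_genotype(obs, ibj5)
  ## the A-only derivatives are interpreted as [N + Df] heterokaryons,
  ## contributing both an N and a Df nucleus
  expect_true(all(c("N", "Df") %in% call$nuclei$type))
})

test_that("simulated heterokaryons round-trip through the classifier", {
  set.seed(51)
  truth <- list(TN = c("T a", "N A"), DpDf = c("Dp a", "Df A"),
                DpN = c("Dp a", "N A"), TDf = c("T a", "Df A"),
                NDf = c("N a", "Df A"), TNDf = c("T a", "N A", "Df A"))
  for (nm in names(truth)) {
    parts <- strsplit(truth[[nm]], " ")
    het <- heterokaryon(lapply(parts, function(p) nucleus(p[1], eb4, p[2])))
    der <- sample_conidial_derivatives(het, 20, eb4)
    obs <- observation_record(nm, junctions_present(het$nuclei, eb4),
                              der[, c("self_fertile", "mat", "junctions")])
    call <- infer_heterokaryon_genotype(obs, eb4, n_min = 10)
    ## the union of called junctions always equals the heterokaryon pattern
    expect_identical(
      sort(unique(unlist(lapply(call$nuclei$type, function(tp)
        switch(tp, T = c("A", "B", "C"), Dp = c("B", "C"), Df = "A",
               character(0)))))),
      obs$het_junctions, label = nm)
    if (nm == "TNDf" &&
        !any(!der$self_fertile & der$junctions == "A")) {
      ## the Df nucleus is only detectable through [N + Df] derivatives;
      ## without one the evidence supports [T + N]
      expect_identical(call_key(call), "N A / T a")
    } else {
      expect_identical(call_key(call),
                       paste(sort(truth[[nm]]), collapse = " / "),
                       label = nm)
    }
    if (nm %in% c("TN", "DpDf", "DpN", "NDf"))
      expect_length(call$flags, 0L)
  }
})

test_that("strain-table aggregation reproduces the published totals", {
  tab <- read_strain_table()
  expect_equal(nrow(tab), 47L)
  ## the seven [Dp(B362i) + Df(B362i)] heterokaryons: 117 derivatives,
  ## every one self-sterile
  agg <- summarize_strain_table(tab, rows = c(35:37, 39:41, 43))
  expect_equal(agg$total_derivatives, 117L)
  expect_equal(agg$total_self_sterile, 117L)
  expect_true(all(agg$all_self_sterile))
  expect_equal(agg$fraction_self_fertile, 0)
  ## single-row totals equal the row
  one <- summarize_strain_table(tab, rows = 5)
  expect_equal(unlist(one[c("total_derivatives", "total_self_sterile",
                            "total_mat_a", "total_mat_A")], use.names = FALSE),
               c(129, 30, 10, 20))
  ## predicate filter and empty filter
  b7 <- summarize_strain_table(tab, rows = function(r) r$rearrangement == "B362i")
  expect_equal(b7$n_strains, 13L)
  empty <- summarize_strain_table(tab, rows = integer(0))
  expect_equal(empty$total_derivatives, 0L)
  expect_true(is.na(empty$fraction_self_fertile))
})
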