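test_that("segmental genotype is total and matches segregation products", {
  cases <- list(  # donor T?, recipient T?, expected label
    list(TRUE,  TRUE,  "T"),
    list(FALSE, FALSE, "N"),
    list(FALSE, TRUE,  "Dp"),
    list(TRUE,  FALSE, "Df"))
  for (r in list(eb4, uk14)) {
    for (cs in cases) {
      d <- chromosome_variant(r, "donor", cs[[1]])
      rc <- chromosome_variant(r, "recipient", cs[[2]])
      expect_identical(segmental_genotype(d, rc, r), cs[[3]])
    }
  }
  ## RT: unbalanced products are per-segment composites
  d <- chromosome_variant(demo_rt, "donor", FALSE)
  rc <- chromosome_variant(demo_rt, "recipient", TRUE)
  expect_identical(segmental_genotype(d, rc, demo_rt), "Dp1/Df2")
  d <- chromosome_variant(demo_rt, "donor", TRUE)
  rc <- chromosome_variant(demo_rt, "recipient", FALSE)
  expect_identical(segmental_genotype(d, rc, demo_rt), "Dp2/Df1")
})

test_that("genotype -> variants -> genotype round trip is the identity", {
  for (g in c("T", "N", "Dp", "Df"))
    expect_identical(nucleus_genotype(nucleus(g, eb4, "A"), eb4), g)
  for (g in c("T", "N", "Dp1/Df2", "Dp2/Df1"))
    expect_identical(nucleus_genotype(nucleus(g, demo_rt, "a"), demo_rt), g)
})

test_that("segment copy number tracks the genotype label", {
  expect_identical(unname(segment_copy_number(nucleus("Dp", eb4, "A"), eb4)), 2L)
  expect_identical(unname(segment_copy_number(nucleus("Df", eb4, "A"), eb4)), 0L)
  expect_identical(unname(segment_copy_number(nucleus("T", eb4, "A"), eb4)), 1L)
  expect_identical(
    unname(segment_copy_number(nucleus("Dp1/Df2", demo_rt, "A"), demo_rt)),
    c(2L, 0L))
})

test_that("variants from different rearrangements are rejected", {
  d <- chromosome_variant(eb4, "donor", TRUE)
  rc <- chromosome_variant(ibj5, "recipient", TRUE)
  expect_error(segmental_genotype(d, rc, eb4), "different rearrangements")
})

test_that("junction content follows the genotype", {
  expect_identical(junctions_present(nucleus("T", eb4, "A"), eb4),
                   c("A", "B", "C"))
  expect_identical(junctions_present(nucleus("Dp", eb4, "A"), eb4),
                   c("B", "C"))
  expect_identical(junctions_present(nucleus("Df", eb4, "A"), eb4), "A")
  expect_identical(junctions_present(nucleus("N", eb4, "A"), eb4),
                   character(0))
  ## QT and RT carry two junction classes in total
  expect_identical(junctions_present(nucleus("T", uk14, "A"), uk14),
                   c("A", "B"))
  expect_identical(junctions_present(nucleus("T", demo_rt, "A"), demo_rt),
                   c("A", "B"))
})

test_that("[T + N] and [Dp + Df] junction patterns are indistinguishable", {
  for (r in list(eb4, ibj5, uk14)) {
    tn <- junctions_present(list(nucleus("T", r, "a"), nucleus("N", r, "A")), r)
    dpdf <- junctions_present(list(nucleus("Dp", r, "a"), nucleus("Df", r, "A")), r)
    expect_identical(tn, dpdf)
    expect_identical(tn, r$junction_classes)
  }
})

test_that("viability: union rule complements within a spore, autonomous does not", {
  df <- nucleus("Df", eb4, "A")
  dp <- nucleus("Dp", eb4, "a")
  n <- nucleus("N", eb4, "A")
  expect_false(spore_viability(df, eb4))
  expect_true(spore_viability(n, eb4))
  expect_true(spore_viability(list(dp, df), eb4))
  expect_false(spore_viability(list(dp, df), eb4, rule = "autonomous"))
  ## RT complementary unbalanced pair: union says yes, autonomous no
  p1 <- nucleus("Dp1/Df2", demo_rt, "a")
  p2 <- nucleus("Dp2/Df1", demo_rt, "A")
  expect_true(spore_viability(list(p1, p2), demo_rt))
  expect_false(spore_viability(list(p1, p2), demo_rt, rule = "autonomous"))
  expect_error(spore_viability(list(), eb4), "at least one nucleus")
})

test_that("union-rule viability is monotone in added nuclei", {
  gts <- c("T", "N", "Dp", "Df")
  for (g1 in gts) for (g2 in gts) {
    base <- list(nucleus(g1, eb4, "a"))
    if (spore_viability(base, eb4))
      expect_true(spore_viability(c(base, list(nucleus(g2, eb4, "A"))), eb4),
                  label = paste("adding", g2, "to viable", g1))
  }
})

test_that("rearrangement constructor enforces kind-specific invariants", {
  expect_identical(rearrangement("x", "IT")$junction_classes, c("A", "B", "C"))
  expect_identical(rearrangement("x", "QT")$junction_classes, c("A", "B"))
  expect_identical(rearrangement("x", "RT")$junction_classes, c("A", "B"))
  expect_length(rearrangement("x", "RT")$segments, 2L)
  expect_error(rearrangement("x", "IT", segments = c("s1", "s2")),
               "exactly 1")
  expect_error(rearrangement("x", "RT", segments = "s1"), "exactly 2")
  expect_error(rearrangement("x", "IT", c_donor = 1.2), "probability")
  expect_error(rearrangement("x", "QT", assay_junctions = "C"),
               "junction classes")
})

test_that("presets carry the published metadata", {
  sizes <- vapply(c("EB4", "IBj5", "UK14-1", "B362i"),
                  function(n) rearrangement_preset(n)$size_bp, 0)
  expect_identical(unname(sizes), c(145282, 405319, 490958, 118782))
  genes <- vapply(c("EB4", "IBj5", "UK14-1", "B362i"),
                  function(n) rearrangement_preset(n)$n_genes, 0L)
  expect_identical(unname(genes), c(39L, 120L, 126L, 36L))
  expect_identical(rearrangement_preset("UK14-1")$kind, "QT")
  ## PCR panels reflect which junctions have assays
  expect_identical(rearrangement_preset("IBj5")$assay_junctions, c("A", "B"))
  expect_identical(rearrangement_preset("UK14-1")$assay_junctions, "A")
  expect_identical(rearrangement_preset("EB4")$assay_junctions,
                   c("A", "B", "C"))
})
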