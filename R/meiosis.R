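#' Cross simulation parameters
#'
#' Bundles the tunable parameters of one simulated cross.  `p_alt` is the
#' probability of alternate (as opposed to adjacent-1) meiosis I segregation
#' of a translocation quadrivalent; the two patterns are equally likely in a
#' typical translocation-heterozygous cross, hence the default 0.5.  Setting
#' `p_alt` to 1 or 0 forces a pattern.  `c_donor`/`c_recipient`, if non-NULL,
#' override the rearrangement's own interstitial crossover probabilities.
#' `replacement_prob` is the per-spore probability that a dikaryotic
#' N. tetrasperma ascospore is replaced by a pair of smaller homokaryotic
#' ones (the route to 5-8-spored asci; elevated in Eight-spore (E) mutant
#' crosses — see [e_mutant_replacement_prob]).  `anomaly_prob` is the
#' per-ascus probability of a packaging anomaly in which one spore receives a
#' third nucleus from an adjacent spore (the route to triple heterokaryons).
#'
#' @param p_alt Probability of alternate segregation, in `[0, 1]`.
#' @param c_donor,c_recipient Optional overrides for the interstitial
#'   crossover probabilities.
#' @param species `"crassa"` (8 uninucleate spores) or `"tetrasperma"`
#'   (4 binucleate spores holding nonsister nuclei).
#' @param replacement_prob Per-spore dikaryotic-to-homokaryotic-pair
#'   replacement probability.
#' @param anomaly_prob Per-ascus 3-nucleus packaging anomaly probability.
#' @param msud_strength Scalar in `[0, 1]` carried along for fertility rules
#'   (see [msud_fertility()]).
#' @param pairing `"ordered"` pairs the j-th nucleus of the pole-1 lineage
#'   with the j-th of pole 2; `"random"` permutes the pole-2 lineage first.
#'   Both guarantee nonsister pairs with one *mat A* and one *mat a* nucleus.
#' @param viability_rule Passed to [spore_viability()].
#' @param fitness_fn Optional `function(nucleus_state) -> numeric` assigning
#'   division fitness to progeny nuclei (e.g. fitness 0 for `Df` nuclei of a
#'   rearrangement deleting a nucleus-limited gene).
#' @return An object of class `"cross_params"`.
#' @export
cross_params <- function(p_alt = 0.5, c_donor = NULL, c_recipient = NULL,
                         species = c("crassa", "tetrasperma"),
                         replacement_prob = 0, anomaly_prob = 0,
                         msud_strength = 0,
                         pairing = c("ordered", "random"),
                         viability_rule = c("union", "autonomous"),
                         fitness_fn = NULL) {
  species <- match.arg(species)
  pairing <- match.arg(pairing)
  viability_rule <- match.arg(viability_rule)
  check_prob(p_alt, "p_alt")
  check_prob(replacement_prob, "replacement_prob")
  check_prob(anomaly_prob, "anomaly_prob")
  check_prob(msud_strength, "msud_strength")
  if (!is.null(c_donor)) check_prob(c_donor, "c_donor")
  if (!is.null(c_recipient)) check_prob(c_recipient, "c_recipient")
  if (!is.null(fitness_fn)) stopifnot(is.function(fitness_fn))
  structure(list(p_alt = p_alt, c_donor = c_donor, c_recipient = c_recipient,
                 species = species, replacement_prob = replacement_prob,
                 anomaly_prob = anomaly_prob, msud_strength = msud_strength,
                 pairing = pairing, viability_rule = viability_rule,
                 fitness_fn = fitness_fn),
            class = "cross_params")
}

#' Replacement probability preset for the Eight-spore (E) mutant
#'
#' The E mutant elevates the frequency with which dikaryotic ascospores are
#' replaced by homokaryotic pairs, with incomplete penetrance.  No
#' quantitative rate has been published; this default of 0.15 is an arbitrary
#' working value, exposed so it can be changed in one place.
#' @export
e_mutant_replacement_prob <- 0.15

## Meiose one rearrangement's quadrivalent at chromatid resolution.
## Returns products[[pole]][[q]] = list(donor = variant, recipient = variant)
## for poles 1:2 and MII products q = 1:2.
meiose_one_rearrangement <- function(r, parent1, parent2, params) {
  v1 <- parent1$variants[[r$id]]
  v2 <- parent2$variants[[r$id]]
  if (is.null(v1) || is.null(v2))
    stop("both parents must carry variant state for rearrangement '",
         r$id, "'")
  c_d <- params$c_donor %||% r$c_donor
  c_r <- params$c_recipient %||% r$c_recipient

  ## two sister chromatids per homolog; content = the variant whose
  ## breakpoint-distal portion the chromatid carries
  donor_tids <- list(list(v1$donor, v1$donor), list(v2$donor, v2$donor))
  recip_tids <- list(list(v1$recipient, v1$recipient),
                     list(v2$recipient, v2$recipient))

  ## at most one interstitial crossover per region: swap the distal portion
  ## between one chromatid of each homolog (a no-op if the homologs are
  ## isosequential)
  if (stats::runif(1) < c_d) {
    i <- sample(2L, 1L); j <- sample(2L, 1L)
    tmp <- donor_tids[[1]][[i]]
    donor_tids[[1]][[i]] <- donor_tids[[2]][[j]]
    donor_tids[[2]][[j]] <- tmp
  }
  if (stats::runif(1) < c_r) {
    i <- sample(2L, 1L); j <- sample(2L, 1L)
    tmp <- recip_tids[[1]][[i]]
    recip_tids[[1]][[i]] <- recip_tids[[2]][[j]]
    recip_tids[[2]][[j]] <- tmp
  }

  ## meiosis I: homologous centromeres separate; in a translocation
  ## heterozygote the quadrivalent disjoins alternate (translocated donor and
  ## recipient centromeres to the same pole) or adjacent-1 (translocated
  ## donor with normal recipient) with probability p_alt / 1 - p_alt
  het_d <- xor(v1$donor$translocated, v2$donor$translocated)
  het_r <- xor(v1$recipient$translocated, v2$recipient$translocated)
  first <- sample(2L, 1L)                 # pole receiving parent1's donor cen
  pole_d <- c(first, 3L - first)          # pole of donor centromere k (k=1 parent1)
  if (het_d && het_r) {
    alt <- stats::runif(1) < params$p_alt
    td <- if (v1$donor$translocated) 1L else 2L
    tr <- if (v1$recipient$translocated) 1L else 2L
    pole_tr <- if (alt) pole_d[td] else 3L - pole_d[td]
    pole_r <- integer(2L)
    pole_r[tr] <- pole_tr
    pole_r[3L - tr] <- 3L - pole_tr
  } else {
    first <- sample(2L, 1L)
    pole_r <- c(first, 3L - first)
  }

  ## meiosis II: sister chromatids of each centromere separate into the two
  ## MII products at that pole; the assortment is random, which is what lets
  ## a crossover chromatid show second-division segregation
  products <- lapply(1:2, function(p) lapply(1:2, function(q) list()))
  for (k in 1:2) {
    p <- pole_d[k]; ord <- sample(2L)
    for (q in 1:2) products[[p]][[q]]$donor <- donor_tids[[k]][[ord[q]]]
  }
  for (k in 1:2) {
    p <- pole_r[k]; ord <- sample(2L)
    for (q in 1:2) products[[p]][[q]]$recipient <- recip_tids[[k]][[ord[q]]]
  }
  products
}

#' Simulate one meiosis into an ordered octet
#'
#' Karyogamy of the two parental nuclei followed by a chromatid-level
#' meiosis: optional interstitial crossovers (at most one per region),
#' meiosis I disjunction of each translocation quadrivalent (alternate with
#' probability `p_alt`), meiosis II separation of sisters, and a postmeiotic
#' mitosis that duplicates each product into adjacent sister positions.
#' Positions 1-4 of the octet descend from pole 1 and 5-8 from pole 2; the
#' mating-type locus always segregates at the first division (no
#' recombination with its centromere), so each pole lineage is uniformly one
#' mating type and every octet holds four *mat A* and four *mat a* nuclei.
#'
#' Without crossovers, alternate segregation of a `T x N` cross gives an
#' octet of 4 `T` + 4 `N` nuclei and adjacent-1 gives 4 `Dp` + 4 `Df`; a
#' single interstitial crossover yields 2 each of `T`, `N`, `Dp`, `Df`
#' under either pattern.
#'
#' @param parent1,parent2 `"nucleus_state"` parents of opposite mating type.
#' @param rearrangements A [rearrangement()] or list of them; each segregates
#'   independently.
#' @param params A [cross_params()] object.
#' @return An object of class `"octet"`: `$nuclei` (ordered list of 8),
#'   `$pole_of` (meiosis I pole per position), `$sister_pairs`, and the
#'   rearrangement list.
#' @examples
#' eb4 <- rearrangement_preset("EB4")
#' oct <- simulate_meiosis_octet(nucleus("T", eb4, "A"),
#'                               nucleus("N", eb4, "a"),
#'                               eb4, cross_params(p_alt = 1))
#' table(octet_genotypes(oct, eb4))
#' @export
simulate_meiosis_octet <- function(parent1, parent2, rearrangements,
                                   params = cross_params()) {
  stopifnot(inherits(parent1, "nucleus_state"),
            inherits(parent2, "nucleus_state"))
  if (parent1$mat == parent2$mat)
    stop("cross refused: both parents are mat ", parent1$mat)
  rl <- as_rearrangement_list(rearrangements)
  per_r <- lapply(rl, meiose_one_rearrangement,
                  parent1 = parent1, parent2 = parent2, params = params)

  ## mat: first-division segregation, random pole orientation
  p1_pole <- sample(2L, 1L)
  parent_of_pole <- list(NULL, NULL)
  parent_of_pole[[p1_pole]] <- parent1
  parent_of_pole[[3L - p1_pole]] <- parent2

  nuclei <- vector("list", 8L)
  pos <- 0L
  for (pole in 1:2) for (q in 1:2) for (s in 1:2) {
    pos <- pos + 1L
    variants <- lapply(per_r, function(pr) pr[[pole]][[q]])
    nu <- nucleus_state(mat = parent_of_pole[[pole]]$mat,
                        variants = variants,
                        markers = parent_of_pole[[pole]]$markers,
                        division_fitness = 1)
    if (!is.null(params$fitness_fn))
      nu$division_fitness <- params$fitness_fn(nu)
    nuclei[[pos]] <- nu
  }
  structure(list(nuclei = nuclei, pole_of = rep(1:2, each = 4L),
                 sister_pairs = list(c(1L, 2L), c(3L, 4L),
                                     c(5L, 6L), c(7L, 8L)),
                 rearrangements = rl),
            class = "octet")
}

#' Genotype labels of the eight octet nuclei
#'
#' @param octet An `"octet"`.
#' @param rearrangement A single [rearrangement()].
#' @return Character vector of 8 genotype labels in octet order.
#' @export
octet_genotypes <- function(octet, rearrangement) {
  vapply(octet$nuclei, nucleus_genotype, "", rearrangement = rearrangement)
}

#' Package an octet into ascospores
#'
#' In `crassa` mode the eight nuclei are partitioned into eight uninucleate
#' spores in octet order.  In `tetrasperma` mode four binucleate spores are
#' formed, the j-th pairing the j-th nucleus of the pole-1 lineage with the
#' j-th of the pole-2 lineage — nonsister nuclei, and necessarily one
#' *mat A* + one *mat a* given first-division segregation of mat.  Each
#' dikaryotic spore is then independently replaced, with probability
#' `replacement_prob`, by two smaller homokaryotic (uninucleate) spores; with
#' probability `anomaly_prob` one binucleate spore receives a third nucleus
#' donated by an adjacent spore.  Nuclei are conserved: every ascus contains
#' exactly eight.
#'
#' @inheritParams octet_genotypes
#' @param params A [cross_params()].
#' @return An object of class `"ascus"`: `$spores` is a list of
#'   `list(nuclei = , viable = )`, plus `$species`.
#' @export
package_ascospores <- function(octet, params = cross_params()) {
  stopifnot(inherits(octet, "octet"))
  rl <- octet$rearrangements
  if (params$species == "crassa") {
    spores <- lapply(octet$nuclei, list)
  } else {
    pole2 <- 5:8
    if (params$pairing == "random") pole2 <- sample(pole2)
    spores <- lapply(1:4, function(j)
      list(octet$nuclei[[j]], octet$nuclei[[pole2[j]]]))
    ## Eight-spore style replacement of dikaryotic spores
    out <- list()
    for (sp in spores) {
      if (length(sp) == 2L && stats::runif(1) < params$replacement_prob)
        out <- c(out, list(sp[1]), list(sp[2]))
      else out <- c(out, list(sp))
    }
    spores <- out
    ## rare packaging anomaly: a spore acquires a third nucleus from a
    ## neighbor (conserving the total of eight nuclei)
    if (stats::runif(1) < params$anomaly_prob) {
      len <- vapply(spores, length, 0L)
      can_recv <- which(len == 2L)
      ok <- Filter(function(i) {
        nb <- c(i - 1L, i + 1L)
        nb <- nb[nb >= 1L & nb <= length(spores)]
        any(vapply(spores[nb], length, 0L) >= 2L)
      }, can_recv)
      if (length(ok)) {
        recv <- sample_one(ok)
        nb <- c(recv - 1L, recv + 1L)
        nb <- nb[nb >= 1L & nb <= length(spores)]
        nb <- nb[vapply(spores[nb], length, 0L) >= 2L]
        donor <- sample_one(nb)
        k <- sample_one(seq_along(spores[[donor]]))
        spores[[recv]] <- c(spores[[recv]], spores[[donor]][k])
        spores[[donor]] <- spores[[donor]][-k]
      }
    }
  }
  spores <- lapply(spores, function(nuc)
    list(nuclei = nuc,
         viable = spore_viability(nuc, rl, rule = params$viability_rule)))
  structure(list(spores = spores, species = params$species), class = "ascus")
}

#' Score an ascus
#'
#' Counts viable (black, B) and inviable (white, W) spores and derives the
#' tally class: for eight-spored asci the black:white label (`"8:0"`,
#' `"6:2"`, `"4:4"`, `"2:6"`, `"0:8"`); for N. tetrasperma asci with fewer
#' spores, the spore-count class (`"4"` ... `"7"`).
#'
#' @param ascus An `"ascus"` from [package_ascospores()].
#' @return A list with `n_black`, `n_white`, `n_spores`, `tally_class`.
#' @export
score_ascus <- function(ascus) {
  stopifnot(inherits(ascus, "ascus"))
  v <- vapply(ascus$spores, `[[`, TRUE, "viable")
  n_black <- sum(v)
  n_white <- sum(!v)
  ns <- length(v)
  cls <- if (ascus$species == "tetrasperma" && ns < 8L) as.character(ns)
         else paste0(n_black, ":", n_white)
  list(n_black = n_black, n_white = n_white, n_spores = ns,
       tally_class = cls)
}

canonical_class_order <- function(classes) {
  counts <- c("4", "5", "6", "7")
  bw <- c("8:0", "7:1", "6:2", "5:3", "4:4", "3:5", "2:6", "1:7", "0:8")
  known <- c(counts, bw)
  c(intersect(known, classes), sort(setdiff(classes, known)))
}

#' Simulate a cross and tally ascus classes
#'
#' Repeats meiosis + packaging + scoring `n_asci` times and tabulates the
#' tally classes, in the shape of the published ascus-type tables (counts and
#' percentages per class).
#'
#' @inheritParams simulate_meiosis_octet
#' @param n_asci Number of asci to simulate (>= 1).
#' @param seed Optional integer seed, recorded in the result.
#' @return A `data.frame` of class `"ascus_tally"` with columns `class`,
#'   `n`, `pct`, and attributes `n_asci`, `seed`, `species`.
#' @examples
#' eb4 <- rearrangement_preset("EB4")
#' simulate_cross_tally(nucleus("T", eb4, "A"), nucleus("N", eb4, "a"),
#'                      eb4, n_asci = 200, seed = 1)
#' @export
simulate_cross_tally <- function(parent1, parent2, rearrangements, n_asci,
                                 params = cross_params(), seed = NULL) {
  stopifnot(n_asci >= 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- character(n_asci)
  for (i in seq_len(n_asci)) {
    oct <- simulate_meiosis_octet(parent1, parent2, rearrangements, params)
    classes[i] <- score_ascus(package_ascospores(oct, params))$tally_class
  }
  tab <- table(classes)
  ord <- canonical_class_order(names(tab))
  out <- data.frame(class = ord, n = as.integer(tab[ord]),
                    stringsAsFactors = FALSE)
  out$pct <- 100 * out$n / n_asci
  attr(out, "n_asci") <- n_asci
  attr(out, "seed") <- seed
  attr(out, "species") <- params$species
  class(out) <- c("ascus_tally", "data.frame")
  out
}

#' @export
print.ascus_tally <- function(x, ...) {
  cat(sprintf("Ascus tally: %d asci (%s)%s\n", attr(x, "n_asci"),
              attr(x, "species"),
              if (is.null(attr(x, "seed"))) ""
              else sprintf(", seed %s", attr(x, "seed"))))
  print.data.frame(cbind(x["class"], x["n"],
                         pct = sprintf("%.1f", x$pct)), row.names = FALSE)
  invisible(x)
}

#' Estimate the alternate-segregation rate from a tally
#'
#' For an eight-spored `IT x N` or `QT x N` cross without crossovers, 8:0
#' asci arise from alternate and 4:4 from adjacent-1 segregation, so
#' `f(8:0) / (f(8:0) + f(4:4))` estimates `p_alt`.
#'
#' @param tally An `"ascus_tally"`.
#' @return List with `estimate`, `n_informative`, and the binomial `se`.
#' @export
estimate_alternate_rate <- function(tally) {
  get_n <- function(cl) {
    i <- match(cl, tally$class)
    if (is.na(i)) 0L else tally$n[i]
  }
  n80 <- get_n("8:0")
  n44 <- get_n("4:4")
  n <- n80 + n44
  if (n == 0) stop("tally contains no informative (8:0 or 4:4) asci")
  p <- n80 / n
  list(estimate = p, n_informative = n, se = sqrt(p * (1 - p) / n))
}
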