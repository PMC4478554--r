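#' Construct a heterokaryon
#'
#' A mycelium with 1-3 genetically distinct nuclear components sharing a
#' cytoplasm, each present at some proportion.  A heterokaryon is self-fertile
#' iff both mating types occur among its division-competent components
#' (those with `division_fitness > 0`).
#'
#' @param nuclei A `"nucleus_state"` or list of 1-3 of them.
#' @param proportions Numeric vector of component proportions summing to 1;
#'   defaults to equal.
#' @return An object of class `"heterokaryon"`.
#' @examples
#' eb4 <- rearrangement_preset("EB4")
#' het <- heterokaryon(list(nucleus("Dp", eb4, "a"), nucleus("Df", eb4, "A")))
#' is_self_fertile(het)
#' @export
heterokaryon <- function(nuclei, proportions = NULL) {
  nuclei <- as_nucleus_list(nuclei)
  k <- length(nuclei)
  if (k < 1L || k > 3L) stop("a heterokaryon has 1-3 nuclear components")
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  if (length(proportions) != k || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-8)
    stop("'proportions' must be ", k, " non-negative values summing to 1")
  structure(list(nuclei = nuclei, proportions = as.numeric(proportions)),
            class = "heterokaryon")
}

#' @rdname heterokaryon
#' @param het A `"heterokaryon"`.
#' @export
is_self_fertile <- function(het) {
  stopifnot(inherits(het, "heterokaryon"))
  fit <- vapply(het$nuclei, `[[`, 0, "division_fitness")
  mats <- vapply(het$nuclei, `[[`, "", "mat")[fit > 0]
  all(c("A", "a") %in% mats)
}

#' Deterministic nuclear-ratio trajectory
#'
#' Iterates the discrete replicator map \eqn{p_i' = p_i f_i / \sum_j p_j f_j}
#' for `generations` nuclear division cycles: each component's share grows in
#' proportion to its division fitness.  With equal fitness the ratio is a
#' fixed point; a component with fitness 0 vanishes after one generation
#' (the model for deletion of a nucleus-limited division gene, under which
#' the deficiency nuclei "rapidly dwindle" from the mycelium).
#'
#' @param proportions Initial component proportions (non-negative, sum 1).
#' @param fitness Non-negative per-component division fitness.
#' @param generations Number of iterations (>= 0).
#' @return A `(generations + 1) x k` matrix of proportions, row 1 the input.
#' @examples
#' evolve_nuclear_ratio(c(0.5, 0.5), c(1, 0.5), 1)  # -> 2/3, 1/3
#' @export
evolve_nuclear_ratio <- function(proportions, fitness, generations) {
  stopifnot(length(fitness) == length(proportions),
            all(fitness >= 0), all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-8, generations >= 0)
  if (all(fitness == 0))
    stop("all components have zero division fitness")
  traj <- matrix(NA_real_, nrow = generations + 1L,
                 ncol = length(proportions))
  traj[1L, ] <- proportions
  p <- proportions
  for (g in seq_len(generations)) {
    w <- p * fitness
    if (sum(w) == 0)
      stop("no surviving component after generation ", g - 1L)
    p <- w / sum(w)
    traj[g + 1L, ] <- p
  }
  traj
}

## zero-truncated Poisson draw (k >= 1)
rtruncpois1 <- function(lambda) {
  repeat {
    k <- stats::rpois(1L, lambda)
    if (k >= 1L) return(k)
  }
}

#' Sample conidial derivatives from a heterokaryon
#'
#' Each conidium (vegetative spore) draws `k` nuclei (by default `k` is
#' zero-truncated Poisson with rate `mean_nuclei`) multinomially from the
#' component proportions weighted by division fitness.  A derivative is
#' germination-viable iff it contains at least one division-competent
#' nucleus; by default inviable draws are rejected and redrawn, mirroring the
#' experimental situation in which only germlings are scored.  A derivative
#' is self-fertile iff both mating types occur among its competent nuclei;
#' its junction pattern is the union of breakpoint junctions over competent
#' nuclei.
#'
#' @param het A [heterokaryon()].
#' @param n Number of viable derivatives to return.
#' @param rearrangements A [rearrangement()] or list of them.
#' @param mean_nuclei Rate of the zero-truncated Poisson for nuclei per
#'   conidium.  The true distribution is unmeasured; this is the main free
#'   parameter controlling the homokaryotic-conidium frequency.
#' @param fixed_k Optional fixed nucleus count per conidium (overrides
#'   `mean_nuclei`).
#' @param keep_inviable If `TRUE`, return exactly `n` draws including
#'   germination-inviable ones (flagged) instead of resampling.
#' @return A `data.frame` with one row per derivative: `derivative_id`, `k`
#'   (nuclei drawn), `viable`, `self_fertile`, `mat` (`"A"`, `"a"`, or
#'   `"het"`), `junctions` (comma list, `"."` = none), `homokaryotic`, and
#'   `components` (comma list of component indices drawn).
#' @examples
#' eb4 <- rearrangement_preset("EB4")
#' het <- heterokaryon(list(nucleus("T", eb4, "a"), nucleus("N", eb4, "A")))
#' set.seed(1)
#' head(sample_conidial_derivatives(het, 5, eb4))
#' @export
sample_conidial_derivatives <- function(het, n, rearrangements,
                                        mean_nuclei = 2.5, fixed_k = NULL,
                                        keep_inviable = FALSE) {
  stopifnot(inherits(het, "heterokaryon"), n >= 1)
  rl <- as_rearrangement_list(rearrangements)
  fit <- vapply(het$nuclei, `[[`, 0, "division_fitness")
  w <- het$proportions * pmax(fit, 0)
  if (sum(w) <= 0)
    stop("no packageable nuclei: every component has zero weight")
  w <- w / sum(w)
  mats <- vapply(het$nuclei, `[[`, "", "mat")

  draw_one <- function(id) {
    k <- if (!is.null(fixed_k)) fixed_k else rtruncpois1(mean_nuclei)
    idx <- sample.int(length(w), k, replace = TRUE, prob = w)
    competent <- idx[fit[idx] > 0]
    ## a germling needs a division-competent nucleus AND a full segment
    ## complement among its competent nuclei: a bare Df conidium carries an
    ## uncomplemented deficiency and never grows into a derivative
    viable <- length(competent) > 0L &&
      spore_viability(het$nuclei[unique(competent)], rl)
    cmats <- unique(mats[competent])
    junc <- if (viable)
      sort(unique(unlist(lapply(rl, function(r)
        junctions_present(het$nuclei[unique(competent)], r)))))
    else character(0)
    data.frame(
      derivative_id = id, k = k, viable = viable,
      self_fertile = viable && all(c("A", "a") %in% cmats),
      mat = if (!viable) NA_character_
            else if (length(cmats) == 2L) "het" else cmats,
      junctions = format_junctions(junc),
      homokaryotic = length(unique(idx)) == 1L,
      components = paste(sort(unique(idx)), collapse = ","),
      stringsAsFactors = FALSE)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    row <- draw_one(i)
    tries <- 1L
    while (!keep_inviable && !row$viable) {
      if ((tries <- tries + 1L) > 10000L)
        stop("no viable conidial derivative obtainable from this heterokaryon")
      row <- draw_one(i)
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Form the zygote of a heterokaryon self-cross
#'
#' Picks one *mat A* and one *mat a* division-competent component (weighted
#' by proportion times fitness when several qualify) for karyogamy, and flags
#' each chosen nucleus as RIP-exposed iff it carries any rearrangement
#' segment at copy number 2.  Repeat-induced point mutation acts on
#' duplicated DNA in the premeiotic dikaryon, so only `Dp`-bearing nuclei are
#' exposed: self-crosses of `[Dp + Df]` heterokaryons can RIP the
#' translocated segment whereas self-crosses of `[T + N]` heterokaryons
#' cannot.
#'
#' @param het A self-fertile [heterokaryon()].
#' @return An object of class `"zygote"`: `$mat_A` and `$mat_a` nuclei and a
#'   named logical `$rip_exposed`.
#' @export
self_cross_zygote <- function(het) {
  stopifnot(inherits(het, "heterokaryon"))
  if (!is_self_fertile(het))
    stop("self-sterile: a self-cross needs both mating types among ",
         "division-competent components")
  fit <- vapply(het$nuclei, `[[`, 0, "division_fitness")
  mats <- vapply(het$nuclei, `[[`, "", "mat")
  pick <- function(m) {
    cand <- which(mats == m & fit > 0)
    if (length(cand) == 1L) return(cand)
    w <- het$proportions[cand] * fit[cand]
    cand[sample.int(length(cand), 1L, prob = w / sum(w))]
  }
  iA <- pick("A")
  ia <- pick("a")
  zygote(het$nuclei[[iA]], het$nuclei[[ia]])
}

#' Construct a zygote from two nuclei
#'
#' @param nucleus_A,nucleus_a Parental nuclei of mating type A and a.
#' @return An object of class `"zygote"`.
#' @export
zygote <- function(nucleus_A, nucleus_a) {
  stopifnot(inherits(nucleus_A, "nucleus_state"),
            inherits(nucleus_a, "nucleus_state"))
  if (nucleus_A$mat != "A" || nucleus_a$mat != "a")
    stop("a zygote needs one mat A and one mat a nucleus")
  structure(list(mat_A = nucleus_A, mat_a = nucleus_a,
                 rip_exposed = c(mat_A = is_rip_exposed(nucleus_A),
                                 mat_a = is_rip_exposed(nucleus_a))),
            class = "zygote")
}

#' @rdname zygote
#' @param x A `"nucleus_state"`.
#' @export
is_rip_exposed <- function(x) {
  stopifnot(inherits(x, "nucleus_state"))
  any(vapply(x$variants, function(v) {
    carried <- c(v$donor$carried_segments, v$recipient$carried_segments)
    any(duplicated(carried))
  }, TRUE))
}

#' Chromosome complement of a zygote
#'
#' Returns the multiset of chromosome variants a zygote contains, as a sorted
#' data frame — two zygotes with the same complement will undergo identical
#' meioses.  A `[Dp + Df]` self-cross zygote has exactly the complement of a
#' `T x N` zygote (normal and translocated donor, translocated and normal
#' recipient), which is why the two heterokaryon genotypes interconvert
#' through self-crosses.
#'
#' @param z A `"zygote"`.
#' @return A data frame with columns `rearrangement`, `chrom`, `role`,
#'   `translocated`, sorted canonically.
#' @export
zygote_chromosome_set <- function(z) {
  stopifnot(inherits(z, "zygote"))
  rows <- list()
  for (nuc in list(z$mat_A, z$mat_a))
    for (id in names(nuc$variants))
      for (side in c("donor", "recipient")) {
        v <- nuc$variants[[id]][[side]]
        rows[[length(rows) + 1L]] <- data.frame(
          rearrangement = id, chrom = v$chrom, role = v$role,
          translocated = v$translocated, stringsAsFactors = FALSE)
      }
  out <- do.call(rbind, rows)
  out <- out[order(out$rearrangement, out$role, out$chrom, out$translocated), ]
  rownames(out) <- NULL
  out
}

#' Reference MSUD strengths
#'
#' Working values for the three cross backgrounds ranked by silencing
#' strength: `OR` (full silencing), `Esm` (intermediate, partial suppressor),
#' `Sad` (semi-dominant suppressor, weakest).  With the default barren
#' threshold of 0.5 in [msud_fertility()], an unpaired duplication is barren
#' against OR and fertile against Esm or Sad backgrounds.
#' @export
msud_presets <- c(OR = 1, Esm = 0.5, Sad = 0.1)

#' Fertility of a cross under meiotic silencing by unpaired DNA
#'
#' MSUD silences genes that fail to pair with a homolog in meiosis;
#' duplication-heterozygous crosses make normal perithecia but almost no
#' ascospores ("barren").  Here a rearrangement segment is unpairable iff its
#' total copy number over the two zygote nuclei is odd: `Dp x N` carries
#' three copies (barren), while `T x N` and a `[Dp + Df]` self-cross zygote
#' each carry two pairable copies (fertile, as observed — translocation
#' heterozygotes pair their segments within the quadrivalent).  The cross is
#' barren iff some segment is unpairable and `msud_strength` exceeds
#' `threshold`; suppressor backgrounds (see [msud_presets]) lower the
#' strength below threshold.
#'
#' @param z A [zygote()].
#' @param msud_strength Scalar in `[0, 1]`; see [msud_presets].
#' @param threshold Barrenness threshold on `msud_strength`.
#' @return `"barren"` or `"fertile"`.
#' @export
msud_fertility <- function(z, msud_strength = msud_presets[["OR"]],
                           threshold = 0.5) {
  stopifnot(inherits(z, "zygote"))
  check_prob(msud_strength, "msud_strength")
  carried <- unlist(lapply(list(z$mat_A, z$mat_a), function(nuc)
    lapply(nuc$variants, function(v)
      c(v$donor$carried_segments, v$recipient$carried_segments))))
  unpaired <- length(carried) && any(table(carried) %% 2L == 1L)
  if (unpaired && msud_strength > threshold) "barren" else "fertile"
}
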