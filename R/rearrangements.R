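#' Define a chromosome rearrangement
#'
#' Constructs the core description of a translocation: its kind (insertional
#' `IT`, quasiterminal `QT`, or reciprocal `RT`), the donor and recipient
#' chromosomes, the translocated segment(s), and the breakpoint junction
#' classes the kind implies.  An `IT` is defined by three junctions — A
#' (the deletion on the donor chromosome) and B and C (the insertion flanks on
#' the recipient) — whereas a `QT` or `RT` is defined by two (A and B).
#'
#' `assay_junctions` records which junctions have working PCR assays; genotype
#' inference interprets derivative PCR patterns against this panel, which may
#' be smaller than the model-level junction set (for two of the shipped
#' presets not every junction has an assay).
#'
#' @param id Short label for the rearrangement.
#' @param kind One of `"IT"`, `"QT"`, `"RT"`.
#' @param donor_chrom,recipient_chrom Chromosome labels.
#' @param segments Labels for the translocated segment(s): one for `IT`/`QT`,
#'   two for `RT`.  Defaults are derived from `id`.
#' @param c_donor,c_recipient Default probabilities of an interstitial
#'   crossover (between centromere and breakpoint) on the donor and recipient
#'   chromosome per meiosis, each in `[0, 1]`.
#' @param assay_junctions Subset of the junction classes for which a PCR
#'   assay exists.  Defaults to all of them.
#' @param size_bp,n_genes Optional metadata: segment size in base pairs and
#'   number of genes.  Carried for reporting only; they do not affect
#'   simulation.
#' @return An object of class `"rearrangement"`.
#' @seealso [rearrangement_preset()] for the four built-in translocations.
#' @examples
#' rt <- rearrangement("demoRT", kind = "RT", donor_chrom = "I",
#'                     recipient_chrom = "II")
#' rt$junction_classes
#' @export
rearrangement <- function(id, kind = c("IT", "QT", "RT"),
                          donor_chrom = "D", recipient_chrom = "R",
                          segments = NULL, c_donor = 0, c_recipient = 0,
                          assay_junctions = NULL,
                          size_bp = NA_real_, n_genes = NA_integer_) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  n_seg <- if (kind == "RT") 2L else 1L
  if (is.null(segments))
    segments <- if (kind == "RT") paste0(id, ".seg", 1:2) else paste0(id, ".seg")
  segments <- as.character(segments)
  if (length(segments) != n_seg || anyDuplicated(segments))
    stop("a ", kind, " rearrangement carries exactly ", n_seg,
         " distinct translocated segment(s)")
  junction_classes <- if (kind == "IT") c("A", "B", "C") else c("A", "B")
  if (is.null(assay_junctions)) assay_junctions <- junction_classes
  assay_junctions <- sort(unique(as.character(assay_junctions)))
  if (!all(assay_junctions %in% junction_classes))
    stop("'assay_junctions' must be drawn from the junction classes {",
         paste(junction_classes, collapse = ", "), "} of a ", kind)
  check_prob(c_donor, "c_donor")
  check_prob(c_recipient, "c_recipient")
  structure(
    list(id = id, kind = kind,
         donor_chrom = donor_chrom, recipient_chrom = recipient_chrom,
         segments = segments, junction_classes = junction_classes,
         assay_junctions = assay_junctions,
         c_donor = c_donor, c_recipient = c_recipient,
         size_bp = size_bp, n_genes = n_genes),
    class = "rearrangement")
}

#' Built-in translocation presets
#'
#' The four rearrangements shipped with the package: the insertional
#' translocations `EB4` (chromosome VR segment into VII; 145,282 bp, 39
#' genes), `IBj5` (VIL into IR; 405,319 bp, 120 genes) and `B362i` (IVR into
#' IL; 118,782 bp, 36 genes), and the quasiterminal translocation `UK14-1`
#' (VIR onto VL; 490,958 bp, 126 genes).  Sizes and gene counts are metadata
#' only.  The PCR panels reflect which junctions have assays: all three for
#' `EB4` and `B362i`, A and B for `IBj5`, and A alone for `UK14-1`.
#'
#' `IBj5` may in reality be a complex rearrangement (possibly with a linked
#' reciprocal exchange); it is modeled here as a plain `IT`.
#'
#' @param name One of `"EB4"`, `"IBj5"`, `"UK14-1"`, `"B362i"`.
#' @return An object of class `"rearrangement"`.
#' @export
rearrangement_preset <- function(name = c("EB4", "IBj5", "UK14-1", "B362i")) {
  name <- match.arg(name)
  switch(name,
    "EB4" = rearrangement("EB4", "IT", donor_chrom = "VR",
                          recipient_chrom = "VII",
                          size_bp = 145282, n_genes = 39L),
    "IBj5" = rearrangement("IBj5", "IT", donor_chrom = "VIL",
                           recipient_chrom = "IR",
                           assay_junctions = c("A", "B"),
                           size_bp = 405319, n_genes = 120L),
    "UK14-1" = rearrangement("UK14-1", "QT", donor_chrom = "VIR",
                             recipient_chrom = "VL",
                             assay_junctions = "A",
                             size_bp = 490958, n_genes = 126L),
    "B362i" = rearrangement("B362i", "IT", donor_chrom = "IVR",
                            recipient_chrom = "IL",
                            size_bp = 118782, n_genes = 36L))
}

#' @export
print.rearrangement <- function(x, ...) {
  cat(sprintf("<rearrangement %s: %s, %s -> %s>\n", x$id, x$kind,
              x$donor_chrom, x$recipient_chrom))
  cat("  segments:", paste(x$segments, collapse = ", "), "\n")
  cat("  junctions:", paste(x$junction_classes, collapse = ", "),
      sprintf("(assayable: %s)\n", paste(x$assay_junctions, collapse = ", ")))
  if (!is.na(x$size_bp))
    cat(sprintf("  segment size: %s bp, %s genes\n",
                format(x$size_bp, big.mark = ","), x$n_genes))
  invisible(x)
}

#' Construct one chromosome variant of a rearrangement
#'
#' A variant is one homolog: the donor or recipient chromosome, in either its
#' translocated (T) or normal-sequence (N) form.  The constructor derives the
#' segments the variant carries and the breakpoint junctions it bears.  For an
#' `IT`: the translocated donor carries junction A and has lost the segment;
#' the translocated recipient carries junctions B and C plus the inserted
#' segment; the normal donor carries the segment in its native position; N
#' forms carry no junctions.  For a `QT` the translocated recipient bears
#' junction B only.  For an `RT` the two chromosomes have reciprocally
#' exchanged terminal segments: the translocated form of each carries the
#' other's segment, with junction A on the donor-side product and B on the
#' recipient-side product.
#'
#' @param rearrangement A [rearrangement()] object.
#' @param role `"donor"` or `"recipient"`.
#' @param translocated Logical: T form (`TRUE`) or N form (`FALSE`).
#' @return An object of class `"chromosome_variant"`.
#' @export
chromosome_variant <- function(rearrangement, role = c("donor", "recipient"),
                               translocated) {
  r <- rearrangement
  stopifnot(inherits(r, "rearrangement"), is.logical(translocated),
            length(translocated) == 1L, !is.na(translocated))
  role <- match.arg(role)
  seg <- r$segments
  if (r$kind %in% c("IT", "QT")) {
    if (role == "donor") {
      carried <- if (translocated) character(0) else seg[1]
      junctions <- if (translocated) "A" else character(0)
    } else {
      carried <- if (translocated) seg[1] else character(0)
      junctions <- if (!translocated) character(0)
        else if (r$kind == "IT") c("B", "C") else "B"
    }
  } else {  # RT: reciprocal exchange of terminal segments
    if (role == "donor") {
      carried <- if (translocated) seg[2] else seg[1]
      junctions <- if (translocated) "A" else character(0)
    } else {
      carried <- if (translocated) seg[1] else seg[2]
      junctions <- if (translocated) "B" else character(0)
    }
  }
  structure(
    list(rearrangement_id = r$id,
         chrom = if (role == "donor") r$donor_chrom else r$recipient_chrom,
         role = role, translocated = translocated,
         carried_segments = carried, junctions = junctions),
    class = "chromosome_variant")
}

#' Segmental genotype of a donor/recipient variant pair
#'
#' Computes the label of the haploid nucleus assembled from one donor and one
#' recipient variant of the same rearrangement, from segment copy number:
#' duplication (`Dp`) at copy number 2, deficiency (`Df`) at 0, and at copy
#' number 1 the translocated (`T`) or normal (`N`) arrangement.  For a
#' reciprocal translocation the two unbalanced products are the per-segment
#' composites `"Dp1/Df2"` and `"Dp2/Df1"`.
#'
#' @param donor,recipient `"chromosome_variant"` objects from the same
#'   rearrangement.
#' @param rearrangement The [rearrangement()] the variants belong to.
#' @return A genotype label: `"T"`, `"N"`, `"Dp"`, `"Df"`, `"Dp1/Df2"`, or
#'   `"Dp2/Df1"`.
#' @export
segmental_genotype <- function(donor, recipient, rearrangement) {
  stopifnot(inherits(donor, "chromosome_variant"),
            inherits(recipient, "chromosome_variant"))
  if (donor$rearrangement_id != recipient$rearrangement_id)
    stop("variants belong to different rearrangements ('",
         donor$rearrangement_id, "' vs '", recipient$rearrangement_id, "')")
  if (donor$rearrangement_id != rearrangement$id)
    stop("variants do not belong to rearrangement '", rearrangement$id, "'")
  if (donor$role != "donor" || recipient$role != "recipient")
    stop("expected one donor and one recipient variant, in that order")
  carried <- c(donor$carried_segments, recipient$carried_segments)
  copies <- vapply(rearrangement$segments, function(s) sum(carried == s), 0L)
  if (rearrangement$kind %in% c("IT", "QT")) {
    if (copies == 2L) return("Dp")
    if (copies == 0L) return("Df")
    return(if (donor$translocated) "T" else "N")
  }
  if (all(copies == 1L)) return(if (donor$translocated) "T" else "N")
  paste0("Dp", which(copies == 2L), "/Df", which(copies == 0L))
}

## inverse map: genotype label -> (donor translocated?, recipient translocated?)
genotype_to_variants <- function(genotype, rearrangement) {
  r <- rearrangement
  valid <- if (r$kind == "RT") c("T", "N", "Dp1/Df2", "Dp2/Df1")
           else c("T", "N", "Dp", "Df")
  if (!genotype %in% valid)
    stop("'", genotype, "' is not a valid segmental genotype for a ", r$kind,
         " (valid: ", paste(valid, collapse = ", "), ")")
  forms <- switch(genotype,
    "T" = c(TRUE, TRUE), "N" = c(FALSE, FALSE),
    "Dp" = c(FALSE, TRUE), "Df" = c(TRUE, FALSE),
    "Dp1/Df2" = c(FALSE, TRUE), "Dp2/Df1" = c(TRUE, FALSE))
  list(donor = chromosome_variant(r, "donor", forms[1]),
       recipient = chromosome_variant(r, "recipient", forms[2]))
}

#' Construct a haploid nucleus state
#'
#' Low-level constructor.  `variants` is a named list (one entry per
#' rearrangement id) of `list(donor = , recipient = )` chromosome-variant
#' pairs.  Most callers will prefer [nucleus()], which builds the variants
#' from genotype labels.
#'
#' @param mat Mating type, `"A"` or `"a"`.
#' @param variants Named list of donor/recipient variant pairs.
#' @param markers Named list of marker alleles (labels only).
#' @param division_fitness Non-negative relative nuclear division rate;
#'   components with fitness 0 cannot divide (and so cannot confer
#'   self-fertility or germinate a conidium).
#' @return An object of class `"nucleus_state"`.
#' @export
nucleus_state <- function(mat, variants, markers = list(),
                          division_fitness = 1) {
  if (!mat %in% c("A", "a")) stop("'mat' must be \"A\" or \"a\"")
  stopifnot(is.list(variants), !is.null(names(variants)))
  for (id in names(variants)) {
    v <- variants[[id]]
    if (!is.list(v) || !all(c("donor", "recipient") %in% names(v)))
      stop("each variants entry needs $donor and $recipient")
    if (v$donor$rearrangement_id != id || v$recipient$rearrangement_id != id)
      stop("variant pair under '", id, "' belongs to another rearrangement")
  }
  if (!is.numeric(division_fitness) || division_fitness < 0)
    stop("'division_fitness' must be a non-negative number")
  structure(list(mat = mat, variants = variants, markers = markers,
                 division_fitness = division_fitness),
            class = "nucleus_state")
}

#' Build a nucleus from segmental genotype labels
#'
#' Convenience wrapper around [nucleus_state()]: give one genotype label per
#' rearrangement and the chromosome variants are derived.
#'
#' @param genotype Character vector of genotype labels (`"T"`, `"N"`, `"Dp"`,
#'   `"Df"`, or for an RT `"Dp1/Df2"`/`"Dp2/Df1"`), one per rearrangement
#'   (recycled if length one).
#' @param rearrangements A [rearrangement()] or list of them.
#' @inheritParams nucleus_state
#' @return An object of class `"nucleus_state"`.
#' @examples
#' eb4 <- rearrangement_preset("EB4")
#' dp <- nucleus("Dp", eb4, mat = "A")
#' nucleus_genotype(dp, eb4)
#' @export
nucleus <- function(genotype, rearrangements, mat = c("A", "a"),
                    markers = list(), division_fitness = 1) {
  mat <- match.arg(mat)
  rl <- as_rearrangement_list(rearrangements)
  if (length(genotype) == 1L) genotype <- rep(genotype, length(rl))
  if (length(genotype) != length(rl))
    stop("need one genotype label per rearrangement")
  variants <- Map(genotype_to_variants, genotype, rl)
  names(variants) <- names(rl)
  nucleus_state(mat, variants, markers, division_fitness)
}

#' Segmental genotype of a nucleus
#'
#' @param x A `"nucleus_state"`.
#' @param rearrangement A single [rearrangement()].
#' @return The genotype label for that rearrangement.
#' @export
nucleus_genotype <- function(x, rearrangement) {
  stopifnot(inherits(x, "nucleus_state"))
  v <- x$variants[[rearrangement$id]]
  if (is.null(v))
    stop("nucleus carries no variant state for rearrangement '",
         rearrangement$id, "'")
  segmental_genotype(v$donor, v$recipient, rearrangement)
}

#' Segment copy numbers of a nucleus
#'
#' @inheritParams nucleus_genotype
#' @return Named integer vector of copy numbers (0, 1, or 2) per segment.
#' @export
segment_copy_number <- function(x, rearrangement) {
  stopifnot(inherits(x, "nucleus_state"))
  v <- x$variants[[rearrangement$id]]
  if (is.null(v))
    stop("nucleus carries no variant state for rearrangement '",
         rearrangement$id, "'")
  carried <- c(v$donor$carried_segments, v$recipient$carried_segments)
  vapply(stats::setNames(rearrangement$segments, rearrangement$segments),
         function(s) sum(carried == s), 0L)
}

#' @export
print.nucleus_state <- function(x, ...) {
  gts <- vapply(names(x$variants), function(id) {
    v <- x$variants[[id]]
    d <- if (v$donor$translocated) "T" else "N"
    r <- if (v$recipient$translocated) "T" else "N"
    paste0(id, ":", d, "/", r)
  }, "")
  cat(sprintf("<nucleus mat %s | %s | fitness %g>\n", x$mat,
              paste(gts, collapse = " "), x$division_fitness))
  invisible(x)
}

#' Breakpoint junctions present in a set of nuclei
#'
#' Union, over the given nuclei, of the junction classes borne by their
#' chromosome variants for one rearrangement.  A single `IT` nucleus yields
#' `{A, B, C}` when `T`, `{B, C}` when `Dp`, `{A}` when `Df`, and the empty
#' set when `N`.  Because the union for a `[T, N]` pair equals that for a
#' `[Dp, Df]` pair, junction presence alone cannot distinguish the two
#' heterokaryon genotypes — the ambiguity the conidial-derivative classifier
#' ([infer_heterokaryon_genotype()]) exists to resolve.
#'
#' @param nuclei A `"nucleus_state"` or a non-empty list of them.
#' @param rearrangement A single [rearrangement()].
#' @return Sorted character vector of junction classes.
#' @export
junctions_present <- function(nuclei, rearrangement) {
  nuclei <- as_nucleus_list(nuclei)
  if (!length(nuclei)) stop("at least one nucleus is required")
  out <- character(0)
  for (nu in nuclei) {
    v <- nu$variants[[rearrangement$id]]
    if (is.null(v))
      stop("nucleus carries no variant state for rearrangement '",
           rearrangement$id, "'")
    out <- c(out, v$donor$junctions, v$recipient$junctions)
  }
  sort(unique(out))
}

#' Ascospore viability
#'
#' Decides whether a spore containing 1-3 nuclei is viable (blackens) or
#' inviable (stays white).  Under the default `"union"` rule a spore is
#' viable iff the union of segments carried over all its nuclei covers every
#' segment of every rearrangement — i.e. complementation between nuclei
#' within a spore is allowed, so a binucleate `[Dp + Df]` spore lives while a
#' uninucleate `Df` spore dies.  The alternative `"autonomous"` rule demands
#' that every nucleus individually carry a full segment complement, under
#' which `[Dp1/Df2 + Dp2/Df1]` spores from a reciprocal-translocation cross
#' are inviable.
#'
#' @param nuclei A `"nucleus_state"` or non-empty list of them (1-3).
#' @param rearrangements A [rearrangement()] or list of them.
#' @param rule `"union"` (default) or `"autonomous"`.
#' @return Logical: `TRUE` for viable/black.
#' @export
spore_viability <- function(nuclei, rearrangements,
                            rule = c("union", "autonomous")) {
  rule <- match.arg(rule)
  nuclei <- as_nucleus_list(nuclei)
  if (!length(nuclei)) stop("a spore must contain at least one nucleus")
  rl <- as_rearrangement_list(rearrangements)
  covers <- function(set) {
    all(vapply(rl, function(r) {
      carried <- unlist(lapply(set, function(nu) {
        v <- nu$variants[[r$id]]
        if (is.null(v))
          stop("nucleus carries no variant state for rearrangement '",
               r$id, "'")
        c(v$donor$carried_segments, v$recipient$carried_segments)
      }))
      all(r$segments %in% carried)
    }, TRUE))
  }
  if (rule == "union") covers(nuclei)
  else all(vapply(nuclei, function(nu) covers(list(nu)), TRUE))
}
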