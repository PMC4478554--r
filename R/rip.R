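#' Pair an ancestral and a derived allele sequence
#'
#' Holds two aligned (equal-length, co-linear) nucleotide sequences plus an
#' optional exon annotation on the ancestral coordinate system.  Exons are
#' 1-based closed intervals internally; BED files (0-based half-open) are
#' converted by [exons_from_bed()].
#'
#' @param ancestral,derived Nucleotide sequences (character scalars or
#'   anything `as.character()` renders as one, e.g. a
#'   `Biostrings::DNAString`).  Must have equal length; gap columns (`-`)
#'   are tolerated and excluded from substitution calling.
#' @param exons Optional `data.frame` with columns `start`, `end` (1-based,
#'   closed, on the ancestral sequence); intervals must lie within the
#'   sequence and not overlap.  Their concatenation, in order, is the CDS.
#' @return An object of class `"sequence_pair"`.
#' @export
sequence_pair <- function(ancestral, derived, exons = NULL) {
  ancestral <- toupper(as.character(ancestral))
  derived <- toupper(as.character(derived))
  stopifnot(length(ancestral) == 1L, length(derived) == 1L)
  if (nchar(ancestral) != nchar(derived))
    stop("alignment required: sequences differ in length (",
         nchar(ancestral), " vs ", nchar(derived), ")")
  if (!is.null(exons)) {
    stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
    exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
    if (any(exons$start < 1) || any(exons$end > nchar(ancestral)) ||
        any(exons$start > exons$end))
      stop("exon intervals must lie within the sequence")
    if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
      stop("exon intervals must not overlap")
    rownames(exons) <- NULL
  }
  structure(list(ancestral = ancestral, derived = derived, exons = exons),
            class = "sequence_pair")
}

#' Read exon intervals from a BED file
#'
#' Reads the first three BED columns (chrom, chromStart, chromEnd; 0-based
#' half-open) and converts them to the 1-based closed convention used by
#' [sequence_pair()].
#'
#' @param path BED file path.
#' @return A `data.frame` with columns `start`, `end`.
#' @export
exons_from_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED needs at least 3 columns")
  data.frame(start = bed[[2]] + 1L, end = bed[[3]])
}

#' Read a sequence pair from FASTA files
#'
#' @param ancestral_fa,derived_fa FASTA paths (first record of each is used).
#' @param exons_bed Optional BED path of exon intervals.
#' @return A [sequence_pair()].
#' @export
read_sequence_pair <- function(ancestral_fa, derived_fa, exons_bed = NULL) {
  anc <- Biostrings::readDNAStringSet(ancestral_fa)[[1]]
  der <- Biostrings::readDNAStringSet(derived_fa)[[1]]
  exons <- if (!is.null(exons_bed)) exons_from_bed(exons_bed)
  sequence_pair(anc, der, exons)
}

in_exon <- function(pos, exons) {
  if (is.null(exons) || !nrow(exons)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= exons$start & p <= exons$end), TRUE)
}

#' Classify the substitutions between two aligned alleles
#'
#' Every aligned column at which both sequences carry an unambiguous base
#' and the bases differ becomes an event, classified on the given (top)
#' strand as `G>A`, `C>T`, `other-transition` (`A>G`/`T>C`), or
#' `transversion`, and assigned to exon or intron by the exon annotation.
#' RIP (repeat-induced point mutation) induces G:C-to-A:T transitions in
#' duplicated DNA with a fixed strand per copy, so `polarity` summarises the
#' RIP-class events: `"G>A"` or `"C>T"` when all of them share that
#' direction, `"mixed"` otherwise, `"none"` with no RIP-class event.
#' `rip_fraction` is the share of events in the two RIP classes
#' (`other-transition` events at G:C sites in the non-RIP direction are
#' excluded).
#'
#' @param pair A [sequence_pair()].
#' @return An object of class `"substitution_report"`: `$events` (data frame
#'   with `position`, `ancestral`, `derived`, `class`, `region`),
#'   `$n_total`, `$n_exonic`, `$n_intronic`, `$polarity`, `$rip_fraction`,
#'   and when exons are annotated `$codon_effects` and
#'   `$n_codons_affected`.
#' @examples
#' rep <- classify_substitutions(sequence_pair("CCGAG", "CTGAA"))
#' rep$n_total; rep$polarity; rep$rip_fraction
#' @export
classify_substitutions <- function(pair) {
  stopifnot(inherits(pair, "sequence_pair"))
  a <- strsplit(pair$ancestral, "", fixed = TRUE)[[1]]
  d <- strsplit(pair$derived, "", fixed = TRUE)[[1]]
  ok <- a %in% c("A", "C", "G", "T") & d %in% c("A", "C", "G", "T")
  idx <- which(ok & a != d)
  cls <- character(length(idx))
  if (length(idx)) {
    ch <- paste0(a[idx], ">", d[idx])
    cls <- ifelse(ch %in% c("G>A", "C>T"), ch,
                  ifelse(ch %in% c("A>G", "T>C"), "other-transition",
                         "transversion"))
  }
  exonic <- in_exon(idx, pair$exons)
  events <- data.frame(position = idx, ancestral = a[idx], derived = d[idx],
                       class = cls,
                       region = ifelse(exonic, "exon", "intron"),
                       stringsAsFactors = FALSE)
  rip_classes <- unique(events$class[events$class %in% c("G>A", "C>T")])
  polarity <- if (!length(rip_classes)) "none"
              else if (length(rip_classes) == 1L) rip_classes
              else "mixed"
  out <- list(events = events,
              n_total = nrow(events),
              n_exonic = sum(exonic),
              n_intronic = sum(!exonic),
              polarity = polarity,
              rip_fraction = if (nrow(events))
                mean(events$class %in% c("G>A", "C>T")) else NA_real_)
  if (!is.null(pair$exons)) {
    ## attach codon effects when the exon annotation defines a translatable
    ## CDS; otherwise report the region split only
    eff <- tryCatch(annotate_codon_effects(pair), error = function(e) NULL)
    if (!is.null(eff)) {
      out$codon_effects <- eff
      out$n_codons_affected <- length(eff)
    }
  }
  structure(out, class = "substitution_report")
}

#' @export
print.substitution_report <- function(x, ...) {
  cat(sprintf("substitutions: %d (%d intronic); polarity %s; RIP fraction %s\n",
              x$n_total, x$n_intronic, x$polarity,
              ifelse(is.na(x$rip_fraction), "NA",
                     sprintf("%.2f", x$rip_fraction))))
  if (!is.null(x$codon_effects) && length(x$codon_effects))
    cat("codon effects:", paste(x$codon_effects, collapse = ", "), "\n")
  invisible(x)
}

splice_cds <- function(seq, exons) {
  paste(vapply(seq_len(nrow(exons)), function(i)
    substr(seq, exons$start[i], exons$end[i]), ""), collapse = "")
}

translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Annotate the codon effects of exonic substitutions
#'
#' Splices the CDS out of both alleles using the pair's exon annotation,
#' translates with the standard genetic code, and for each codon containing
#' at least one substitution emits
#' `"<ancestral aa><1-based residue><derived aa>"` — e.g. `"H22Y"`, a
#' nonsense change as `"Q122*"`, a synonymous change as `"N97N"`.
#'
#' @param pair A [sequence_pair()] with exons annotated.
#' @return Character vector of effect strings in residue order.
#' @examples
#' p <- sequence_pair("ATGCAGTAA", "ATGTAGTAA",
#'                    exons = data.frame(start = 1, end = 9))
#' annotate_codon_effects(p)  # "Q2*"
#' @export
annotate_codon_effects <- function(pair) {
  stopifnot(inherits(pair, "sequence_pair"))
  if (is.null(pair$exons))
    stop("codon annotation requires an exon annotation")
  anc_cds <- splice_cds(pair$ancestral, pair$exons)
  der_cds <- splice_cds(pair$derived, pair$exons)
  if (nchar(anc_cds) %% 3L != 0L)
    stop("CDS length (", nchar(anc_cds), ") is not a multiple of 3")
  anc_aa <- translate_cds(anc_cds)
  der_aa <- translate_cds(der_cds)
  a <- strsplit(anc_cds, "", fixed = TRUE)[[1]]
  d <- strsplit(der_cds, "", fixed = TRUE)[[1]]
  hit <- sort(unique((which(a != d) - 1L) %/% 3L + 1L))
  vapply(hit, function(i) paste0(anc_aa[i], i, der_aa[i]), "")
}

#' Simulate one round of RIP on a duplicated sequence
#'
#' A duplication passing through a sexual cross exposes both copies to RIP.
#' The simulator mutates, independently per copy, every eligible site with
#' probability `rate`: a copy with polarity `"C>T"` mutates top-strand Cs to
#' T, a copy with polarity `"G>A"` mutates Gs to A (equivalently, Cs of the
#' bottom strand) — by default the two copies receive opposite polarities,
#' the pattern seen when one duplicated copy suffers only G-to-A and the
#' other only C-to-T changes.  Positions outside `region` (the duplicated
#' span) are never touched.
#'
#' @param sequence Nucleotide sequence (character scalar or `DNAString`).
#' @param rate Per-eligible-site mutation probability in `[0, 1]`.
#' @param polarities Length-2 character, polarity per copy; default
#'   `c("C>T", "G>A")`.
#' @param region Optional `c(start, end)` (1-based, closed) restricting
#'   mutable positions.
#' @return List of two mutated copies (character), with attribute
#'   `"n_mutations"`.
#' @examples
#' set.seed(7)
#' copies <- rip_mutate("ACGTCCGGAT", rate = 1)
#' copies[[1]]  # every C -> T
#' @export
rip_mutate <- function(sequence, rate, polarities = c("C>T", "G>A"),
                       region = NULL) {
  check_prob(rate, "rate")
  seq <- toupper(as.character(sequence))
  stopifnot(length(seq) == 1L, length(polarities) == 2L,
            all(polarities %in% c("C>T", "G>A")))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  eligible <- rep(TRUE, length(chars))
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] >= 1,
              region[2] <= length(chars), region[1] <= region[2])
    eligible <- seq_along(chars) >= region[1] & seq_along(chars) <= region[2]
  }
  n_mut <- integer(2L)
  copies <- lapply(1:2, function(i) {
    from <- if (polarities[i] == "C>T") "C" else "G"
    to <- if (polarities[i] == "C>T") "T" else "A"
    out <- chars
    sites <- which(out == from & eligible)
    hit <- sites[stats::runif(length(sites)) < rate]
    out[hit] <- to
    n_mut[i] <<- length(hit)
    paste(out, collapse = "")
  })
  attr(copies, "n_mutations") <- n_mut
  attr(copies, "polarities") <- polarities
  copies
}
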