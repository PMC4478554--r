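## Deterministic DNA keyed on a string, via a small LCG.  Independent of R's
## global RNG so that fixture motifs never perturb, and are never perturbed
## by, simulation seeds.
deterministic_dna <- function(key, n) {
  codes <- utf8ToInt(key)
  x <- sum(codes * seq_along(codes)) %% 2147483648
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  for (i in seq_len(n)) {
    x <- (x * 69069 + 1) %% 2147483648
    out[i] <- bases[(x %/% 1024) %% 4 + 1]
  }
  paste(out, collapse = "")
}

#' Junction and segment motifs for a toy genome
#'
#' Deterministic marker sequences standing in for the breakpoint-junction
#' amplicons (and the translocated segment) of a rearrangement, for use with
#' [simulate_junction_pcr()].  Regeneration from the same rearrangement id is
#' byte-identical.
#'
#' @param rearrangement A [rearrangement()].
#' @param motif_length Motif length in bases.
#' @return Named character vector, one motif per junction class.
#' @export
junction_motifs <- function(rearrangement, motif_length = 24) {
  cls <- rearrangement$junction_classes
  stats::setNames(vapply(cls, function(cl)
    deterministic_dna(paste0(rearrangement$id, ":junction:", cl),
                      motif_length), ""), cls)
}

segment_motifs <- function(rearrangement, motif_length = 24) {
  segs <- rearrangement$segments
  stats::setNames(vapply(segs, function(s)
    deterministic_dna(paste0(rearrangement$id, ":segment:", s),
                      motif_length), ""), segs)
}

#' Build a toy genome for a segmental genotype
#'
#' Emits one short synthetic sequence per chromosome variant of the given
#' genotype, with the junction motifs the variant bears (and the segment
#' motifs it carries) embedded between chromosome-specific backbone flanks.
#' [simulate_junction_pcr()] on these sequences detects exactly the
#' junctions [junctions_present()] predicts for the genotype.
#'
#' @param rearrangement A [rearrangement()].
#' @param genotype Segmental genotype label (see [nucleus()]).
#' @param motif_length Motif length in bases.
#' @param flank Backbone flank length in bases.
#' @return A `Biostrings::DNAStringSet` of two sequences (donor, recipient).
#' @export
build_toy_genome <- function(rearrangement, genotype, motif_length = 24,
                             flank = 40) {
  v <- genotype_to_variants(genotype, rearrangement)
  jm <- junction_motifs(rearrangement, motif_length)
  sm <- segment_motifs(rearrangement, motif_length)
  one <- function(var) {
    paste0(deterministic_dna(paste0(var$chrom, ":flank5"), flank),
           paste(jm[var$junctions], collapse = ""),
           paste(sm[var$carried_segments], collapse = ""),
           deterministic_dna(paste0(var$chrom, ":flank3"), flank))
  }
  seqs <- c(one(v$donor), one(v$recipient))
  names(seqs) <- paste0(rearrangement$id, "_", genotype, "_",
                        c(v$donor$chrom, v$recipient$chrom))
  Biostrings::DNAStringSet(seqs)
}

#' In-silico breakpoint-junction PCR
#'
#' Presence/absence detection of junction classes: a junction is detected
#' iff its motif occurs as a substring of any provided sequence — the model
#' of PCR with junction-specific primers on pooled (heterokaryon) DNA, under
#' which a `[Dp + Df]` DNA mixture is indistinguishable from `[T + N]`.
#' Given model nuclei instead of sequences, falls back to
#' [junctions_present()].
#'
#' @param x A `DNAStringSet`/character vector of sequences, or a
#'   `"nucleus_state"`/list of them.
#' @param motifs Named character vector of junction motifs (required for
#'   sequences); must be unique.
#' @param rearrangement Required when `x` is nuclei.
#' @return Sorted character vector of detected junction classes.
#' @examples
#' eb4 <- rearrangement_preset("EB4")
#' simulate_junction_pcr(build_toy_genome(eb4, "T"), junction_motifs(eb4))
#' @export
simulate_junction_pcr <- function(x, motifs = NULL, rearrangement = NULL) {
  if (inherits(x, "nucleus_state") ||
      (is.list(x) && length(x) && inherits(x[[1]], "nucleus_state"))) {
    if (is.null(rearrangement))
      stop("'rearrangement' is required for model nuclei")
    return(junctions_present(x, rearrangement))
  }
  if (is.null(motifs) || is.null(names(motifs)))
    stop("named junction 'motifs' are required for sequence input")
  if (anyDuplicated(motifs))
    stop("config error: junction motifs must be unique")
  seqs <- as.character(x)
  detected <- names(motifs)[vapply(motifs, function(m)
    any(grepl(m, seqs, fixed = TRUE)), TRUE)]
  sort(detected)
}

#' Fixture generation configuration
#'
#' @param preset Built-in rearrangement name (see [rearrangement_preset()]).
#' @param n_derivatives Conidial derivatives sampled per simulated strain.
#' @param n_asci Asci for the tally fixture.
#' @param rip_length Length of the synthetic ancestral allele.
#' @param rip_rate Per-site RIP mutation rate for the allele pair fixture.
#' @param motif_length Junction motif length.
#' @param seed Master seed; regeneration with the same config is
#'   byte-identical.
#' @param out_dir Output directory.
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(preset = "EB4", n_derivatives = 25, n_asci = 300,
                           rip_length = 600, rip_rate = 0.05,
                           motif_length = 24, seed = 1,
                           out_dir = tempfile("octadkit_fixtures")) {
  structure(list(preset = preset, n_derivatives = n_derivatives,
                 n_asci = n_asci, rip_length = rip_length,
                 rip_rate = rip_rate, motif_length = motif_length,
                 seed = seed, out_dir = out_dir),
            class = "fixture_config")
}

#' Generate a self-contained fixture set
#'
#' Writes, under `config$out_dir`: toy FASTA genomes for the T/N/Dp/Df
#' genotypes of the chosen preset; an observation TSV of simulated conidial
#' derivatives for six known heterokaryon genotypes (ground truth in the
#' manifest); an ascus tally TSV; a RIP-mutated allele pair (FASTA) with
#' known polarity; a copy of the packaged strain table; and a JSON manifest
#' recording the seed and ground truth.  Running twice with the same config
#' yields byte-identical files.
#'
#' @param config A [fixture_config()].
#' @return Invisibly, the manifest as a list.
#' @export
generate_fixtures <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  r <- rearrangement_preset(config$preset)
  paths <- list()

  ## toy genomes
  for (g in c("T", "N", "Dp", "Df")) {
    f <- file.path(config$out_dir, paste0("genome_", g, ".fa"))
    Biostrings::writeXStringSet(
      build_toy_genome(r, g, motif_length = config$motif_length), f)
    paths[[paste0("genome_", g)]] <- f
  }

  ## observation table for six known heterokaryon genotypes
  truth <- list(TN = c("T", "N"), DpDf = c("Dp", "Df"), DpN = c("Dp", "N"),
                TDf = c("T", "Df"), NDf = c("N", "Df"),
                TNDf = c("T", "N", "Df"))
  records <- vector("list", length(truth))
  names(records) <- names(truth)
  for (nm in names(truth)) {
    gts <- truth[[nm]]
    mats <- c("a", "A", "A")[seq_along(gts)]
    het <- heterokaryon(Map(function(g, m) nucleus(g, r, m), gts, mats))
    der <- sample_conidial_derivatives(het, config$n_derivatives, r)
    records[[nm]] <- observation_record(
      nm, junctions_present(het$nuclei, r),
      der[, c("self_fertile", "mat", "junctions")])
  }
  paths$observations <- file.path(config$out_dir, "observations.tsv")
  write_observations(records, paths$observations)

  ## ascus tally
  tally <- simulate_cross_tally(nucleus("T", r, "A"), nucleus("N", r, "a"),
                                r, n_asci = config$n_asci)
  paths$tally <- file.path(config$out_dir, "tally.tsv")
  utils::write.table(as.data.frame(tally), paths$tally, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## RIP'd allele pair with known polarity
  anc <- paste(sample(c("A", "C", "G", "T"), config$rip_length,
                      replace = TRUE), collapse = "")
  copies <- rip_mutate(anc, config$rip_rate)
  rip_set <- Biostrings::DNAStringSet(
    c(ancestral = anc, copy1_CtoT = copies[[1]], copy2_GtoA = copies[[2]]))
  paths$rip_alleles <- file.path(config$out_dir, "rip_alleles.fa")
  Biostrings::writeXStringSet(rip_set, paths$rip_alleles)

  ## packaged strain table
  paths$strain_table <- file.path(config$out_dir, "table2_strains.tsv")
  file.copy(system.file("extdata", "table2_strains.tsv",
                        package = "octadkit"),
            paths$strain_table, overwrite = TRUE)

  manifest <- list(
    seed = config$seed, preset = config$preset,
    n_derivatives = config$n_derivatives, n_asci = config$n_asci,
    rip = list(rate = config$rip_rate, length = config$rip_length,
               polarities = c("C>T", "G>A"),
               n_mutations = attr(copies, "n_mutations")),
    ground_truth = lapply(truth, function(g)
      paste(g, c("a", "A", "A")[seq_along(g)])),
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
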