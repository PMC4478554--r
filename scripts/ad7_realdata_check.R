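#!/usr/bin/env Rscript

## OPT-IN real-data check (requires network access; not part of the default
## test suite).  Downloads the ad-7 allele sequences from GenBank, aligns
## the ancestral 85 A allele (KP006652) against the RIP-induced mutant RIP1
## (KP006653), and reports the substitution counts and codon effects for
## comparison with the published table (expected: 45 differences, 6 of them
## intronic, 39 affected codons including nonsense changes such as Q122*).
##
## Usage: Rscript scripts/ad7_realdata_check.R [--exons exons.bed]
## The exon BED (ad-7 coordinates on KP006652) must be supplied by the user;
## without it only total difference counts are reported.

suppressPackageStartupMessages({
  library(optparse)
  library(octadkit)
  library(Biostrings)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--exons", type = "character", default = NULL,
              help = "BED file of ad-7 exon intervals on KP006652"),
  make_option("--dir", type = "character", default = "scratch/ad7",
              help = "download directory [default %default]")
)))

fetch <- function(acc, dir) {
  dest <- file.path(dir, paste0(acc, ".fa"))
  if (!file.exists(dest)) {
    url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                  "efetch.fcgi?db=nuccore&id=", acc,
                  "&rettype=fasta&retmode=text")
    utils::download.file(url, dest, quiet = TRUE)
  }
  readDNAStringSet(dest)[[1]]
}

dir.create(opts$dir, recursive = TRUE, showWarnings = FALSE)
anc <- fetch("KP006652", opts$dir)   # 85 A ancestral ad-7
rip1 <- fetch("KP006653", opts$dir)  # RIP1 mutant allele

## global alignment (the alleles are co-linear)
aln <- pairwiseAlignment(anc, rip1, type = "global")
pair <- sequence_pair(as.character(alignedPattern(aln)),
                      as.character(alignedSubject(aln)),
                      exons = if (!is.null(opts$exons))
                        exons_from_bed(opts$exons))
rep <- classify_substitutions(pair)
print(rep)
cat(sprintf("total differences: %d (intronic: %d, exonic: %d)\n",
            rep$n_total, rep$n_intronic, rep$n_exonic))
if (!is.null(rep$codon_effects))
  cat("codon effects:", paste(rep$codon_effects, collapse = ", "), "\n")
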