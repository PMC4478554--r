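## shared fixtures and the independent brute-force oracle

eb4 <- rearrangement_preset("EB4")
ibj5 <- rearrangement_preset("IBj5")
uk14 <- rearrangement_preset("UK14-1")
demo_rt <- rearrangement("demoRT", kind = "RT",
                         donor_chrom = "I", recipient_chrom = "II")

## sorted composition key of an octet
octet_key <- function(octet, r) {
  paste(sort(octet_genotypes(octet, r)), collapse = ",")
}

## Independent enumeration oracle for an IT/QT T x N cross.
##
## Works directly from the figure-level rules, not from the package's
## chromatid code: each homolog contributes two sister chromatids whose
## breakpoint-distal content is its own form unless a crossover swapped one
## chromatid's content with the other homolog; MI sends the translocated
## donor centromere with (alternate) or opposite to (adjacent-1) the
## translocated recipient centromere; at each pole the two donor and two
## recipient chromatids pair into two MII products in one of two ways; the
## postmeiotic mitosis doubles each product.  Genotype of a (donor content,
## recipient content) pair: TT -> T, NN -> N, NT -> Dp, TN -> Df.
enumerate_octet_compositions <- function(pattern = c("alt", "adj"),
                                         cross_donor = FALSE,
                                         cross_recipient = FALSE) {
  pattern <- match.arg(pattern)
  genotype_of <- function(d, r) {
    if (d == "T" && r == "T") "T"
    else if (d == "N" && r == "N") "N"
    else if (d == "N" && r == "T") "Dp"
    else "Df"
  }
  d_tcen <- if (cross_donor) c("T", "N") else c("T", "T")
  d_ncen <- if (cross_donor) c("N", "T") else c("N", "N")
  r_tcen <- if (cross_recipient) c("T", "N") else c("T", "T")
  r_ncen <- if (cross_recipient) c("N", "T") else c("N", "N")
  if (pattern == "alt") {
    poles <- list(list(d = d_tcen, r = r_tcen), list(d = d_ncen, r = r_ncen))
  } else {
    poles <- list(list(d = d_tcen, r = r_ncen), list(d = d_ncen, r = r_tcen))
  }
  keys <- character(0)
  for (pair1 in 1:2) for (pair2 in 1:2) {
    pairing <- c(pair1, pair2)
    labels <- character(0)
    for (p in 1:2) {
      d <- poles[[p]]$d
      r <- if (pairing[p] == 1) poles[[p]]$r else rev(poles[[p]]$r)
      labels <- c(labels, genotype_of(d[1], r[1]), genotype_of(d[2], r[2]))
    }
    keys <- c(keys, paste(sort(rep(labels, 2)), collapse = ","))
  }
  sort(unique(keys))
}

## observation_record built from per-class derivative counts:
## classes = list(list(n =, mat =, junctions = )), junctions as comma string
make_obs <- function(strain, het, classes) {
  rows <- do.call(rbind, lapply(classes, function(cl)
    data.frame(self_fertile = isTRUE(cl$self_fertile),
               mat = cl$mat, junctions = cl$junctions,
               stringsAsFactors = FALSE)[rep(1, cl$n), ]))
  observation_record(strain, het, rows)
}

## canonical comparable form of a genotype call
call_key <- function(call) {
  paste(sort(paste(call$nuclei$type, call$nuclei$mat)), collapse = " / ")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
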