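#' Exact binomial probability of a mating-type split at least as skewed
#'
#' Under equal sampling of a heterokaryon's two nuclei (p = 0.5), the
#' two-sided exact binomial tail probability of observing a homokaryon-class
#' split at least as extreme as `(n1, n2)`, capped at 1.  Small values mean
#' the observed one-sidedness is unlikely under balanced sampling — evidence
#' that one nuclear type cannot form viable homokaryons (i.e. is a `Df`).
#'
#' @param n1,n2 Non-negative counts of the two homokaryon classes.
#' @return A probability in `(0, 1]`; `(0, 0)` returns 1.
#' @examples
#' balanced_split_probability(6, 0)   # 2 * (1/2)^6 = 0.03125
#' balanced_split_probability(5, 5)   # 1
#' @export
balanced_split_probability <- function(n1, n2) {
  stopifnot(length(n1) == 1L, length(n2) == 1L, n1 >= 0, n2 >= 0)
  n <- n1 + n2
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(n1, n2), n, 0.5))
}

#' Bundle the observations made on one self-fertile strain
#'
#' The data the discrimination procedure works from: the junction-PCR
#' pattern of the heterokaryon's own DNA, and per conidial derivative its
#' self-fertility, mating type, and (optionally) junction-PCR pattern.
#' Derivative junction sets must be subsets of the heterokaryon's pattern.
#'
#' @param strain_id Strain label.
#' @param het_junctions Character vector of junction classes amplified from
#'   heterokaryon DNA.
#' @param derivatives A `data.frame` with columns `self_fertile` (logical),
#'   `mat` (`"A"`, `"a"`, or `"het"`), and optionally `junctions`
#'   (comma-separated classes, `"."` for none detected, `NA` for not
#'   assayed).
#' @return An object of class `"observation_record"`.
#' @export
observation_record <- function(strain_id, het_junctions, derivatives) {
  het_junctions <- sort(unique(as.character(het_junctions)))
  stopifnot(is.data.frame(derivatives),
            all(c("self_fertile", "mat") %in% names(derivatives)))
  if (is.null(derivatives$junctions))
    derivatives$junctions <- NA_character_
  if (!all(derivatives$mat %in% c("A", "a", "het")))
    stop("derivative 'mat' must be \"A\", \"a\", or \"het\"")
  for (i in seq_len(nrow(derivatives))) {
    j <- derivatives$junctions[i]
    if (is.na(j)) next
    js <- parse_junctions(j)
    if (!all(js %in% het_junctions))
      stop("data error (strain ", strain_id, ", derivative ", i,
           "): junction set {", j,
           "} is not a subset of the heterokaryon's pattern {",
           paste(het_junctions, collapse = ","), "}")
  }
  structure(list(strain_id = strain_id, het_junctions = het_junctions,
                 derivatives = derivatives),
            class = "observation_record")
}

## junction pattern -> nucleus type, relative to the rearrangement's PCR panel
derivative_pattern_type <- function(junctions, rearrangement) {
  panel <- rearrangement$assay_junctions
  t_pat <- panel
  dp_pat <- setdiff(panel, "A")
  if (length(junctions) && setequal(junctions, t_pat)) return("T")
  if (!length(junctions)) return("N")
  if (setequal(junctions, dp_pat)) return("Dp")
  if (setequal(junctions, "A")) return("Df_het")
  "unknown"
}

## junctions a nucleus of a given type shows on the PCR panel
nucleus_type_junctions <- function(type, rearrangement) {
  panel <- rearrangement$assay_junctions
  switch(type,
         "T" = panel,
         "Dp" = setdiff(panel, "A"),
         "Df" = intersect("A", panel),
         "N" = character(0),
         "?" = character(0),
         stop("unknown nucleus type '", type, "'"))
}

new_genotype_call <- function(strain_id, nuclei, flags, skew_p, n_ss,
                              n_informative, n_min, alpha) {
  structure(list(strain_id = strain_id, nuclei = nuclei, flags = flags,
                 skew_p = skew_p, n_self_sterile = n_ss,
                 n_informative = n_informative,
                 params = list(n_min = n_min, alpha = alpha)),
            class = "genotype_call")
}

format_nuclei <- function(nuclei) {
  if (is.null(nuclei) || !nrow(nuclei)) return("ND")
  ord <- order(match(nuclei$mat, c("a", "A", "?")))
  nuclei <- nuclei[ord, , drop = FALSE]
  paste0("[", paste(paste(nuclei$type, nuclei$mat), collapse = " + "), "]")
}

#' @export
format.genotype_call <- function(x, ...) format_nuclei(x$nuclei)

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$strain_id, format(x)))
  cat(sprintf("  self-sterile derivatives: %d (%d with junction PCR); skew p = %.4g\n",
              x$n_self_sterile, x$n_informative, x$skew_p))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

add_nucleus <- function(nuclei, type, mat) {
  if (any(nuclei$type == type & nuclei$mat == mat)) return(nuclei)
  rbind(nuclei, data.frame(type = type, mat = mat, stringsAsFactors = FALSE))
}

#' Infer a heterokaryon genotype from derivative observations
#'
#' Implements the discrimination procedure for self-fertile
#' N. tetrasperma strains: `[T + N]` heterokaryons yield homokaryotic
#' conidial derivatives of both mating types, whereas `[Dp + Df]`
#' heterokaryons yield viable homokaryons only of the `Dp` nucleus's mating
#' type (a `Df` homokaryon is inviable).  The rule cascade:
#'
#' 1. Each self-sterile derivative's junction pattern is mapped to a nucleus
#'    type against the rearrangement's PCR panel: the full panel indicates
#'    `T`; the panel minus junction A indicates `Dp`; the empty set `N`; and
#'    junction A alone indicates a `[N + Df]` heterokaryotic derivative
#'    (an A-only homokaryon would carry an uncomplemented deficiency and
#'    could not be viable), hence a `Df` nucleus in the parent.
#' 2. The evident nuclei are assembled and the set completed so its junction
#'    union equals the heterokaryon's own pattern — in particular a `Df` is
#'    added when junction A is present in heterokaryon DNA but in no
#'    derivative's `T` pattern.
#' 3. A nucleus added this way takes the mating type absent (or evidenced)
#'    among the derivatives.
#' 4. If only one homokaryon class was observed, the unseen partner is
#'    called `Df` when junction A is in the heterokaryon pattern (else `N`),
#'    and when the evidence is weak — fewer than `n_min` derivatives, or a
#'    split that skewed sampling could explain
#'    ([balanced_split_probability()] at or above `alpha`) — the call is
#'    flagged with the unexcluded alternative.  A single informative
#'    derivative leaves the partner `"?"` (undetermined).
#' 5. Three evident nucleus types produce a triple-heterokaryon call.
#'
#' When no derivative has junction data the classifier falls back to the
#' mating-type split alone and marks the call `"mat-only evidence"`.
#'
#' @param obs An [observation_record()].
#' @param rearrangement The [rearrangement()] whose junctions were assayed.
#' @param n_min Minimum derivative count for an unflagged single-class call.
#' @param alpha Significance threshold on the skew probability.
#' @return An object of class `"genotype_call"`; `format()` renders it in
#'   the conventional bracket notation, e.g. `"[Df a + Dp A]"`.
#' @examples
#' eb4 <- rearrangement_preset("EB4")
#' obs <- observation_record("1E1", c("A", "B", "C"),
#'   data.frame(self_fertile = FALSE, mat = "A", junctions = "B,C")[rep(1, 25), ])
#' format(infer_heterokaryon_genotype(obs, eb4))
#' @export
infer_heterokaryon_genotype <- function(obs, rearrangement, n_min = 10,
                                        alpha = 0.05) {
  stopifnot(inherits(obs, "observation_record"),
            inherits(rearrangement, "rearrangement"))
  der <- obs$derivatives
  het <- obs$het_junctions
  if (!all(het %in% rearrangement$assay_junctions))
    stop("heterokaryon junctions outside the PCR panel of '",
         rearrangement$id, "'")
  flags <- character(0)

  ss <- der[!der$self_fertile & der$mat %in% c("A", "a"), , drop = FALSE]
  n_ss <- nrow(ss)
  skew_p <- balanced_split_probability(sum(ss$mat == "a"), sum(ss$mat == "A"))
  empty <- data.frame(type = character(0), mat = character(0),
                      stringsAsFactors = FALSE)

  if (n_ss == 0L)
    return(new_genotype_call(obs$strain_id, empty,
                             "no self-sterile derivatives: genotype not determined",
                             skew_p, 0L, 0L, n_min, alpha))

  info <- ss[!is.na(ss$junctions), , drop = FALSE]
  n_info <- nrow(info)
  nuclei <- empty

  if (n_info == 0L) {
    ## mating-type evidence only
    flags <- c(flags, "mat-only evidence")
    mats_seen <- unique(ss$mat)
    if (length(mats_seen) == 2L) {
      nuclei <- add_nucleus(nuclei, "T", "?")
      nuclei <- add_nucleus(nuclei, "N", "?")
      flags <- c(flags,
                 "[T + N] indicated; nucleus mating types unassigned")
    } else if (n_ss == 1L) {
      nuclei <- add_nucleus(nuclei, "?", mats_seen)
      nuclei <- add_nucleus(nuclei, "?", setdiff(c("a", "A"), mats_seen))
      flags <- c(flags, "single derivative: genotype undetermined")
    } else {
      other <- setdiff(c("a", "A"), mats_seen)
      nuclei <- add_nucleus(nuclei, "Dp", mats_seen)
      nuclei <- add_nucleus(nuclei, "Df", other)
      if (n_ss < n_min || skew_p >= alpha)
        flags <- c(flags, sprintf(
          "alternative %s not excluded (n=%d, skew p=%.3g)",
          format_nuclei(data.frame(type = c("T", "N"),
                                   mat = c(mats_seen, other))),
          n_ss, skew_p))
    }
    return(new_genotype_call(obs$strain_id, nuclei, flags, skew_p, n_ss,
                             0L, n_min, alpha))
  }

  ptype <- vapply(info$junctions, function(j)
    derivative_pattern_type(parse_junctions(j), rearrangement), "",
    USE.NAMES = FALSE)
  if (any(ptype == "unknown"))
    stop("uninterpretable derivative junction pattern for strain ",
         obs$strain_id)

  ## (1)-(2): evident homokaryon classes, then Df evidence from A-only
  ## ([N + Df]) derivatives
  for (i in which(ptype %in% c("T", "Dp", "N")))
    nuclei <- add_nucleus(nuclei, ptype[i], info$mat[i])
  df_rows <- which(ptype == "Df_het")
  for (i in df_rows) {
    nuclei <- add_nucleus(nuclei, "N", info$mat[i])
    nuclei <- add_nucleus(nuclei, "Df", info$mat[i])
  }

  ## junction completion against the heterokaryon's own pattern
  junc_union <- function(nuc) sort(unique(unlist(
    lapply(nuc$type, nucleus_type_junctions, rearrangement = rearrangement))))
  missing <- setdiff(het, junc_union(nuclei))
  if (length(missing)) {
    absent_mat <- setdiff(c("a", "A"), unique(nuclei$mat))
    fill_mat <- if (length(absent_mat) == 1L) absent_mat else "?"
    panel <- rearrangement$assay_junctions
    if (setequal(missing, panel)) {
      nuclei <- add_nucleus(nuclei, "T", fill_mat)
    } else if (length(setdiff(panel, "A")) &&
               setequal(missing, setdiff(panel, "A"))) {
      nuclei <- add_nucleus(nuclei, "Dp", fill_mat)
    } else if (setequal(missing, "A")) {
      nuclei <- add_nucleus(nuclei, "Df", fill_mat)
    } else {
      if ("A" %in% missing) nuclei <- add_nucleus(nuclei, "Df", fill_mat)
      nuclei <- add_nucleus(nuclei, "Dp", fill_mat)
    }
  }

  ## (4): partner completion when only one mating type is evidenced
  mats_present <- unique(nuclei$mat)
  if (!all(c("a", "A") %in% mats_present)) {
    other <- setdiff(c("a", "A"), mats_present)
    if (n_ss == 1L) {
      nuclei <- add_nucleus(nuclei, "?", other)
      flags <- c(flags,
                 "single derivative: second nucleus undetermined")
    } else {
      partner <- if ("A" %in% het) "Df" else "N"
      nuclei <- add_nucleus(nuclei, partner, other)
      single_class <- length(unique(paste(ptype, info$mat))) == 1L
      if (single_class && (n_ss < n_min || skew_p >= alpha)) {
        if (partner == "Df") {
          alt <- nuclei
          alt$type[alt$type == "Df" & alt$mat == other] <- "N"
          flags <- c(flags, sprintf(
            "alternative %s not excluded (n=%d, skew p=%.3g)",
            format_nuclei(alt), n_ss, skew_p))
        } else {
          flags <- c(flags, sprintf(
            "single derivative class observed (n=%d, skew p=%.3g): call provisional",
            n_ss, skew_p))
        }
      }
    }
  }

  rownames(nuclei) <- NULL
  new_genotype_call(obs$strain_id, nuclei, flags, skew_p, n_ss, n_info,
                    n_min, alpha)
}

#' Read / write observation tables
#'
#' Long-format TSV with columns `strain`, `het_junctions`, `derivative_id`,
#' `self_fertile` (0/1), `mat`, `junctions` (comma list, `"."` for none, `NA`
#' for not assayed).
#'
#' @param records A list of [observation_record()]s.
#' @param path File path.
#' @return `read_observations()` returns a named list of observation
#'   records; `write_observations()` returns `path` invisibly.
#' @export
write_observations <- function(records, path) {
  records <- as_object_list(records, "observation_record")
  rows <- lapply(records, function(r) {
    d <- r$derivatives
    data.frame(strain = r$strain_id,
               het_junctions = format_junctions(r$het_junctions),
               derivative_id = seq_len(nrow(d)),
               self_fertile = as.integer(d$self_fertile),
               mat = d$mat,
               junctions = d$junctions,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA",
                           colClasses = c(junctions = "character"))
  out <- lapply(split(tab, tab$strain), function(d) {
    observation_record(d$strain[1], parse_junctions(d$het_junctions[1]),
                       data.frame(self_fertile = d$self_fertile == 1,
                                  mat = d$mat, junctions = d$junctions,
                                  stringsAsFactors = FALSE))
  })
  out[unique(tab$strain)]
}

#' The packaged self-fertile strain table
#'
#' A transcription of the published table of 47 self-fertile strains from
#' the four introgressions: per strain the number of conidial derivatives
#' examined, how many were self-sterile, their mating-type split, and the
#' genotype indicated by PCR (`ND` where not determined).  Shipped as a
#' plain TSV under `extdata`.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return A `data.frame` with columns `serial`, `strain`, `rearrangement`,
#'   `conidial_derivatives`, `self_sterile`, `mat_a`, `mat_A`, `genotype`,
#'   `footnote`.
#' @export
read_strain_table <- function(path = system.file("extdata",
                                                 "table2_strains.tsv",
                                                 package = "octadkit")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  needed <- c("serial", "strain", "rearrangement", "conidial_derivatives",
              "self_sterile", "mat_a", "mat_A", "genotype")
  if (!all(needed %in% names(tab)))
    stop("malformed strain table: missing column(s) ",
         paste(setdiff(needed, names(tab)), collapse = ", "))
  bad <- which(is.na(tab$conidial_derivatives) | is.na(tab$self_sterile) |
               tab$self_sterile > tab$conidial_derivatives)
  if (length(bad))
    stop("malformed strain table row(s): serial ",
         paste(tab$serial[bad], collapse = ", "))
  tab
}

#' Aggregate a strain observation table
#'
#' Exact integer totals over a chosen subset of strain-table rows, plus the
#' fraction of derivatives that were self-fertile and a flag for rows whose
#' derivatives were all self-sterile.
#'
#' @param tab A strain table from [read_strain_table()].
#' @param rows Optional subset: serial numbers, a logical vector, or a
#'   predicate `function(row) -> logical`.
#' @return A list with `n_strains`, `total_derivatives`,
#'   `total_self_sterile`, `total_mat_a`, `total_mat_A`,
#'   `fraction_self_fertile`, and `all_self_sterile` (named per strain).
#' @examples
#' tab <- read_strain_table()
#' summarize_strain_table(tab, rows = c(35:37, 39:41, 43))$total_derivatives
#' @export
summarize_strain_table <- function(tab, rows = NULL) {
  if (is.null(rows)) {
    sel <- rep(TRUE, nrow(tab))
  } else if (is.function(rows)) {
    sel <- vapply(seq_len(nrow(tab)), function(i) isTRUE(rows(tab[i, ])), TRUE)
  } else if (is.logical(rows)) {
    stopifnot(length(rows) == nrow(tab))
    sel <- rows
  } else {
    sel <- tab$serial %in% rows
  }
  sub <- tab[sel, , drop = FALSE]
  td <- sum(sub$conidial_derivatives)
  ts <- sum(sub$self_sterile)
  list(n_strains = nrow(sub),
       total_derivatives = td,
       total_self_sterile = ts,
       total_mat_a = sum(sub$mat_a),
       total_mat_A = sum(sub$mat_A),
       fraction_self_fertile = if (td > 0) (td - ts) / td else NA_real_,
       all_self_sterile = stats::setNames(
         sub$conidial_derivatives > 0 &
           sub$self_sterile == sub$conidial_derivatives,
         sub$strain))
}
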