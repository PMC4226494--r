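#' @title File ingestion and emission
#' @description
#' Readers for the standard genotype-imputation formats (VCF with DS/GP
#' FORMAT fields via \pkg{vcfR}; MaCH/minimac-style dosage and
#' probability text files), phenotype/covariate tables, the recommended
#' post-imputation quality filter, and writers for simulator output.
#' Internally, dosages and probabilities are always minor-allele coded
#' (required by the Dirichlet model's MAF parameter); markers whose coded
#' allele is the major one are flipped on ingestion and the flip flag is
#' kept so effect directions can be reported for the original coding.
#' @name io-module
NULL

new_marker_record <- function(id, chrom = NA, pos = NA, a_coded = NA,
                              a_other = NA, probs = NULL, dosage = NULL,
                              rsq = NA_real_, samples = NULL,
                              flipped = FALSE, flagged = FALSE,
                              note = "") {
  structure(list(id = id, chrom = chrom, pos = pos, a_coded = a_coded,
                 a_other = a_other, probs = probs, dosage = dosage,
                 rsq = rsq, samples = samples, flipped = flipped,
                 flagged = flagged, note = note),
            class = "marker_record")
}

# Flip a record to minor-allele coding when the coded-allele frequency
# exceeds 0.5; records the flip for sign-correct reporting.
orient_minor <- function(rec) {
  d <- rec$dosage
  if (is.null(d) && !is.null(rec$probs)) d <- dosage_from_probs(rec$probs)
  if (is.null(d)) return(rec)
  if (mean(d, na.rm = TRUE) / 2 > 0.5) {
    rec$flipped <- TRUE
    if (!is.null(rec$dosage)) rec$dosage <- 2 - rec$dosage
    if (!is.null(rec$probs)) rec$probs <- rec$probs[, 3:1, drop = FALSE]
    tmp <- rec$a_coded; rec$a_coded <- rec$a_other; rec$a_other <- tmp
  }
  rec
}

parse_info_rsq <- function(info) {
  m <- regmatches(info, regexpr("(^|;)(R2|DR2|RSQ|INFO)=[0-9.eE+-]+", info))
  if (!length(m) || !nzchar(m)) return(NA_real_)
  as.numeric(sub(".*=", "", m))
}

#' Read imputed markers from a VCF file
#'
#' Extracts per-sample dosages (`DS`) or genotype probabilities (`GP`,
#' ordered as P(0), P(1), P(2) copies of the ALT allele) for every
#' marker. GP triples are renormalized when their sum deviates from 1 by
#' no more than rounding error (0.03), otherwise the marker is flagged
#' and skipped. Markers are converted
#' to minor-allele coding (probabilities reversed, dosage reflected)
#' with the flip recorded. The imputation quality is taken from the
#' INFO keys `R2`, `DR2`, `RSQ` or `INFO` when present.
#'
#' @param path VCF file (plain or bgzipped).
#' @param field `"GP"` or `"DS"`.
#' @return List of `marker_record` objects (flagged markers excluded;
#'   their ids are in attribute `"skipped"`).
#' @export
read_vcf <- function(path, field = c("GP", "DS")) {
  field <- match.arg(field)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-marker files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- vcf@gt[, 1L]
  has <- vapply(strsplit(fmt, ":"), function(x) field %in% x, logical(1))
  if (!all(has))
    stop("read_vcf: FORMAT field ", field, " missing for marker(s) ",
         paste(fix[!has, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = field)
  samples <- colnames(gt)
  records <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(gt))) {
    id <- unname(fix[i, "ID"])
    if (is.na(id)) id <- paste0(fix[i, "CHROM"], ":", fix[i, "POS"])
    rsq <- parse_info_rsq(vcf@fix[i, "INFO"])
    if (field == "DS") {
      d <- as.numeric(gt[i, ])
      rec <- new_marker_record(id, unname(fix[i, "CHROM"]),
                               as.integer(fix[i, "POS"]),
                               unname(fix[i, "ALT"]), unname(fix[i, "REF"]),
                               dosage = d, rsq = rsq, samples = samples)
    } else {
      gp <- do.call(rbind, lapply(strsplit(gt[i, ], ","), as.numeric))
      if (any(grepl("/|\\|", gt[i, ])) || ncol(gp) != 3L)
        stop("read_vcf: unsupported GP ploidy/shape at marker ", id)
      sums <- rowSums(gp)
      if (any(abs(sums - 1) > 0.03 + 1e-9)) {
        skipped <- c(skipped, id)
        next
      }
      gp <- gp / sums
      rec <- new_marker_record(id, unname(fix[i, "CHROM"]),
                               as.integer(fix[i, "POS"]),
                               unname(fix[i, "ALT"]), unname(fix[i, "REF"]),
                               probs = gp, dosage = dosage_from_probs(gp),
                               rsq = rsq, samples = samples)
    }
    records[[length(records) + 1L]] <- orient_minor(rec)
  }
  if (length(skipped))
    message("read_vcf: skipped ", length(skipped),
            " marker(s) with GP sums off by > 0.03: ",
            paste(skipped, collapse = ", "))
  attr(records, "skipped") <- skipped
  records
}

#' Read MaCH/minimac-style dosage files
#'
#' Whitespace-delimited layout: one row per sample, `ID ML_DOSE d1 d2
#' ...`. Marker names, alleles and Rsq come from the companion `.info`
#' table when supplied (columns `SNP`, `Al1`, `Al2`, `Rsq`).
#'
#' @param dose_path dosage file.
#' @param info_path optional `.info` file.
#' @return List of `marker_record` objects, minor-allele coded.
#' @export
read_mach_dose <- function(dose_path, info_path = NULL) {
  tab <- read.table(dose_path, header = FALSE, stringsAsFactors = FALSE)
  ids <- sub(".*->", "", tab[, 1L])
  dmat <- as.matrix(tab[, -(1:2), drop = FALSE])
  info <- if (!is.null(info_path))
    read.table(info_path, header = TRUE, stringsAsFactors = FALSE)
  else NULL
  lapply(seq_len(ncol(dmat)), function(j) {
    rec <- new_marker_record(
      id = if (!is.null(info)) info$SNP[j] else paste0("marker", j),
      a_coded = if (!is.null(info)) info$Al1[j] else NA,
      a_other = if (!is.null(info)) info$Al2[j] else NA,
      dosage = as.numeric(dmat[, j]),
      rsq = if (!is.null(info) && "Rsq" %in% names(info))
        as.numeric(info$Rsq[j]) else NA_real_,
      samples = ids)
    orient_minor(rec)
  })
}

#' Read MaCH-style probability files
#'
#' Layout: one row per sample, `ID ML_PROB` then per-marker probability
#' values — either pairs `(P(0 copies), P(1 copy))` with the third
#' implied as `1 - p0 - p1` (clipped at 0; implied values below -0.02
#' flag the marker), or full triples.
#'
#' @param prob_path probability file.
#' @param info_path optional `.info` file (see [read_mach_dose()]).
#' @param layout `"pairs"` (MaCH default) or `"triples"`.
#' @return List of `marker_record` objects, minor-allele coded.
#' @export
read_mach_prob <- function(prob_path, info_path = NULL,
                           layout = c("pairs", "triples")) {
  layout <- match.arg(layout)
  tab <- read.table(prob_path, header = FALSE, stringsAsFactors = FALSE)
  ids <- sub(".*->", "", tab[, 1L])
  pm <- as.matrix(tab[, -(1:2), drop = FALSE])
  k <- if (layout == "pairs") 2L else 3L
  if (ncol(pm) %% k != 0L)
    stop("read_mach_prob: column count not a multiple of ", k)
  n_mark <- ncol(pm) %/% k
  info <- if (!is.null(info_path))
    read.table(info_path, header = TRUE, stringsAsFactors = FALSE)
  else NULL
  lapply(seq_len(n_mark), function(j) {
    block <- pm[, (j - 1L) * k + seq_len(k), drop = FALSE]
    if (layout == "pairs") {
      p2 <- 1 - block[, 1L] - block[, 2L]
      flagged <- any(p2 < -0.02)
      probs <- cbind(block, pmax(p2, 0))
    } else {
      probs <- block
      flagged <- any(abs(rowSums(probs) - 1) > 0.02)
    }
    probs <- unname(probs / rowSums(probs))
    rec <- new_marker_record(
      id = if (!is.null(info)) info$SNP[j] else paste0("marker", j),
      a_coded = if (!is.null(info)) info$Al1[j] else NA,
      a_other = if (!is.null(info)) info$Al2[j] else NA,
      probs = probs, dosage = dosage_from_probs(probs),
      rsq = if (!is.null(info) && "Rsq" %in% names(info))
        as.numeric(info$Rsq[j]) else NA_real_,
      samples = ids, flagged = flagged,
      note = if (flagged) "implied probability below -0.02" else "")
    orient_minor(rec)
  })
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with a header; rows with missing trait or covariate
#' values are dropped (and counted in a message).
#'
#' @param path TSV file.
#' @param trait_col trait column name.
#' @param covar_cols character vector of covariate column names (or
#'   `NULL`).
#' @param id_col sample-ID column name (default: first column).
#' @return List with `ids`, `y`, `z` (matrix, possibly 0 columns).
#' @export
read_pheno <- function(path, trait_col, covar_cols = NULL, id_col = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (is.null(id_col)) id_col <- names(tab)[1L]
  need <- c(id_col, trait_col, covar_cols)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("read_pheno: missing column(s): ", paste(miss, collapse = ", "))
  keep <- complete.cases(tab[, c(trait_col, covar_cols), drop = FALSE])
  if (any(!keep))
    message("read_pheno: dropped ", sum(!keep),
            " sample(s) with missing trait/covariates")
  tab <- tab[keep, , drop = FALSE]
  z <- if (length(covar_cols))
    as.matrix(tab[, covar_cols, drop = FALSE])
  else matrix(numeric(0), nrow(tab), 0)
  list(ids = as.character(tab[[id_col]]), y = as.numeric(tab[[trait_col]]),
       z = z)
}

#' Post-imputation quality filter
#'
#' Excludes markers whose estimated imputation quality is at or below
#' `rsq_min` (default 0.1, the recommended threshold below which the
#' quality estimate tends to be over- rather than under-estimated).
#' Markers without a quality estimate pass through untouched.
#'
#' @param records list of `marker_record` objects.
#' @param rsq_min exclusion threshold in `[0, 1]`.
#' @return Filtered list; attribute `"excluded"` carries the removed ids.
#' @export
apply_quality_filter <- function(records, rsq_min = 0.1) {
  stopifnot(rsq_min >= 0, rsq_min <= 1)
  bad <- vapply(records, function(r) !is.na(r$rsq) && r$rsq <= rsq_min,
                logical(1))
  if (any(bad))
    message("apply_quality_filter: excluded ", sum(bad),
            " marker(s) with Rsq <= ", rsq_min, ": ",
            paste(vapply(records[bad], `[[`, "", "id"), collapse = ", "))
  out <- records[!bad]
  attr(out, "excluded") <- vapply(records[bad], `[[`, "", "id")
  out
}

#' Association scan over a list of marker records
#'
#' Inner-joins each marker's samples with the phenotype table, runs the
#' requested test, and returns one row per marker.
#'
#' @param records list of `marker_record` objects.
#' @param pheno a [read_pheno()] result (fields `ids`, `y`, `z`).
#' @param method one of `"emlrt-prob"`, `"emlrt-dose"`, `"dosage"`,
#'   `"mixture"`.
#' @param rsq_default imputation quality used for `"emlrt-dose"` when a
#'   record carries none.
#' @param seed seed for the conditional draw in `"emlrt-dose"`.
#' @param settings EM settings, see [emlrt_prob_test()].
#' @return Data frame with columns `marker, n, maf, method, beta1_hat,
#'   lrs, df, pvalue, n_iter, converged, flipped`.
#' @export
emlrt_scan <- function(records, pheno, method = c("emlrt-prob",
                                                  "emlrt-dose", "dosage",
                                                  "mixture"),
                       rsq_default = NA, seed = 1L, settings = list()) {
  method <- match.arg(method)
  rows <- lapply(records, function(rec) {
    idx <- match(pheno$ids, rec$samples)
    keep <- !is.na(idx)
    if (sum(keep) < 10)
      stop("emlrt_scan: fewer than 10 samples overlap for marker ", rec$id)
    cohort <- cohort_data(pheno$y[keep],
                          if (ncol(pheno$z) > 0)
                            pheno$z[keep, , drop = FALSE] else NULL)
    sidx <- idx[keep]
    d <- rec$dosage[sidx]
    res <- switch(method,
      "dosage" = dosage_test(d, cohort),
      "emlrt-prob" = {
        if (is.null(rec$probs))
          stop("emlrt_scan: marker ", rec$id, " has no probabilities; ",
               "use method 'emlrt-dose' or 'dosage'")
        emlrt_prob_test(rec$probs[sidx, , drop = FALSE], cohort, settings)
      },
      "mixture" = {
        if (is.null(rec$probs))
          stop("emlrt_scan: marker ", rec$id, " has no probabilities")
        mixture_test(rec$probs[sidx, , drop = FALSE], cohort)
      },
      "emlrt-dose" = {
        rsq <- if (!is.na(rec$rsq)) rec$rsq else rsq_default
        emlrt_dose_test(d, cohort, rsq = rsq, maf = mean(d) / 2,
                        settings = settings, seed = seed)
      })
    sign <- if (isTRUE(rec$flipped)) -1 else 1
    data.frame(marker = rec$id, n = sum(keep), maf = mean(d) / 2,
               method = res$method, beta1_hat = sign * res$beta1_hat,
               lrs = res$lrs, df = res$df, pvalue = res$pvalue,
               n_iter = if (!is.null(res$diagnostics$n_iter))
                 res$diagnostics$n_iter else NA_integer_,
               converged = if (!is.null(res$diagnostics$converged))
                 res$diagnostics$converged else NA,
               flipped = isTRUE(rec$flipped))
  })
  do.call(rbind, rows)
}

#' Write simulated data to standard files
#'
#' Emits `<prefix>.probs.tsv`, `<prefix>.dose.tsv`, `<prefix>.geno.tsv`,
#' `<prefix>.pheno.tsv` and (optionally) `<prefix>.vcf` with DS and GP
#' FORMAT fields for the single synthetic marker.
#'
#' @param sim a [simulate_marker_data()] result.
#' @param prefix output path prefix.
#' @param vcf also write a VCF.
#' @param digits printed precision.
#' @return Invisibly, the vector of written paths.
#' @export
write_simulated_files <- function(sim, prefix, vcf = TRUE, digits = 6) {
  ids <- paste0("S", seq_along(sim$y))
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  paths <- character(0)
  wr <- function(df, suffix, col.names) {
    p <- paste0(prefix, suffix)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = col.names)
    paths <<- c(paths, p)
  }
  wr(data.frame(ID = ids, P0 = fmt(sim$probs[, 1]), P1 = fmt(sim$probs[, 2]),
                P2 = fmt(sim$probs[, 3])), ".probs.tsv", TRUE)
  wr(data.frame(ID = ids, DOSE = fmt(sim$dosage)), ".dose.tsv", TRUE)
  wr(data.frame(ID = ids, GENO = sim$g), ".geno.tsv", TRUE)
  pheno <- data.frame(ID = ids, TRAIT = fmt(sim$y))
  if (ncol(sim$z) > 0) {
    zz <- as.data.frame(apply(sim$z, 2, fmt))
    names(zz) <- paste0("COVAR", seq_len(ncol(sim$z)))
    pheno <- cbind(pheno, zz)
  }
  wr(pheno, ".pheno.tsv", TRUE)
  if (vcf) {
    p <- paste0(prefix, ".vcf")
    gp <- apply(sim$probs, 1, function(r)
      paste(formatC(r, digits = 4, format = "f"), collapse = ","))
    body <- paste(formatC(sim$dosage, digits = 4, format = "f"), gp,
                  sep = ":")
    lines <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
      paste0("##FORMAT=<ID=GP,Number=G,Type=Float,",
             "Description=\"Genotype probabilities\">"),
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", ids), collapse = "\t"),
      paste(c("1", "10000", "sim1", "A", "C", ".", "PASS",
              paste0("R2=", sim$marker$rsq), "DS:GP", body),
            collapse = "\t"))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
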