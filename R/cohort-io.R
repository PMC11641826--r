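#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped) into a [genotype_table()].
#' Multi-allelic records are split into one biallelic variant per alternate
#' allele, with genotypes recoded as the dosage of that allele. Missing
#' genotypes (`./.`) and half calls (e.g. `./1`) become `NA`. Records
#' without an rsID get the synthesized `"REF > ALT"` identifier.
#'
#' @param path path to a VCF file with GT fields.
#' @return A [genotype_table()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  gt_raw <- tryCatch(
    vcfR::extract.gt(vcf, element = "GT"),
    error = function(e) stop("VCF has no genotype (GT) data: ", path, call. = FALSE)
  )
  if (is.null(gt_raw) || ncol(gt_raw) == 0) {
    stop("VCF contains no samples: ", path)
  }
  samples <- colnames(gt_raw)

  chroms <- character(0); poss <- integer(0)
  refs <- character(0); alts <- character(0); ids <- character(0)
  call_cols <- list()

  for (i in seq_len(nrow(fix))) {
    alt_alleles <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gt_strings <- gt_raw[i, ]
    # allele index pairs; NA for missing or half calls
    parsed <- lapply(gt_strings, function(g) {
      if (is.na(g) || g == ".") return(c(NA_integer_, NA_integer_))
      parts <- strsplit(g, "[/|]")[[1]]
      if (length(parts) != 2 || any(parts == ".")) return(c(NA_integer_, NA_integer_))
      suppressWarnings(as.integer(parts))
    })
    for (k in seq_along(alt_alleles)) {
      dosage <- vapply(parsed, function(al) {
        if (anyNA(al)) NA_integer_ else sum(al == k)
      }, integer(1))
      chroms <- c(chroms, fix[i, "CHROM"])
      poss <- c(poss, as.integer(fix[i, "POS"]))
      refs <- c(refs, fix[i, "REF"])
      alts <- c(alts, alt_alleles[k])
      ids <- c(ids, fix[i, "ID"])
      call_cols[[length(call_cols) + 1L]] <- dosage
    }
  }
  calls <- do.call(cbind, call_cols)
  genotype_table(
    data.frame(chrom = chroms, pos = poss, ref = refs, alt = alts, id = ids,
               stringsAsFactors = FALSE),
    samples, calls
  )
}

#' Write a genotype table as VCF
#'
#' Emits a minimal VCF 4.2 file with one biallelic record per variant and
#' GT-only genotype fields, suitable for round-tripping through
#' [read_vcf()]. rsID-less variants (ids of the `"REF > ALT"` form) are
#' written with a `.` ID.
#'
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  v <- gt$variants
  id_out <- ifelse(v$id == paste(v$ref, ">", v$alt), ".", v$id)
  gt_str <- apply(gt$calls, 2, function(col) {
    out <- rep("./.", length(col))
    out[!is.na(col) & col == 0L] <- "0/0"
    out[!is.na(col) & col == 1L] <- "0/1"
    out[!is.na(col) & col == 2L] <- "1/1"
    out
  })
  if (is.null(dim(gt_str))) gt_str <- matrix(gt_str, nrow = length(gt$samples))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], id_out[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", "GT", gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a case/control phenotype table
#'
#' Reads a two-column delimited file `sample_id<TAB>status` using the
#' PLINK-style coding 1 = control, 2 = case.
#'
#' @param path path to the phenotype file (no header).
#' @return A named character vector mapping sample id to `"case"` or
#'   `"control"`, of class `phenotype_map`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character"),
    error = function(e) stop("no samples in phenotype file: ", path, call. = FALSE)
  )
  if (nrow(raw) == 0) stop("no samples in phenotype file: ", path)
  if (ncol(raw) < 2) stop("phenotype file must have two columns: sample_id, status")
  ids <- raw[[1]]; codes <- raw[[2]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  bad <- !codes %in% c("1", "2")
  if (any(bad)) {
    stop("invalid status code for sample(s) ", paste(ids[bad], collapse = ", "),
         " (expected 1=control, 2=case)")
  }
  phenotype_map(ids, ifelse(codes == "2", "case", "control"))
}

#' Construct a phenotype map
#'
#' @param samples character vector of sample identifiers.
#' @param status character vector, `"case"` or `"control"`, same length.
#' @return A named character vector of class `phenotype_map`.
#' @export
phenotype_map <- function(samples, status) {
  if (length(samples) != length(status)) stop("samples and status lengths differ")
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (!all(status %in% c("case", "control"))) stop("status must be 'case' or 'control'")
  if (!all(c("case", "control") %in% status)) {
    stop("both cases and controls are required")
  }
  structure(as.character(status), names = as.character(samples),
            class = "phenotype_map")
}

#' Per-variant case/control allele counts
#'
#' Builds the 2x2 allele-count table for one variant: alternate and
#' reference allele counts in cases and controls. Missing genotypes
#' contribute no alleles.
#'
#' @param gt a [genotype_table()].
#' @param ph a [phenotype_map()] covering all genotyped samples.
#' @param v variant column index.
#' @return An [allele_count_table()].
#' @export
allele_counts <- function(gt, ph, v) {
  stopifnot(inherits(gt, "genotype_table"))
  if (length(v) != 1 || v < 1 || v > nrow(gt$variants)) {
    stop("variant index out of range: ", v)
  }
  unknown <- setdiff(gt$samples, names(ph))
  if (length(unknown) > 0) {
    stop("samples without phenotype: ", paste(unknown, collapse = ", "))
  }
  status <- unclass(ph)[gt$samples]
  dos <- gt$calls[, v]
  case_dos <- dos[status == "case"]
  ctrl_dos <- dos[status == "control"]
  a <- sum(case_dos, na.rm = TRUE)
  b <- 2L * sum(!is.na(case_dos)) - a
  cc <- sum(ctrl_dos, na.rm = TRUE)
  d <- 2L * sum(!is.na(ctrl_dos)) - cc
  allele_count_table(a, b, cc, d)
}

#' Restrict a genotype table to extended gene loci
#'
#' Keeps variants falling within any supplied gene region extended by
#' `flank` bases on each side (default 5 kb upstream and downstream,
#' including the gene boundary). Coordinates are 1-based inclusive.
#'
#' @param gt a [genotype_table()].
#' @param regions data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @param flank flank size in bp added to both sides of each region.
#' @return A `genotype_table` with the retained variants, in their
#'   original order; each variant appears once even if several regions
#'   overlap it.
#' @export
extract_gene_loci <- function(gt, regions, flank = 5000) {
  stopifnot(inherits(gt, "genotype_table"))
  regions <- as.data.frame(regions)
  if (any(regions$start > regions$end)) stop("region start > end")
  keep <- rep(FALSE, nrow(gt$variants))
  for (r in seq_len(nrow(regions))) {
    keep <- keep | (gt$variants$chrom == regions$chrom[r] &
                      gt$variants$pos >= regions$start[r] - flank &
                      gt$variants$pos <= regions$end[r] + flank)
  }
  subset_variants(gt, keep)
}

#' Literature gene panel for opioid use disorder
#'
#' Returns the packaged panel of genes previously reported to harbor
#' variants associated with opioid use disorder (OPRM1, OPRD1, DRD2, BDNF,
#' APBB2, KCNG2, KCNC1, CNIH3, RGMA, DRD3, DRD4, NRXN3), with GRCh38 gene
#' coordinates, in the format [extract_gene_loci()] expects.
#'
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
gene_panel <- function() {
  path <- system.file("extdata", "gene_panel.tsv", package = "casexnet",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a gene-region table
#'
#' Reads a tab-delimited region file with columns `gene`, `chrom`,
#' `start`, `end` (1-based inclusive).
#'
#' @param path path to the TSV file.
#' @return data.frame of regions.
#' @export
read_gene_regions <- function(path) {
  if (!file.exists(path)) stop("gene-region file not found: ", path)
  regions <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  required <- c("gene", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    stop("gene-region file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(regions$start > regions$end)) stop("region start > end in ", path)
  regions
}
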