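# Genotype and metadata I/O under a fixed coordinate convention:
# all positions are 1-based and intervals are closed on both ends.

#' Create a genomic interval
#'
#' Intervals use 1-based, fully inclusive coordinates, so a single base is
#' represented as `start == end` and has length 1.
#'
#' @param chrom Chromosome label (e.g. `"17"`).
#' @param start First base of the interval (1-based, inclusive).
#' @param end Last base of the interval (inclusive); must be `>= start`.
#' @return An object of class `genomic_interval`.
#' @examples
#' iv <- genomic_interval("17", 3596108, 3596806)
#' interval_length(iv)  # 699
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    stop("chrom, start and end must be scalars")
  if (is.na(start) || is.na(end) || start < 1)
    stop("interval positions must be >= 1")
  if (end < start)
    stop(sprintf("invalid interval: end (%s) < start (%s)", end, start))
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' Parse a region string like "17:3596108-3596806"
#'
#' @param x Region string `chrom:start-end` (1-based inclusive) or
#'   `chrom:pos` for a single base.
#' @return A `genomic_interval`.
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)(?:-([0-9]+))?$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse region string: ", x)
  end <- if (m[4] == "") m[3] else m[4]
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(end))
}

#' Length of a genomic interval in base pairs
#'
#' Under the 1-based inclusive convention the length is
#' `end - start + 1`.
#'
#' @param iv A `genomic_interval`.
#' @return Integer number of bases spanned.
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start + 1
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%s-%s (%d bp)\n",
              x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), interval_length(x)))
  invisible(x)
}

#' Construct a genotype matrix
#'
#' Container for unphased biallelic genotypes: a samples x variants matrix
#' of alt-allele dosages in `{0, 1, 2, NA}` plus a variant annotation table.
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2}` or `NA` for missing.
#' @param variants Data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, one row per column of `dosages`. Only biallelic SNVs (single
#'   character ref/alt, ref != alt) are accepted.
#' @param samples Character vector of unique sample identifiers (defaults
#'   to rownames of `dosages`).
#' @param n_skipped Count of records dropped on import (multiallelic or
#'   non-SNV), carried for logging.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `variants`, `samples` and attribute `n_skipped`.
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages),
                            n_skipped = 0L) {
  dosages <- as.matrix(dosages)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants table must have columns: ", paste(need, collapse = ", "))
  if (nrow(variants) != ncol(dosages))
    stop("variants rows (", nrow(variants), ") != dosage columns (",
         ncol(dosages), ")")
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  if (anyDuplicated(samples)) stop("duplicated sample IDs")
  if (length(samples) != nrow(dosages))
    stop("samples length != dosage rows")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L))
    stop("only single-character alleles (SNVs) are accepted")
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ")
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, need, drop = FALSE]
  rownames(variants) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- list(samples, variants$id)
  structure(list(dosages = dosages, variants = variants,
                 samples = as.character(samples)),
            class = "genotype_matrix", n_skipped = as.integer(n_skipped))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%d record(s) skipped on import)\n",
              length(x$samples), nrow(x$variants),
              attr(x, "n_skipped") %||% 0L))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read unphased genotypes from VCF or genotype TSV
#'
#' VCF input keeps only biallelic single-nucleotide records; multiallelic
#' or indel records are skipped and counted (reported via a message and the
#' `n_skipped` attribute). Genotypes are treated as unphased regardless of
#' the `/` or `|` separator. The TSV dialect is the one written by
#' [write_genotypes()]: `##variant=id,chrom,pos,ref,alt` header lines, then
#' a header row `sample_id` plus one column per variant holding allele
#' pairs such as `G/C` (`./.` for missing).
#'
#' @param path File path.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @param region Optional `genomic_interval`; variants whose position lies
#'   inside it (inclusive on both ends) are kept.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           region = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  gm <- if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_tsv(path)
  if (!is.null(region)) {
    stopifnot(inherits(region, "genomic_interval"))
    keep <- gm$variants$chrom == region$chrom &
      gm$variants$pos >= region$start & gm$variants$pos <= region$end
    if (!any(keep)) warning("no variants in region ", region$chrom, ":",
                            region$start, "-", region$end)
    gm <- genotype_matrix(gm$dosages[, keep, drop = FALSE],
                          gm$variants[keep, , drop = FALSE],
                          gm$samples, attr(gm, "n_skipped"))
  }
  gm
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", path)
  snv <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  n_skipped <- sum(!snv)
  if (n_skipped > 0)
    message(n_skipped, " non-biallelic-SNV record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snv, , drop = FALSE]
  fix <- fix[snv, , drop = FALSE]
  # count "1" alleles; phased or unphased separators both accepted
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  })
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  genotype_matrix(
    t(dos),
    data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS), id = ids,
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    samples = colnames(gt), n_skipped = n_skipped)
}

read_genotypes_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^##variant=", lines, value = TRUE)
  if (length(meta) == 0L)
    stop("genotype TSV lacks ##variant= header lines: ", path)
  vparts <- strsplit(sub("^##variant=", "", meta), ",")
  bad <- which(lengths(vparts) != 5L)
  if (length(bad))
    stop("malformed ##variant line ", bad[1], " in ", path)
  variants <- data.frame(
    id = vapply(vparts, `[`, "", 1L),
    chrom = vapply(vparts, `[`, "", 2L),
    pos = as.numeric(vapply(vparts, `[`, "", 3L)),
    ref = vapply(vparts, `[`, "", 4L),
    alt = vapply(vparts, `[`, "", 5L),
    stringsAsFactors = FALSE)
  body <- lines[!grepl("^##", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, colClasses = "character")
  if (names(tab)[1] != "sample_id")
    stop("first TSV column must be sample_id")
  miss <- setdiff(variants$id, names(tab))
  if (length(miss)) stop("TSV missing genotype columns: ",
                         paste(miss, collapse = ", "))
  dos <- matrix(NA_real_, nrow(tab), nrow(variants),
                dimnames = list(tab$sample_id, variants$id))
  for (j in seq_len(nrow(variants))) {
    pairs <- strsplit(tab[[variants$id[j]]], "/", fixed = TRUE)
    dos[, j] <- vapply(pairs, function(al) {
      if (length(al) != 2L || any(al == "."))
        return(NA_real_)
      ok <- al %in% c(variants$ref[j], variants$alt[j])
      if (!all(ok)) stop("allele not in {ref, alt} for ", variants$id[j],
                         ": ", paste(al, collapse = "/"))
      sum(al == variants$alt[j])
    }, numeric(1))
  }
  genotype_matrix(dos, variants, samples = tab$sample_id)
}

#' Write a genotype matrix to VCF or genotype TSV
#'
#' Inverse of [read_genotypes()]: `read_genotypes(write_genotypes(x))`
#' reproduces the dosages exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param format `"vcf"` or `"tsv"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("auto", "vcf", "tsv")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  v <- gm$variants
  if (format == "vcf") {
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    lines <- c(
      "##fileformat=VCFv4.2",
      "##source=hapbiva",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", gm$samples), collapse = "\t"))
    for (j in seq_len(nrow(v))) {
      gts <- ifelse(is.na(gm$dosages[, j]), "./.",
                    gt_code[as.character(gm$dosages[, j])])
      lines <- c(lines, paste(c(v$chrom[j],
                                format(v$pos[j], scientific = FALSE),
                                v$id[j], v$ref[j], v$alt[j], ".", "PASS",
                                ".", "GT", gts), collapse = "\t"))
    }
  } else {
    meta <- sprintf("##variant=%s,%s,%s,%s,%s", v$id, v$chrom,
                    format(v$pos, scientific = FALSE), v$ref, v$alt)
    body <- vapply(seq_along(gm$samples), function(i) {
      g <- vapply(seq_len(nrow(v)), function(j) {
        d <- gm$dosages[i, j]
        if (is.na(d)) return("./.")
        paste(c(rep(v$ref[j], 2 - d), rep(v$alt[j], d)), collapse = "/")
      }, character(1))
      paste(c(gm$samples[i], g), collapse = "\t")
    }, character(1))
    lines <- c(meta, paste(c("sample_id", v$id), collapse = "\t"), body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Expects a CSV with at least `id` and `sex` columns; recognised numeric
#' columns are coerced, with unparseable entries set to missing under a
#' warning. Sex must be coded `M`/`F`.
#'
#' @param path CSV path.
#' @return Data frame of class `subject_table`, one row per subject.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  mandatory <- c("id", "sex")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("subject table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  dup <- df$id[duplicated(df$id)]
  if (length(dup))
    stop("duplicated subject ID(s): ", paste(unique(dup), collapse = ", "))
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be coded M or F")
  num_cols <- intersect(
    c("age", "height_cm", "weight_kg", "arm_circ_cm", "waist_circ_cm",
      "calf_circ_cm", "R_ohm", "Xc_ohm", "capsaicin_threshold",
      "prop_score"), names(df))
  for (cl in num_cols) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & raw != "" & is.na(val)
    if (any(bad))
      warning(sum(bad), " unparseable value(s) in column '", cl,
              "' set to missing")
    df[[cl]] <- val
  }
  class(df) <- c("subject_table", "data.frame")
  df
}

#' Write a subject metadata table
#'
#' @param subjects Data frame as returned by [read_subjects()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(as.data.frame(subjects), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
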