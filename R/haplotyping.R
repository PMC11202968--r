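# Named block haplotypes and rule-based diplotype calling from unphased
# genotypes under a same-phase assumption: a call is the unique unordered
# pair of defined haplotypes whose allele union reproduces the observed
# genotype at every block-defining site.

#' Define the haplotypes of one block
#'
#' @param block_name Block label, e.g. `"H1"`.
#' @param states Data frame: one row per tag SNP with columns `id`, `pos`
#'   (optional), and one column per haplotype label holding the allele
#'   character carried by that haplotype.
#' @param labels Haplotype label columns of `states`; default = every
#'   column after `id`/`pos`/`chrom`.
#' @return Object of class `haplotype_block`.
#' @export
haplotype_block <- function(block_name, states, labels = NULL) {
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  if (!"id" %in% names(states)) stop("states needs an 'id' column")
  if (is.null(labels))
    labels <- setdiff(names(states), c("id", "pos", "chrom"))
  if (length(labels) < 2L) stop("need at least two haplotype labels")
  if (anyDuplicated(labels)) stop("haplotype labels must be unique")
  for (l in labels) {
    if (any(is.na(states[[l]]) | nchar(states[[l]]) != 1L))
      stop("haplotype '", l, "' must give one allele per tag SNP")
  }
  structure(list(block_name = block_name, snp_ids = states$id,
                 states = states, labels = labels),
            class = "haplotype_block")
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("<haplotype_block> %s: %d tag SNPs, haplotypes {%s}\n",
              x$block_name, length(x$snp_ids),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Default block definitions for the TRPV1 H1/H2 haplotype blocks
#'
#' Allele states of the three H1 haplotypes (five tag SNPs in the 5'UTR
#' region) and two H2 haplotypes (three intronic tag SNPs), positive
#' strand, GRCh38 coordinates. The exonic variant rs877610 maps within the
#' H2 region but is not in linkage with the block and is excluded from
#' calling.
#'
#' @return Named list of two [haplotype_block()] objects, `H1` and `H2`.
#' @export
default_blocks <- function() {
  h1 <- haplotype_block("H1", data.frame(
    id = c("rs10491215", "rs73303323", "rs73303325", "rs7211511",
           "rs7211517"),
    chrom = "17",
    pos = c(3596159, 3596281, 3596443, 3596744, 3596752),
    a = c("G", "T", "C", "C", "C"),
    b = c("C", "C", "T", "T", "G"),
    c = c("C", "C", "G", "T", "G"),
    stringsAsFactors = FALSE))
  h2 <- haplotype_block("H2", data.frame(
    id = c("rs224548", "rs224549", "rs224550"),
    chrom = "17",
    pos = c(3572073, 3572111, 3572270),
    a = c("G", "T", "T"),
    b = c("T", "C", "C"),
    stringsAsFactors = FALSE))
  list(H1 = h1, H2 = h2)
}

#' Call the diplotype of one subject at one block
#'
#' The genotype at each tag SNP is an unordered allele pair; the call is
#' the unordered pair of defined haplotypes whose allele union matches the
#' observed pair at every site (the same-phase assumption: recombinant,
#' undefined haplotypes are excluded by construction). If no defined pair
#' fits, the call is `INCONSISTENT`; if more than one fits, or any tag SNP
#' genotype is missing, it is `AMBIGUOUS` (candidates listed) — ambiguous
#' genotypes are never frequency-guessed.
#'
#' @param genotypes Named character vector, tag SNP id -> allele pair like
#'   `"G/C"` (order irrelevant; `NA` or `"./."` = missing).
#' @param block A [haplotype_block()].
#' @return List of class `diplotype_call`: `block_name`, `pair` (sorted
#'   two-character label string such as `"ab"`, or `"AMBIGUOUS"` /
#'   `"INCONSISTENT"`), and `candidates`.
#' @export
call_diplotype <- function(genotypes, block) {
  stopifnot(inherits(block, "haplotype_block"))
  missing_ids <- setdiff(block$snp_ids, names(genotypes))
  if (length(missing_ids))
    stop("tag SNP(s) absent from genotype input: ",
         paste(missing_ids, collapse = ", "))
  g <- genotypes[block$snp_ids]
  obs <- lapply(g, function(x) {
    if (is.na(x) || x %in% c("./.", ".")) return(NULL)
    al <- sort(strsplit(x, "/", fixed = TRUE)[[1]])
    if (length(al) != 2L) stop("genotype must be an allele pair: ", x)
    al
  })
  if (any(vapply(obs, is.null, logical(1))))
    return(structure(list(block_name = block$block_name,
                          pair = "AMBIGUOUS", candidates = character(0)),
                     class = "diplotype_call"))
  labs <- block$labels
  fits <- character(0)
  for (i in seq_along(labs)) {
    for (j in i:length(labs)) {
      ok <- all(vapply(seq_along(block$snp_ids), function(k) {
        expected <- sort(c(block$states[[labs[i]]][k],
                           block$states[[labs[j]]][k]))
        identical(expected, obs[[k]])
      }, logical(1)))
      if (ok) fits <- c(fits, paste0(sort(c(labs[i], labs[j])),
                                     collapse = ""))
    }
  }
  fits <- unique(fits)
  pair <- if (length(fits) == 1L) fits else
    if (length(fits) == 0L) "INCONSISTENT" else "AMBIGUOUS"
  structure(list(block_name = block$block_name, pair = pair,
                 candidates = fits),
            class = "diplotype_call")
}

#' Call diplotypes for every sample of a genotype matrix
#'
#' Dosages are translated back to allele pairs through the matrix's
#' ref/alt annotation, then each sample is called with
#' [call_diplotype()].
#'
#' @param gm A [genotype_matrix()] containing all tag SNPs of `block`.
#' @param block A [haplotype_block()].
#' @return Data frame: `subject_id`, `block`, `pair`.
#' @export
call_diplotypes <- function(gm, block) {
  stopifnot(inherits(gm, "genotype_matrix"))
  missing_ids <- setdiff(block$snp_ids, gm$variants$id)
  if (length(missing_ids))
    stop("tag SNP(s) absent from genotype matrix: ",
         paste(missing_ids, collapse = ", "))
  idx <- match(block$snp_ids, gm$variants$id)
  pairs <- vapply(seq_along(gm$samples), function(i) {
    g <- vapply(idx, function(j) {
      d <- gm$dosages[i, j]
      if (is.na(d)) return(NA_character_)
      r <- gm$variants$ref[j]; a <- gm$variants$alt[j]
      paste(c(rep(r, 2 - d), rep(a, d)), collapse = "/")
    }, character(1))
    names(g) <- block$snp_ids
    call_diplotype(g, block)$pair
  }, character(1))
  data.frame(subject_id = gm$samples, block = block$block_name,
             pair = pairs, stringsAsFactors = FALSE)
}

#' Group resolved diplotype calls for association analysis
#'
#' Schemes: `raw` keeps the called pairs; `merge_c_into_b` relabels the
#' rare `c` haplotype as `b` before pairing (so `bc -> bb`, `ac -> ab`);
#' `carrier_vs_aa` collapses to the binary contrast `aa` vs `b-carrier`
#' (any pair containing `b` — after `c` is merged into `b`).
#'
#' @param pairs Character vector of resolved calls (e.g. `"aa"`, `"ab"`);
#'   `AMBIGUOUS`/`INCONSISTENT` entries raise an error.
#' @param scheme `"raw"`, `"merge_c_into_b"` or `"carrier_vs_aa"`.
#' @return Character vector of group labels.
#' @export
group_diplotypes <- function(pairs,
                             scheme = c("raw", "merge_c_into_b",
                                        "carrier_vs_aa")) {
  scheme <- match.arg(scheme)
  if (any(pairs %in% c("AMBIGUOUS", "INCONSISTENT")))
    stop("unresolved calls present; exclude them before grouping")
  merge_c <- function(p) {
    vapply(strsplit(p, ""), function(h)
      paste(sort(ifelse(h == "c", "b", h)), collapse = ""), character(1))
  }
  switch(scheme,
         raw = pairs,
         merge_c_into_b = merge_c(pairs),
         carrier_vs_aa = ifelse(grepl("b", merge_c(pairs)),
                                "b-carrier", "aa"))
}

#' Count copies of one haplotype in diplotype calls
#'
#' Additive genotype coding for regression: number of copies (0/1/2) of
#' `hap` in each resolved call, with `merge_c_into_b` applied first when
#' requested.
#'
#' @param pairs Resolved diplotype calls.
#' @param hap Haplotype label counted (default `"b"`).
#' @param merge_c Merge `c` into `b` first (default TRUE).
#' @return Integer vector of copy counts.
#' @export
haplotype_copies <- function(pairs, hap = "b", merge_c = TRUE) {
  if (merge_c) pairs <- group_diplotypes(pairs, "merge_c_into_b")
  vapply(strsplit(pairs, ""), function(h) sum(h == hap), integer(1))
}

#' Write diplotype calls as TSV
#'
#' @param calls Data frame with columns `subject_id` and one column per
#'   block (e.g. as assembled from [call_diplotypes()] results).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diplotypes <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
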