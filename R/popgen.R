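# Screening statistics for biallelic variant panels: allele frequencies,
# two-group Fst, two-locus LD with EM haplotype-frequency estimation,
# contiguous-run LD-block detection, and Tajima's D.
#
# Missing-data policy: per-site complete observations for MAF and Fst,
# pairwise-complete genotypes for LD.

alt_freq <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) return(NA_real_)
  sum(d) / (2 * length(d))
}

#' Minor allele frequency at one site
#'
#' @param dosages Alt-allele dosages (0/1/2, NA = missing) at one site.
#' @return `min(p, 1 - p)` of the alt-allele frequency over non-missing
#'   alleles; always in `[0, 0.5]`.
#' @export
compute_maf <- function(dosages) {
  p <- alt_freq(dosages)
  if (is.na(p)) stop("all genotypes missing: frequency undefined")
  min(p, 1 - p)
}

#' Two-group Fst at one site
#'
#' Two estimators of the fixation index between exactly two groups:
#' `weir_cockerham` (the variance-components estimator of standard
#' genotype-based tools, default) and `hudson` (the frequency-based
#' `1 - Hw/Hb`, which is exactly 0 for identical frequencies and exactly 1
#' for a fixed difference). Negative Weir-Cockerham estimates are reported
#' as computed, with `negative = TRUE`; downstream classification uses the
#' conventional descriptive thresholds (0.15 moderately high, 0.25 high).
#'
#' @param dosages Alt-allele dosages at one site.
#' @param group_labels Vector with exactly two distinct labels, aligned
#'   with `dosages`.
#' @param estimator `"weir_cockerham"` or `"hudson"`.
#' @return List of class `fst_result`: `fst`, `estimator`, per-group alt
#'   frequencies `subpop_freqs`, per-group non-missing allele counts
#'   `subpop_sizes`, and `negative` flag.
#' @export
compute_fst <- function(dosages,
                        group_labels,
                        estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  stopifnot(length(dosages) == length(group_labels))
  groups <- unique(group_labels[!is.na(group_labels)])
  if (length(groups) != 2L) stop("exactly two groups required")
  dd <- split(dosages, factor(group_labels, levels = groups))
  dd <- lapply(dd, function(x) x[!is.na(x)])
  n_dip <- vapply(dd, length, integer(1))
  if (any(n_dip == 0L))
    stop("a group is entirely missing at this site: Fst undefined")
  p <- vapply(dd, function(x) sum(x) / (2 * length(x)), numeric(1))
  if (estimator == "hudson") {
    hw <- p[1] * (1 - p[1]) + p[2] * (1 - p[2])
    hb <- p[1] * (1 - p[2]) + p[2] * (1 - p[1])
    fst <- if (hb == 0) NA_real_ else 1 - hw / hb
  } else {
    # Weir & Cockerham (1984) single-locus, two-allele theta-hat with
    # heterozygosity term; r populations (here r = 2).
    r <- 2
    h <- vapply(dd, function(x) mean(x == 1), numeric(1))
    nbar <- mean(n_dip)
    nc <- (r * nbar - sum(n_dip^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_dip * p) / (r * nbar)
    s2 <- sum(n_dip * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_dip * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    fst <- if ((a + b + cc) == 0) NA_real_ else a / (a + b + cc)
  }
  structure(list(fst = unname(fst), estimator = estimator,
                 subpop_freqs = p, subpop_sizes = 2 * n_dip,
                 negative = isTRUE(!is.na(fst) && fst < 0)),
            class = "fst_result")
}

#' Classify an Fst value against descriptive thresholds
#'
#' @param fst Fst value(s).
#' @param moderate,high Thresholds (defaults 0.15 and 0.25).
#' @return Character vector: `"low"`, `"moderately_high"` or `"high"`.
#' @export
classify_fst <- function(fst, moderate = 0.15, high = 0.25) {
  ifelse(is.na(fst), NA_character_,
         ifelse(fst > high, "high",
                ifelse(fst > moderate, "moderately_high", "low")))
}

# EM over the double-heterozygote phase ambiguity for two biallelic loci.
# Haplotypes indexed by (allele at a, allele at b) with 1 = alt.
em_haplotype_freq <- function(da, db, tol = 1e-12, max_iter = 1000L) {
  ok <- !is.na(da) & !is.na(db)
  da <- da[ok]; db <- db[ok]
  n <- length(da)
  if (n < 2L) stop("need >= 2 complete double genotypes")
  pa <- sum(da) / (2 * n)
  pb <- sum(db) / (2 * n)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("monomorphic site: LD undefined")
  # fixed haplotype contributions from unambiguous genotypes
  n_dh <- sum(da == 1 & db == 1)
  base <- c(h11 = 0, h10 = 0, h01 = 0, h00 = 0)
  for (i in seq_len(n)) {
    if (da[i] == 1 && db[i] == 1) next
    # each locus contributes alleles independently when at most one is het
    a_alleles <- c(rep(1, da[i]), rep(0, 2 - da[i]))
    b_alleles <- c(rep(1, db[i]), rep(0, 2 - db[i]))
    if (da[i] != 1) {            # a homozygous: pairing unambiguous
      base <- base + tabulate_haps(a_alleles, b_alleles)
    } else {                     # b homozygous, a het
      base <- base + tabulate_haps(a_alleles, b_alleles[c(1, 2)])
    }
  }
  h <- c(pa * pb, pa * (1 - pb), (1 - pa) * pb, (1 - pa) * (1 - pb))
  names(h) <- names(base)
  for (it in seq_len(max_iter)) {
    # E: split double heterozygotes between cis (11/00) and trans (10/01)
    cis_w <- h["h11"] * h["h00"]
    trans_w <- h["h10"] * h["h01"]
    pc <- if ((cis_w + trans_w) == 0) 0.5 else cis_w / (cis_w + trans_w)
    cnt <- base
    cnt["h11"] <- cnt["h11"] + n_dh * pc
    cnt["h00"] <- cnt["h00"] + n_dh * pc
    cnt["h10"] <- cnt["h10"] + n_dh * (1 - pc)
    cnt["h01"] <- cnt["h01"] + n_dh * (1 - pc)
    h_new <- cnt / (2 * n)
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  h
}

tabulate_haps <- function(a_alleles, b_alleles) {
  out <- c(h11 = 0, h10 = 0, h01 = 0, h00 = 0)
  for (k in 1:2) {
    key <- paste0("h", a_alleles[k], b_alleles[k])
    out[key] <- out[key] + 1
  }
  out
}

#' Pairwise linkage disequilibrium between two sites
#'
#' Estimates the alt-alt haplotype frequency by expectation-maximisation
#' over the double-heterozygote phase ambiguity, then derives
#' `D = p_ab - p_a p_b`, `D' = |D| / Dmax`, and
#' `r2 = D^2 / (p_a(1-p_a) p_b(1-p_b))`.
#'
#' @param dosages_a,dosages_b Alt-allele dosages at the two sites
#'   (pairwise-complete genotypes used).
#' @return List of class `ld_pair`: `p_a`, `p_b`, `p_ab`, `d`, `d_prime`,
#'   `r2`.
#' @export
compute_ld <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b))
  h <- em_haplotype_freq(dosages_a, dosages_b)
  p_a <- h["h11"] + h["h10"]
  p_b <- h["h11"] + h["h01"]
  d <- h["h11"] - p_a * p_b
  dmax <- if (d > 0) min(p_a * (1 - p_b), p_b * (1 - p_a)) else
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  d_prime <- if (dmax == 0) 0 else abs(d) / dmax
  r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  structure(list(p_a = unname(p_a), p_b = unname(p_b),
                 p_ab = unname(h["h11"]), d = unname(d),
                 d_prime = unname(min(d_prime, 1)),
                 r2 = unname(min(r2, 1))),
            class = "ld_pair")
}

#' Detect LD blocks as maximal runs of mutually linked variants
#'
#' A block is a maximal run of consecutive (position-sorted) variants in
#' which every within-run pair satisfies `d_prime > d_prime_min` and
#' `r2 > r2_min`. Singleton runs are not reported. Monomorphic variants
#' cannot belong to a block (their LD is undefined).
#'
#' @param gm A [genotype_matrix()] (variants position-sorted by
#'   construction).
#' @param d_prime_min,r2_min Thresholds (both default 0.75, strict
#'   inequality).
#' @return List of blocks; each has `ids`, `indices`, and `interval` (the
#'   spanned [genomic_interval()]).
#' @export
detect_blocks <- function(gm, d_prime_min = 0.75, r2_min = 0.75) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- ncol(gm$dosages)
  if (m < 2L) return(list())
  poly <- vapply(seq_len(m), function(j) {
    p <- alt_freq(gm$dosages[, j])
    !is.na(p) && p > 0 && p < 1
  }, logical(1))
  pair_ok <- function(i, j) {
    if (!poly[i] || !poly[j]) return(FALSE)
    ld <- tryCatch(compute_ld(gm$dosages[, i], gm$dosages[, j]),
                   error = function(e) NULL)
    !is.null(ld) && ld$d_prime > d_prime_min && ld$r2 > r2_min
  }
  blocks <- list()
  start <- 1L
  while (start < m) {
    end <- start
    # greedily extend while the candidate keeps all pairs above threshold
    while (end < m &&
           all(vapply(start:end, function(i) pair_ok(i, end + 1L),
                      logical(1)))) {
      end <- end + 1L
    }
    if (end > start) {
      idx <- start:end
      v <- gm$variants[idx, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- list(
        ids = v$id, indices = idx,
        interval = genomic_interval(v$chrom[1], min(v$pos), max(v$pos)))
    }
    start <- end + 1L
  }
  blocks
}

#' Write an LD-block report as a BED-like TSV
#'
#' Coordinates are 1-based inclusive; a header comment declares the
#' convention.
#'
#' @param blocks Result of [detect_blocks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_report <- function(blocks, path) {
  lines <- c("# LD block report; coordinates 1-based inclusive",
             "chrom\tstart\tend\tn_snps\tsnp_ids")
  for (b in blocks) {
    lines <- c(lines, paste(b$interval$chrom,
                            format(b$interval$start, scientific = FALSE),
                            format(b$interval$end, scientific = FALSE),
                            length(b$ids), paste(b$ids, collapse = ","),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Tajima constants for a sample of n sequences
#'
#' @param n Number of sequences (>= 2).
#' @return Named list `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D over a region
#'
#' Contrasts the mean number of pairwise differences (pi) with the
#' Watterson estimate from segregating sites. Haplotype input is an
#' n_sequences x n_sites 0/1 matrix; unphased diploid input (`input =
#' "genotype"`, a dosages matrix) contributes two sequences per individual
#' and computes pi from allele frequencies with the unbiased
#' pairwise-difference estimator `sum_j 2 k_j (n - k_j) / (n (n - 1))` — a
#' documented approximation that is exact for pi but cannot see phase.
#'
#' @param mat 0/1 haplotype matrix (sequences x sites) or 0/1/2 dosage
#'   matrix (individuals x sites).
#' @param input `"haplotype"` or `"genotype"`.
#' @return List of class `tajima`: `n`, `s`, `pi`, `theta_w`, the
#'   constants, `d` (NA with `defined = FALSE` when `s == 0`).
#' @export
tajimas_d <- function(mat, input = c("haplotype", "genotype")) {
  input <- match.arg(input)
  mat <- as.matrix(mat)
  if (input == "haplotype") {
    if (!all(mat %in% c(0, 1))) stop("haplotype matrix must be 0/1")
    n <- nrow(mat)
    k <- colSums(mat)
  } else {
    if (!all(mat %in% c(0, 1, 2))) stop("dosage matrix must be 0/1/2")
    n <- 2 * nrow(mat)
    k <- colSums(mat)
  }
  if (n < 4) stop("need at least 4 sequences")
  seg <- k > 0 & k < n
  s <- sum(seg)
  pi <- sum(2 * k[seg] * (n - k[seg])) / (n * (n - 1))
  cst <- tajima_constants(n)
  theta_w <- s / cst$a1
  if (s == 0) {
    d <- NA_real_; defined <- FALSE
  } else {
    vd <- cst$e1 * s + cst$e2 * s * (s - 1)
    if (vd <= 0) {
      d <- NA_real_; defined <- FALSE
    } else {
      d <- (pi - theta_w) / sqrt(vd)
      defined <- TRUE
    }
  }
  structure(c(list(n = n, s = s, pi = pi, theta_w = theta_w, d = d,
                   defined = defined), cst),
            class = "tajima")
}

#' @export
print.tajima <- function(x, ...) {
  cat(sprintf("<tajima> n = %d sequences, S = %d, pi = %.4f, theta_w = %.4f, D = %s\n",
              x$n, x$s, x$pi, x$theta_w,
              if (x$defined) sprintf("%.4f", x$d) else "undefined (S = 0)"))
  invisible(x)
}

#' Per-variant screening table: MAF and two-group Fst
#'
#' @param gm A [genotype_matrix()].
#' @param group_labels Optional two-group labels aligned with samples; when
#'   supplied, Fst columns are added.
#' @param estimator Fst estimator, see [compute_fst()].
#' @return Data frame, one row per variant: `id`, `chrom`, `pos`, `maf`,
#'   and when groups are given `fst` and `fst_class`.
#' @export
screen_variants <- function(gm, group_labels = NULL,
                            estimator = "weir_cockerham") {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- gm$variants[, c("id", "chrom", "pos")]
  out$maf <- vapply(seq_len(ncol(gm$dosages)), function(j)
    tryCatch(compute_maf(gm$dosages[, j]), error = function(e) NA_real_),
    numeric(1))
  if (!is.null(group_labels)) {
    out$fst <- vapply(seq_len(ncol(gm$dosages)), function(j)
      tryCatch(compute_fst(gm$dosages[, j], group_labels, estimator)$fst,
               error = function(e) NA_real_), numeric(1))
    out$fst_class <- classify_fst(out$fst)
  }
  out
}
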