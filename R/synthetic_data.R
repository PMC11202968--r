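# Synthetic-cohort generator: complete studies (genotypes with haplotype
# block structure, anthropometry, bioimpedance, perception phenotypes)
# with a ground-truth record, so every pipeline stage can be scored
# without external data.

# bivariate normal draws via Cholesky of the covariance
rbvnorm <- function(n, mean, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("covariance not positive-definite"))
  matrix(stats::rnorm(2 * n), n, 2) %*% ch +
    rep(mean, each = n)
}

bv_cov <- function(sds, corr) {
  cv <- corr * sds[1] * sds[2]
  matrix(c(sds[1]^2, cv, cv, sds[2]^2), 2, 2)
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the structure of a two-ancestry sensory/body-
#' composition study: 46 donors of sub-Saharan ancestry (34 M, 12 F) and
#' 46 Italian donors (21 M, 25 F); a three-haplotype block H1 at
#' intermediate frequency in the African-like group (b = 0.433, c =
#' 0.022) and absent in the European-like group, and a two-haplotype
#' block H2 (b = 0.444 vs 0); sex- and ancestry-structured bivariate
#' (Rsp, Xcsp) distributions with women carrying longer vectors and
#' narrower phase angles than men; a female-restricted additive shift per
#' H2-b copy that lengthens Zsp and lowers PhA; and ordinal capsaicin
#' thresholds concentrated below swab 6 with none above swab 8.
#'
#' @param groups Data frame `ancestry`, `sex`, `n` defining strata sizes.
#' @param blocks Named list of [haplotype_block()] definitions.
#' @param haplotype_freqs Per block, per ancestry named haplotype
#'   frequency vectors (must sum to 1).
#' @param biva_model Per `"ancestry_sex"` key: list `mean` (rsp, xcsp),
#'   `sds`, `corr`.
#' @param effect List `block`, `hap`, `sex`, `per_copy` (named rsp/xcsp
#'   shift in ohm*cm per haplotype copy, applied in the stated sex only),
#'   or NULL for no injected effect.
#' @param unlinked_snps Data frame `id, chrom, pos, ref, alt` plus one
#'   alt-frequency column per ancestry, for SNPs outside the blocks.
#' @param anthropometry Per sex: list of `mean`/`sd` for height, weight
#'   and the three circumferences (cm/kg).
#' @param genotyping_error Per-allele flip probability at block SNPs.
#' @param threshold_probs Length-10 probability vector over capsaicin
#'   threshold categories.
#' @param prop_mean,prop_sd Mean/SD of the PROP LMS score (truncated to
#'   0-100).
#' @param seed Integer seed fixing the whole stream.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(
    groups = data.frame(
      ancestry = c("SSA", "SSA", "ITA", "ITA"),
      sex = c("M", "F", "M", "F"),
      n = c(34L, 12L, 21L, 25L),
      stringsAsFactors = FALSE),
    blocks = default_blocks(),
    haplotype_freqs = list(
      H1 = list(SSA = c(a = 0.545, b = 0.433, c = 0.022),
                ITA = c(a = 1, b = 0, c = 0)),
      H2 = list(SSA = c(a = 0.556, b = 0.444),
                ITA = c(a = 1, b = 0))),
    biva_model = list(
      SSA_F = list(mean = c(rsp = 499.2, xcsp = 54.1),
                   sds = c(105, 11), corr = 0.75),
      ITA_F = list(mean = c(rsp = 405.4, xcsp = 40.3),
                   sds = c(70, 7), corr = 0.75),
      SSA_M = list(mean = c(rsp = 370, xcsp = 45),
                   sds = c(60, 7), corr = 0.70),
      ITA_M = list(mean = c(rsp = 350, xcsp = 42),
                   sds = c(55, 6.5), corr = 0.70)),
    effect = list(block = "H2", hap = "b", sex = "F",
                  per_copy = c(rsp = 50, xcsp = 1.5)),
    unlinked_snps = default_unlinked_snps(),
    anthropometry = list(
      M = list(height = c(176, 7), weight = c(75, 10), arm = c(30, 3),
               waist = c(85, 9), calf = c(37, 3)),
      F = list(height = c(163, 6), weight = c(60, 8), arm = c(27, 2.5),
               waist = c(75, 8), calf = c(35, 2.5))),
    genotyping_error = 0,
    threshold_probs = c(0.15, 0.20, 0.17, 0.15, 0.18, 0.08, 0.05, 0.02,
                        0, 0),
    prop_mean = 62, prop_sd = 16,
    seed = 1L) {
  for (bn in names(haplotype_freqs)) {
    for (anc in names(haplotype_freqs[[bn]])) {
      f <- haplotype_freqs[[bn]][[anc]]
      if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
        stop("haplotype frequencies for ", bn, "/", anc,
             " must be nonnegative and sum to 1")
      if (!all(names(f) %in% blocks[[bn]]$labels))
        stop("frequency labels not defined in block ", bn)
    }
  }
  if (genotyping_error < 0 || genotyping_error > 1)
    stop("genotyping_error must be in [0, 1]")
  if (length(threshold_probs) != 10L ||
      abs(sum(threshold_probs) - 1) > 1e-8)
    stop("threshold_probs must be 10 probabilities summing to 1")
  structure(list(groups = groups, blocks = blocks,
                 haplotype_freqs = haplotype_freqs,
                 biva_model = biva_model, effect = effect,
                 unlinked_snps = unlinked_snps,
                 anthropometry = anthropometry,
                 genotyping_error = genotyping_error,
                 threshold_probs = threshold_probs,
                 prop_mean = prop_mean, prop_sd = prop_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default unlinked SNP panel
#'
#' The six genotyped variants outside the H1/H2 blocks, with
#' ancestry-specific alt-allele frequencies (GRCh38 positions). Two of
#' them fall inside the H1 positional span, so on the full panel the
#' contiguous-run block rule splits H1 into sub-runs — the generator
#' accepts any replacement panel when an uninterrupted block is wanted.
#'
#' @return Data frame `id, chrom, pos, ref, alt, SSA, ITA`.
#' @export
default_unlinked_snps <- function() {
  data.frame(
    id = c("rs73303327", "rs161383", "rs114890125", "rs877610",
           "rs877611", "rs877612"),
    chrom = "17",
    pos = c(3596528, 3596724, 3596764, 3572196, 3572271, 3572292),
    ref = c("G", "A", "C", "C", "T", "C"),
    alt = c("A", "G", "T", "T", "C", "T"),
    SSA = c(0.378, 0.044, 0.043, 0.122, 0.122, 0.122),
    ITA = c(0.033, 0.189, 0.000, 0.011, 0.322, 0.011),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Haplotype pairs are drawn independently per block from the
#' ancestry-specific frequencies; block SNP alleles are emitted from the
#' haplotype states with optional per-allele flip error; unlinked SNPs
#' are drawn binomially at their ancestry frequencies; (R, Xc) are
#' produced by inverting the specific standardisation from the sampled
#' (Rsp, Xcsp) — including any injected female-restricted haplotype
#' effect — and the sampled anthropometry. Deterministic under the spec's
#' seed.
#'
#' Genotypes are returned both as an allele-pair table (the per-amplicon
#' representation used for diplotype calling — it can carry a third
#' allele such as the H1-c state at rs73303325) and as a biallelic
#' [genotype_matrix()] in which any third allele is recorded as missing.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_study`: `subjects` (subject table),
#'   `genotypes` (genotype_matrix), `genotype_pairs` (allele-pair data
#'   frame), `truth` (per-block haplotype pairs, b-copy counts, injected
#'   effect, spec).
#' @export
generate_study <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  g <- spec$groups
  n_total <- sum(g$n)
  ancestry <- rep(g$ancestry, g$n)
  sex <- rep(g$sex, g$n)
  ids <- sprintf("%s_%s_%02d", ancestry, sex,
                 unlist(lapply(g$n, seq_len)))

  # --- haplotype truth, per block ---
  hap_pairs <- list()
  for (bn in names(spec$blocks)) {
    freqs <- spec$haplotype_freqs[[bn]]
    h1 <- character(n_total); h2 <- character(n_total)
    for (anc in unique(ancestry)) {
      idx <- which(ancestry == anc)
      f <- freqs[[anc]]
      if (is.null(f)) stop("no haplotype frequencies for ancestry ", anc)
      h1[idx] <- sample(names(f), length(idx), replace = TRUE, prob = f)
      h2[idx] <- sample(names(f), length(idx), replace = TRUE, prob = f)
    }
    hap_pairs[[bn]] <- data.frame(
      hap1 = h1, hap2 = h2,
      pair = vapply(seq_len(n_total), function(i)
        paste(sort(c(h1[i], h2[i])), collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  }

  # --- anthropometry ---
  draw <- function(par, idx) {
    pmax(stats::rnorm(length(idx), par[1], par[2]), par[1] / 3)
  }
  height <- weight <- arm <- waist <- calf <- numeric(n_total)
  for (s in c("M", "F")) {
    idx <- which(sex == s)
    a <- spec$anthropometry[[s]]
    height[idx] <- draw(a$height, idx)
    weight[idx] <- draw(a$weight, idx)
    arm[idx] <- draw(a$arm, idx)
    waist[idx] <- draw(a$waist, idx)
    calf[idx] <- draw(a$calf, idx)
  }
  geom <- derive_geometry(height, weight, arm, waist, calf)

  # --- bioelectrical phenotypes ---
  rsp <- xcsp <- numeric(n_total)
  for (key in unique(paste(ancestry, sex, sep = "_"))) {
    idx <- which(paste(ancestry, sex, sep = "_") == key)
    m <- spec$biva_model[[key]]
    if (is.null(m)) stop("no biva model for stratum ", key)
    xy <- rbvnorm(length(idx), m$mean, bv_cov(m$sds, m$corr))
    rsp[idx] <- xy[, 1]; xcsp[idx] <- xy[, 2]
  }
  b_copies <- integer(n_total)
  if (!is.null(spec$effect)) {
    ef <- spec$effect
    hp <- hap_pairs[[ef$block]]
    b_copies <- (hp$hap1 == ef$hap) + (hp$hap2 == ef$hap)
    tgt <- sex == ef$sex
    rsp[tgt] <- rsp[tgt] + b_copies[tgt] * ef$per_copy["rsp"]
    xcsp[tgt] <- xcsp[tgt] + b_copies[tgt] * ef$per_copy["xcsp"]
  }
  rsp <- pmax(rsp, 50); xcsp <- pmax(xcsp, 5)
  k <- geom$a_factor / geom$l_factor
  r_ohm <- rsp / k
  xc_ohm <- xcsp / k

  # --- perception phenotypes ---
  thr <- sample(1:10, n_total, replace = TRUE,
                prob = spec$threshold_probs)
  prop <- pmin(pmax(stats::rnorm(n_total, spec$prop_mean, spec$prop_sd),
                    0), 100)

  # --- genotypes ---
  pair_tab <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  var_rows <- list()
  dos_cols <- list()
  for (bn in names(spec$blocks)) {
    blk <- spec$blocks[[bn]]
    hp <- hap_pairs[[bn]]
    for (k_snp in seq_along(blk$snp_ids)) {
      sid <- blk$snp_ids[k_snp]
      al1 <- vapply(hp$hap1, function(h) blk$states[[h]][k_snp],
                    character(1))
      al2 <- vapply(hp$hap2, function(h) blk$states[[h]][k_snp],
                    character(1))
      site_alleles <- unique(vapply(blk$labels, function(l)
        blk$states[[l]][k_snp], character(1)))
      if (spec$genotyping_error > 0) {
        flip <- function(x) {
          hit <- stats::runif(length(x)) < spec$genotyping_error
          x[hit] <- vapply(x[hit], function(a) {
            alt <- setdiff(site_alleles, a)
            if (length(alt) == 0) a else sample(alt, 1)
          }, character(1))
          x
        }
        al1 <- flip(al1); al2 <- flip(al2)
      }
      pair_tab[[sid]] <- paste(al1, al2, sep = "/")
      # biallelic encoding: ref = a-state, alt = b-state; third alleles
      # (e.g. the H1-c state) cannot be encoded and become missing
      ref <- blk$states[["a"]][k_snp]
      alt <- blk$states[[setdiff(blk$labels, "a")[1]]][k_snp]
      dos <- ifelse(al1 %in% c(ref, alt) & al2 %in% c(ref, alt),
                    (al1 == alt) + (al2 == alt), NA_real_)
      var_rows[[sid]] <- data.frame(
        chrom = blk$states$chrom[k_snp] %||% "17",
        pos = blk$states$pos[k_snp], id = sid, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
      dos_cols[[sid]] <- dos
    }
  }
  us <- spec$unlinked_snps
  if (!is.null(us) && nrow(us) > 0) {
    for (k_snp in seq_len(nrow(us))) {
      sid <- us$id[k_snp]
      dos <- numeric(n_total)
      for (anc in unique(ancestry)) {
        idx <- which(ancestry == anc)
        if (!anc %in% names(us))
          stop("unlinked_snps lacks a frequency column for ", anc)
        dos[idx] <- stats::rbinom(length(idx), 2, us[[anc]][k_snp])
      }
      pair_tab[[sid]] <- vapply(dos, function(d)
        paste(c(rep(us$ref[k_snp], 2 - d), rep(us$alt[k_snp], d)),
              collapse = "/"), character(1))
      var_rows[[sid]] <- data.frame(
        chrom = us$chrom[k_snp], pos = us$pos[k_snp], id = sid,
        ref = us$ref[k_snp], alt = us$alt[k_snp],
        stringsAsFactors = FALSE)
      dos_cols[[sid]] <- dos
    }
  }
  variants <- do.call(rbind, var_rows)
  dosages <- do.call(cbind, dos_cols)
  rownames(dosages) <- ids
  gm <- genotype_matrix(dosages, variants, samples = ids)

  age_mean <- ifelse(ancestry == "SSA", 32, 26)
  age_sd <- ifelse(ancestry == "SSA", 10.9, 4.9)
  subjects <- data.frame(
    id = ids, sex = sex, ancestry = ancestry,
    age = round(pmax(stats::rnorm(n_total, age_mean, age_sd), 18)),
    height_cm = round(height, 1), weight_kg = round(weight, 1),
    arm_circ_cm = round(arm, 1), waist_circ_cm = round(waist, 1),
    calf_circ_cm = round(calf, 1),
    R_ohm = round(r_ohm, 2), Xc_ohm = round(xc_ohm, 2),
    capsaicin_threshold = thr, prop_score = round(prop, 1),
    stringsAsFactors = FALSE)
  class(subjects) <- c("subject_table", "data.frame")

  structure(list(
    subjects = subjects, genotypes = gm, genotype_pairs = pair_tab,
    truth = list(hap_pairs = hap_pairs, b_copies = b_copies,
                 rsp_true = rsp, xcsp_true = xcsp,
                 effect = spec$effect, spec = spec)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d subjects, %d variants, blocks: %s\n",
              nrow(x$subjects), nrow(x$genotypes$variants),
              paste(names(x$truth$hap_pairs), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic study through the standard I/O layer
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @param format Genotype format, `"vcf"` or `"tsv"`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir, format = "vcf") {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- file.path(dir, paste0("genotypes.", format))
  subj <- file.path(dir, "subjects.csv")
  write_genotypes(study$genotypes, geno, format)
  write_subjects(study$subjects, subj)
  invisible(c(genotypes = geno, subjects = subj))
}

#' Generate a haplotype matrix under a stylised evolutionary scenario
#'
#' Scenario generators for the Tajima statistic: `singleton_excess`
#' assigns every derived allele to a single sequence (star-like genealogy,
#' negative D); `balanced_two_class` builds two haplotype classes at the
#' stated frequency differing at every site (intermediate-frequency
#' excess, positive D); `binomial_neutral` draws each site's derived count
#' from the neutral frequency spectrum (probability proportional to 1/i),
#' centring D on zero.
#'
#' @param n_sequences Number of haploid sequences (>= 4).
#' @param n_sites Number of segregating sites.
#' @param model One of `"singleton_excess"`, `"balanced_two_class"`,
#'   `"binomial_neutral"`.
#' @param seed Optional integer seed.
#' @param class_freq Frequency of the derived class for
#'   `balanced_two_class` (default 0.5).
#' @return 0/1 matrix, sequences in rows.
#' @export
generate_neutral_region <- function(n_sequences, n_sites,
                                    model = c("binomial_neutral",
                                              "singleton_excess",
                                              "balanced_two_class"),
                                    seed = NULL, class_freq = 0.5) {
  model <- match.arg(model)
  if (n_sequences < 4) stop("need n_sequences >= 4")
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0L, n_sequences, n_sites)
  if (model == "singleton_excess") {
    for (j in seq_len(n_sites))
      m[((j - 1) %% n_sequences) + 1L, j] <- 1L
  } else if (model == "balanced_two_class") {
    k <- round(class_freq * n_sequences)
    if (k < 1 || k >= n_sequences)
      stop("class_freq leaves an empty class")
    m[seq_len(k), ] <- 1L
  } else {
    i <- seq_len(n_sequences - 1)
    for (j in seq_len(n_sites)) {
      cnt <- sample(i, 1, prob = 1 / i)
      m[sample(n_sequences, cnt), j] <- 1L
    }
  }
  m
}
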